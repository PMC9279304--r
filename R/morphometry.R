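#' Axial bounds delimiting the pharyngeal airway
#'
#' Physical z coordinates (mm) of the superior and inferior borders of the
#' measured airway segment, standing in for the anatomical landmark planes
#' (palatal plane above, C2 below) that require manual landmarking.
#'
#' @param superior_z,inferior_z mm; `superior_z > inferior_z`.
#' @return a `cbct_airway_bounds` list.
#' @export
airway_bounds <- function(superior_z, inferior_z) {
  if (!(superior_z > inferior_z)) stopf("superior_z must exceed inferior_z")
  structure(list(superior_z = superior_z, inferior_z = inferior_z),
            class = "cbct_airway_bounds")
}

#' Extract the pharyngeal airway mask
#'
#' Selects airway-class voxels whose physical z lies within the bounds and
#' keeps the largest 26-connected component.
#'
#' @param labels a `cbct_labels`.
#' @param bounds an [airway_bounds()], or `NULL` for the full extent.
#' @param airway_class integer class code of the airway (default 5).
#' @return a logical 3D array (same grid as `labels`).
#' @export
extract_airway <- function(labels, bounds = NULL, airway_class = 5L) {
  stopifnot(inherits(labels, "cbct_labels"))
  mask <- labels$labels == airway_class
  if (!is.null(bounds)) {
    stopifnot(inherits(bounds, "cbct_airway_bounds"))
    z <- labels$origin[3] + (seq_len(dim(mask)[3]) - 1) * labels$spacing[3]
    keep <- z >= bounds$inferior_z & z <= bounds$superior_z
    mask[, , !keep] <- FALSE
  }
  if (!any(mask)) stopf("no airway in bounds")
  lab <- label_components3(as.logical(mask), dim(mask), 26L)
  n <- attr(lab, "n_components")
  if (n > 1L) {
    sizes <- tabulate(lab, n)
    mask <- array(lab == which.max(sizes), dim(mask))
  }
  mask
}

#' Airway volume in cubic centimetres
#' @param mask logical 3D array. @param spacing mm triple.
#' @return volume in cc (`count * sx*sy*sz / 1000`); 0 for an empty mask.
#' @export
airway_volume_cc <- function(mask, spacing) {
  sum(mask) * prod(spacing) / 1000
}

#' Per-axial-slice cross-sectional areas
#' @param mask logical 3D array (nonempty). @param spacing mm triple.
#' @return numeric vector, one area (mm^2) per axial slice (`sy*sx` per voxel).
#' @export
cross_sectional_areas <- function(mask, spacing) {
  if (!any(mask)) stopf("empty airway mask")
  apply(mask, 3L, sum) * spacing[1] * spacing[2]
}

#' Narrowest point of the airway
#'
#' The narrow slice is the axial slice with the minimal nonzero
#' cross-sectional area. The linear "narrowest point" measure is the extent of
#' that slice's largest in-plane (8-connected) component along the chosen
#' axis, by default anteroposterior (y); `measure = "min_extent"` takes the
#' smaller of the x/y extents instead.
#'
#' @param mask logical 3D array (nonempty). @param spacing mm triple.
#' @param measure `"ap_extent"` (default) or `"min_extent"`.
#' @param origin mm triple locating the first voxel centre.
#' @return list: `narrowest_mm`, `min_csa_mm2`, `narrow_slice_z` (mm),
#'   `narrow_slice_index`.
#' @export
narrowest_point <- function(mask, spacing, measure = c("ap_extent", "min_extent"),
                            origin = c(0, 0, 0)) {
  measure <- match.arg(measure)
  areas <- cross_sectional_areas(mask, spacing)
  nz <- which(areas > 0)
  k <- nz[which.min(areas[nz])]
  sl <- mask[, , k]
  lab <- label_components2(as.logical(sl), dim(sl), 8L)
  n <- attr(lab, "n_components")
  sizes <- tabulate(lab, n)
  comp <- matrix(lab == which.max(sizes), nrow = dim(sl)[1])
  ys <- which(apply(comp, 2L, any))
  xs <- which(apply(comp, 1L, any))
  ext_y <- (max(ys) - min(ys) + 1L) * spacing[2]
  ext_x <- (max(xs) - min(xs) + 1L) * spacing[1]
  narrow <- if (measure == "ap_extent") ext_y else min(ext_x, ext_y)
  list(narrowest_mm = narrow, min_csa_mm2 = areas[k],
       narrow_slice_z = origin[3] + (k - 1) * spacing[3],
       narrow_slice_index = k)
}

#' Full airway morphometry report
#'
#' @param labels a `cbct_labels` segmentation.
#' @param bounds optional [airway_bounds()].
#' @param airway_class airway class code.
#' @param measure linear narrow-point measure (see [narrowest_point()]).
#' @return a `cbct_airway_metrics` list: `volume_cc`, `min_csa_mm2`,
#'   `narrowest_mm`, `narrow_slice_z`, `areas_mm2`.
#' @export
airway_metrics <- function(labels, bounds = NULL, airway_class = 5L,
                           measure = "ap_extent") {
  mask <- extract_airway(labels, bounds, airway_class)
  np <- narrowest_point(mask, labels$spacing, measure, labels$origin)
  structure(list(volume_cc = airway_volume_cc(mask, labels$spacing),
                 min_csa_mm2 = np$min_csa_mm2,
                 narrowest_mm = np$narrowest_mm,
                 narrow_slice_z = np$narrow_slice_z,
                 areas_mm2 = cross_sectional_areas(mask, labels$spacing)),
            class = "cbct_airway_metrics")
}

#' @export
print.cbct_airway_metrics <- function(x, ...) {
  cat(sprintf("<airway metrics> volume %.2f cc | min CSA %.2f mm^2 | narrowest %.2f mm (z = %.1f mm)\n",
              x$volume_cc, x$min_csa_mm2, x$narrowest_mm, x$narrow_slice_z))
  invisible(x)
}

# ---- surface export -------------------------------------------------------

# Triangulated 0.5-level isosurface of a binary mask: the voxel-boundary
# (cuberille) surface. Every face between an inside and an outside voxel
# (after zero padding) yields two triangles with outward orientation, so the
# mesh is closed, its area is the exact voxel surface area, and its signed
# volume equals the voxel volume.
mask_to_mesh <- function(mask, spacing) {
  if (!any(mask)) stopf("empty mask")
  d <- dim(mask)
  p <- array(FALSE, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  verts <- list(); tris <- list(); nv <- 0L
  # for each axis and direction, exposed faces = inside & !shifted-neighbour
  shift <- function(a, axis, by) {
    idx <- seq_len(dim(a)[axis]) - by
    idx[idx < 1L | idx > dim(a)[axis]] <- NA
    out <- switch(axis, a[idx, , ], a[, idx, ], a[, , idx])
    out[is.na(out)] <- FALSE
    array(out, dim(a))
  }
  add_faces <- function(axis, dir) {
    faces <- p & !shift(p, axis, -dir) # neighbour on the `dir` side is outside
    w <- which(faces, arr.ind = TRUE)
    if (nrow(w) == 0L) return(invisible(NULL))
    # padded 1-based index q maps to original 0-based voxel centre q - 2;
    # face corners sit at centre +/- 0.5 voxel
    c0 <- w - 2
    offs <- .face_corner_offsets(axis, dir)
    v0 <- c0 + matrix(offs[1, ], nrow(w), 3, byrow = TRUE)
    v1 <- c0 + matrix(offs[2, ], nrow(w), 3, byrow = TRUE)
    v2 <- c0 + matrix(offs[3, ], nrow(w), 3, byrow = TRUE)
    v3 <- c0 + matrix(offs[4, ], nrow(w), 3, byrow = TRUE)
    vs <- rbind(v0, v1, v2, v3)
    n <- nrow(w)
    i0 <- nv + seq_len(n); i1 <- i0 + n; i2 <- i1 + n; i3 <- i2 + n
    verts[[length(verts) + 1L]] <<- vs
    tris[[length(tris) + 1L]] <<- rbind(cbind(i0, i1, i2), cbind(i0, i2, i3))
    nv <<- nv + 4L * n
  }
  for (axis in 1:3) for (dir in c(-1L, 1L)) add_faces(axis, dir)
  V <- do.call(rbind, verts)
  V <- sweep(V, 2L, spacing, "*") # mm coordinates
  list(vertices = V, triangles = do.call(rbind, tris))
}

# corner offsets (in voxel units, around the centre) of the face on side
# `dir` of axis `axis`, ordered counter-clockwise seen from outside
.face_corner_offsets <- function(axis, dir) {
  h <- 0.5
  base <- switch(axis,
    rbind(c(dir * h, -h, -h), c(dir * h, h, -h), c(dir * h, h, h), c(dir * h, -h, h)),
    rbind(c(-h, dir * h, -h), c(-h, dir * h, h), c(h, dir * h, h), c(h, dir * h, -h)),
    rbind(c(-h, -h, dir * h), c(h, -h, dir * h), c(h, h, dir * h), c(-h, h, dir * h)))
  if (dir < 0) base[4:1, ] else base
}

mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

mesh_signed_volume <- function(mesh) {
  a <- mesh$vertices[mesh$triangles[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$triangles[, 2], , drop = FALSE]
  c_ <- mesh$vertices[mesh$triangles[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Export a binary mask surface as binary STL
#'
#' Writes the closed, consistently oriented 0.5-level voxel-boundary surface
#' of the mask, with vertices in mm coordinates.
#'
#' @param mask logical 3D array (nonempty).
#' @param spacing mm triple.
#' @param path output `.stl` path.
#' @return `path`, invisibly; the mesh is attached as attribute `"mesh"`.
#' @export
export_stl <- function(mask, spacing, path) {
  mesh <- mask_to_mesh(mask, spacing)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  nt <- nrow(mesh$triangles)
  writeBin(as.integer(nt), con, size = 4, endian = "little")
  V <- mesh$vertices; Tm <- mesh$triangles
  for (t in seq_len(nt)) {
    a <- V[Tm[t, 1], ]; b <- V[Tm[t, 2], ]; c_ <- V[Tm[t, 3], ]
    u <- b - a; v <- c_ - a
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nl <- sqrt(sum(nrm^2)); if (nl > 0) nrm <- nrm / nl
    writeBin(as.numeric(c(nrm, a, b, c_)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  attr(path, "mesh") <- mesh
  invisible(path)
}
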