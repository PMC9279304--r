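#' Configuration of the synthetic CBCT head phantom
#'
#' The phantom emulates the intensity structure of a craniomaxillofacial CBCT:
#' exterior air (~ -1000), a soft-tissue head, an upper-skull shell and a
#' mandible arc of bone (~ 1200), two tooth rows (~ 1800), and a curved
#' vertical airway tube of z-varying caliber filled with air, plus Gaussian
#' acquisition noise. Labels are painted from exactly the same geometry, so
#' ground truth is consistent with the image by construction. The airway
#' radius profile (end radii, waist radius, waist position) is honoured
#' exactly; per-subject randomness (seed) jitters head shape, tube curvature
#' and structure placement, never the configured radii.
#'
#' @param shape voxel triple (default 64^3).
#' @param spacing mm triple (default 1 mm isotropic).
#' @param seed integer subject seed.
#' @param r_end,r_waist airway end/waist radii, mm.
#' @param waist_z waist position, mm (default mid-tube).
#' @param intensities named list of per-tissue means (air, soft, bone, teeth).
#' @param noise_sd additive Gaussian intensity noise sd.
#' @param include_epiglottis_flap if `TRUE`, a soft-tissue flap protrudes into
#'   the lumen below the waist, emulating an epiglottis-like confounder.
#' @param flap_fraction fraction of the local cross-section blocked by the flap.
#' @return a `cbct_phantom_config` list.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                           seed = 1L, r_end = 7, r_waist = 4,
                           waist_z = NULL,
                           intensities = list(air = -1000, soft = 40,
                                              bone = 1200, teeth = 1800),
                           noise_sd = 30,
                           include_epiglottis_flap = FALSE,
                           flap_fraction = 0.5) {
  stopifnot(r_waist > 0, r_end >= r_waist, noise_sd >= 0)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 seed = as.integer(seed), r_end = r_end, r_waist = r_waist,
                 waist_z = waist_z, intensities = intensities,
                 noise_sd = noise_sd,
                 include_epiglottis_flap = include_epiglottis_flap,
                 flap_fraction = flap_fraction),
            class = "cbct_phantom_config")
}

#' Generate a synthetic CBCT head phantom with ground-truth labels
#'
#' @param cfg a [phantom_config()].
#' @return list with `volume` (`cbct_volume`), `labels` (`cbct_labels`, 6
#'   classes) and `config`.
#' @export
generate_head_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "cbct_phantom_config"))
  d <- cfg$shape; sp <- cfg$spacing
  ext <- (d - 1) * sp
  # physical mm coordinate grids of voxel centres
  gx <- rep((seq_len(d[1]) - 1) * sp[1], times = d[2] * d[3])
  gy <- rep(rep((seq_len(d[2]) - 1) * sp[2], each = d[1]), times = d[3])
  gz <- rep((seq_len(d[3]) - 1) * sp[3], each = d[1] * d[2])
  ctr <- ext / 2

  with_seed(cfg$seed, {
    jit <- runif(3, 0.92, 1.08)          # head shape jitter
    off <- runif(2, -1, 1)               # lateral head offset, mm
    curve_amp <- runif(1, 0.5, 1.5)      # airway centreline curvature, mm
    curve_phase <- runif(1, 0, 2 * pi)

    cx <- ctr[1] + off[1]; cy <- ctr[2] + off[2]; cz <- ctr[3]
    ax <- 0.40 * ext[1] * jit[1]; ay <- 0.37 * ext[2] * jit[2]
    az <- 0.45 * ext[3] * jit[3]
    head <- ((gx - cx) / ax)^2 + ((gy - cy) / ay)^2 + ((gz - cz) / az)^2 <= 1

    # class 0 covers both exterior air and unlabelled soft tissue
    lab <- integer(prod(d))
    intens <- rep(cfg$intensities$air, prod(d))
    soft <- head
    intens[soft] <- cfg$intensities$soft

    # upper skull: upper-half ellipsoidal shell (class 1)
    sh_o <- ((gx - cx) / (0.33 * ext[1]))^2 + ((gy - cy) / (0.30 * ext[2]))^2 +
            ((gz - cz) / (0.38 * ext[3]))^2
    sh_i <- ((gx - cx) / (0.26 * ext[1]))^2 + ((gy - cy) / (0.23 * ext[2]))^2 +
            ((gz - cz) / (0.31 * ext[3]))^2
    skull <- head & sh_o <= 1 & sh_i > 1 & gz > cz
    lab[skull] <- 1L; intens[skull] <- cfg$intensities$bone

    # mandible: anterior half-ring in a lower axial band (class 2)
    rin <- sqrt((gx - cx)^2 + (gy - cy)^2)
    band_m <- gz > cz - 0.30 * ext[3] & gz < cz - 0.18 * ext[3]
    mand <- head & band_m & rin >= 0.17 * ext[1] & rin <= 0.24 * ext[1] & gy > cy
    lab[mand] <- 2L; intens[mand] <- cfg$intensities$bone

    # tooth rows: short anterior arcs above/below the occlusal plane
    band_up <- gz >= cz - 0.10 * ext[3] & gz < cz - 0.04 * ext[3]
    band_lo <- gz >= cz - 0.17 * ext[3] & gz < cz - 0.11 * ext[3]
    arc <- rin >= 0.16 * ext[1] & rin <= 0.22 * ext[1] & gy > cy + 0.08 * ext[2]
    up_t <- head & band_up & arc
    lo_t <- head & band_lo & arc
    lab[up_t] <- 3L; intens[up_t] <- cfg$intensities$teeth
    lab[lo_t] <- 4L; intens[lo_t] <- cfg$intensities$teeth

    # airway: curved vertical tube with a smooth waist (class 5)
    z0 <- 0.12 * ext[3]; z1 <- 0.88 * ext[3]
    waist_z <- cfg$waist_z %||% ((z0 + z1) / 2)
    tube_cx <- cx + curve_amp * sin(2 * pi * (gz - z0) / (z1 - z0) + curve_phase)
    tube_cy <- cy - 0.10 * ext[2]
    bump <- exp(-((gz - waist_z)^2) / (2 * (0.12 * (z1 - z0))^2))
    r_z <- cfg$r_end - (cfg$r_end - cfg$r_waist) * bump
    tube <- gz >= z0 & gz <= z1 &
      (gx - tube_cx)^2 + (gy - tube_cy)^2 <= r_z^2
    tube <- tube & soft
    lab[tube] <- 5L; intens[tube] <- cfg$intensities$air

    if (cfg$include_epiglottis_flap) {
      flap_z <- waist_z + 0.10 * (z1 - z0)
      flap <- tube & abs(gz - flap_z) <= 1.5 * sp[3] &
        gy <= tube_cy - (1 - 2 * cfg$flap_fraction) * r_z
      lab[flap] <- 0L # flap voxels become (unlabelled) soft tissue
      intens[flap] <- cfg$intensities$soft
    }

    noisy <- intens + rnorm(prod(d), sd = cfg$noise_sd)
  })

  vol <- volume(array(noisy, d), sp)
  labels <- label_volume(array(lab, d), 6L, sp)
  list(volume = vol, labels = labels, config = cfg)
}

#' Generate a cohort of phantom subjects
#'
#' @param n number of subjects.
#' @param base_cfg a [phantom_config()] shared by all subjects.
#' @param seed cohort seed; subject s uses seed `seed + s`.
#' @return named list of phantoms (`p01`, `p02`, ...).
#' @export
generate_phantom_cohort <- function(n, base_cfg = phantom_config(), seed = 1L) {
  out <- lapply(seq_len(n), function(s) {
    cfg <- base_cfg
    cfg$seed <- as.integer(seed + s)
    generate_head_phantom(cfg)
  })
  names(out) <- sprintf("p%02d", seq_len(n))
  out
}

#' Simulate a subjects-by-methods measurement table
#'
#' `value(i, m) = mean_level + subject_i + bias_m + noise`, with
#' `subject_i ~ N(0, between_subject_sd)` and `noise ~ N(0, noise_sd)`;
#' the additive-effects model underlying the consistency ICC.
#'
#' @param n subjects (>= 2). @param methods method count k or label vector.
#' @param per_method_bias length-k offsets (recycled).
#' @param noise_sd,between_subject_sd standard deviations (>= 0).
#' @param mean_level grand mean of the metric.
#' @param seed integer seed.
#' @return a [measurement_table()].
#' @export
generate_measurement_table <- function(n, methods = 2L, per_method_bias = 0,
                                       noise_sd = 1, between_subject_sd = 3,
                                       mean_level = 20, seed = 1L) {
  stopifnot(n >= 2L, noise_sd >= 0, between_subject_sd >= 0)
  if (length(methods) == 1L) methods <- paste0("m", seq_len(methods))
  k <- length(methods)
  stopifnot(k >= 2L)
  bias <- rep_len(per_method_bias, k)
  with_seed(seed, {
    subj <- rnorm(n, sd = between_subject_sd)
    vals <- outer(subj, bias, "+") + mean_level +
      matrix(rnorm(n * k, sd = noise_sd), n, k)
  })
  measurement_table(vals, subjects = sprintf("s%03d", seq_len(n)),
                    methods = methods)
}
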