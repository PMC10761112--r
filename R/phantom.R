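#' Parameters for a synthetic dorsal-horn section phantom
#'
#' The phantom is a stylized transverse section: the dorsal horn is a
#' half-elliptical dome whose curved dorsal surface carries a superficial
#' band (the SDH analog, delineated in real tissue by CGRP-positive
#' staining of peptidergic afferent terminals), with the remainder of the
#' dome standing in for the deeper dorsal horn (DDH) and everything outside
#' the dome for white matter. Only region-mean intensity contrasts matter
#' to the downstream densitometry, so the geometry is deliberately not
#' anatomically faithful.
#'
#' The target ("CB1") channel has expected intensity `I0 * rho` in the SDH
#' band, `I0` in the DDH, and `I0 * background_frac` outside the dome. The
#' marker ("CGRP") channel has expected intensity `cgrp_peak` inside the
#' band and zero elsewhere. Noise is Poisson shot noise (photon gain
#' `poisson_gain`; `0` disables it) plus additive Gaussian read noise,
#' the standard model for fluorescence microscopy.
#'
#' @param height,width image size in pixels.
#' @param horn_center_col column of the dome axis (default `0.45 * width`).
#' @param horn_semiaxis_col,horn_semiaxis_row ellipse semi-axes in pixels.
#' @param horn_base_row row of the flat ventral base of the dome.
#' @param band_px SDH band thickness at the dome apex, pixels; must be
#'   strictly less than `horn_semiaxis_row`.
#' @param base_intensity `I0`, expected DDH intensity in arbitrary
#'   fluorescence units.
#' @param rho SDH/DDH mean-intensity contrast (dimensionless, > 0). The
#'   cohort-level ground truth that the pipeline's SDH/DDH ratio estimates.
#' @param background_frac white-matter intensity as a fraction of `I0`,
#'   in `[0, 1)`.
#' @param cgrp_peak expected marker intensity inside the band.
#' @param poisson_gain photons per intensity unit for shot noise; `0`
#'   disables the Poisson component.
#' @param read_noise_sd additive Gaussian noise standard deviation
#'   (intensity units).
#' @param subject_sd log-scale standard deviation of the multiplicative
#'   subject effect (lognormal, unit mean).
#' @param replicate_sd log-scale standard deviation of the per-slide
#'   (technical replicate) multiplicative effect.
#' @param background_box_px side of the ground-truth white-matter sampling
#'   box, pixels.
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(height = 160, width = 160,
                           horn_center_col = round(0.45 * width),
                           horn_semiaxis_col = round(0.34 * width),
                           horn_semiaxis_row = round(0.68 * height),
                           horn_base_row = round(0.85 * height),
                           band_px = round(0.12 * height),
                           base_intensity = 100,
                           rho = 1.78,
                           background_frac = 0.2,
                           cgrp_peak = 150,
                           poisson_gain = 1,
                           read_noise_sd = 5,
                           subject_sd = 0.10,
                           replicate_sd = 0.05,
                           background_box_px = 24) {
  p <- list(
    height = as.integer(height), width = as.integer(width),
    horn_center_col = as.integer(horn_center_col),
    horn_semiaxis_col = as.integer(horn_semiaxis_col),
    horn_semiaxis_row = as.integer(horn_semiaxis_row),
    horn_base_row = as.integer(horn_base_row),
    band_px = as.integer(band_px),
    base_intensity = base_intensity, rho = rho,
    background_frac = background_frac, cgrp_peak = cgrp_peak,
    poisson_gain = poisson_gain, read_noise_sd = read_noise_sd,
    subject_sd = subject_sd, replicate_sd = replicate_sd,
    background_box_px = as.integer(background_box_px)
  )
  check_that(p$height >= 32 && p$width >= 32, "image must be at least 32x32 pixels")
  check_that(p$rho > 0, "`rho` must be > 0")
  check_that(p$background_frac >= 0 && p$background_frac < 1,
             "`background_frac` must be in [0, 1)")
  check_that(p$base_intensity >= 0 && p$cgrp_peak >= 0, "intensities must be >= 0")
  check_that(p$read_noise_sd >= 0 && p$poisson_gain >= 0, "noise parameters must be >= 0")
  check_that(p$subject_sd >= 0 && p$replicate_sd >= 0, "variance parameters must be >= 0")
  check_that(p$band_px >= 1 && p$band_px < p$horn_semiaxis_row,
             "SDH band must be >= 1 px thick and strictly inside the dorsal horn")
  check_that(p$horn_base_row - p$horn_semiaxis_row >= 1,
             "dorsal horn dome must fit inside the image (top edge)")
  check_that(p$horn_base_row <= p$height, "dorsal horn base must lie inside the image")
  structure(p, class = "phantom_params")
}

# Elliptical radial coordinate of every pixel relative to the dome; t <= 1
# and row <= base_row defines the dorsal horn.
horn_geometry <- function(p) {
  row <- matrix(seq_len(p$height), p$height, p$width)
  col <- matrix(seq_len(p$width), p$height, p$width, byrow = TRUE)
  t2 <- ((p$horn_base_row - row) / p$horn_semiaxis_row)^2 +
    ((col - p$horn_center_col) / p$horn_semiaxis_col)^2
  horn <- t2 <= 1 & row <= p$horn_base_row
  tau <- p$band_px / p$horn_semiaxis_row
  sdh <- horn & t2 > (1 - tau)^2
  ddh <- horn & !sdh
  list(horn = horn, sdh = sdh, ddh = ddh)
}

# Deterministic ground-truth white-matter box: in the medial strip beside
# the dome, clear of the horn.
truth_background_box <- function(p, horn) {
  s <- p$background_box_px
  right_edge <- min(p$horn_center_col + p$horn_semiaxis_col + 3L, p$width)
  c0 <- right_edge + 2L
  if (c0 + s - 1L > p$width) {
    stop("no room for the white-matter background box medial to the dorsal horn",
         call. = FALSE)
  }
  r0 <- 2L
  mask <- matrix(FALSE, p$height, p$width)
  mask[r0:(r0 + s - 1L), c0:(c0 + s - 1L)] <- TRUE
  check_that(!any(mask & horn), "background box overlaps the dorsal horn")
  mask
}

#' Generate one synthetic two-channel section
#'
#' @param params a [phantom_params()] object.
#' @param subject_effect multiplicative subject-level scale applied to both
#'   channels (drawn once per subject by [generate_cohort()]).
#' @param replicate_index technical-replicate (slide) index, for provenance.
#' @param seed integer seed for this section's noise and replicate effect.
#' @return An object of class `section_phantom`: numeric matrices `cb1` and
#'   `cgrp`, a ground-truth [roi_set()] in `$rois`, the dorsal-horn mask in
#'   `$horn_mask`, and provenance fields (`params`, `subject_effect`,
#'   `replicate_index`, `seed`).
#' @export
generate_section <- function(params, subject_effect = 1, replicate_index = 1L,
                             seed = 1L) {
  check_that(inherits(params, "phantom_params"), "`params` must come from phantom_params()")
  check_that(is_scalar_num(subject_effect) && subject_effect > 0,
             "`subject_effect` must be a positive scalar")
  geo <- horn_geometry(params)
  check_that(any(geo$ddh), "degenerate geometry: SDH band fills the whole dorsal horn")
  bg_box <- truth_background_box(params, geo$horn)

  p <- params
  mean_cb1 <- matrix(p$base_intensity * p$background_frac, p$height, p$width)
  mean_cb1[geo$ddh] <- p$base_intensity
  mean_cb1[geo$sdh] <- p$base_intensity * p$rho
  mean_cgrp <- matrix(0, p$height, p$width)
  mean_cgrp[geo$sdh] <- p$cgrp_peak

  with_seed(seed, {
    rep_effect <- if (p$replicate_sd > 0) {
      rlnorm(1, meanlog = -p$replicate_sd^2 / 2, sdlog = p$replicate_sd)
    } else {
      1
    }
    scale <- subject_effect * rep_effect
    cb1 <- add_noise(mean_cb1 * scale, p)
    cgrp <- add_noise(mean_cgrp * scale, p)
  })

  rois <- roi_set(sdh = geo$sdh, ddh = geo$ddh, background = bg_box)
  structure(list(
    cb1 = cb1, cgrp = cgrp, rois = rois, horn_mask = geo$horn,
    params = params, subject_effect = subject_effect,
    replicate_index = as.integer(replicate_index), seed = as.integer(seed)
  ), class = "section_phantom")
}

add_noise <- function(mu, p) {
  x <- mu
  if (p$poisson_gain > 0) {
    x <- matrix(rpois(length(mu), lambda = p$poisson_gain * mu) / p$poisson_gain,
                nrow(mu), ncol(mu))
  }
  if (p$read_noise_sd > 0) {
    x <- x + matrix(rnorm(length(mu), sd = p$read_noise_sd), nrow(mu), ncol(mu))
  }
  pmax(x, 0)
}

#' Describe a synthetic cohort design
#'
#' One design cell per sex x species combination, mirroring a staining
#' study in which every rat is stained in triplicate and every human donor
#' in duplicate.
#'
#' @param n_per_cell subjects per design cell.
#' @param replicates technical replicates (slides) per subject.
#' @param sexes,species factor levels crossed to form the design cells.
#' @param params a [phantom_params()] object, or a named list of them (one
#'   per `"<sex>.<species>"` cell) to vary conditions across cells.
#' @param segment segment label recorded in the metadata (e.g. "lumbar").
#' @param master_seed master seed; all subject effects and section seeds
#'   are split from it (see [split_seed()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 6L, replicates = 3L,
                        sexes = c("female", "male"), species = "rat",
                        params = phantom_params(), segment = "lumbar",
                        master_seed = 1L) {
  check_that(is_scalar_num(n_per_cell) && n_per_cell >= 1, "`n_per_cell` must be >= 1")
  check_that(is_scalar_num(replicates) && replicates >= 1, "`replicates` must be >= 1")
  cells <- as.vector(outer(sexes, species, paste, sep = "."))
  if (inherits(params, "phantom_params")) {
    params <- setNames(rep(list(params), length(cells)), cells)
  }
  check_that(all(cells %in% names(params)),
             "`params` must be a phantom_params object or a named list covering every design cell")
  structure(list(
    n_per_cell = as.integer(n_per_cell), replicates = as.integer(replicates),
    sexes = sexes, species = species, params = params, segment = segment,
    master_seed = as.integer(master_seed)
  ), class = "cohort_spec")
}

#' Generate a synthetic cohort of section phantoms
#'
#' Subject effects are drawn once per subject (lognormal with unit mean and
#' log-sd `subject_sd`) and shared across that subject's technical
#' replicates; each section then gets its own split seed for replicate
#' effects and pixel noise. The whole cohort is reproducible from
#' `master_seed`.
#'
#' @param spec a [cohort_spec()] object.
#' @return A list with `sections` (list of `section_phantom`) and
#'   `metadata` (one row per section: subject, sex, species, segment,
#'   replicate, subject_effect, seed).
#' @export
generate_cohort <- function(spec) {
  check_that(inherits(spec, "cohort_spec"), "`spec` must come from cohort_spec()")
  sections <- list()
  meta <- list()
  subj_index <- 0L
  for (sp in spec$species) {
    for (sx in spec$sexes) {
      cell <- paste(sx, sp, sep = ".")
      p <- spec$params[[cell]]
      for (i in seq_len(spec$n_per_cell)) {
        subj_index <- subj_index + 1L
        subject_id <- sprintf("%s_%s_%02d", substr(sp, 1, 3), substr(sx, 1, 1), i)
        subj_seed <- split_seed(spec$master_seed, subj_index)
        subject_effect <- if (p$subject_sd > 0) {
          with_seed(subj_seed,
                    rlnorm(1, meanlog = -p$subject_sd^2 / 2, sdlog = p$subject_sd))
        } else {
          1
        }
        for (r in seq_len(spec$replicates)) {
          sec_seed <- split_seed(subj_seed, r)
          sec <- generate_section(p, subject_effect = subject_effect,
                                  replicate_index = r, seed = sec_seed)
          sec$subject_id <- subject_id
          sections[[length(sections) + 1L]] <- sec
          meta[[length(meta) + 1L]] <- data.frame(
            subject = subject_id, sex = sx, species = sp,
            segment = spec$segment, replicate = r,
            subject_effect = subject_effect, seed = sec_seed,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  list(sections = sections, metadata = do.call(rbind, meta))
}

#' @export
print.section_phantom <- function(x, ...) {
  cat(sprintf(
    "section_phantom: %dx%d px, rho = %.3g, subject %s, replicate %d, seed %d\n",
    nrow(x$cb1), ncol(x$cb1), x$params$rho,
    if (is.null(x$subject_id)) "?" else x$subject_id,
    x$replicate_index, x$seed
  ))
  invisible(x)
}
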