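#' Integrated intensity and density of a region
#'
#' "Optical density" here is integrated fluorescence intensity divided by
#' region area (the mean gray value an ImageJ measurement would report),
#' not absorbance: the signal is fluorescence in a confocal image.
#'
#' @param channel numeric matrix.
#' @param mask nonempty logical matrix of the same dimensions.
#' @param label region label, one of `"SDH"`, `"DDH"`, `"background"`.
#' @param pixel_size optional micrometres per pixel; if given, `area` is in
#'   square micrometres instead of pixels.
#' @return An object of class `region_density` with fields `label`,
#'   `integrated`, `area`, `density`.
#' @export
region_density <- function(channel, mask, label = "SDH", pixel_size = NULL) {
  check_that(is.matrix(channel) && is.numeric(channel), "`channel` must be a numeric matrix")
  check_that(identical(dim(channel), dim(mask)), "channel and mask must share dimensions")
  check_that(any(mask), "empty region mask")
  integrated <- sum(channel[mask])
  area <- sum(mask)
  if (!is.null(pixel_size)) area <- area * pixel_size^2
  structure(list(label = label, integrated = integrated, area = area,
                 density = integrated / area),
            class = "region_density")
}

#' Normalize a region density to the background region
#'
#' Dividing by the white-matter background density cancels global gain
#' factors (laser power, exposure, subject-level staining efficiency),
#' which is why multiplicative subject effects drop out of the normalized
#' values.
#'
#' @param region,background [region_density()] objects.
#' @return Dimensionless normalized density.
#' @export
normalize_to_background <- function(region, background) {
  check_that(inherits(region, "region_density") && inherits(background, "region_density"),
             "inputs must be region_density objects")
  if (background$density <= 0) {
    stop("background density is not positive; background box placement failed",
         call. = FALSE)
  }
  region$density / background$density
}

#' Mean across technical replicates
#'
#' Each subject is immunostained on several slides (triplicate for
#' rat-like, duplicate for human-like cohorts); slide-level values are
#' averaged into one value per subject before any inference.
#'
#' @param values numeric vector of per-slide values, length >= 1.
#' @return The arithmetic mean, with the replicate count in attribute `n`.
#' @export
replicate_mean <- function(values) {
  check_that(is.numeric(values) && length(values) >= 1, "need at least one replicate value")
  check_that(all(is.finite(values)), "replicate values must be finite")
  structure(mean(values), n = length(values))
}

#' SDH/DDH localization ratio for one subject
#'
#' @param sdh,ddh replicate-averaged normalized densities; `ddh` must be
#'   positive.
#' @return `sdh / ddh`.
#' @export
subject_ratio <- function(sdh, ddh) {
  check_that(is_scalar_num(sdh) && is_scalar_num(ddh), "inputs must be scalars")
  if (ddh <= 0) stop("nonpositive DDH value; cannot form SDH/DDH ratio", call. = FALSE)
  sdh / ddh
}

#' Measure one section
#'
#' Runs the densitometry chain on a single two-channel section: region
#' densities for SDH, DDH and background, then background normalization
#' and the per-slide ratio.
#'
#' @param cb1_channel numeric matrix, the target channel.
#' @param rois a [roi_set()].
#' @return A one-row data frame: `sdh_raw`, `ddh_raw`, `background_raw`
#'   (densities, a.u./px), `sdh`, `ddh` (background-normalized), `ratio`.
#' @export
measure_section <- function(cb1_channel, rois) {
  check_that(inherits(rois, "roi_set"), "`rois` must be a roi_set")
  d_sdh <- region_density(cb1_channel, rois$sdh, "SDH", rois$pixel_size)
  d_ddh <- region_density(cb1_channel, rois$ddh, "DDH", rois$pixel_size)
  d_bg <- region_density(cb1_channel, rois$background, "background", rois$pixel_size)
  n_sdh <- normalize_to_background(d_sdh, d_bg)
  n_ddh <- normalize_to_background(d_ddh, d_bg)
  data.frame(sdh_raw = d_sdh$density, ddh_raw = d_ddh$density,
             background_raw = d_bg$density,
             sdh = n_sdh, ddh = n_ddh, ratio = subject_ratio(n_sdh, n_ddh))
}

#' Build the per-subject cohort table from per-slide records
#'
#' Averages each subject's normalized SDH and DDH values across technical
#' replicates, then ratios the means — matching a workflow in which "a mean
#' of the slides" is taken per region before the ratio. The mean of
#' per-slide ratios is also reported (`ratio_slidewise`) as a sensitivity
#' output, because the two orders of operations differ in general.
#'
#' @param slide_records data frame with columns `subject`, `sdh`, `ddh`
#'   (one row per slide), e.g. stacked [measure_section()] rows.
#' @param metadata data frame with columns `subject`, `sex`, `species`,
#'   `segment` (one row per slide or per subject; deduplicated by subject).
#' @param expected_replicates if given, subjects with fewer slides are kept
#'   with a warning (a lost slide does not drop the subject).
#' @return A `cohort_table` data frame: one row per subject with design
#'   labels, `sdh`, `ddh`, `ratio`, `ratio_slidewise`, `n_replicates`.
#' @export
build_cohort_table <- function(slide_records, metadata, expected_replicates = NULL) {
  check_that(all(c("subject", "sdh", "ddh") %in% names(slide_records)),
             "`slide_records` needs subject, sdh, ddh columns")
  check_that(all(c("subject", "sex", "species") %in% names(metadata)),
             "`metadata` needs subject, sex, species columns")
  meta <- unique(metadata[, intersect(c("subject", "sex", "species", "segment"),
                                      names(metadata))])
  check_that(!anyDuplicated(meta$subject),
             "duplicate subject with conflicting design labels in metadata")
  orphans <- setdiff(slide_records$subject, meta$subject)
  check_that(length(orphans) == 0,
             paste("slides with no subject metadata:", paste(orphans, collapse = ", ")))

  per_subject <- lapply(split(slide_records, slide_records$subject), function(d) {
    s <- replicate_mean(d$sdh)
    dd <- replicate_mean(d$ddh)
    data.frame(subject = d$subject[1],
               sdh = as.numeric(s), ddh = as.numeric(dd),
               ratio = subject_ratio(as.numeric(s), as.numeric(dd)),
               ratio_slidewise = mean(d$sdh / d$ddh),
               n_replicates = attr(s, "n"))
  })
  tab <- do.call(rbind, per_subject)
  rownames(tab) <- NULL
  if (!is.null(expected_replicates)) {
    short <- tab$subject[tab$n_replicates < expected_replicates]
    if (length(short)) {
      warning(sprintf("subjects with fewer than %d replicates kept: %s",
                      expected_replicates, paste(short, collapse = ", ")))
    }
  }
  tab <- merge(meta, tab, by = "subject", sort = TRUE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Measure a whole synthetic cohort
#'
#' Applies per-section measurement and subject aggregation to the output of
#' [generate_cohort()], with ROIs taken either from the generator's ground
#' truth or re-derived by marker-guided segmentation.
#'
#' @param cohort output of [generate_cohort()].
#' @param roi_source `"segment"` to run [segment_rois()] on each section
#'   (the full pipeline), or `"truth"` to use the phantom's ground-truth
#'   masks.
#' @param seg_params a [segmentation_params()] object, used when
#'   `roi_source = "segment"`.
#' @return A list with `slides` (per-slide measurements joined to
#'   metadata) and `cohort` (the per-subject `cohort_table`).
#' @export
measure_cohort <- function(cohort, roi_source = c("segment", "truth"),
                           seg_params = segmentation_params()) {
  roi_source <- match.arg(roi_source)
  rows <- lapply(seq_along(cohort$sections), function(i) {
    sec <- cohort$sections[[i]]
    rois <- if (roi_source == "truth") {
      sec$rois
    } else {
      segment_rois(sec$cb1, sec$cgrp, sec$horn_mask, seg_params)
    }
    cbind(cohort$metadata[i, c("subject", "sex", "species", "segment", "replicate")],
          measure_section(sec$cb1, rois))
  })
  slides <- do.call(rbind, rows)
  rownames(slides) <- NULL
  cohort_tab <- build_cohort_table(slides, cohort$metadata)
  list(slides = slides, cohort = cohort_tab)
}
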