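#' Construct an ROI set
#'
#' The three analysis regions for one section: the SDH mask (outlined in
#' real tissue where CGRP-positive staining is maximal), the DDH mask (the
#' rest of the dorsal horn), and a square white-matter background box. The
#' three masks must be pairwise disjoint.
#'
#' @param sdh,ddh logical matrices, nonempty, same dimensions.
#' @param background logical matrix; must be a filled rectangle.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(sdh, ddh, background, pixel_size = NULL) {
  check_that(is.logical(sdh) && is.matrix(sdh), "`sdh` must be a logical matrix")
  check_that(identical(dim(sdh), dim(ddh)) && identical(dim(sdh), dim(background)),
             "ROI masks must share dimensions")
  check_that(any(sdh), "SDH mask is empty")
  check_that(any(ddh), "DDH mask is empty")
  check_that(any(background), "background mask is empty")
  check_that(!any(sdh & ddh) && !any(sdh & background) && !any(ddh & background),
             "ROI masks must be pairwise disjoint")
  check_that(is_filled_rectangle(background), "background mask must be a filled rectangle")
  structure(list(sdh = sdh, ddh = ddh, background = background,
                 pixel_size = pixel_size), class = "roi_set")
}

is_filled_rectangle <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  sum(mask) == length(rows) * length(cols) &&
    all(diff(rows) == 1) && all(diff(cols) == 1)
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("roi_set: SDH %d px, DDH %d px, background %d px (%dx%d image)\n",
              sum(x$sdh), sum(x$ddh), sum(x$background), nrow(x$sdh), ncol(x$sdh)))
  invisible(x)
}

#' Segmentation parameters
#'
#' @param smooth_sigma Gaussian smoothing scale in pixels applied to the
#'   marker channel before thresholding (0 disables smoothing).
#' @param threshold `"otsu"` for a bimodal Otsu split on the smoothed
#'   channel (scale-invariant), or a fixed numeric threshold in intensity
#'   units.
#' @param min_area minimum connected-component area in pixels; smaller
#'   components are discarded before the largest is kept.
#' @param box_px side length of the background box, pixels.
#' @param box_margin margin in pixels kept between the box and the
#'   dorsal-horn mask during automatic placement.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(smooth_sigma = 2, threshold = "otsu",
                                min_area = 64L, box_px = 24L, box_margin = 2L) {
  check_that(is_scalar_num(smooth_sigma) && smooth_sigma >= 0,
             "`smooth_sigma` must be >= 0")
  check_that(identical(threshold, "otsu") || is_scalar_num(threshold),
             "`threshold` must be \"otsu\" or a numeric value")
  check_that(is_scalar_num(min_area) && min_area >= 0, "`min_area` must be >= 0")
  check_that(is_scalar_num(box_px) && box_px >= 1, "`box_px` must be >= 1")
  check_that(is_scalar_num(box_margin) && box_margin >= 0, "`box_margin` must be >= 0")
  structure(list(smooth_sigma = smooth_sigma, threshold = threshold,
                 min_area = as.integer(min_area), box_px = as.integer(box_px),
                 box_margin = as.integer(box_margin)),
            class = "segmentation_params")
}

#' Segment the SDH band from the marker channel
#'
#' Deterministic stand-in for the manual contour drawn around the region of
#' maximal CGRP-positive staining: smooth the marker channel, threshold it
#' (Otsu by default, so the result is invariant to global intensity
#' rescaling), discard components below `min_area`, keep the largest
#' connected component, and fill its holes.
#'
#' @param cgrp_channel nonnegative, nonconstant numeric matrix.
#' @param params a [segmentation_params()] object.
#' @return A logical SDH mask.
#' @export
segment_sdh <- function(cgrp_channel, params = segmentation_params()) {
  check_that(is.matrix(cgrp_channel) && is.numeric(cgrp_channel),
             "`cgrp_channel` must be a numeric matrix")
  check_that(all(cgrp_channel >= 0), "`cgrp_channel` must be nonnegative")
  rng <- range(cgrp_channel)
  if (diff(rng) == 0) stop("no CGRP band detected: marker channel is constant", call. = FALSE)

  img <- cgrp_channel
  if (params$smooth_sigma > 0) {
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::as.Image(img), sigma = params$smooth_sigma)
    ))
  }
  thr <- if (identical(params$threshold, "otsu")) {
    r <- range(img)
    scaled <- (img - r[1]) / (r[2] - r[1])
    EBImage::otsu(EBImage::as.Image(scaled), range = c(0, 1)) * (r[2] - r[1]) + r[1]
  } else {
    params$threshold
  }
  bw <- img > thr
  if (!any(bw)) stop("no CGRP band detected: nothing above threshold", call. = FALSE)

  lab <- EBImage::bwlabel(EBImage::as.Image(bw))
  sizes <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  sizes <- sizes[sizes >= params$min_area]
  if (length(sizes) == 0) {
    stop("no CGRP band detected: all components below minimum area", call. = FALSE)
  }
  keep <- as.integer(names(sizes)[which.max(sizes)])
  comp <- EBImage::imageData(lab) == keep
  filled <- EBImage::fillHull(EBImage::as.Image(comp * 1))
  mask <- as.matrix(EBImage::imageData(filled)) > 0
  dimnames(mask) <- NULL
  mask
}

#' Derive the DDH mask
#'
#' The deeper dorsal horn is everything in the dorsal-horn contour not
#' claimed by the SDH band.
#'
#' @param dorsal_horn_mask,sdh_mask logical matrices; `sdh_mask` must be a
#'   subset of `dorsal_horn_mask`.
#' @return A logical DDH mask, disjoint from the SDH by construction.
#' @export
derive_ddh <- function(dorsal_horn_mask, sdh_mask) {
  check_that(identical(dim(dorsal_horn_mask), dim(sdh_mask)),
             "masks must share dimensions")
  check_that(!any(sdh_mask & !dorsal_horn_mask),
             "SDH mask must lie inside the dorsal-horn mask")
  ddh <- dorsal_horn_mask & !sdh_mask
  if (!any(ddh)) stop("degenerate DDH: SDH covers the whole dorsal horn", call. = FALSE)
  ddh
}

#' Place the white-matter background box
#'
#' Automatic mode slides an `s x s` box over every position whose pixels
#' all lie outside the (margin-dilated) dorsal-horn mask and returns the
#' placement minimizing mean target-channel intensity — the algorithmic
#' reading of "a square selection of the white matter where there should be
#' minimal fluorescence". Exact intensity ties break lexicographically by
#' (row, column). User mode places the box at given coordinates after
#' bounds and overlap checks.
#'
#' @param cb1_channel numeric matrix, the target channel.
#' @param dorsal_horn_mask logical matrix the box must avoid.
#' @param params a [segmentation_params()] object (`box_px`, `box_margin`).
#' @param at optional `c(row, col)` top-left corner for user mode.
#' @return A logical box mask.
#' @export
place_background_box <- function(cb1_channel, dorsal_horn_mask,
                                 params = segmentation_params(), at = NULL) {
  H <- nrow(cb1_channel); W <- ncol(cb1_channel)
  check_that(identical(dim(cb1_channel), dim(dorsal_horn_mask)),
             "channel and mask must share dimensions")
  s <- params$box_px
  check_that(s <= H && s <= W, "background box larger than the image")

  if (!is.null(at)) {
    r0 <- as.integer(at[1]); c0 <- as.integer(at[2])
    check_that(r0 >= 1 && c0 >= 1 && r0 + s - 1 <= H && c0 + s - 1 <= W,
               "user-specified background box exceeds image bounds")
    mask <- matrix(FALSE, H, W)
    mask[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- TRUE
    if (any(mask & dorsal_horn_mask)) {
      stop("background box placement error: box overlaps the dorsal horn", call. = FALSE)
    }
    return(mask)
  }

  avoid <- dorsal_horn_mask
  if (params$box_margin > 0) {
    avoid <- as.matrix(EBImage::imageData(EBImage::dilate(
      EBImage::as.Image(dorsal_horn_mask * 1),
      EBImage::makeBrush(2L * params$box_margin + 1L, shape = "box")
    ))) > 0
  }
  Sint <- padded_cumsum2d(cb1_channel)
  Smask <- padded_cumsum2d(avoid * 1)
  r0s <- seq_len(H - s + 1L)
  c0s <- seq_len(W - s + 1L)
  best <- NULL; best_mean <- Inf
  for (r0 in r0s) {
    r1 <- r0 + s - 1L
    overlap <- box_sum(Smask, r0, r1, c0s, c0s + s - 1L)
    means <- box_sum(Sint, r0, r1, c0s, c0s + s - 1L) / (s * s)
    means[overlap > 0] <- Inf
    i <- which(means < best_mean) # strict: preserves (row, column) tie-break
    if (length(i)) {
      i <- i[1]
      best_mean <- means[i]
      best <- c(r0, c0s[i])
    }
  }
  if (is.null(best)) {
    stop("background box placement error: no admissible position outside the dorsal horn",
         call. = FALSE)
  }
  mask <- matrix(FALSE, H, W)
  mask[best[1]:(best[1] + s - 1L), best[2]:(best[2] + s - 1L)] <- TRUE
  mask
}

#' Segment a full ROI set from a section
#'
#' Convenience wrapper running [segment_sdh()], [derive_ddh()] and
#' [place_background_box()] on one two-channel section.
#'
#' @param cb1_channel,cgrp_channel numeric matrices.
#' @param dorsal_horn_mask logical dorsal-horn contour (from the phantom
#'   ground truth or a manual contour).
#' @param params a [segmentation_params()] object.
#' @return A [roi_set()].
#' @export
segment_rois <- function(cb1_channel, cgrp_channel, dorsal_horn_mask,
                         params = segmentation_params()) {
  sdh <- segment_sdh(cgrp_channel, params)
  # clip to the dorsal-horn contour, as the manual workflow would
  sdh <- sdh & dorsal_horn_mask
  if (!any(sdh)) stop("no CGRP band detected inside the dorsal horn", call. = FALSE)
  ddh <- derive_ddh(dorsal_horn_mask, sdh)
  bg <- place_background_box(cb1_channel, dorsal_horn_mask, params)
  roi_set(sdh = sdh, ddh = ddh, background = bg)
}

#' Load manually drawn ROIs from files
#'
#' Accepts PNG mask images (nonzero = inside) or polygon CSVs with `row`
#' and `col` columns (vertices in pixel coordinates, filled by even-odd
#' rule). Pixels claimed by both SDH and DDH are assigned to the SDH with a
#' warning, matching how an analyst would resolve a sloppy double contour.
#'
#' @param sdh,ddh,background file paths (PNG or CSV as above).
#' @param dim image dimensions `c(rows, cols)`; required for polygon CSVs,
#'   checked against mask images.
#' @param pixel_size optional micrometres per pixel.
#' @return A [roi_set()].
#' @export
load_manual_rois <- function(sdh, ddh, background, dim = NULL, pixel_size = NULL) {
  m_sdh <- load_mask_file(sdh, dim)
  m_ddh <- load_mask_file(ddh, dim %||% dim(m_sdh))
  m_bg <- load_mask_file(background, dim %||% dim(m_sdh))
  check_that(identical(dim(m_sdh), dim(m_ddh)) && identical(dim(m_sdh), dim(m_bg)),
             "ROI mask dimensions disagree")
  overlap <- m_sdh & m_ddh
  if (any(overlap)) {
    warning(sprintf("%d pixels claimed by both SDH and DDH assigned to SDH", sum(overlap)))
    m_ddh <- m_ddh & !m_sdh
  }
  roi_set(sdh = m_sdh, ddh = m_ddh, background = m_bg, pixel_size = pixel_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_mask_file <- function(path, dim = NULL) {
  check_that(file.exists(path), paste("file not found:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(base::dim(img)) == 3) img <- img[, , 1]
    mask <- img > 0
    if (!is.null(dim)) {
      check_that(identical(base::dim(mask), as.integer(dim)),
                 paste("mask dimensions do not match image:", path))
    }
  } else if (ext == "csv") {
    check_that(!is.null(dim), "polygon CSV masks need explicit `dim`")
    poly <- read.csv(path)
    check_that(all(c("row", "col") %in% names(poly)),
               "polygon CSV must have `row` and `col` columns")
    mask <- polygon_mask(poly$row, poly$col, dim[1], dim[2])
  } else {
    stop("unsupported mask format: ", path, call. = FALSE)
  }
  if (!any(mask)) stop("empty mask: ", path, call. = FALSE)
  mask
}

# Even-odd (ray casting) polygon fill at pixel centers.
polygon_mask <- function(vr, vc, H, W) {
  n <- length(vr)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  inside <- matrix(FALSE, H, W)
  j <- n
  for (i in seq_len(n)) {
    cross <- ((vr[i] > rows) != (vr[j] > rows)) &
      (cols < (vc[j] - vc[i]) * (rows - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Dice similarity of two masks
#'
#' @param a,b logical matrices.
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice <- function(a, b) {
  check_that(identical(dim(a), dim(b)), "masks must share dimensions")
  2 * sum(a & b) / (sum(a) + sum(b))
}
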