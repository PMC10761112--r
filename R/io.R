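#' Write a section phantom to disk
#'
#' Writes a two-channel float TIFF (channel 1 = target, channel 2 =
#' marker), PNG ground-truth masks, and a JSON provenance sidecar holding
#' the generator parameters, subject, replicate and seed.
#'
#' @param phantom a `section_phantom`.
#' @param dir output directory (created if needed).
#' @param stem file stem; defaults to `<subject>_r<replicate>`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_phantom <- function(phantom, dir, stem = NULL) {
  check_that(inherits(phantom, "section_phantom"), "`phantom` must be a section_phantom")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(stem)) {
    stem <- sprintf("%s_r%d", phantom$subject_id %||% "section", phantom$replicate_index)
  }
  paths <- c(
    image = file.path(dir, paste0(stem, ".tif")),
    sdh = file.path(dir, paste0(stem, "_sdh.png")),
    ddh = file.path(dir, paste0(stem, "_ddh.png")),
    background = file.path(dir, paste0(stem, "_background.png")),
    horn = file.path(dir, paste0(stem, "_horn.png")),
    provenance = file.path(dir, paste0(stem, ".json"))
  )
  tiff::writeTIFF(list(phantom$cb1 / max(phantom$cb1, 1),
                       phantom$cgrp / max(phantom$cgrp, 1)),
                  paths[["image"]], bits.per.sample = 32L)
  png::writePNG(phantom$rois$sdh * 1, paths[["sdh"]])
  png::writePNG(phantom$rois$ddh * 1, paths[["ddh"]])
  png::writePNG(phantom$rois$background * 1, paths[["background"]])
  png::writePNG(phantom$horn_mask * 1, paths[["horn"]])
  prov <- c(unclass(phantom$params),
            list(subject = phantom$subject_id %||% NA,
                 subject_effect = phantom$subject_effect,
                 replicate = phantom$replicate_index, seed = phantom$seed,
                 tiff_scale = c(max(phantom$cb1, 1), max(phantom$cgrp, 1))))
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a section phantom written by [write_phantom()]
#'
#' @param dir directory containing the files.
#' @param stem file stem used at write time.
#' @return A list with `cb1`, `cgrp`, `rois`, `horn_mask`, `provenance`.
#' @export
read_phantom <- function(dir, stem) {
  prov <- jsonlite::read_json(file.path(dir, paste0(stem, ".json")),
                              simplifyVector = TRUE)
  channels <- tiff::readTIFF(file.path(dir, paste0(stem, ".tif")), all = TRUE)
  cb1 <- channels[[1]] * prov$tiff_scale[1]
  cgrp <- channels[[2]] * prov$tiff_scale[2]
  rois <- load_manual_rois(file.path(dir, paste0(stem, "_sdh.png")),
                           file.path(dir, paste0(stem, "_ddh.png")),
                           file.path(dir, paste0(stem, "_background.png")))
  horn <- load_mask_file(file.path(dir, paste0(stem, "_horn.png")))
  list(cb1 = cb1, cgrp = cgrp, rois = rois, horn_mask = horn, provenance = prov)
}

#' Write / read a cohort table as CSV
#'
#' UTF-8 CSV with a header row and `.` decimal separator; the round trip is
#' lossless for the numeric columns up to full double precision.
#'
#' @param tab a `cohort_table` (or any data frame).
#' @param path CSV path.
#' @return `path` (write) or the table with class restored (read).
#' @export
write_cohort_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Write a count matrix as MatrixMarket with gene/cell sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv`, `cells.tsv` and `annotation.csv`
#' (cluster, laminae, class plus per-cell cluster labels in
#' `cell_clusters.csv`) under `dir`.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param annotation a [cluster_annotation()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, annotation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts), "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "cells.tsv"))
  utils::write.csv(annotation$clusters, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  utils::write.csv(annotation$cells, file.path(dir, "cell_clusters.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory containing the MTX bundle.
#' @return A list with `counts` (dense integer matrix) and `annotation`.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- as.matrix(m)
  storage.mode(counts) <- "integer"
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "cells.tsv"))
  ann <- cluster_annotation(
    cells = utils::read.csv(file.path(dir, "cell_clusters.csv"),
                            stringsAsFactors = FALSE),
    clusters = utils::read.csv(file.path(dir, "annotation.csv"),
                               stringsAsFactors = FALSE)
  )
  list(counts = counts, annotation = ann)
}

#' @importFrom methods as
NULL
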