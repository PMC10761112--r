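#' Cluster annotation for a count matrix
#'
#' Maps every cell to a neuronal cluster and every cluster to a laminar
#' annotation (and an excitatory/inhibitory class), the structure needed to
#' pool clusters into SDH / DDH / dorsal-horn-overall groups.
#'
#' @param cells data frame with columns `cell`, `cluster`.
#' @param clusters data frame with columns `cluster`, `laminae`, and
#'   optionally `class`.
#' @return An object of class `cluster_annotation`.
#' @export
cluster_annotation <- function(cells, clusters) {
  check_that(all(c("cell", "cluster") %in% names(cells)),
             "`cells` needs cell and cluster columns")
  check_that(all(c("cluster", "laminae") %in% names(clusters)),
             "`clusters` needs cluster and laminae columns")
  check_that(!anyDuplicated(cells$cell), "cell identifiers must be unique")
  check_that(!anyDuplicated(clusters$cluster), "cluster names must be unique")
  missing <- setdiff(cells$cluster, clusters$cluster)
  check_that(length(missing) == 0,
             paste("clusters without laminar annotation:", paste(missing, collapse = ", ")))
  check_that(all(nzchar(clusters$laminae)), "laminar annotations must be nonempty")
  if (!"class" %in% names(clusters)) clusters$class <- NA_character_
  structure(list(cells = cells, clusters = clusters), class = "cluster_annotation")
}

# Roman numerals used for dorsal-horn laminae.
.lamina_order <- c("I", "II", "III", "IV", "V", "VI")

#' Parse a laminar annotation string into lamina tokens
#'
#' Accepts forms like `"laminae I-II"`, `"lamina IIo"`, `"laminae II, IIi"`
#' or `"laminae III-VI"`. Ranges over plain roman numerals are expanded
#' (`"III-VI"` -> III, IV, V, VI); the sublamina markers `IIo` and `IIi`
#' are kept as distinct tokens. Unrecognized tokens raise an error naming
#' them.
#'
#' @param ann annotation string.
#' @return Character vector of tokens from `I, II, IIo, IIi, III..VI`.
#' @export
parse_laminae <- function(ann) {
  check_that(is.character(ann) && length(ann) == 1, "`ann` must be a single string")
  s <- gsub("laminae?", "", ann, ignore.case = TRUE)
  s <- gsub("–|—", "-", s) # en/em dash -> hyphen
  parts <- trimws(unlist(strsplit(s, "[,/;]| and ")))
  parts <- parts[nzchar(parts)]
  check_that(length(parts) > 0, paste("unresolvable laminar annotation:", ann))
  valid <- c(.lamina_order, "IIo", "IIi")
  tokens <- character()
  for (p in parts) {
    if (grepl("-", p)) {
      ends <- trimws(unlist(strsplit(p, "-")))
      if (length(ends) != 2 || !all(ends %in% .lamina_order)) {
        stop("unresolvable laminar range in annotation \"", ann, "\": ", p, call. = FALSE)
      }
      i <- match(ends, .lamina_order)
      tokens <- c(tokens, .lamina_order[i[1]:i[2]])
    } else if (p %in% valid) {
      tokens <- c(tokens, p)
    } else {
      stop("unresolvable laminar token in annotation \"", ann, "\": ", p, call. = FALSE)
    }
  }
  unique(tokens)
}

#' Laminar grouping scheme
#'
#' Named groups, each defined by the set of lamina tokens it accepts; a
#' cluster joins every group whose token set intersects its own parsed
#' annotation, so groups may overlap (lamina II clusters sit in both SDH
#' and DDH under the default scheme, mirroring how superficial and deeper
#' pools are defined in the field). A `DH` group containing every cell
#' exactly once is always added.
#'
#' @param groups named list of character vectors of lamina tokens. The
#'   default pools `I, II, IIo` into SDH and `II, IIi, III-VI` into DDH.
#' @return An object of class `grouping_scheme`.
#' @export
grouping_scheme <- function(groups = list(
                              SDH = c("I", "II", "IIo"),
                              DDH = c("II", "IIi", "III", "IV", "V", "VI"))) {
  check_that(is.list(groups), "`groups` must be a named list (possibly empty)")
  if (length(groups)) {
    check_that(!is.null(names(groups)) && all(nzchar(names(groups))),
               "every group needs a name")
    valid <- c(.lamina_order, "IIo", "IIi")
    bad <- setdiff(unlist(groups), valid)
    check_that(length(bad) == 0,
               paste("unknown lamina tokens in scheme:", paste(bad, collapse = ", ")))
    check_that(!"DH" %in% names(groups), "`DH` is reserved for the overall group")
  }
  structure(list(groups = groups), class = "grouping_scheme")
}

#' Pool cells into laminar groups
#'
#' @param annotation a [cluster_annotation()].
#' @param scheme a [grouping_scheme()].
#' @return Named list of character vectors of cell identifiers, one per
#'   group (scheme groups in order, then `DH` with every cell once).
#' @export
pool_groups <- function(annotation, scheme = grouping_scheme()) {
  check_that(inherits(annotation, "cluster_annotation"),
             "`annotation` must be a cluster_annotation")
  check_that(inherits(scheme, "grouping_scheme"), "`scheme` must be a grouping_scheme")
  tokens <- lapply(annotation$clusters$laminae, parse_laminae)
  names(tokens) <- annotation$clusters$cluster
  memberships <- lapply(scheme$groups, function(accepted) {
    in_group <- vapply(tokens, function(t) any(t %in% accepted), TRUE)
    clusters <- names(tokens)[in_group]
    annotation$cells$cell[annotation$cells$cluster %in% clusters]
  })
  memberships$DH <- annotation$cells$cell
  memberships
}

#' Counts-per-million normalization
#'
#' Each cell's counts are divided by that cell's total and scaled by 1e6,
#' so every retained cell's CPM column sums to one million. Cells with zero
#' total counts cannot be normalized and are dropped with a warning. All
#' genes in the matrix contribute to the denominator (no feature filtering
#' before normalization).
#'
#' @param counts genes x cells matrix (base or `Matrix` sparse) of
#'   nonnegative counts.
#' @return A CPM matrix of the same class, possibly with fewer columns.
#' @export
cpm_normalize <- function(counts) {
  check_that(length(dim(counts)) == 2, "`counts` must be a genes x cells matrix")
  check_that(min(counts) >= 0, "counts must be nonnegative")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (all(zero)) stop("every cell has zero total counts; CPM undefined", call. = FALSE)
  if (any(zero)) {
    warning(sprintf("dropping %d cell(s) with zero total counts", sum(zero)))
    counts <- counts[, !zero, drop = FALSE]
    totals <- totals[!zero]
  }
  if (inherits(counts, "Matrix")) {
    counts %*% Matrix::Diagonal(x = 1e6 / totals)
  } else {
    sweep(counts, 2, totals, "/") * 1e6
  }
}

#' Average CPM of a gene over a group of cells
#'
#' @param cpm CPM matrix from [cpm_normalize()] with gene row names and
#'   cell column names.
#' @param cells nonempty character vector of cell identifiers.
#' @param gene gene identifier.
#' @return Arithmetic mean CPM.
#' @export
average_cpm <- function(cpm, cells, gene) {
  check_that(length(cells) >= 1, "empty cell group")
  check_that(gene %in% rownames(cpm), paste("gene not in matrix:", gene))
  check_that(all(cells %in% colnames(cpm)), "unknown cell identifiers in group")
  mean(as.numeric(cpm[gene, cells]))
}

#' Percent of a group's cells expressing a gene
#'
#' Computed on raw counts: the fraction of cells with count > 0, times 100.
#'
#' @param counts genes x cells count matrix.
#' @param cells nonempty character vector of cell identifiers.
#' @param gene gene identifier.
#' @return Percent in `[0, 100]`.
#' @export
percent_expressed <- function(counts, cells, gene) {
  check_that(length(cells) >= 1, "empty cell group")
  check_that(gene %in% rownames(counts), paste("gene not in matrix:", gene))
  check_that(all(cells %in% colnames(counts)), "unknown cell identifiers in group")
  100 * sum(counts[gene, cells] > 0) / length(cells)
}

#' Z-score dot-plot color values for one gene
#'
#' Standardizes `log10(avg CPM + 1)` across the gene's displayed groups
#' using the population (divide-by-n) standard deviation, so the two-group
#' case gives exactly -1/+1. A single group, or zero variance across
#' groups, maps to z = 0 everywhere by convention.
#'
#' @param avg_cpm numeric vector of average CPM values, one per group.
#' @return Numeric z values of the same length (mean zero).
#' @export
color_zscore <- function(avg_cpm) {
  check_that(is.numeric(avg_cpm) && length(avg_cpm) >= 1, "need at least one value")
  check_that(all(avg_cpm >= 0), "average CPM must be >= 0")
  x <- log10(avg_cpm + 1)
  s <- pop_sd(x)
  if (length(x) == 1 || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Dot-plot summary table
#'
#' The full per-(gene, group) summary behind a dot plot: average CPM,
#' percent expressed, the z-scored color value, and group size.
#'
#' @param counts genes x cells count matrix with dimnames.
#' @param annotation a [cluster_annotation()] covering the matrix columns.
#' @param scheme a [grouping_scheme()].
#' @param genes target genes to display. Genes absent from the matrix are
#'   an error (all missing) or reported in a warning (some missing), never
#'   silently dropped.
#' @return A `dot_plot_table` data frame with columns `gene`, `group`,
#'   `avg_cpm`, `pct_expressed`, `z`, `n_cells`.
#' @export
dot_plot_table <- function(counts, annotation, scheme = grouping_scheme(),
                           genes) {
  check_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
             "`counts` needs gene row names and cell column names")
  missing <- setdiff(genes, rownames(counts))
  if (length(missing) == length(genes)) {
    stop("none of the target genes are present in the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(missing)) {
    warning("target genes absent from the matrix: ", paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  cpm <- cpm_normalize(counts)
  groups <- pool_groups(annotation, scheme)
  groups <- lapply(groups, intersect, colnames(cpm))
  check_that(all(vapply(groups, length, 1L) >= 1), "a pooled group has no cells")
  tab <- do.call(rbind, lapply(genes, function(g) {
    avg <- vapply(groups, function(cells) average_cpm(cpm, cells, g), 1)
    pct <- vapply(groups, function(cells) percent_expressed(counts, cells, g), 1)
    data.frame(gene = g, group = names(groups), avg_cpm = unname(avg),
               pct_expressed = unname(pct), z = color_zscore(unname(avg)),
               n_cells = unname(vapply(groups, length, 1L)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  class(tab) <- c("dot_plot_table", "data.frame")
  tab
}

#' Render a dot plot
#'
#' Gene x group grid with dot size proportional to percent expressed and
#' color mapped from the z-scored average expression on a fixed diverging
#' scale. Layout is deterministic: genes and groups keep their table order.
#'
#' @param table a [dot_plot_table()].
#' @param path output file (format from extension, e.g. `.pdf` or `.png`).
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_dot_plot <- function(table, path, width = 5, height = 3.5) {
  check_that(inherits(table, "data.frame") && nrow(table) > 0,
             "dot-plot table is empty")
  check_that(all(c("gene", "group", "pct_expressed", "z") %in% names(table)),
             "not a dot-plot table")
  tab <- as.data.frame(table)
  tab$gene <- factor(tab$gene, levels = unique(tab$gene))
  tab$group <- factor(tab$group, levels = unique(tab$group))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$gene)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$pct_expressed, color = .data$z)) +
    ggplot2::scale_size_area(name = "% expressed", limits = c(0, 100),
                             max_size = 10) +
    ggplot2::scale_color_gradient2(name = "z(log10(CPM+1))", low = "#2166AC",
                                   mid = "#F7F7F7", high = "#B2182B",
                                   limits = c(-2.5, 2.5), oob = scales_squish) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

# Clamp out-of-bounds values to the limits (avoids a scales dependency).
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @importFrom ggplot2 .data
NULL
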