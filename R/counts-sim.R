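#' Specify a clustered synthetic count matrix
#'
#' Describes a genes x cells negative-binomial count matrix with designated
#' neuronal clusters, each carrying a laminar annotation (so clusters can
#' later be pooled into SDH / DDH / dorsal-horn-overall groups). The
#' negative binomial is the standard overdispersion model for single-cell
#' and single-nucleus RNA counts; `dispersion` is the NB size parameter, so
#' the Poisson limit is recovered as `dispersion -> Inf`.
#'
#' @param genes character vector of gene identifiers.
#' @param clusters character vector of cluster names (e.g. `"Excit-1"`).
#' @param cells_per_cluster integer, scalar or one per cluster.
#' @param means genes x clusters matrix of NB means (>= 0); dimnames are
#'   set from `genes` and `clusters`.
#' @param dispersion NB size parameter (> 0): scalar or genes x clusters
#'   matrix. Use `Inf` for Poisson counts.
#' @param laminae character vector, one laminar annotation per cluster
#'   (e.g. `"laminae I-II"`, `"laminae III-VI"`).
#' @param classes optional excitatory/inhibitory class per cluster.
#' @param target_genes optional character vector of genes of interest
#'   (e.g. a CNR1 analog enriched in SDH clusters and a CNR2 analog that is
#'   near zero everywhere); must be a subset of `genes`.
#' @param seed integer seed.
#' @return An object of class `counts_spec`.
#' @export
counts_spec <- function(genes, clusters, cells_per_cluster, means,
                        dispersion = 2, laminae, classes = NULL,
                        target_genes = character(), seed = 1L) {
  means <- as.matrix(means)
  check_that(length(genes) == nrow(means) && length(clusters) == ncol(means),
             "`means` must be a genes x clusters matrix")
  check_that(!anyDuplicated(genes) && !anyDuplicated(clusters),
             "gene and cluster identifiers must be unique")
  check_that(all(means >= 0), "NB means must be >= 0")
  if (length(cells_per_cluster) == 1) {
    cells_per_cluster <- rep(cells_per_cluster, length(clusters))
  }
  check_that(length(cells_per_cluster) == length(clusters) && all(cells_per_cluster >= 1),
             "`cells_per_cluster` must be >= 1 for every cluster")
  if (is.matrix(dispersion)) {
    check_that(identical(dim(dispersion), dim(means)),
               "matrix `dispersion` must match `means` in shape")
    check_that(all(dispersion > 0), "dispersions must be > 0")
  } else {
    check_that(is_scalar_num(dispersion) || identical(dispersion, Inf),
               "`dispersion` must be a positive scalar or matrix")
    check_that(dispersion > 0, "dispersions must be > 0")
    dispersion <- matrix(dispersion, nrow(means), ncol(means))
  }
  check_that(length(laminae) == length(clusters),
             "every cluster needs a laminar annotation")
  check_that(all(nzchar(laminae)), "laminar annotations must be nonempty strings")
  check_that(all(target_genes %in% genes),
             paste("target genes absent from `genes`:",
                   paste(setdiff(target_genes, genes), collapse = ", ")))
  if (is.null(classes)) {
    classes <- ifelse(grepl("^I", clusters), "inhibitory", "excitatory")
  }
  dimnames(means) <- list(genes, clusters)
  dimnames(dispersion) <- list(genes, clusters)
  structure(list(genes = genes, clusters = clusters,
                 cells_per_cluster = as.integer(cells_per_cluster),
                 means = means, dispersion = dispersion,
                 laminae = laminae, classes = classes,
                 target_genes = target_genes, seed = as.integer(seed)),
            class = "counts_spec")
}

#' Default synthetic count-matrix specification
#'
#' A small dorsal-horn-like design: excitatory and inhibitory clusters
#' spanning superficial and deeper laminae, a `Cnr1`-analog with 10x higher
#' mean in SDH-annotated clusters, a `Cnr2`-analog with near-zero mean
#' everywhere, and background genes shared across clusters.
#'
#' @param n_background number of background genes besides the two targets.
#' @param cells_per_cluster cells per cluster.
#' @param seed integer seed.
#' @return A [counts_spec()].
#' @export
default_counts_spec <- function(n_background = 48, cells_per_cluster = 150, seed = 1L) {
  clusters <- c("Excit-1", "Excit-2", "Excit-3", "Inhib-1", "Inhib-2", "Inhib-3")
  laminae <- c("laminae I-II", "lamina IIo", "laminae III-IV",
               "laminae I-II", "lamina IIi", "laminae III-VI")
  genes <- c("Cnr1", "Cnr2", sprintf("Bg%02d", seq_len(n_background)))
  sdh_cluster <- vapply(laminae, function(ann) {
    any(parse_laminae(ann) %in% c("I", "II", "IIo"))
  }, TRUE)
  means <- matrix(0, length(genes), length(clusters),
                  dimnames = list(genes, clusters))
  means["Cnr1", ] <- ifelse(sdh_cluster, 5, 0.5)
  means["Cnr2", ] <- 0.01
  bg <- with_seed(split_seed(seed, 0L),
                  matrix(rlnorm(n_background * length(clusters), meanlog = 0.5, sdlog = 1),
                         n_background, length(clusters)))
  means[-(1:2), ] <- bg
  counts_spec(genes = genes, clusters = clusters,
              cells_per_cluster = cells_per_cluster, means = means,
              dispersion = 2, laminae = laminae,
              target_genes = c("Cnr1", "Cnr2"), seed = seed)
}

#' Generate a synthetic clustered count matrix
#'
#' @param spec a [counts_spec()].
#' @return A list with `counts` (integer genes x cells matrix, cell names
#'   `<cluster>.<index>`) and `annotation` (a [cluster_annotation()]).
#' @export
generate_counts <- function(spec) {
  check_that(inherits(spec, "counts_spec"), "`spec` must come from counts_spec()")
  blocks <- with_seed(spec$seed, {
    lapply(seq_along(spec$clusters), function(j) {
      nc <- spec$cells_per_cluster[j]
      mu <- spec$means[, j]
      size <- spec$dispersion[, j]
      m <- matrix(0L, length(spec$genes), nc)
      for (i in seq_along(mu)) {
        if (mu[i] == 0) next
        m[i, ] <- if (is.infinite(size[i])) {
          rpois(nc, lambda = mu[i])
        } else {
          rnbinom(nc, mu = mu[i], size = size[i])
        }
      }
      m
    })
  })
  counts <- do.call(cbind, blocks)
  rownames(counts) <- spec$genes
  cell_cluster <- rep(spec$clusters, spec$cells_per_cluster)
  colnames(counts) <- paste(cell_cluster,
                            unlist(lapply(spec$cells_per_cluster, seq_len)),
                            sep = ".")
  ann <- cluster_annotation(
    cells = data.frame(cell = colnames(counts), cluster = cell_cluster,
                       stringsAsFactors = FALSE),
    clusters = data.frame(cluster = spec$clusters, laminae = spec$laminae,
                          class = spec$classes, stringsAsFactors = FALSE)
  )
  list(counts = counts, annotation = ann)
}
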