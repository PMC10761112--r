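#' Validate a pipeline configuration
#'
#' Configurations are plain named lists (or a YAML file path); the schema
#' is checked before any work is done and unknown keys are rejected, so a
#' typo fails fast instead of silently using a default.
#'
#' @param config named list or path to a YAML file.
#' @param pipeline `"ihc"`, `"expression"`, or `"synth"`.
#' @return The validated config list with defaults filled in.
#' @export
validate_config <- function(config, pipeline = c("ihc", "expression", "synth")) {
  pipeline <- match.arg(pipeline)
  if (is.character(config) && length(config) == 1) {
    check_that(file.exists(config), paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  check_that(is.list(config), "`config` must be a named list or a YAML path")
  schema <- switch(pipeline,
    ihc = list(
      input_dir = NULL, n_per_cell = 6L, replicates = 3L,
      sexes = c("female", "male"), species = "rat", segment = "lumbar",
      rho = 1.78, phantom = list(), roi_source = "segment",
      segmentation = list(), ratio_variant = "ratio-of-means",
      alpha = 0.05, test_mode = "asymptotic", out_dir = NULL, seed = 1L
    ),
    expression = list(
      input_dir = NULL, n_background = 48L, cells_per_cluster = 150L,
      target_genes = c("Cnr1", "Cnr2"), scheme = NULL,
      out_dir = NULL, seed = 1L
    ),
    synth = list(
      out_dir = NULL, n_per_cell = 6L, replicates = 3L,
      sexes = c("female", "male"), species = "rat", segment = "lumbar",
      rho = 1.78, phantom = list(), counts = TRUE, seed = 1L
    )
  )
  unknown <- setdiff(names(config), names(schema))
  check_that(length(unknown) == 0,
             paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  check_that(!is.null(names(config)) || length(config) == 0,
             "config entries must be named")
  out <- utils::modifyList(schema, config)
  if (pipeline %in% c("ihc", "synth")) {
    check_that(out$n_per_cell >= 1, "`n_per_cell` must be >= 1")
    check_that(out$replicates >= 1, "`replicates` must be >= 1")
    check_that(out$rho > 0, "`rho` must be > 0")
    check_that((out$ratio_variant %||% "ratio-of-means") %in%
                 c("ratio-of-means", "mean-of-ratios"),
               "`ratio_variant` must be ratio-of-means or mean-of-ratios")
  }
  if (!is.null(out$input_dir)) {
    check_that(dir.exists(out$input_dir),
               paste("input directory not found:", out$input_dir))
  }
  check_that(!is.null(out$out_dir), "`out_dir` is required")
  out
}

ihc_phantom_params <- function(config) {
  do.call(phantom_params, utils::modifyList(list(rho = config$rho), config$phantom))
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  writeLines(msg, con)
  message(msg)
}

#' Run the imaging (densitometry + statistics) pipeline
#'
#' End to end: obtain a cohort of two-channel sections (synthesized from
#' the config, or read from `input_dir` as written by
#' [write_synthetic_fixtures()]), derive ROIs, measure background-
#' normalized optical densities, aggregate technical replicates per
#' subject, and run the statistical battery:
#'
#' * paired SDH vs DDH comparison (Wilcoxon signed-rank) per sex x species
#'   cell,
#' * assumption-gated comparison of SDH/DDH ratios across sex within each
#'   species (and across species when both are present),
#' * a two-way aligned rank transform ANOVA across sex x species for the
#'   SDH values, the DDH values and the ratios (requires two levels of
#'   each factor).
#'
#' Writes `slides.csv`, `cohort.csv`, `stats.json` and `run.log` under
#' `out_dir`.
#'
#' @param config named list or YAML path; see [validate_config()] keys for
#'   `"ihc"`.
#' @return A list with `slides`, `cohort`, `stats`, `paths`.
#' @export
run_ihc_pipeline <- function(config) {
  config <- validate_config(config, "ihc")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  log_line(con, "ihc pipeline: seed %d, roi_source %s", config$seed, config$roi_source)

  stage <- "cohort generation"
  result <- tryCatch({
    cohort <- if (is.null(config$input_dir)) {
      spec <- cohort_spec(n_per_cell = config$n_per_cell,
                          replicates = config$replicates,
                          sexes = config$sexes, species = config$species,
                          params = ihc_phantom_params(config),
                          segment = config$segment,
                          master_seed = config$seed)
      generate_cohort(spec)
    } else {
      read_fixture_cohort(config$input_dir)
    }
    log_line(con, "cohort: %d sections, %d subjects", length(cohort$sections),
             length(unique(cohort$metadata$subject)))

    stage <- "densitometry"
    seg <- do.call(segmentation_params, config$segmentation)
    measured <- measure_cohort(cohort, roi_source = config$roi_source,
                               seg_params = seg)
    tab <- measured$cohort
    if (config$ratio_variant == "mean-of-ratios") {
      tab$ratio_primary <- tab$ratio_slidewise
    } else {
      tab$ratio_primary <- tab$ratio
    }

    stage <- "statistics"
    stats_out <- ihc_statistics(tab, alpha = config$alpha,
                                mode = config$test_mode)
    log_line(con, "statistics: %d tests", length(stats_out$tests))

    stage <- "output"
    paths <- c(slides = file.path(config$out_dir, "slides.csv"),
               cohort = file.path(config$out_dir, "cohort.csv"),
               stats = file.path(config$out_dir, "stats.json"),
               log = log_path)
    write_cohort_csv(measured$slides, paths[["slides"]])
    write_cohort_csv(tab, paths[["cohort"]])
    jsonlite::write_json(stats_json(stats_out, config), paths[["stats"]],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(con, "done")
    list(slides = measured$slides, cohort = tab, stats = stats_out, paths = paths)
  }, error = function(e) {
    log_line(con, "ABORT in stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("ihc pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

# The statistical battery over a per-subject cohort table.
ihc_statistics <- function(tab, alpha = 0.05, mode = "asymptotic") {
  tests <- list()
  cells <- unique(tab[, c("sex", "species")])
  for (i in seq_len(nrow(cells))) {
    sub <- tab[tab$sex == cells$sex[i] & tab$species == cells$species[i], ]
    if (nrow(sub) < 3) next
    key <- sprintf("paired_sdh_vs_ddh.%s.%s", cells$sex[i], cells$species[i])
    tests[[key]] <- wilcoxon_signed_rank(sub$sdh, sub$ddh, mode = mode)
  }
  for (sp in unique(tab$species)) {
    sub <- tab[tab$species == sp, ]
    sexes <- unique(sub$sex)
    if (length(sexes) != 2) next
    groups <- split(sub$ratio_primary, sub$sex)
    if (any(vapply(groups, length, 1L) < 3)) next
    rep <- assumption_checks(groups, alpha)
    plan <- select_test("independent", rep)
    key <- sprintf("ratio_across_sex.%s", sp)
    tests[[key]] <- if (plan$test == "one_way_anova") {
      one_way_anova(groups)
    } else {
      mann_whitney_u(groups[[1]], groups[[2]], mode = mode)
    }
    tests[[key]]$notes <- c(tests[[key]]$notes, plan$note)
  }
  if (length(unique(tab$species)) == 2) {
    groups <- split(tab$ratio_primary, tab$species)
    if (all(vapply(groups, length, 1L) >= 3)) {
      rep <- assumption_checks(groups, alpha)
      plan <- select_test("independent", rep)
      tests[["ratio_across_species"]] <- if (plan$test == "one_way_anova") {
        one_way_anova(groups)
      } else {
        mann_whitney_u(groups[[1]], groups[[2]], mode = mode)
      }
      tests[["ratio_across_species"]]$notes <-
        c(tests[["ratio_across_species"]]$notes, plan$note)
    }
  }
  art <- list()
  if (length(unique(tab$sex)) == 2 && length(unique(tab$species)) == 2 &&
      all(table(tab$sex, tab$species) >= 2)) {
    for (response in c("sdh", "ddh", "ratio_primary")) {
      art[[response]] <- art_anova(tab[[response]], tab$sex, tab$species, alpha)
    }
  }
  list(tests = tests, art = art, alpha = alpha)
}

stats_json <- function(stats_out, config) {
  list(
    provenance = list(
      package = "dhquant",
      version = as.character(utils::packageVersion("dhquant")),
      seed = config$seed,
      alpha = stats_out$alpha,
      config_hash = substr(jsonlite::base64_enc(serialize(config, NULL)), 1, 24)
    ),
    tests = lapply(stats_out$tests, function(t) {
      list(method = t$method, mode = t$mode,
           statistic = as.list(t$statistic), p = t$p,
           n = as.list(t$n), notes = t$notes)
    }),
    art = lapply(stats_out$art, function(a) {
      list(effects = a$effects,
           max_abs_aligned_sum = max(abs(a$diagnostics$aligned_sum)))
    })
  )
}

#' Run the expression (dot-plot) pipeline
#'
#' Obtains a clustered count matrix (synthesized, or read from an MTX
#' bundle under `input_dir`), builds the dot-plot table over the pooled
#' laminar groups, and writes `dot_plot.csv`, `dot_plot.pdf` and `run.log`
#' under `out_dir`.
#'
#' @param config named list or YAML path; see [validate_config()] keys for
#'   `"expression"`.
#' @return A list with `table` and `paths`.
#' @export
run_expression_pipeline <- function(config) {
  config <- validate_config(config, "expression")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  log_line(con, "expression pipeline: seed %d", config$seed)

  stage <- "counts"
  result <- tryCatch({
    data <- if (is.null(config$input_dir)) {
      generate_counts(default_counts_spec(
        n_background = config$n_background,
        cells_per_cluster = config$cells_per_cluster,
        seed = config$seed
      ))
    } else {
      read_counts_mtx(config$input_dir)
    }
    log_line(con, "counts: %d genes x %d cells", nrow(data$counts), ncol(data$counts))

    stage <- "summarization"
    scheme <- if (is.null(config$scheme)) grouping_scheme() else {
      grouping_scheme(lapply(config$scheme, unlist))
    }
    tab <- dot_plot_table(data$counts, data$annotation, scheme,
                          genes = config$target_genes)

    stage <- "output"
    paths <- c(table = file.path(config$out_dir, "dot_plot.csv"),
               figure = file.path(config$out_dir, "dot_plot.pdf"),
               log = log_path)
    utils::write.csv(as.data.frame(tab), paths[["table"]], row.names = FALSE)
    render_dot_plot(tab, paths[["figure"]])
    log_line(con, "done")
    list(table = tab, paths = paths)
  }, error = function(e) {
    log_line(con, "ABORT in stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("expression pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  result
}

#' Write a directory of synthetic fixtures
#'
#' Materializes a phantom cohort (multichannel TIFFs, PNG ground-truth
#' masks, JSON provenance sidecars, `cohort_metadata.csv`) and, optionally,
#' a count-matrix bundle under `out_dir/counts`. [validate_fixtures()]
#' checks such a directory.
#'
#' @param config named list or YAML path; see [validate_config()] keys for
#'   `"synth"`.
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(config) {
  config <- validate_config(config, "synth")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(n_per_cell = config$n_per_cell,
                      replicates = config$replicates,
                      sexes = config$sexes, species = config$species,
                      params = ihc_phantom_params(config),
                      segment = config$segment, master_seed = config$seed)
  cohort <- generate_cohort(spec)
  meta <- cohort$metadata
  meta$stem <- sprintf("%s_r%d", meta$subject, meta$replicate)
  for (i in seq_along(cohort$sections)) {
    write_phantom(cohort$sections[[i]], file.path(config$out_dir, "sections"),
                  stem = meta$stem[i])
  }
  utils::write.csv(meta, file.path(config$out_dir, "cohort_metadata.csv"),
                   row.names = FALSE)
  if (isTRUE(config$counts)) {
    data <- generate_counts(default_counts_spec(seed = config$seed))
    write_counts_mtx(data$counts, data$annotation, file.path(config$out_dir, "counts"))
  }
  invisible(config$out_dir)
}

read_fixture_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort_metadata.csv")
  check_that(file.exists(meta_path), paste("no cohort_metadata.csv under", dir))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  sections <- lapply(seq_len(nrow(meta)), function(i) {
    ph <- read_phantom(file.path(dir, "sections"), meta$stem[i])
    structure(list(cb1 = ph$cb1, cgrp = ph$cgrp, rois = ph$rois,
                   horn_mask = ph$horn_mask, params = ph$provenance,
                   subject_id = meta$subject[i],
                   replicate_index = meta$replicate[i], seed = meta$seed[i]),
              class = "section_phantom")
  })
  list(sections = sections, metadata = meta)
}

#' Validate a synthetic fixture directory
#'
#' Re-reads every section and the optional counts bundle, checking ROI-set
#' invariants, channel shape agreement and metadata joins.
#'
#' @param dir fixture directory from [write_synthetic_fixtures()].
#' @return `TRUE` invisibly; errors describe the first failure.
#' @export
validate_fixtures <- function(dir) {
  cohort <- read_fixture_cohort(dir)
  for (sec in cohort$sections) {
    check_that(identical(dim(sec$cb1), dim(sec$cgrp)),
               "channel dimensions disagree")
    check_that(inherits(sec$rois, "roi_set"), "invalid ROI set")
    check_that(all(sec$cb1 >= 0) && all(sec$cgrp >= 0), "negative pixel values")
  }
  counts_dir <- file.path(dir, "counts")
  if (dir.exists(counts_dir)) {
    data <- read_counts_mtx(counts_dir)
    check_that(all(data$counts >= 0), "negative counts")
    check_that(setequal(colnames(data$counts), data$annotation$cells$cell),
               "cell identifiers disagree between matrix and annotation")
  }
  invisible(TRUE)
}
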