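#' Pipeline configuration
#'
#' Bundles all stage configurations for [run_pipeline()].  Input PSMs come
#' either from the synthetic generator (`generator`, with ground truth for
#' the recovery report) or from an existing PSM table on disk
#' (`psm_table`).
#'
#' @param generator A [generator_config()], or `NULL` when reading from
#'   `psm_table`.
#' @param psm_table Optional path to a PSM table; overrides `generator`.
#' @param filter A [filter_config()].
#' @param threshold Regulation threshold in channel standard deviations.
#' @param robust_sd Use the MAD-based channel scale (see
#'   [fit_tag_distribution()]).
#' @param strict_merge Require cross-experiment concordance when merging
#'   duplicates (see [merge_experiments()]).
#' @param pool_fdr Estimate q-values over all experiments pooled instead
#'   of per labeling experiment.
#' @param annotation,edges Optional paths to an annotation table and an
#'   interaction edge list for the downstream summaries.
#' @param score_cutoff Edge-confidence cutoff for the network summary.
#' @param out_dir Optional directory; when given, every stage output and a
#'   JSON run report are written there.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            psm_table = NULL,
                            filter = filter_config(),
                            threshold = 2,
                            robust_sd = FALSE,
                            strict_merge = FALSE,
                            pool_fdr = FALSE,
                            annotation = NULL,
                            edges = NULL,
                            score_cutoff = 0.4,
                            out_dir = NULL) {
  if (is.null(psm_table)) {
    if (!inherits(generator, "generator_config"))
      stop("'generator' must be a generator_config() when no psm_table is given",
           call. = FALSE)
  } else if (!file.exists(psm_table)) {
    stop("psm_table '", psm_table, "' does not exist", call. = FALSE)
  }
  if (!inherits(filter, "filter_config"))
    stop("'filter' must be a filter_config()", call. = FALSE)
  for (p in c(annotation, edges))
    if (!is.null(p) && !file.exists(p))
      stop("file '", p, "' does not exist", call. = FALSE)
  structure(list(generator = generator, psm_table = psm_table,
                 filter = filter, threshold = threshold,
                 robust_sd = robust_sd, strict_merge = strict_merge,
                 pool_fdr = pool_fdr, annotation = annotation,
                 edges = edges, score_cutoff = score_cutoff,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `generator` and `filter` sections hold the arguments of
#' [generator_config()] and [filter_config()].
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("generator", "filter"))]
  args$generator <- if (is.null(y$generator)) generator_config() else
    do.call(generator_config, y$generator)
  args$filter <- if (is.null(y$filter)) filter_config() else
    do.call(filter_config, y$filter)
  do.call(pipeline_config, args)
}

.pipeline_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  res
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> estimate q-values -> filter -> aggregate to
#' protein ratios -> median-normalize -> merge duplicate experiments ->
#' fit per-channel distributions -> call regulation for both contrasts ->
#' classify by the two treatment-contrast criteria -> optional
#' molecular-function and network summaries.  With synthetic input the
#' report additionally scores group recovery against ground truth.
#' Identical configuration (including the generator seed) gives an
#' identical report.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `"pipeline_report"`: list with stage counts
#'   (`n_psms_in`, `n_psms_filtered`, `n_decoys_in`, `n_proteins`,
#'   `n_regulated_vehicle`, `n_regulated_u0126`, `group_sizes`), the
#'   fitted `distributions`, normalization `offsets`, result tables
#'   (`ratios`, `calls_vehicle`, `calls_u0126`, `groups`) and, when ground
#'   truth is available, `recovery` with sensitivity and specificity of
#'   group-1 and group-2 recovery.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be created by pipeline_config()", call. = FALSE)

  truth <- NULL
  if (!is.null(config$psm_table)) {
    psms <- .pipeline_stage(NULL, "read",
                            read_psm_table(config$psm_table))
  } else {
    sim <- .pipeline_stage(NULL, "simulate",
                           generate_experiment(config$generator))
    psms <- sim$psms
    truth <- sim$truth
  }

  psms <- .pipeline_stage(NULL, "qvalues",
                          estimate_qvalues(psms,
                                           per_experiment = !config$pool_fdr))
  filtered <- .pipeline_stage(NULL, "filter",
                              apply_psm_filter(psms, config$filter))
  ratios <- .pipeline_stage(NULL, "quantify", {
    agg <- aggregate_protein(filtered)
    norm <- median_normalize(agg)
    merged <- merge_experiments(norm$ratios, strict = config$strict_merge)
    list(merged = merged, offsets = norm$offsets)
  })

  dist_v <- .pipeline_stage(NULL, "fit_vehicle",
                            fit_tag_distribution(ratios$merged, "vehicle",
                                                 robust = config$robust_sd))
  dist_u <- .pipeline_stage(NULL, "fit_u0126",
                            fit_tag_distribution(ratios$merged, "u0126",
                                                 robust = config$robust_sd))
  calls_v <- call_regulation(ratios$merged, dist_v, config$threshold)
  calls_u <- call_regulation(ratios$merged, dist_u, config$threshold)
  groups <- .pipeline_stage(NULL, "classify",
                            classify_contrast(calls_v, calls_u))

  report <- list(
    n_psms_in = nrow(psms),
    n_decoys_in = sum(psms$is_decoy),
    n_psms_filtered = nrow(filtered),
    n_proteins = length(unique(ratios$merged$accession)),
    n_regulated_vehicle = sum(calls_v$status != "unchanged"),
    n_regulated_u0126 = sum(calls_u$status != "unchanged"),
    group_sizes = vapply(c("group1", "group2", "persistent_up",
                           "persistent_down", "none"),
                         function(g) sum(groups$group == g), 0L),
    distributions = list(vehicle = dist_v, u0126 = dist_u),
    offsets = ratios$offsets,
    ratios = ratios$merged,
    calls_vehicle = calls_v,
    calls_u0126 = calls_u,
    groups = groups
  )

  if (!is.null(truth)) {
    score_group <- function(label, positive) {
      called <- groups$accession[groups$group == label]
      pos <- truth$accession[positive]
      neg <- setdiff(truth$accession, pos)
      tp <- sum(pos %in% called)
      tn <- sum(!neg %in% called)
      list(sensitivity = if (length(pos)) tp / length(pos) else NA_real_,
           specificity = if (length(neg)) tn / length(neg) else NA_real_)
    }
    report$recovery <- list(
      group1 = score_group("group1",
                           truth$status_vehicle == "up" & truth$reversed),
      group2 = score_group("group2",
                           truth$status_vehicle == "down" & truth$reversed))
    report$truth <- truth
  }

  if (!is.null(config$annotation)) {
    ann <- read_annotation(config$annotation)
    report$category_breakdown <- list(
      group1 = summarize_categories(groups$accession[groups$group == "group1"],
                                    ann),
      group2 = summarize_categories(groups$accession[groups$group == "group2"],
                                    ann))
  }
  if (!is.null(config$edges)) {
    ed <- read_edges(config$edges)
    report$network <- list(
      group1 = network_components(groups$accession[groups$group == "group1"],
                                  ed, config$score_cutoff),
      group2 = network_components(groups$accession[groups$group == "group2"],
                                  ed, config$score_cutoff))
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) .write_pipeline_outputs(report, config)
  report
}

.write_pipeline_outputs <- function(report, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(report$ratios, p("protein_ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$calls_vehicle, p("calls_vehicle.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$calls_u0126, p("calls_u0126.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$groups, p("groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- report[c("n_psms_in", "n_decoys_in", "n_psms_filtered",
                      "n_proteins", "n_regulated_vehicle",
                      "n_regulated_u0126")]
  summary$group_sizes <- as.list(report$group_sizes)
  if (!is.null(report$recovery)) summary$recovery <- report$recovery
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("iTRAQ regulation pipeline report\n")
  cat(sprintf("  PSMs: %d in (%d decoys) -> %d after FDR/score filter\n",
              x$n_psms_in, x$n_decoys_in, x$n_psms_filtered))
  cat(sprintf("  proteins quantified: %d\n", x$n_proteins))
  cat(sprintf("  regulated: %d (vehicle vs sham), %d (U0126 vs sham)\n",
              x$n_regulated_vehicle, x$n_regulated_u0126))
  gs <- x$group_sizes
  cat(sprintf("  groups: group1 %d, group2 %d, persistent %d up / %d down\n",
              gs[["group1"]], gs[["group2"]], gs[["persistent_up"]],
              gs[["persistent_down"]]))
  if (!is.null(x$recovery))
    cat(sprintf("  group-1 recovery: sensitivity %.3f, specificity %.3f\n",
                x$recovery$group1$sensitivity, x$recovery$group1$specificity))
  invisible(x)
}
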