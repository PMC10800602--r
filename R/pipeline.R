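#' Run the full dysfunction-connectome analysis
#'
#' Executes the whole pipeline on a cohort of ROI time series: per-subject
#' Pearson FC, cohort-wide magnitude screening, edge-wise group regression
#' adjusting for age and sex, Bonferroni binarization into a signed
#' dysfunction graph, single-/network-FC classification with per-region
#' ratios and the whole-brain summary, hub/module detection, and the
#' head-motion QC comparison. Results can optionally be written to an
#' output directory (edge lists with JSON sidecars, per-region ratio CSV,
#' module JSON).
#'
#' @param timeseries list of `roi_ts` objects (one per subject, same order
#'   as `meta`).
#' @param meta subject metadata data.frame.
#' @param r_threshold screening threshold on `|r|` (default 0.23).
#' @param policy screening policy, see [consensus_screen()].
#' @param alpha family-wise level for the Bonferroni step (default 0.05).
#' @param m number of comparisons; `NULL` = all atlas pairs.
#' @param seeds optional hub-seed override for [detect_modules()].
#' @param output_dir optional directory for on-disk outputs.
#' @return list of class `dysconn_result`: `fcs`, `mask`, `edge_tests`,
#'   `graph`, `degree`, `classifications`, `edge_classes`, `summary`,
#'   `ratio_map`, `modules`, `motion_qc`.
#' @export
run_pipeline <- function(timeseries, meta, r_threshold = 0.23,
                         policy = "all", alpha = 0.05, m = NULL,
                         seeds = NULL, output_dir = NULL) {
  assert_that(length(timeseries) == nrow(meta),
              "one time series per metadata row required")
  fcs <- lapply(timeseries, compute_fc)
  mask <- consensus_screen(fcs, r_threshold = r_threshold, policy = policy)
  tests <- test_all_edges(fcs, meta, mask)
  nodes <- colnames(mask)
  graph <- bonferroni_binarize(tests, nodes, alpha = alpha, m = m)
  cls <- classify_all_regions(graph)
  modules <- if (nrow(graph$edges) > 0) detect_modules(graph, seeds) else NULL
  res <- structure(list(
    fcs = fcs,
    mask = mask,
    edge_tests = tests,
    graph = graph,
    degree = degree_profile(graph),
    classifications = cls,
    edge_classes = classify_edges(graph),
    summary = whole_brain_summary(cls),
    ratio_map = ratio_map(cls),
    modules = modules,
    motion_qc = if ("fd_power" %in% names(meta) &&
                    !anyNA(meta$fd_power)) compare_motion(meta) else NULL),
    class = "dysconn_result")
  if (!is.null(output_dir)) write_results(res, output_dir)
  res
}

#' @export
print.dysconn_result <- function(x, ...) {
  cat("dysfunction-connectome analysis\n")
  cat("  screened edges:", sum(x$mask) / 2,
      sprintf("(|r| > %g, policy '%s')\n", attr(x$mask, "r_threshold"),
              attr(x$mask, "policy")))
  print(x$graph)
  bd <- x$degree$breakdown
  cat(sprintf("  regions: %d isolated, %d with one edge, %d with several\n",
              bd["n_zero"], bd["n_one"], bd["n_multi"]))
  s <- x$summary
  cat(sprintf("  favour single-FC: %.1f%%, favour network-FC: %.1f%%\n",
              s$pct_favor_single, s$pct_favor_network))
  invisible(x)
}

# write the standard output tree for a pipeline result
write_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(res$mask, file.path(dir, "screened_edges.tsv"))
  stats <- res$edge_tests
  stats$survives_bonferroni <- stats$p_value < res$graph$alpha / res$graph$m
  stats$sign <- ifelse(stats$t_stat > 0, "increased", "decreased")
  write.table(stats, file.path(dir, "edge_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_edge_list(res$graph, file.path(dir, "dysfunction_graph.tsv"))
  cls <- do.call(rbind, lapply(res$classifications, function(cl) {
    data.frame(region = cl$region, n_single = cl$n_single,
               n_network = cl$n_network, degree = cl$degree,
               single_ratio = cl$single_ratio,
               network_ratio = cl$network_ratio,
               stringsAsFactors = FALSE)
  }))
  write.csv(cls, file.path(dir, "region_classification.csv"),
            row.names = FALSE)
  out <- list(summary = res$summary)
  if (!is.null(res$modules)) {
    out$hub_seeds <- res$modules$hub_seeds
    out$levels <- as.list(res$modules$levels)
    out$network_modules <- res$modules$network_modules
  }
  if (!is.null(res$motion_qc)) out$motion_qc <- res$motion_qc
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
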