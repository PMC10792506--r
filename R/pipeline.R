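#' Run the full TF/CWP prioritization pipeline
#'
#' Executes the stages in order: per-experiment DEG calling; binomial
#' stable-DEG calling; orphan-CWP pruning of the network; drought-process TF
#' filter; restriction of TFs to stable DEGs; per-TF per-experiment
#' hypergeometric enrichment; STF computation; priority-TF selection; network
#' reduction; SCWP computation; ranking; and functional-class summary.
#' Deterministic given its inputs: re-running with the same inputs reproduces
#' identical outputs.
#'
#' Supply exactly one of `experiments` (expression matrices; DE statistics are
#' computed with [compute_de_table()]) or `de_tables` (precomputed
#' differential-expression results).
#'
#' @param network A [regnet()] object.
#' @param experiments List of expression experiments (see
#'   [read_expression_experiment()]).
#' @param de_tables List of DE tibbles or one stacked tibble with
#'   `experiment_id`.
#' @param p_threshold,lfc_threshold Per-experiment DEG thresholds
#'   ([call_degs()]).
#' @param p0,alpha_stable Binomial vote-counting parameters
#'   ([call_stable_degs()]).
#' @param alpha_enrich Enrichment significance level ([tf_enrichment()]).
#' @param filter A [process_filter()]; `NULL` skips the process-filter stage.
#' @param scwp_mode `"reduced"` (default) computes SCWP on the reduced
#'   priority-TF network; `"prefilter"` computes it on the network as it
#'   stood before priority reduction (after the stable-DEG restriction).
#' @param universe Gene universe for the enrichment tests. `"pruned"`
#'   (default): all CWP genes with at least one TF interaction (the
#'   orphan-pruned network) that were measured in the experiment — the whole
#'   TF-connected cell wall gene set, so a drought TF's target list is judged
#'   against cell wall genes at large. `"filtered"`: only CWP genes surviving
#'   the process and stable-DEG filters (a much narrower universe that can
#'   saturate when most remaining genes respond). `"measured"`: every gene
#'   measured in the experiment.
#' @param adjust P-value adjustment across TFs within each experiment
#'   (default `"none"`).
#' @return An object of class `tfprio_result`: a list with `de_tables`
#'   (stacked tibble), `stable_degs`, `networks` (list: `input`, `pruned`,
#'   `process_filtered`, `stable_restricted`, `reduced`), `enrichment`,
#'   `tf_scores`, `priority_tfs`, `cwp_scores`, `class_summary`, `stages`
#'   (node/edge counts per stage) and `params`.
#' @export
run_pipeline <- function(network,
                         experiments = NULL,
                         de_tables = NULL,
                         p_threshold = 0.05,
                         lfc_threshold = 1.0,
                         p0 = 0.05,
                         alpha_stable = 0.05,
                         alpha_enrich = 0.05,
                         filter = process_filter(),
                         scwp_mode = c("reduced", "prefilter"),
                         universe = c("pruned", "filtered", "measured"),
                         adjust = "none") {
  stopifnot(inherits(network, "tfprio_regnet"))
  scwp_mode <- match.arg(scwp_mode)
  universe <- match.arg(universe)
  if (is.null(experiments) == is.null(de_tables)) {
    abort("supply exactly one of `experiments` or `de_tables`.")
  }
  for (thr in c(p_threshold, alpha_stable, alpha_enrich)) {
    if (thr <= 0 || thr > 1) abort("significance thresholds must lie in (0, 1].")
  }

  raw <- if (!is.null(experiments)) {
    purrr::map(experiments, compute_de_table)
  } else if (is.data.frame(de_tables)) {
    split(de_tables, de_tables$experiment_id)
  } else {
    de_tables
  }
  de <- purrr::map(raw, call_degs,
                   p_threshold = p_threshold, lfc_threshold = lfc_threshold)

  stable <- call_stable_degs(de, p0 = p0, alpha = alpha_stable)

  nets <- list(input = network)
  nets$pruned <- prune_unconnected_targets(network)
  nets$process_filtered <- if (is.null(filter)) {
    nets$pruned
  } else {
    filter_tfs_by_process(nets$pruned, filter)
  }
  nets$stable_restricted <- restrict_tfs_to_stable_degs(nets$process_filtered, stable)

  enrichment <- if (length(tf_ids(nets$stable_restricted)) == 0 ||
                    length(cwp_ids(nets$stable_restricted)) == 0) {
    empty_enrichment()
  } else {
    purrr::map(de, function(tbl) {
      uni <- switch(universe,
        pruned = intersect(cwp_ids(nets$pruned), tbl$gene_id),
        filtered = NULL,
        measured = "measured"
      )
      tf_enrichment(nets$stable_restricted, tbl, universe = uni,
                    alpha_enrich = alpha_enrich, adjust = adjust)
    }) |> dplyr::bind_rows()
  }

  stf <- compute_stf(enrichment)
  priority <- select_priority_tfs(stf)
  nets$reduced <- reduce_network(nets$stable_restricted, priority)

  scwp_net <- if (scwp_mode == "reduced") nets$reduced else nets$stable_restricted
  scwp <- compute_scwp(scwp_net)

  tf_scores <- build_tf_scores(stf, enrichment, priority)
  cwp_scores <- build_cwp_scores(scwp, scwp_net, stable)
  summary_tbl <- class_summary(nets$reduced, stable)

  stages <- purrr::imap(nets, function(n, name) {
    tibble::tibble(stage = name,
                   n_tf = length(tf_ids(n)),
                   n_cwp = length(cwp_ids(n)),
                   n_edges = nrow(n$edges))
  }) |> dplyr::bind_rows()

  structure(
    list(
      de_tables = dplyr::bind_rows(de),
      stable_degs = stable,
      networks = nets,
      enrichment = enrichment,
      tf_scores = tf_scores,
      priority_tfs = priority,
      cwp_scores = cwp_scores,
      class_summary = summary_tbl,
      stages = stages,
      params = list(p_threshold = p_threshold, lfc_threshold = lfc_threshold,
                    p0 = p0, alpha_stable = alpha_stable,
                    alpha_enrich = alpha_enrich, scwp_mode = scwp_mode,
                    universe = universe, adjust = adjust)
    ),
    class = "tfprio_result"
  )
}

build_tf_scores <- function(stf, enrichment, priority) {
  pvals <- enrichment |>
    dplyr::select("tf_id", "experiment_id", "p_value") |>
    tidyr::pivot_wider(names_from = "experiment_id", values_from = "p_value",
                       names_prefix = "p_")
  if (nrow(stf) == 0) {
    return(tibble::tibble(tf_id = character(), stf = integer(),
                          priority = logical(), rank = integer()))
  }
  rank_scores(stf, "tf_id", "stf") |>
    dplyr::left_join(pvals, by = "tf_id") |>
    dplyr::mutate(priority = .data$tf_id %in% priority) |>
    dplyr::relocate("rank", .after = dplyr::last_col())
}

build_cwp_scores <- function(scwp, net, stable) {
  if (nrow(scwp) == 0) {
    return(tibble::tibble(gene_id = character(), scwp = integer(),
                          functional_class = character(),
                          stable_direction = integer(), rank = integer()))
  }
  rank_scores(scwp, "gene_id", "scwp") |>
    dplyr::left_join(net$cwp_classes, by = "gene_id", multiple = "first") |>
    dplyr::left_join(
      dplyr::select(stable, "gene_id", stable_direction = "direction"),
      by = "gene_id"
    ) |>
    dplyr::relocate("rank", .after = dplyr::last_col())
}

#' Summarise a network's CWP genes by functional class
#'
#' One row per functional class present among the network's CWP genes, with
#' the gene count and how many of those genes are stably activated
#' (`direction = +1`) or suppressed (`-1`). Genes without a class label are
#' grouped under `"unclassified"`; genes without a stable call contribute to
#' `n_genes` only. Rows are sorted by `n_genes` descending, ties
#' alphabetically by class.
#'
#' @param net A [regnet()] object.
#' @param stable Stable-DEG tibble from [call_stable_degs()].
#' @return A tibble `functional_class`, `n_genes`, `n_up`, `n_down`.
#' @export
class_summary <- function(net, stable) {
  stopifnot(inherits(net, "tfprio_regnet"))
  genes <- tibble::tibble(gene_id = cwp_ids(net))
  if (nrow(genes) == 0) {
    return(tibble::tibble(functional_class = character(), n_genes = integer(),
                          n_up = integer(), n_down = integer()))
  }
  genes |>
    dplyr::left_join(net$cwp_classes, by = "gene_id", multiple = "first") |>
    dplyr::mutate(functional_class =
                    dplyr::coalesce(.data$functional_class, "unclassified")) |>
    dplyr::left_join(dplyr::select(stable, "gene_id", "direction"),
                     by = "gene_id") |>
    dplyr::group_by(.data$functional_class) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      n_up = sum(.data$direction == 1L, na.rm = TRUE),
      n_down = sum(.data$direction == -1L, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$functional_class)
}

#' @export
print.tfprio_result <- function(x, ...) {
  cat("<tfprio pipeline result>\n")
  cat(sprintf("  experiments: %d   stable DEGs: %d\n",
              dplyr::n_distinct(x$de_tables$experiment_id),
              nrow(x$stable_degs)))
  funnel <- paste(sprintf("%s %d TF/%d CWP", x$stages$stage, x$stages$n_tf,
                          x$stages$n_cwp), collapse = " -> ")
  cat("  funnel:", funnel, "\n")
  cat(sprintf("  priority TFs: %d   ranked CWP genes: %d\n",
              length(x$priority_tfs), nrow(x$cwp_scores)))
  invisible(x)
}

#' Write the pipeline result bundle to a directory
#'
#' Writes `de_tables.tsv`, `stable_degs.tsv`, `tf_scores.tsv`,
#' `cwp_scores.tsv`, `class_summary.tsv`, `stages.tsv` and the reduced
#' network (TSV, SIF, GraphML). Floating-point values are printed at 6
#' significant digits; all tables have a deterministic row order, so a rerun
#' of the same configuration yields byte-identical files.
#'
#' @param result A `tfprio_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a tibble manifest (`kind`, `path`).
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "tfprio_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    de_tables = result$de_tables,
    stable_degs = result$stable_degs,
    tf_scores = result$tf_scores,
    cwp_scores = result$cwp_scores,
    class_summary = result$class_summary,
    stages = result$stages
  )
  rows <- purrr::imap(tables, function(tbl, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    write_tsv_report(tbl, path)
    tibble::tibble(kind = name, path = path)
  })
  net_paths <- write_network(result$networks$reduced,
                             file.path(dir, "reduced_network"))
  manifest <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble::tibble(kind = names(net_paths), path = unname(net_paths))
  )
  relative <- dplyr::mutate(manifest, path = basename(.data$path))
  write_tsv_report(relative, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
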