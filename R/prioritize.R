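#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K` marked
#' items, and `n` draws without replacement. This is the enrichment p-value
#' for observing at least `k` DEGs among a TF's `K` targets when the
#' experiment produced `n` DEGs in a universe of `N` genes. Exact (no normal
#' approximation); `k = 0` returns exactly 1.
#'
#' @param k Observed overlap, `0 <= k <= min(K, n)` (vectorised).
#' @param K Number of marked items (TF target-set size in the universe).
#' @param n Number of draws (DEG count in the universe).
#' @param N Universe size.
#' @return The upper-tail probability in `(0, 1]`.
#' @export
#' @examples
#' hypergeometric_tail(3, 4, 5, 10) # 66/252
hypergeometric_tail <- function(k, K, n, N) {
  if (any(K > N) || any(n > N)) abort("K and n must not exceed N.")
  if (any(k < 0) || any(k > pmin(K, n))) abort("k must lie in [0, min(K, n)].")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Per-TF hypergeometric enrichment of targets in one experiment's DEGs
#'
#' For each TF of the network, tests whether its cell wall target genes are
#' over-represented among the experiment's DEGs. The default universe is the
#' set of CWP genes of the network that were measured in the experiment (i.e.
#' appear in `de_table`); within it, `K` counts the TF's targets, `n` the
#' DEGs, and `k` their overlap. TFs without targets in the universe are
#' retained as degenerate records with `p_value = 1` and `enriched = FALSE`.
#'
#' @param net A [regnet()] object.
#' @param de_table One experiment's DE table with `direction` set by
#'   [call_degs()].
#' @param tfs TFs to test; default all TFs of `net`.
#' @param universe Gene universe; default CWP genes of `net` measured in the
#'   experiment. `"measured"` uses every gene in `de_table`.
#' @param alpha_enrich Enrichment significance level (strict), default 0.05.
#' @param adjust P-value adjustment method across the tested TFs within this
#'   experiment, as accepted by [stats::p.adjust()]; default `"none"`.
#' @return A tibble of enrichment records: `tf_id`, `experiment_id`, `k`, `K`,
#'   `n`, `N`, `p_value`, `enriched`, `degenerate`.
#' @export
tf_enrichment <- function(net, de_table, tfs = NULL, universe = NULL,
                          alpha_enrich = 0.05, adjust = "none") {
  stopifnot(inherits(net, "tfprio_regnet"),
            all(c("experiment_id", "gene_id", "direction") %in% names(de_table)))
  if (is.null(tfs)) tfs <- tf_ids(net)
  missing_tfs <- setdiff(tfs, tf_ids(net))
  if (length(missing_tfs) > 0) {
    abort(paste0("TF(s) not in network: ", paste(head(missing_tfs, 5), collapse = ", ")))
  }
  if (is.null(universe)) {
    universe <- intersect(cwp_ids(net), de_table$gene_id)
  } else if (identical(universe, "measured")) {
    universe <- unique(de_table$gene_id)
  }
  if (length(tfs) == 0) return(empty_enrichment())
  if (length(universe) == 0) abort("empty enrichment universe.")

  N <- length(universe)
  degs <- intersect(de_table$gene_id[de_table$direction != 0L], universe)
  n <- length(degs)
  reg <- net$edges[net$edges$relation == "regulates", ]
  exp_id <- unique(de_table$experiment_id)
  if (length(exp_id) != 1) abort("de_table must contain exactly one experiment.")

  rec <- purrr::map(tfs, function(tf) {
    targets <- intersect(reg$target_id[reg$source_id == tf], universe)
    K <- length(targets)
    k <- length(intersect(targets, degs))
    p <- if (K == 0) 1 else hypergeometric_tail(k, K, n, N)
    tibble::tibble(tf_id = tf, experiment_id = exp_id,
                   k = k, K = K, n = n, N = N,
                   p_value = p, degenerate = K == 0)
  }) |> dplyr::bind_rows()
  rec$p_adjusted <- stats::p.adjust(rec$p_value, method = adjust)
  rec$enriched <- !rec$degenerate & rec$p_adjusted < alpha_enrich
  rec[, c("tf_id", "experiment_id", "k", "K", "n", "N",
          "p_value", "p_adjusted", "enriched", "degenerate")]
}

empty_enrichment <- function() {
  tibble::tibble(
    tf_id = character(), experiment_id = character(),
    k = integer(), K = integer(), n = integer(), N = integer(),
    p_value = double(), p_adjusted = double(),
    enriched = logical(), degenerate = logical()
  )
}

#' STF: count of experiments in which a TF's target set is enriched
#'
#' The score of a transcription factor (STF) is the number of experiments in
#' which its cell wall target-gene set is significantly enriched for that
#' experiment's DEGs. Takes the stacked enrichment records of all experiments
#' (one [tf_enrichment()] result per experiment).
#'
#' @param records Tibble of enrichment records across experiments.
#' @return A tibble `tf_id`, `stf` covering every TF in `records`.
#' @export
compute_stf <- function(records) {
  stopifnot(all(c("tf_id", "experiment_id", "enriched") %in% names(records)))
  if (anyDuplicated(records[, c("tf_id", "experiment_id")]) > 0) {
    abort("duplicate (tf_id, experiment_id) among enrichment records.")
  }
  records |>
    dplyr::group_by(.data$tf_id) |>
    dplyr::summarise(stf = sum(.data$enriched), .groups = "drop") |>
    dplyr::arrange(.data$tf_id)
}

#' Select priority TFs
#'
#' A TF is a priority TF when its target set is enriched in at least one
#' experiment, i.e. `stf >= 1`.
#'
#' @param stf_table Tibble with columns `tf_id`, `stf` (from [compute_stf()]).
#' @return Character vector of priority TF IDs (sorted).
#' @export
#' @examples
#' select_priority_tfs(tibble::tibble(tf_id = c("A", "B", "C"), stf = c(2, 0, 1)))
select_priority_tfs <- function(stf_table) {
  stopifnot(all(c("tf_id", "stf") %in% names(stf_table)))
  sort(stf_table$tf_id[stf_table$stf >= 1])
}

#' Reduce the network to priority TFs and their targets
#'
#' Keeps exactly the priority TFs, the CWP genes with at least one incoming
#' edge from a priority TF, the `regulates` edges among them, and metabolite
#' `affects` edges onto retained TFs.
#'
#' @param net A [regnet()] object.
#' @param priority Character vector of priority TF IDs (must be TFs of `net`).
#' @return The reduced network.
#' @export
reduce_network <- function(net, priority) {
  stopifnot(inherits(net, "tfprio_regnet"))
  stray <- setdiff(priority, tf_ids(net))
  if (length(stray) > 0) {
    abort(paste0("priority TF(s) not in network: ", paste(head(stray, 5), collapse = ", ")))
  }
  drop_tfs <- setdiff(tf_ids(net), priority)
  out <- subset_regnet(net, setdiff(net$nodes$id, drop_tfs))
  prune_dangling_metabolites(prune_unconnected_targets(out))
}

#' SCWP: number of distinct TFs regulating each cell wall gene
#'
#' The score of a cell wall protein (SCWP) is the in-degree of the gene from
#' TFs via `regulates` edges in the chosen network — priority is given to
#' genes under the densest TF regulation. Defined (possibly 0) for every CWP
#' node of the network.
#'
#' @param net A [regnet()] object.
#' @return A tibble `gene_id`, `scwp`, sorted by `gene_id`.
#' @export
compute_scwp <- function(net) {
  stopifnot(inherits(net, "tfprio_regnet"))
  reg <- net$edges[net$edges$relation == "regulates", ]
  counts <- reg |>
    dplyr::distinct(.data$source_id, .data$target_id) |>
    dplyr::count(.data$target_id, name = "scwp")
  tibble::tibble(gene_id = cwp_ids(net)) |>
    dplyr::left_join(counts, by = c(gene_id = "target_id")) |>
    dplyr::mutate(scwp = as.integer(dplyr::coalesce(.data$scwp, 0L))) |>
    dplyr::arrange(.data$gene_id)
}

#' Rank identifiers by a score, descending
#'
#' Deterministic ordering: descending by score, ties broken by lexicographic
#' ID. Highest score means highest priority (rank 1).
#'
#' @param scores Tibble with an ID column and a numeric score column.
#' @param id_col,score_col Column names (strings).
#' @return The tibble reordered with an integer `rank` column appended.
#' @export
#' @examples
#' rank_scores(tibble::tibble(gene_id = c("B", "A", "C"), scwp = c(3, 3, 7)))
rank_scores <- function(scores, id_col = names(scores)[1],
                        score_col = names(scores)[2]) {
  if (nrow(scores) == 0) abort("scores must be nonempty.")
  out <- scores[order(-scores[[score_col]], scores[[id_col]]), ]
  out$rank <- seq_len(nrow(out))
  tibble::as_tibble(out)
}
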