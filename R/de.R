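#' Per-gene differential expression for one two-group experiment
#'
#' Computes, for every gene of one experiment, the log2 fold change
#' (mean stress minus mean control on the log2 scale) and a two-sided
#' unequal-variance (Welch) two-group test p-value. This is a deliberately
#' plain test: the pipeline accepts precomputed differential-expression tables
#' from any upstream fit (e.g. a moderated linear model), and this function
#' exists so that expression matrices — in particular the synthetic
#' compendium — can be analysed end to end without external tooling.
#'
#' Degenerate rows are handled deterministically: if both group variances are
#' zero the p-value is 1 when the means agree and 0 when they differ.
#'
#' @param experiment An experiment as produced by
#'   [generate_expression_compendium()] or [read_expression_experiment()]: a
#'   list with `experiment_id` (string), `expr` (tibble, first column
#'   `gene_id`, remaining columns samples, values log2 intensities) and
#'   `samples` (tibble with columns `sample_id`, `group` where group is
#'   `"control"` or `"stress"`).
#' @return A tibble with columns `experiment_id`, `gene_id`, `logFC`,
#'   `p_value`, `direction`. `direction` is initialised to 0; use
#'   [call_degs()] to set it from thresholds.
#' @seealso [call_degs()], [call_stable_degs()]
#' @export
compute_de_table <- function(experiment) {
  stopifnot(is.list(experiment), !is.null(experiment$expr), !is.null(experiment$samples))
  expr <- experiment$expr
  samples <- experiment$samples
  if (anyDuplicated(expr$gene_id) > 0) abort("duplicate gene IDs in expression matrix.")
  sample_cols <- setdiff(names(expr), "gene_id")
  missing_group <- setdiff(sample_cols, samples$sample_id)
  if (length(missing_group) > 0) {
    abort(paste0("samples without group assignment: ", paste(missing_group, collapse = ", ")))
  }
  groups <- setNames(samples$group, samples$sample_id)[sample_cols]
  if (!all(groups %in% c("control", "stress"))) {
    abort("groups must be 'control' or 'stress'.")
  }
  ctrl <- as.matrix(expr[, sample_cols[groups == "control"], drop = FALSE])
  strs <- as.matrix(expr[, sample_cols[groups == "stress"], drop = FALSE])
  if (ncol(ctrl) < 2 || ncol(strs) < 2) abort("each group needs at least 2 samples.")
  if (!all(is.finite(ctrl)) || !all(is.finite(strs))) {
    bad <- expr$gene_id[!stats::complete.cases(cbind(ctrl, strs)) |
      rowSums(!is.finite(cbind(ctrl, strs))) > 0]
    abort(paste0("non-finite expression values for gene(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  welch <- welch_rows(strs, ctrl)
  tibble::tibble(
    experiment_id = experiment$experiment_id,
    gene_id = expr$gene_id,
    logFC = welch$diff,
    p_value = welch$p,
    direction = 0L
  )
}

# Row-wise Welch unequal-variance two-group comparison: difference of means
# (x minus y) and two-sided p via the Welch-Satterthwaite approximation.
welch_rows <- function(x, y) {
  nx <- ncol(x)
  ny <- ncol(y)
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * pt(-abs(tstat), df)
  # zero variance in both groups: identical constants => p = 1, separated
  # constants => p = 0
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
  }
  list(diff = mx - my, p = p)
}

#' Call differentially expressed genes from thresholds
#'
#' Sets the `direction` column of a differential-expression table:
#' `sign(logFC)` where both `p_value < p_threshold` and
#' `|logFC| > lfc_threshold` hold (strict inequalities), else 0. A logFC of
#' exactly zero never yields a call. The operation is idempotent and touches
#' no other column.
#'
#' @param de_table Tibble with columns `gene_id`, `logFC`, `p_value` (and
#'   optionally `experiment_id`).
#' @param p_threshold P-value cutoff, default 0.05.
#' @param lfc_threshold Absolute log2-fold-change cutoff, default 1.
#' @return The input tibble with `direction` set to -1, 0 or +1.
#' @export
#' @examples
#' de <- tibble::tibble(gene_id = c("a", "b"), logFC = c(1.2, 3), p_value = c(0.01, 0.05))
#' call_degs(de)$direction # +1, then 0 (p not strictly below the threshold)
call_degs <- function(de_table, p_threshold = 0.05, lfc_threshold = 1.0) {
  stopifnot(all(c("gene_id", "logFC", "p_value") %in% names(de_table)))
  if (p_threshold <= 0 || lfc_threshold < 0) abort("thresholds must be positive.")
  if (any(de_table$p_value < 0 | de_table$p_value > 1, na.rm = TRUE)) {
    abort("p_value outside [0, 1].")
  }
  dplyr::mutate(
    de_table,
    direction = as.integer(
      sign(.data$logFC) *
        (.data$p_value < p_threshold & abs(.data$logFC) > lfc_threshold)
    )
  )
}

#' Stable unidirectional DEGs across a compendium of experiments
#'
#' Aggregates per-experiment DEG calls by vote counting. A gene is a stable
#' DEG when (a) all of its nonzero per-experiment directions agree, and
#' (b) the number of experiments calling it is at least
#' [min_consistent_experiments()] evaluated at the number of experiments in
#' which the gene was measured. Genes absent from an experiment (platform
#' differences) simply have a smaller `n_measured`; absence is not treated as
#' evidence against differential expression.
#'
#' @param de_tables Either a list of per-experiment DE tables (as returned by
#'   [call_degs()]) or a single tibble with an `experiment_id` column. At
#'   least two experiments are required, and the per-experiment gene sets must
#'   share at least one gene.
#' @param p0 Null per-experiment probability of a directional DEG call,
#'   default 0.05.
#' @param alpha Significance level of the binomial rule, default 0.05.
#' @return A tibble with columns `gene_id`, `direction` (-1 or +1),
#'   `n_called`, `n_measured`, one row per stable DEG, sorted by `gene_id`.
#'   Attributes `p0`, `alpha` and `n_experiments` record the rule.
#' @export
call_stable_degs <- function(de_tables, p0 = 0.05, alpha = 0.05) {
  if (is.data.frame(de_tables)) {
    calls <- de_tables
  } else {
    calls <- dplyr::bind_rows(de_tables)
  }
  stopifnot(all(c("experiment_id", "gene_id", "direction") %in% names(calls)))
  experiments <- unique(calls$experiment_id)
  if (length(experiments) < 2) abort("need DE tables from at least 2 experiments.")
  gene_sets <- lapply(split(calls$gene_id, calls$experiment_id), unique)
  if (length(Reduce(intersect, gene_sets)) == 0) {
    abort("gene sets of the experiments have an empty intersection.")
  }
  if (anyDuplicated(calls[, c("experiment_id", "gene_id")]) > 0) {
    abort("duplicate gene within one experiment's DE table.")
  }

  per_gene <- calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_measured = dplyr::n(),
      n_called = sum(.data$direction != 0L),
      unidirectional = dplyr::n_distinct(.data$direction[.data$direction != 0L]) <= 1L,
      direction = if (any(.data$direction != 0L)) {
        as.integer(sign(sum(sign(.data$direction))))
      } else 0L,
      .groups = "drop"
    )

  kstar <- vapply(
    sort(unique(per_gene$n_measured)),
    function(n) min_consistent_experiments(n, p0, alpha),
    integer(1)
  )
  names(kstar) <- sort(unique(per_gene$n_measured))

  out <- per_gene |>
    dplyr::filter(
      .data$unidirectional,
      .data$n_called >= kstar[as.character(.data$n_measured)]
    ) |>
    dplyr::select("gene_id", "direction", "n_called", "n_measured") |>
    dplyr::arrange(.data$gene_id)

  attr(out, "p0") <- p0
  attr(out, "alpha") <- alpha
  attr(out, "n_experiments") <- length(experiments)
  out
}
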