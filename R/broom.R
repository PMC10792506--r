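#' Tidy a pipeline result
#'
#' Returns one tibble of scored entities: TFs with their STF and CWP genes
#' with their SCWP, in a long broom-style layout.
#'
#' @param x A `tfprio_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble with columns `id`, `kind` (`"TF"`/`"CWP"`), `score`
#'   (STF or SCWP), `rank` and `priority`.
#' @method tidy tfprio_result
#' @export
tidy.tfprio_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      id = x$tf_scores$tf_id, kind = "TF",
      score = as.numeric(x$tf_scores$stf),
      rank = x$tf_scores$rank, priority = x$tf_scores$priority
    ),
    tibble::tibble(
      id = x$cwp_scores$gene_id, kind = "CWP",
      score = as.numeric(x$cwp_scores$scwp),
      rank = x$cwp_scores$rank, priority = NA
    )
  )
}

#' One-row summary of a pipeline run
#'
#' @param x A `tfprio_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble: experiment count, stable-DEG count, node counts
#'   per filtering stage, priority-TF count and reduced-network size.
#' @method glance tfprio_result
#' @export
glance.tfprio_result <- function(x, ...) {
  st <- x$stages
  count_of <- function(stage, col) st[[col]][st$stage == stage]
  tibble::tibble(
    n_experiments = dplyr::n_distinct(x$de_tables$experiment_id),
    n_stable_degs = nrow(x$stable_degs),
    n_tf_input = count_of("input", "n_tf"),
    n_cwp_input = count_of("input", "n_cwp"),
    n_tf_process = count_of("process_filtered", "n_tf"),
    n_tf_stable = count_of("stable_restricted", "n_tf"),
    n_priority_tfs = length(x$priority_tfs),
    n_tf_reduced = count_of("reduced", "n_tf"),
    n_cwp_reduced = count_of("reduced", "n_cwp")
  )
}

#' Plot a pipeline result
#'
#' `autoplot()` draws the per-TF STF scores as a bar chart, priority TFs
#' highlighted.
#'
#' @param object A `tfprio_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tfprio_result
#' @export
autoplot.tfprio_result <- function(object, ...) {
  plot_stf(object$tf_scores)
}

#' @export
#' @rdname autoplot.tfprio_result
#' @param tf_scores The `tf_scores` tibble of a pipeline result.
plot_stf <- function(tf_scores) {
  df <- dplyr::mutate(tf_scores,
                      tf_id = stats::reorder(.data$tf_id, .data$stf))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tf_id, y = .data$stf,
                                   fill = .data$priority)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "STF (experiments with enriched target set)",
                  fill = "priority TF") +
    ggplot2::theme_minimal()
}

#' Plot the funnel of network sizes across filtering stages
#'
#' @param result A `tfprio_result`.
#' @return A ggplot object showing TF and CWP counts per pipeline stage.
#' @export
plot_funnel <- function(result) {
  stopifnot(inherits(result, "tfprio_result"))
  df <- result$stages |>
    dplyr::mutate(stage = factor(.data$stage, levels = .data$stage)) |>
    tidyr::pivot_longer(c("n_tf", "n_cwp"), names_to = "kind",
                        values_to = "count") |>
    dplyr::mutate(kind = dplyr::recode(.data$kind, n_tf = "TF", n_cwp = "CWP"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$count,
                                   group = .data$kind, colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "nodes retained", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the functional-class composition of the reduced network
#'
#' Bars give the CWP gene count per functional class, split into stably
#' activated, stably suppressed and unstable genes.
#'
#' @param result A `tfprio_result`.
#' @return A ggplot object.
#' @export
plot_class_summary <- function(result) {
  stopifnot(inherits(result, "tfprio_result"))
  df <- result$class_summary |>
    dplyr::mutate(n_other = .data$n_genes - .data$n_up - .data$n_down) |>
    tidyr::pivot_longer(c("n_up", "n_down", "n_other"),
                        names_to = "status", values_to = "count") |>
    dplyr::mutate(status = dplyr::recode(.data$status, n_up = "activated",
                                         n_down = "suppressed",
                                         n_other = "no stable call"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$functional_class, .data$n_genes),
    y = .data$count, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "CWP genes", fill = NULL) +
    ggplot2::theme_minimal()
}
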