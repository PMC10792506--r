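#' Construct a typed bipartite regulatory network
#'
#' The central container of the pipeline: a directed graph whose `regulates`
#' edges run from transcription factors (TFs) to target genes (cell wall
#' protein genes or other TFs) and whose optional `affects` edges run from
#' metabolite nodes to TFs. TF nodes may carry biological-process annotations;
#' CWP nodes may carry one of the nine functional-class labels. Stored as a
#' list of tibbles so results compose with dplyr verbs.
#'
#' Validation enforces: node kinds in {TF, CWP, metabolite}; no self-edges; no
#' duplicate edges (duplicates are merged silently); every edge endpoint
#' present in `nodes`; `regulates` sources are TFs; `affects` edges run
#' metabolite -> TF only.
#'
#' @param nodes Tibble with columns `id`, `kind`.
#' @param edges Tibble with columns `source_id`, `target_id` and optionally
#'   `relation` (default `"regulates"`).
#' @param tf_processes Optional tibble `tf_id`, `process`.
#' @param cwp_classes Optional tibble `gene_id`, `functional_class`.
#' @return An object of class `tfprio_regnet`.
#' @export
#' @examples
#' net <- regnet(
#'   nodes = tibble::tibble(id = c("TF1", "g1"), kind = c("TF", "CWP")),
#'   edges = tibble::tibble(source_id = "TF1", target_id = "g1")
#' )
#' net
regnet <- function(nodes, edges,
                   tf_processes = NULL, cwp_classes = NULL) {
  nodes <- tibble::as_tibble(nodes)[, c("id", "kind")]
  edges <- tibble::as_tibble(edges)
  if (!"relation" %in% names(edges)) edges$relation <- "regulates"
  edges <- dplyr::distinct(edges[, c("source_id", "target_id", "relation")])

  if (anyDuplicated(nodes$id) > 0) abort("duplicate node IDs.")
  if (!all(nodes$kind %in% c("TF", "CWP", "metabolite"))) {
    abort("node kind must be one of TF, CWP, metabolite.")
  }
  if (!all(edges$relation %in% c("regulates", "affects"))) {
    abort("edge relation must be 'regulates' or 'affects'.")
  }
  if (any(edges$source_id == edges$target_id)) abort("self-edges are not allowed.")
  unknown <- setdiff(c(edges$source_id, edges$target_id), nodes$id)
  if (length(unknown) > 0) {
    abort(paste0("edge endpoint(s) not in nodes: ", paste(head(unknown, 5), collapse = ", ")))
  }
  kind <- setNames(nodes$kind, nodes$id)
  reg <- edges$relation == "regulates"
  if (any(kind[edges$source_id[reg]] != "TF")) {
    abort("'regulates' edges must originate from TF nodes.")
  }
  if (any(kind[edges$target_id[reg]] == "metabolite")) {
    abort("'regulates' edges cannot target metabolites.")
  }
  aff <- !reg
  if (any(kind[edges$source_id[aff]] != "metabolite") ||
      any(kind[edges$target_id[aff]] != "TF")) {
    abort("'affects' edges must run metabolite -> TF.")
  }

  if (is.null(tf_processes)) {
    tf_processes <- tibble::tibble(tf_id = character(), process = character())
  }
  if (is.null(cwp_classes)) {
    cwp_classes <- tibble::tibble(gene_id = character(), functional_class = character())
  }
  tf_processes <- dplyr::distinct(tibble::as_tibble(tf_processes)[, c("tf_id", "process")])
  cwp_classes <- dplyr::distinct(tibble::as_tibble(cwp_classes)[, c("gene_id", "functional_class")])

  structure(
    list(
      nodes = dplyr::arrange(nodes, .data$id),
      edges = dplyr::arrange(edges, .data$source_id, .data$target_id),
      tf_processes = dplyr::filter(tf_processes, .data$tf_id %in% nodes$id),
      cwp_classes = dplyr::filter(cwp_classes, .data$gene_id %in% nodes$id)
    ),
    class = "tfprio_regnet"
  )
}

#' @export
print.tfprio_regnet <- function(x, ...) {
  counts <- table(factor(x$nodes$kind, levels = c("TF", "CWP", "metabolite")))
  cat("<regulatory network>\n")
  cat(sprintf("  nodes: %d TF, %d CWP, %d metabolite\n",
              counts["TF"], counts["CWP"], counts["metabolite"]))
  cat(sprintf("  edges: %d regulates, %d affects\n",
              sum(x$edges$relation == "regulates"),
              sum(x$edges$relation == "affects")))
  invisible(x)
}

#' Node ID accessors
#'
#' @param net A [regnet()] object.
#' @return Character vector of node IDs of the given kind.
#' @export
tf_ids <- function(net) net$nodes$id[net$nodes$kind == "TF"]

#' @rdname tf_ids
#' @export
cwp_ids <- function(net) net$nodes$id[net$nodes$kind == "CWP"]

# Rebuild a regnet restricted to a set of node IDs (edges among them only).
subset_regnet <- function(net, keep_ids) {
  nodes <- dplyr::filter(net$nodes, .data$id %in% keep_ids)
  edges <- dplyr::filter(net$edges,
                         .data$source_id %in% keep_ids,
                         .data$target_id %in% keep_ids)
  regnet(nodes, edges, net$tf_processes, net$cwp_classes)
}

#' Remove CWP genes with no incoming TF regulation
#'
#' Drops every CWP node lacking at least one incoming `regulates` edge from a
#' TF. TF and metabolite nodes are untouched. Idempotent.
#'
#' @param net A [regnet()] object.
#' @return The pruned network.
#' @export
prune_unconnected_targets <- function(net) {
  stopifnot(inherits(net, "tfprio_regnet"))
  reg <- net$edges[net$edges$relation == "regulates", ]
  connected_cwp <- intersect(cwp_ids(net), reg$target_id)
  keep <- c(net$nodes$id[net$nodes$kind != "CWP"], connected_cwp)
  subset_regnet(net, keep)
}

#' Build a biological-process filter for TFs
#'
#' The default process names are the four drought-related processes used to
#' select drought TFs: "response to water deprivation", "obsolete drought
#' tolerance", "drought recovery" and "response to water". In `exact` mode a
#' TF matches when its annotation set intersects `process_names`; in
#' `substring` mode when any of its process names contains any filter string.
#' Matching is case-insensitive unless `case_sensitive = TRUE`.
#'
#' @param process_names Nonempty character vector of process names (exact
#'   mode) or keywords (substring mode).
#' @param match_mode `"exact"` or `"substring"`.
#' @param case_sensitive Logical, default `FALSE`.
#' @return A list of class `process_filter`.
#' @export
#' @examples
#' process_filter() # the four drought processes, exact matching
#' process_filter(c("drought", "water"), match_mode = "substring")
process_filter <- function(process_names = c(
                             "response to water deprivation",
                             "obsolete drought tolerance",
                             "drought recovery",
                             "response to water"
                           ),
                           match_mode = c("exact", "substring"),
                           case_sensitive = FALSE) {
  if (length(process_names) == 0) abort("process_names must be nonempty.")
  structure(
    list(
      process_names = process_names,
      match_mode = match.arg(match_mode),
      case_sensitive = isTRUE(case_sensitive)
    ),
    class = "process_filter"
  )
}

#' Keep only TFs annotated with given biological processes
#'
#' Retains exactly the TFs whose process annotations match `filter`; all other
#' TFs are removed together with their edges, and CWP genes thereby left
#' without TF regulation are pruned via [prune_unconnected_targets()].
#' Metabolite nodes survive only while they still affect a retained TF.
#'
#' @param net A [regnet()] object.
#' @param filter A [process_filter()].
#' @return The filtered network.
#' @export
filter_tfs_by_process <- function(net, filter = process_filter()) {
  stopifnot(inherits(net, "tfprio_regnet"), inherits(filter, "process_filter"))
  ann <- net$tf_processes
  fold <- if (filter$case_sensitive) identity else tolower
  wanted <- fold(filter$process_names)
  matched <- if (filter$match_mode == "exact") {
    fold(ann$process) %in% wanted
  } else {
    purrr::map_lgl(fold(ann$process), function(p) {
      any(purrr::map_lgl(wanted, function(w) grepl(w, p, fixed = TRUE)))
    })
  }
  keep_tfs <- unique(ann$tf_id[matched])
  drop_tfs <- setdiff(tf_ids(net), keep_tfs)
  out <- subset_regnet(net, setdiff(net$nodes$id, drop_tfs))
  prune_dangling_metabolites(prune_unconnected_targets(out))
}

#' Keep only TFs that are stable unidirectional DEGs
#'
#' Retains exactly the TFs present in a stable-DEG set (from
#' [call_stable_degs()]); CWP genes left without TF regulation are pruned.
#'
#' @param net A [regnet()] object.
#' @param stable A tibble of stable DEGs with a `gene_id` column.
#' @return The filtered network.
#' @export
restrict_tfs_to_stable_degs <- function(net, stable) {
  stopifnot(inherits(net, "tfprio_regnet"), "gene_id" %in% names(stable))
  drop_tfs <- setdiff(tf_ids(net), stable$gene_id)
  out <- subset_regnet(net, setdiff(net$nodes$id, drop_tfs))
  prune_dangling_metabolites(prune_unconnected_targets(out))
}

# Metabolites persist only while they still affect some retained TF.
prune_dangling_metabolites <- function(net) {
  mets <- net$nodes$id[net$nodes$kind == "metabolite"]
  live <- unique(net$edges$source_id[net$edges$relation == "affects"])
  subset_regnet(net, setdiff(net$nodes$id, setdiff(mets, live)))
}
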