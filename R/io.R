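#' Read a regulatory network from an edge list plus annotation tables
#'
#' The edge file may be a TSV with columns `source_id`, `target_id` and
#' optional `relation` (header required; relation defaults to `regulates`),
#' or a SIF file (`source<TAB or space>relation<TAB or space>target`), chosen
#' by the `.sif` extension. Node kinds are inferred: sources of `regulates`
#' edges are TFs, sources of `affects` edges are metabolites, remaining nodes
#' listed in `class_file` are CWP genes, and any other target defaults to CWP.
#' Duplicate edges are merged.
#'
#' @param edge_file Path to the edge list (TSV or SIF).
#' @param annotation_file Optional TSV `tf_id<TAB>process_name`, one pair per
#'   line, no header required (a header line `tf_id process` is tolerated).
#' @param class_file Optional TSV `gene_id<TAB>functional_class`.
#' @return A [regnet()] object.
#' @export
read_network <- function(edge_file, annotation_file = NULL, class_file = NULL) {
  if (!file.exists(edge_file)) abort(paste0("edge file not found: ", edge_file))
  if (grepl("\\.sif$", edge_file, ignore.case = TRUE)) {
    lines <- readLines(edge_file)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(lengths(parts) != 3)
    if (length(bad) > 0) {
      abort(paste0("malformed SIF line ", bad[1], " in ", edge_file))
    }
    edges <- tibble::tibble(
      source_id = purrr::map_chr(parts, 1),
      relation = purrr::map_chr(parts, 2),
      target_id = purrr::map_chr(parts, 3)
    )[, c("source_id", "target_id", "relation")]
  } else {
    edges <- readr::read_tsv(edge_file, show_col_types = FALSE, progress = FALSE)
    if (!all(c("source_id", "target_id") %in% names(edges))) {
      abort(paste0("edge TSV needs columns source_id, target_id: ", edge_file))
    }
    if (!"relation" %in% names(edges)) edges$relation <- "regulates"
    edges <- edges[, c("source_id", "target_id", "relation")]
    edges$relation[is.na(edges$relation)] <- "regulates"
  }
  if (!all(edges$relation %in% c("regulates", "affects"))) {
    bad <- setdiff(unique(edges$relation), c("regulates", "affects"))
    abort(paste0("unknown edge relation(s): ", paste(bad, collapse = ", ")))
  }

  tf_processes <- if (!is.null(annotation_file)) {
    read_two_col(annotation_file, c("tf_id", "process"))
  }
  cwp_classes <- if (!is.null(class_file)) {
    read_two_col(class_file, c("gene_id", "functional_class"))
  }

  tf_nodes <- unique(c(
    edges$source_id[edges$relation == "regulates"],
    # annotated TFs are TF nodes even when they currently have no targets
    if (!is.null(tf_processes)) tf_processes$tf_id
  ))
  met_nodes <- unique(edges$source_id[edges$relation == "affects"])
  other <- setdiff(unique(edges$target_id), c(tf_nodes, met_nodes))
  nodes <- dplyr::bind_rows(
    tibble::tibble(id = tf_nodes, kind = "TF"),
    tibble::tibble(id = met_nodes, kind = "metabolite"),
    tibble::tibble(id = other, kind = "CWP")
  )
  # classed genes that never appear in an edge are still CWP nodes
  if (!is.null(cwp_classes)) {
    orphan <- setdiff(cwp_classes$gene_id, nodes$id)
    nodes <- dplyr::bind_rows(nodes, tibble::tibble(id = orphan, kind = "CWP"))
  }
  regnet(nodes, edges, tf_processes, cwp_classes)
}

read_two_col <- function(path, col_names) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) != 2) abort(paste0("expected 2 tab-separated columns in ", path))
  names(x) <- col_names
  # tolerate a header row naming the columns
  if (identical(unname(unlist(x[1, ])), col_names)) x <- x[-1, ]
  x
}

#' Write a regulatory network to TSV, SIF and GraphML
#'
#' Writes `<stem>_edges.tsv`, `<stem>_edges.sif`, `<stem>_tf_processes.tsv`,
#' `<stem>_cwp_classes.tsv` and `<stem>.graphml` (node attributes `kind` and
#' `functional_class`). The TSV/annotation files round-trip losslessly through
#' [read_network()].
#'
#' @param net A [regnet()] object.
#' @param stem Path prefix for the output files.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_network <- function(net, stem) {
  stopifnot(inherits(net, "tfprio_regnet"))
  dir.create(dirname(stem), recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    edges_tsv = paste0(stem, "_edges.tsv"),
    edges_sif = paste0(stem, "_edges.sif"),
    tf_processes = paste0(stem, "_tf_processes.tsv"),
    cwp_classes = paste0(stem, "_cwp_classes.tsv"),
    graphml = paste0(stem, ".graphml")
  )
  readr::write_tsv(net$edges, paths["edges_tsv"], progress = FALSE)
  writeLines(sprintf("%s\t%s\t%s", net$edges$source_id, net$edges$relation,
                     net$edges$target_id), paths["edges_sif"])
  readr::write_tsv(net$tf_processes, paths["tf_processes"],
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(net$cwp_classes, paths["cwp_classes"],
                   col_names = FALSE, progress = FALSE)
  g <- as_igraph(net)
  igraph::write_graph(g, paths["graphml"], format = "graphml")
  invisible(paths)
}

#' Convert a regulatory network to an igraph graph
#'
#' Vertices carry attributes `kind` and `functional_class`; edges carry
#' `relation`.
#'
#' @param net A [regnet()] object.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "tfprio_regnet"))
  vs <- dplyr::left_join(net$nodes, net$cwp_classes,
                         by = c(id = "gene_id"), multiple = "first")
  vs$functional_class[is.na(vs$functional_class)] <- ""
  igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE,
    vertices = data.frame(name = vs$id, kind = vs$kind,
                          functional_class = vs$functional_class)
  )
}

#' Read one expression experiment from TSV files
#'
#' @param expr_file TSV, first column `gene_id`, remaining columns sample IDs,
#'   values log2 intensities.
#' @param sample_file TSV with columns `sample_id`, `group` (control/stress).
#' @param experiment_id Identifier for the experiment; defaults to the
#'   expression file name without extension.
#' @return An experiment list (`experiment_id`, `expr`, `samples`) accepted by
#'   [compute_de_table()].
#' @export
read_expression_experiment <- function(expr_file, sample_file,
                                       experiment_id = NULL) {
  for (f in c(expr_file, sample_file)) {
    if (!file.exists(f)) abort(paste0("file not found: ", f))
  }
  expr <- readr::read_tsv(expr_file, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "gene_id") abort("first column of expression TSV must be gene_id.")
  samples <- readr::read_tsv(sample_file, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("sample sheet needs columns sample_id, group.")
  }
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[^.]*$", "", basename(expr_file))
  }
  list(experiment_id = experiment_id, expr = expr,
       samples = samples[, c("sample_id", "group")])
}

#' Read a precomputed differential-expression table
#'
#' @param de_file TSV with columns `gene_id`, `logFC`, `p_value` (an existing
#'   `direction` column is ignored; directions are assigned by [call_degs()]).
#' @param experiment_id Identifier; defaults to the file name without
#'   extension.
#' @return A tibble with columns `experiment_id`, `gene_id`, `logFC`,
#'   `p_value`, `direction` (0).
#' @export
read_de_table <- function(de_file, experiment_id = NULL) {
  if (!file.exists(de_file)) abort(paste0("file not found: ", de_file))
  x <- readr::read_tsv(de_file, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene_id", "logFC", "p_value") %in% names(x))) {
    abort("DE TSV needs columns gene_id, logFC, p_value.")
  }
  if (is.null(experiment_id)) {
    experiment_id <- sub("\\.[^.]*$", "", basename(de_file))
  }
  tibble::tibble(
    experiment_id = experiment_id,
    gene_id = x$gene_id, logFC = x$logFC, p_value = x$p_value, direction = 0L
  )
}

#' Write a simulated study to disk as plain-text fixtures
#'
#' Writes one expression TSV and sample sheet per experiment, the edge list
#' (TSV and SIF), the TF process annotations, the CWP functional-class table,
#' the list of planted TFs and the realized ground-truth DEG manifest
#' (`gene_id`, `experiment_id`, `direction`). Expression values are written at
#' full (round-trip) precision so reloading reproduces the matrices exactly.
#'
#' @param dir Output directory (created if needed).
#' @param network A [regnet()] object.
#' @param truth Ground-truth list from [generate_expression_compendium()].
#' @param experiments List of experiment objects.
#' @return A tibble manifest with columns `kind` and `path`.
#' @export
write_fixtures <- function(dir, network, truth, experiments) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  rows <- list()
  add <- function(kind, path) rows[[length(rows) + 1]] <<- tibble::tibble(kind = kind, path = path)

  for (exp in experiments) {
    ep <- file.path(dir, paste0(exp$experiment_id, "_expression.tsv"))
    sp <- file.path(dir, paste0(exp$experiment_id, "_samples.tsv"))
    readr::write_tsv(exp$expr, ep, progress = FALSE)
    readr::write_tsv(exp$samples, sp, progress = FALSE)
    add("expression", ep)
    add("samples", sp)
  }
  net_paths <- write_network(network, file.path(dir, "network"))
  for (i in seq_along(net_paths)) add(names(net_paths)[i], unname(net_paths[i]))

  tp <- file.path(dir, "planted_tfs.txt")
  writeLines(truth$planted_tfs, tp)
  add("planted_tfs", tp)

  gt <- file.path(dir, "ground_truth.tsv")
  readr::write_tsv(
    truth$true_degs[, c("gene_id", "experiment_id", "direction")],
    gt, progress = FALSE
  )
  add("ground_truth", gt)

  dplyr::bind_rows(rows)
}

#' Reload a fixture directory written by [write_fixtures()]
#'
#' @param dir Directory containing the fixture files.
#' @return A list with `network`, `experiments` and `truth` (with
#'   `planted_tfs` and `true_degs`).
#' @export
read_fixtures <- function(dir) {
  network <- read_network(
    file.path(dir, "network_edges.tsv"),
    file.path(dir, "network_tf_processes.tsv"),
    file.path(dir, "network_cwp_classes.tsv")
  )
  expr_files <- sort(list.files(dir, pattern = "_expression\\.tsv$", full.names = TRUE))
  experiments <- purrr::map(expr_files, function(f) {
    id <- sub("_expression\\.tsv$", "", basename(f))
    read_expression_experiment(f, file.path(dir, paste0(id, "_samples.tsv")), id)
  })
  truth <- list(
    planted_tfs = readLines(file.path(dir, "planted_tfs.txt")),
    true_degs = readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                                show_col_types = FALSE, progress = FALSE)
  )
  list(network = network, experiments = experiments, truth = truth)
}
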