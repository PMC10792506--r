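#' Parameters of the synthetic regulatory-network and expression simulator
#'
#' Bundles and validates the knobs of the synthetic-data generator. The
#' defaults describe the study conditions the package is designed around: a
#' compendium of 5 two-group microarray-style experiments over 800 cell wall
#' protein (CWP) genes and 60 transcription factors, 6 of which are planted
#' drought regulators whose 30-gene target sets respond to stress far more
#' often (`deg_rate_planted = 0.5`) than background genes
#' (`deg_rate_background = 0.05`), with a 2 log2-unit shift against a
#' within-group standard deviation of 0.5.
#'
#' @param n_tf Number of transcription factors.
#' @param n_cwp Number of CWP (target) genes.
#' @param n_experiments Number of experiments in the compendium.
#' @param n_replicates_per_group Samples per group (control/stress), `>= 2`.
#' @param edge_prob_background Probability that any given TF regulates any
#'   given CWP gene, independently per pair.
#' @param n_planted_tf Number of planted drought TFs (`<= n_tf`).
#' @param planted_target_count Target-set size of each planted TF
#'   (`<= n_cwp`), drawn without replacement.
#' @param deg_rate_background Per-experiment probability that a background
#'   gene is a true DEG.
#' @param deg_rate_planted Per-experiment probability that a planted TF or one
#'   of its targets is a true DEG; must exceed `deg_rate_background`.
#' @param effect_size Log2 fold-change magnitude of a true DEG (`> 0`).
#' @param noise_sd Within-group standard deviation on the log2 scale (`> 0`).
#' @param frac_annotated_drought Fraction of planted TFs annotated with the
#'   drought process "response to water deprivation".
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class `sim_params`.
#' @export
#' @examples
#' sim_params(n_tf = 10, n_cwp = 50, n_planted_tf = 2, planted_target_count = 10)
sim_params <- function(n_tf = 60,
                       n_cwp = 800,
                       n_experiments = 5,
                       n_replicates_per_group = 3,
                       edge_prob_background = 0.02,
                       n_planted_tf = 6,
                       planted_target_count = 30,
                       deg_rate_background = 0.05,
                       deg_rate_planted = 0.5,
                       effect_size = 2,
                       noise_sd = 0.5,
                       frac_annotated_drought = 1.0,
                       seed = 1L) {
  p <- list(
    n_tf = as.integer(n_tf), n_cwp = as.integer(n_cwp),
    n_experiments = as.integer(n_experiments),
    n_replicates_per_group = as.integer(n_replicates_per_group),
    edge_prob_background = edge_prob_background,
    n_planted_tf = as.integer(n_planted_tf),
    planted_target_count = as.integer(planted_target_count),
    deg_rate_background = deg_rate_background,
    deg_rate_planted = deg_rate_planted,
    effect_size = effect_size, noise_sd = noise_sd,
    frac_annotated_drought = frac_annotated_drought,
    seed = as.integer(seed)
  )
  if (p$n_tf < 1 || p$n_cwp < 1 || p$n_experiments < 1) {
    abort("n_tf, n_cwp and n_experiments must be positive.")
  }
  if (p$n_replicates_per_group < 2) abort("n_replicates_per_group must be >= 2.")
  if (p$n_planted_tf > p$n_tf) abort("n_planted_tf exceeds n_tf.")
  if (p$n_planted_tf < 0) abort("n_planted_tf must be non-negative.")
  if (p$planted_target_count > p$n_cwp) abort("planted_target_count exceeds n_cwp.")
  probs <- c(p$edge_prob_background, p$deg_rate_background, p$deg_rate_planted,
             p$frac_annotated_drought)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1].")
  if (p$n_planted_tf > 0 && p$deg_rate_planted <= p$deg_rate_background) {
    abort("deg_rate_planted must exceed deg_rate_background.")
  }
  if (p$effect_size <= 0) abort("effect_size must be > 0.")
  if (p$noise_sd <= 0) abort("noise_sd must be > 0.")
  structure(p, class = "sim_params")
}

#' The drought process annotation planted on synthetic drought TFs
#' @return A string.
#' @keywords internal
#' @noRd
planted_drought_process <- function() "response to water deprivation"

#' Generate a synthetic bipartite TF-to-CWP regulatory network
#'
#' Builds a directed bipartite network of `n_tf` transcription factors over
#' `n_cwp` cell wall genes. Each planted TF receives exactly
#' `planted_target_count` targets sampled without replacement; every TF/CWP
#' pair additionally carries a background `regulates` edge independently with
#' probability `edge_prob_background`; duplicates are merged. Planted TFs are
#' annotated with the process "response to water deprivation" with probability
#' `frac_annotated_drought`; every TF carries the neutral annotation
#' "regulation of transcription". CWP genes are assigned one of the nine
#' functional classes ([cwp_functional_classes()]) uniformly at random.
#'
#' The generator is a pure function of `params` (including `params$seed`):
#' identical parameters give identical output.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `network` (a [regnet()] object) and `truth`
#'   (list with `planted_tfs`, `planted_targets`, `network_edges`;
#'   `true_degs` is filled in by [generate_expression_compendium()]).
#' @export
#' @examples
#' sim <- generate_regulatory_network(sim_params(n_tf = 5, n_cwp = 20,
#'   n_planted_tf = 1, planted_target_count = 5, seed = 7))
#' sim$truth$planted_tfs
generate_regulatory_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tf_ids <- sprintf("TF%03d", seq_len(params$n_tf))
  cwp_ids <- sprintf("CWP%04d", seq_len(params$n_cwp))
  planted <- tf_ids[seq_len(params$n_planted_tf)]

  set.seed(params$seed)
  planted_edges <- dplyr::bind_rows(
    tibble::tibble(source_id = character(), target_id = character()),
    purrr::map(planted, function(tf) {
      tibble::tibble(
        source_id = tf,
        target_id = sample(cwp_ids, params$planted_target_count)
      )
    })
  )

  hit <- runif(params$n_tf * params$n_cwp) < params$edge_prob_background
  background_edges <- tibble::tibble(
    source_id = rep(tf_ids, each = params$n_cwp)[hit],
    target_id = rep(cwp_ids, times = params$n_tf)[hit]
  )

  edges <- dplyr::bind_rows(planted_edges, background_edges) |>
    dplyr::distinct() |>
    dplyr::mutate(relation = "regulates") |>
    dplyr::arrange(.data$source_id, .data$target_id)

  annotated <- planted[runif(length(planted)) < params$frac_annotated_drought |
                         params$frac_annotated_drought >= 1]
  tf_processes <- dplyr::bind_rows(
    tibble::tibble(tf_id = tf_ids, process = "regulation of transcription"),
    tibble::tibble(tf_id = annotated,
                   process = rep(planted_drought_process(), length(annotated)))
  ) |> dplyr::arrange(.data$tf_id, .data$process)

  cwp_classes <- tibble::tibble(
    gene_id = cwp_ids,
    functional_class = sample(cwp_functional_classes(), params$n_cwp, replace = TRUE)
  )

  nodes <- dplyr::bind_rows(
    tibble::tibble(id = tf_ids, kind = "TF"),
    tibble::tibble(id = cwp_ids, kind = "CWP")
  )

  network <- regnet(nodes, edges, tf_processes, cwp_classes)
  truth <- list(
    planted_tfs = planted,
    planted_targets = unique(planted_edges$target_id),
    network_edges = edges[, c("source_id", "target_id")],
    true_degs = NULL
  )
  list(network = network, truth = truth)
}

#' Simulate a multi-experiment expression compendium over a network
#'
#' Draws, for every experiment of the compendium, a log2-scale expression
#' matrix over all genes of the network (TFs and CWP genes). Per-gene baseline
#' means come from Normal(8, 1); each gene owns a single response direction
#' (+1/-1, drawn once, shared by all experiments, so that true responders are
#' unidirectional by construction); in each experiment a gene is a true DEG
#' with probability `deg_rate_planted` if it is a planted TF or a target of
#' one, else `deg_rate_background`; stress samples of a true DEG are shifted
#' by `direction * effect_size`; all samples carry Normal(0, `noise_sd`^2)
#' noise.
#'
#' Per-experiment random streams are derived from the master seed as
#' `seed + experiment index`, so increasing `n_experiments` leaves earlier
#' experiments unchanged.
#'
#' @param network A [regnet()] object from [generate_regulatory_network()].
#' @param truth The matching ground-truth list.
#' @param params The same [sim_params()] used for the network.
#' @return A list with `experiments` (list of experiment objects, each with
#'   `experiment_id`, `expr`, `samples`) and `truth` (input truth with
#'   `true_degs` added: a tibble `experiment_id`, `gene_id`, `direction`).
#' @export
generate_expression_compendium <- function(network, truth, params) {
  stopifnot(inherits(params, "sim_params"), inherits(network, "tfprio_regnet"))
  if (params$n_replicates_per_group < 2) abort("n_replicates_per_group must be >= 2.")
  gene_ids <- network$nodes$id
  n_genes <- length(gene_ids)
  responsive <- gene_ids %in% c(truth$planted_tfs, truth$planted_targets)
  rate <- ifelse(responsive, params$deg_rate_planted, params$deg_rate_background)

  set.seed(params$seed)
  mu <- rnorm(n_genes, mean = 8, sd = 1)
  gene_direction <- sample(c(-1L, 1L), n_genes, replace = TRUE)

  m <- params$n_replicates_per_group
  experiments <- vector("list", params$n_experiments)
  deg_list <- vector("list", params$n_experiments)
  for (i in seq_len(params$n_experiments)) {
    set.seed(params$seed + i)
    is_deg <- runif(n_genes) < rate
    shift <- ifelse(is_deg, gene_direction * params$effect_size, 0)
    noise <- matrix(rnorm(n_genes * 2 * m, sd = params$noise_sd), nrow = n_genes)
    mat <- mu + cbind(matrix(0, n_genes, m), matrix(shift, n_genes, m)) + noise
    exp_id <- sprintf("E%d", i)
    sample_ids <- c(sprintf("%s_ctrl_%d", exp_id, seq_len(m)),
                    sprintf("%s_strs_%d", exp_id, seq_len(m)))
    colnames(mat) <- sample_ids
    experiments[[i]] <- list(
      experiment_id = exp_id,
      expr = dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                              tibble::as_tibble(mat)),
      samples = tibble::tibble(
        sample_id = sample_ids,
        group = rep(c("control", "stress"), each = m)
      )
    )
    deg_list[[i]] <- tibble::tibble(
      experiment_id = exp_id,
      gene_id = gene_ids,
      direction = as.integer(ifelse(is_deg, gene_direction, 0L))
    )
  }
  truth$true_degs <- dplyr::bind_rows(deg_list)
  list(experiments = experiments, truth = truth)
}

#' Generate network, ground truth and expression compendium in one call
#'
#' @param params A [sim_params()] object.
#' @return A list with `network`, `truth` and `experiments`.
#' @export
#' @examples
#' sim <- simulate_study(sim_params(n_tf = 8, n_cwp = 40, n_planted_tf = 2,
#'   planted_target_count = 10, n_experiments = 3, seed = 42))
#' length(sim$experiments)
simulate_study <- function(params) {
  net <- generate_regulatory_network(params)
  comp <- generate_expression_compendium(net$network, net$truth, params)
  list(network = net$network, truth = comp$truth, experiments = comp$experiments)
}
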