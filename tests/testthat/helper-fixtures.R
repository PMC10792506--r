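# In-code fixtures and independent oracles shared across the suite.

# Small hand-written network: TFs A, B, C over g1..g3.
#   A -> g1, g2;  B -> g2, g3;  C -> g3
toy_network <- function() {
  regnet(
    nodes = tibble::tibble(
      id = c("A", "B", "C", "g1", "g2", "g3"),
      kind = c("TF", "TF", "TF", "CWP", "CWP", "CWP")
    ),
    edges = tibble::tibble(
      source_id = c("A", "A", "B", "B", "C"),
      target_id = c("g1", "g2", "g2", "g3", "g3")
    ),
    tf_processes = tibble::tibble(
      tf_id = c("A", "B"),
      process = c("response to water deprivation", "leaf development")
    ),
    cwp_classes = tibble::tibble(
      gene_id = c("g1", "g2", "g3"),
      functional_class = c("proteases", "proteases", "oxidoreductases")
    )
  )
}

# Random bipartite network for property-style sweeps.
random_network <- function(n_tf, n_cwp, p_edge, seed) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  genes <- sprintf("g%03d", seq_len(n_cwp))
  hit <- runif(n_tf * n_cwp) < p_edge
  edges <- tibble::tibble(
    source_id = rep(tfs, each = n_cwp)[hit],
    target_id = rep(genes, times = n_tf)[hit]
  )
  regnet(
    nodes = tibble::tibble(id = c(tfs, genes),
                           kind = rep(c("TF", "CWP"), c(n_tf, n_cwp))),
    edges = edges,
    tf_processes = tibble::tibble(
      tf_id = tfs,
      process = sample(c("response to water deprivation", "leaf development"),
                       n_tf, replace = TRUE)
    ),
    cwp_classes = tibble::tibble(
      gene_id = genes,
      functional_class = sample(cwp_functional_classes(), n_cwp, replace = TRUE)
    )
  )
}

# One two-group experiment from explicit per-gene control/stress matrices.
make_experiment <- function(id, gene_ids, ctrl, strs) {
  ctrl <- matrix(ctrl, nrow = length(gene_ids))
  strs <- matrix(strs, nrow = length(gene_ids))
  samples <- c(sprintf("c%d", seq_len(ncol(ctrl))),
               sprintf("s%d", seq_len(ncol(strs))))
  expr <- cbind(ctrl, strs)
  colnames(expr) <- samples
  list(
    experiment_id = id,
    expr = dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                            tibble::as_tibble(expr)),
    samples = tibble::tibble(
      sample_id = samples,
      group = rep(c("control", "stress"), c(ncol(ctrl), ncol(strs)))
    )
  )
}

# A DE table with directions assigned directly (bypasses expression data).
direction_table <- function(experiment_id, gene_ids, directions) {
  tibble::tibble(
    experiment_id = experiment_id,
    gene_id = gene_ids,
    logFC = 2 * directions,
    p_value = ifelse(directions == 0, 0.9, 0.001),
    direction = as.integer(directions)
  )
}

# --- independent oracles -----------------------------------------------------

# Hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws.
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / choose(N, n)
}

# Binomial upper tail by enumeration of all 2^n success patterns.
binom_tail_enum <- function(k, n, p0) {
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- apply(patterns, 1, function(x) prod(ifelse(x == 1, p0, 1 - p0)))
  sum(w[rowSums(patterns) >= k])
}

# Exact probability that the vote-counting rule declares a gene stable when
# each experiment independently calls +1 or -1 with probability q1 each:
# all nonzero calls must share one sign and number at least k_star.
stable_prob_enum <- function(n, q1, k_star) {
  p <- 0
  for (j in k_star:n) {
    p <- p + choose(n, j) * 2 * q1^j * (1 - 2 * q1)^(n - j)
  }
  p
}
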