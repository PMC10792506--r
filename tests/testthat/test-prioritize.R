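test_that("hypergeometric tail matches exhaustive draw enumeration", {
  # frozen hand-countable case: P(X >= 3) with 4 marked of 10, 5 drawn
  #   = [C(4,3)C(6,2) + C(4,4)C(6,1)] / C(10,5) = 66/252
  expect_equal(hypergeometric_tail(3, 4, 5, 10), 66 / 252)
  expect_equal(hypergeometric_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeometric_tail(5, 10, 5, 10), 1) # every gene marked

  for (N in c(5, 8, 9)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in max(0, K + n - N):min(K, n)) {
          expect_equal(hypergeometric_tail(k, K, n, N),
                       hyper_tail_enum(k, K, n, N),
                       tolerance = 1e-12,
                       info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N))
        }
      }
    }
  }
})

test_that("hypergeometric tail is strictly decreasing in k on its support", {
  for (par in list(c(6, 8, 20), c(4, 4, 10), c(10, 15, 30))) {
    K <- par[1]; n <- par[2]; N <- par[3]
    ks <- max(0, K + n - N):min(K, n)
    tails <- hypergeometric_tail(ks, K, n, N)
    expect_true(all(diff(tails) < 0))
  }
  expect_error(hypergeometric_tail(5, 4, 5, 10), "min")
  expect_error(hypergeometric_tail(1, 12, 5, 10), "exceed")
})

test_that("per-TF enrichment counts overlaps in the declared universe", {
  genes <- sprintf("g%d", 1:10)
  net <- regnet(
    nodes = tibble::tibble(id = c("TFa", genes),
                           kind = c("TF", rep("CWP", 10))),
    edges = tibble::tibble(source_id = "TFa", target_id = sprintf("g%d", 1:4))
  )
  de <- direction_table("E1", genes, c(1, 1, -1, 0, 0, 0, 0, 0, 0, 0))
  rec <- tf_enrichment(net, de)
  expect_equal(rec$k, 3)
  expect_equal(rec$K, 4)
  expect_equal(rec$n, 3)
  expect_equal(rec$N, 10)
  expect_equal(rec$p_value, 4 / 120) # C(4,3)/C(10,3), all three DEGs in targets
  expect_true(rec$enriched)

  # disjoint DEGs: tail from zero is 1
  de2 <- direction_table("E2", genes, c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0))
  rec2 <- tf_enrichment(net, de2)
  expect_equal(rec2$k, 0)
  expect_equal(rec2$p_value, 1)
  expect_false(rec2$enriched)
})

test_that("degenerate and saturated universes cannot show enrichment", {
  genes <- sprintf("g%d", 1:4)
  net <- regnet(
    nodes = tibble::tibble(id = c("TFa", "TFb", genes),
                           kind = c("TF", "TF", rep("CWP", 4))),
    edges = tibble::tibble(source_id = "TFa", target_id = genes)
  )
  de <- direction_table("E1", genes, c(1, 1, 0, 0))
  rec <- tf_enrichment(net, de)
  # TFa's targets are the whole universe -> k = n, p = 1
  a <- rec[rec$tf_id == "TFa", ]
  expect_equal(a$K, a$N)
  expect_equal(a$p_value, 1)
  expect_false(a$enriched)
  # TFb has no targets: degenerate record, never enriched
  b <- rec[rec$tf_id == "TFb", ]
  expect_true(b$degenerate)
  expect_equal(b$p_value, 1)
})

test_that("STF counts enriched experiments and rejects duplicate records", {
  genes <- sprintf("g%d", 1:10)
  net <- regnet(
    nodes = tibble::tibble(id = c("TFa", genes), kind = c("TF", rep("CWP", 10))),
    edges = tibble::tibble(source_id = "TFa", target_id = sprintf("g%d", 1:4))
  )
  recs <- dplyr::bind_rows(
    tf_enrichment(net, direction_table("E1", genes,
                                       c(1, 1, -1, 0, 0, 0, 0, 0, 0, 0))),
    tf_enrichment(net, direction_table("E2", genes,
                                       c(0, 0, 0, 0, 1, 1, 0, 0, 0, 0)))
  )
  expect_equal(compute_stf(recs)$stf, 1L) # enriched in E1 only

  none <- dplyr::mutate(recs, enriched = FALSE)
  expect_equal(compute_stf(none)$stf, 0L)
  all5 <- dplyr::bind_rows(lapply(sprintf("E%d", 1:5), function(e) {
    dplyr::mutate(recs[1, ], experiment_id = e, enriched = TRUE)
  }))
  expect_equal(compute_stf(all5)$stf, 5L)
  expect_error(compute_stf(dplyr::bind_rows(recs, recs)), "duplicate")
})

test_that("STF is invariant to experiment relabelling", {
  net <- random_network(8, 40, 0.12, seed = 2)
  genes <- cwp_ids(net)
  set.seed(7)
  des <- lapply(1:3, function(i) {
    direction_table(sprintf("E%d", i), genes,
                    sample(c(-1, 0, 1), length(genes), replace = TRUE,
                           prob = c(0.1, 0.7, 0.2)))
  })
  recs <- dplyr::bind_rows(lapply(des, function(d) tf_enrichment(net, d)))
  relabel <- dplyr::mutate(recs, experiment_id = dplyr::recode(
    experiment_id, E1 = "E3", E2 = "E1", E3 = "E2"
  ))
  expect_equal(compute_stf(recs), compute_stf(relabel))
})

test_that("priority TFs are exactly those enriched at least once", {
  stf <- tibble::tibble(tf_id = c("A", "B", "C"), stf = c(2L, 0L, 1L))
  expect_equal(select_priority_tfs(stf), c("A", "C"))
  expect_equal(select_priority_tfs(tibble::tibble(tf_id = "A", stf = 0L)),
               character(0))
  expect_equal(select_priority_tfs(tibble::tibble(tf_id = "A", stf = 5L)), "A")
})

test_that("network reduction keeps priority TFs, their targets and edges", {
  nodes <- tibble::tibble(id = c("A", "B", "C", "g1", "g2", "g3"),
                          kind = rep(c("TF", "CWP"), each = 3))
  edges <- tibble::tibble(source_id = c("A", "A", "B", "B", "C"),
                          target_id = c("g1", "g2", "g2", "g3", "g3"))
  net <- regnet(nodes, edges)

  red <- reduce_network(net, "A")
  expect_setequal(red$nodes$id, c("A", "g1", "g2"))
  expect_equal(nrow(red$edges), 2)

  expect_equal(reduce_network(net, c("A", "B", "C"))$nodes, net$nodes)
  expect_equal(nrow(reduce_network(net, character(0))$nodes), 0)
  expect_error(reduce_network(net, "nope"), "not in network")
})

test_that("SCWP is the TF in-degree and satisfies the handshake identity", {
  nodes <- tibble::tibble(id = c("A", "B", "C", "g1", "g2"),
                          kind = c("TF", "TF", "TF", "CWP", "CWP"))
  edges <- tibble::tibble(source_id = c("A", "B", "C", "A"),
                          target_id = c("g1", "g1", "g1", "g2"))
  net <- regnet(nodes, edges)
  scwp <- compute_scwp(net)
  expect_equal(scwp$scwp[scwp$gene_id == "g1"], 3L)
  expect_equal(scwp$scwp[scwp$gene_id == "g2"], 1L)
  expect_equal(sum(scwp$scwp), nrow(net$edges))

  for (seed in 1:5) {
    rnd <- random_network(7, 30, 0.15, seed = seed)
    expect_equal(sum(compute_scwp(rnd)$scwp),
                 sum(rnd$edges$relation == "regulates"))
  }
})

test_that("SCWP is invariant to edge-list line order", {
  net <- random_network(6, 25, 0.2, seed = 3)
  shuffled <- regnet(net$nodes, net$edges[sample(nrow(net$edges)), ],
                     net$tf_processes, net$cwp_classes)
  expect_equal(compute_scwp(shuffled), compute_scwp(net))
})

test_that("reduction never increases any gene's SCWP", {
  for (seed in 1:5) {
    net <- random_network(9, 40, 0.12, seed = 100 + seed)
    before <- compute_scwp(net)
    priority <- sort(tf_ids(net))[1:4]
    after <- compute_scwp(reduce_network(net, priority))
    joined <- dplyr::inner_join(before, after, by = "gene_id",
                                suffix = c("_pre", "_post"))
    expect_true(all(joined$scwp_post <= joined$scwp_pre))
  }
})

test_that("ranking is descending with lexicographic tie-break", {
  r <- rank_scores(tibble::tibble(id = c("X", "Y"), s = c(5, 7)), "id", "s")
  expect_equal(r$id, c("Y", "X"))
  r <- rank_scores(tibble::tibble(id = c("B", "A"), s = c(3, 3)), "id", "s")
  expect_equal(r$id, c("A", "B"))
  expect_equal(r$rank, 1:2)
  single <- rank_scores(tibble::tibble(id = "Z", s = 0), "id", "s")
  expect_equal(single$id, "Z")
  expect_error(rank_scores(tibble::tibble(id = character(), s = numeric())),
               "nonempty")
})
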