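test_that("the constructor validates node kinds, endpoints and edge typing", {
  nodes <- tibble::tibble(id = c("T1", "g1", "m1"),
                          kind = c("TF", "CWP", "metabolite"))
  net <- regnet(nodes, tibble::tibble(
    source_id = c("T1", "m1"), target_id = c("g1", "T1"),
    relation = c("regulates", "affects")
  ))
  expect_s3_class(net, "tfprio_regnet")
  expect_equal(nrow(net$edges), 2)

  expect_error(regnet(nodes, tibble::tibble(source_id = "T1", target_id = "T1")),
               "self-edges")
  expect_error(regnet(nodes, tibble::tibble(source_id = "T1", target_id = "zz")),
               "not in nodes")
  expect_error(regnet(nodes, tibble::tibble(source_id = "g1", target_id = "T1")),
               "originate from TF")
  expect_error(regnet(nodes, tibble::tibble(source_id = "m1", target_id = "g1",
                                            relation = "affects")),
               "metabolite -> TF")
})

test_that("the loader handles empty files, duplicates and counts correctly", {
  dir <- withr::local_tempdir()
  empty <- file.path(dir, "empty.tsv")
  writeLines("source_id\ttarget_id", empty)
  expect_equal(nrow(read_network(empty)$edges), 0)

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("source_id\ttarget_id",
               "T1\tg1", "T1\tg1", "T1\tg2"), dup)
  net <- read_network(dup)
  expect_equal(nrow(net$edges), 2) # duplicate line merged

  full <- file.path(dir, "full.tsv")
  writeLines(c("source_id\ttarget_id",
               as.vector(outer(paste0("T", 1:3), paste0("g", 1:2),
                               function(a, b) paste(a, b, sep = "\t")))), full)
  net <- read_network(full)
  expect_equal(nrow(net$edges), 6)
  expect_equal(nrow(net$nodes), 5)
  expect_setequal(tf_ids(net), paste0("T", 1:3))
})

test_that("SIF files load with kinds inferred and bad lines reported", {
  dir <- withr::local_tempdir()
  sif <- file.path(dir, "net.sif")
  writeLines(c("T1 regulates g1", "T1\tregulates\tg2", "ABA affects T1"), sif)
  net <- read_network(sif)
  expect_setequal(tf_ids(net), "T1")
  expect_setequal(cwp_ids(net), c("g1", "g2"))
  expect_equal(net$nodes$kind[net$nodes$id == "ABA"], "metabolite")

  bad <- file.path(dir, "bad.sif")
  writeLines(c("T1 regulates g1", "T1 g2"), bad)
  expect_error(read_network(bad), "line 2")
})

test_that("networks round-trip through the writer and loader", {
  net <- random_network(6, 25, 0.15, seed = 4)
  stem <- file.path(withr::local_tempdir(), "net")
  write_network(net, stem)
  back <- read_network(paste0(stem, "_edges.tsv"),
                       paste0(stem, "_tf_processes.tsv"),
                       paste0(stem, "_cwp_classes.tsv"))
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$tf_processes, net$tf_processes)
  expect_equal(back$cwp_classes, net$cwp_classes)
  # GraphML written alongside is a readable graph of the same size
  g <- igraph::read_graph(paste0(stem, ".graphml"), format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
})

test_that("pruning removes exactly the CWP genes without TF regulation", {
  nodes <- tibble::tibble(
    id = c("T1", "T2", sprintf("g%d", 1:10)),
    kind = c("TF", "TF", rep("CWP", 10))
  )
  edges <- tibble::tibble(source_id = c("T1", "T1", "T2", "T2", "T2", "T1"),
                          target_id = c("g1", "g2", "g3", "g4", "g5", "g6"))
  net <- regnet(nodes, edges)
  pruned <- prune_unconnected_targets(net)
  expect_setequal(cwp_ids(pruned), sprintf("g%d", 1:6)) # 4 orphans dropped
  expect_setequal(tf_ids(pruned), c("T1", "T2"))
  expect_equal(pruned$edges, net$edges)
  # idempotent, and a fixed point when nothing is orphaned
  expect_equal(prune_unconnected_targets(pruned), pruned)
})

test_that("the process filter keeps matching TFs and prunes the fallout", {
  net <- toy_network() # A: water deprivation, B: leaf development, C: none
  kept <- filter_tfs_by_process(net, process_filter())
  expect_setequal(tf_ids(kept), "A")
  expect_setequal(cwp_ids(kept), c("g1", "g2")) # g3 lost both regulators

  # unannotated TFs can never match
  none <- filter_tfs_by_process(net, process_filter("no such process"))
  expect_equal(length(tf_ids(none)), 0)
  expect_equal(length(cwp_ids(none)), 0)
})

test_that("substring matching is case-insensitive by default", {
  net <- regnet(
    nodes = tibble::tibble(id = c("T1", "T2", "g1"), kind = c("TF", "TF", "CWP")),
    edges = tibble::tibble(source_id = c("T1", "T2"), target_id = c("g1", "g1")),
    tf_processes = tibble::tibble(tf_id = c("T1", "T2"),
                                  process = c("Drought Recovery", "cold response"))
  )
  sub <- filter_tfs_by_process(net, process_filter("drought", match_mode = "substring"))
  expect_setequal(tf_ids(sub), "T1")
  strict <- filter_tfs_by_process(
    net, process_filter("drought", match_mode = "substring", case_sensitive = TRUE)
  )
  expect_equal(length(tf_ids(strict)), 0)
})

test_that("restricting TFs to stable DEGs behaves at both extremes", {
  net <- toy_network()
  empty <- restrict_tfs_to_stable_degs(net, tibble::tibble(gene_id = character()))
  expect_equal(length(tf_ids(empty)), 0)
  expect_equal(length(cwp_ids(empty)), 0)

  all_in <- restrict_tfs_to_stable_degs(net, tibble::tibble(gene_id = c("A", "B", "C")))
  expect_equal(all_in$nodes, net$nodes)
  expect_equal(all_in$edges, net$edges)

  # exclusive targets fall with their TF
  nodes <- tibble::tibble(id = c("X", "Y", "Z", "g1", "g2", "g3"),
                          kind = rep(c("TF", "CWP"), each = 3))
  edges <- tibble::tibble(source_id = c("X", "Y", "Z"),
                          target_id = c("g1", "g2", "g3"))
  net2 <- regnet(nodes, edges)
  one <- restrict_tfs_to_stable_degs(net2, tibble::tibble(gene_id = "Y"))
  expect_setequal(tf_ids(one), "Y")
  expect_setequal(cwp_ids(one), "g2")
})

test_that("filters are monotone: outputs are node and edge subsets", {
  stable <- tibble::tibble(gene_id = sprintf("T%02d", seq(1, 9, by = 2)))
  for (seed in 1:5) {
    net <- random_network(10, 60, 0.08, seed = seed)
    for (filtered in list(
      prune_unconnected_targets(net),
      filter_tfs_by_process(net, process_filter()),
      restrict_tfs_to_stable_degs(net, stable)
    )) {
      expect_true(all(filtered$nodes$id %in% net$nodes$id))
      edge_key <- function(n) paste(n$edges$source_id, n$edges$target_id)
      expect_true(all(edge_key(filtered) %in% edge_key(net)))
    }
  }
})

test_that("metabolite edges ride along filters but dangling metabolites drop", {
  nodes <- tibble::tibble(
    id = c("T1", "T2", "g1", "g2", "ABA"),
    kind = c("TF", "TF", "CWP", "CWP", "metabolite")
  )
  edges <- tibble::tibble(
    source_id = c("T1", "T2", "ABA"), target_id = c("g1", "g2", "T1"),
    relation = c("regulates", "regulates", "affects")
  )
  ann <- tibble::tibble(tf_id = "T1", process = "response to water deprivation")
  net <- regnet(nodes, edges, tf_processes = ann)
  kept <- filter_tfs_by_process(net, process_filter())
  expect_true("ABA" %in% kept$nodes$id) # still affects a retained TF
  expect_true(any(kept$edges$relation == "affects"))

  gone <- restrict_tfs_to_stable_degs(net, tibble::tibble(gene_id = "T2"))
  expect_false("ABA" %in% gone$nodes$id) # its only TF was removed
})
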