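chain_map <- function() {
  annotation_map(
    tibble::tibble(gene_id = "g1", term_id = "C"),
    tibble::tibble(child = c("C", "B"), parent = c("B", "A"))
  )
}

test_that("annotations propagate to the full ancestral closure", {
  m <- propagate_annotations(chain_map())
  expect_setequal(m$annotations$term_id[m$annotations$gene_id == "g1"],
                  c("A", "B", "C"))
  # idempotent
  m2 <- propagate_annotations(m)
  expect_identical(m$annotations, m2$annotations)
})

test_that("a root-only annotation is unchanged by propagation", {
  m <- annotation_map(tibble::tibble(gene_id = "g1", term_id = "A"),
                      tibble::tibble(child = c("C", "B"),
                                     parent = c("B", "A")))
  out <- propagate_annotations(m)
  expect_equal(out$annotations$term_id, "A")
})

test_that("the M-band term propagates up to the cellular_component root", {
  m <- annotation_map(tibble::tibble(gene_id = "ttn", term_id = "GO:0031430"),
                      mband_dag())
  out <- propagate_annotations(m)
  terms <- out$annotations$term_id
  for (anc in c("GO:0030017", "GO:0030016", "GO:0043292", "GO:0005575")) {
    expect_true(anc %in% terms)
  }
  # siblings are NOT acquired
  expect_false("GO:0030018" %in% terms)
})

test_that("a cyclic term graph is rejected, naming a cycle", {
  m <- annotation_map(tibble::tibble(gene_id = "g1", term_id = "A"),
                      tibble::tibble(child = c("A", "B", "C"),
                                     parent = c("B", "C", "A")))
  expect_error(propagate_annotations(m), "cycle")
})

test_that("single-cut scan reproduces the hypergeometric enumeration", {
  # 10 genes, term on ranks 1-3, cut at 5: table [[3,2],[0,5]]
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                           stat = 10:1)
  map <- annotation_map(
    tibble::tibble(gene_id = sprintf("g%02d", 1:3), term_id = "T"),
    tibble::tibble(child = character(), parent = character())
  )
  res <- partition_scan(ranked, map, cuts = 5)
  expect_equal(nrow(res), 1L)
  expect_equal(res$n_ann_above, 3L)
  expect_equal(res$n_unann_above, 2L)
  expect_equal(res$n_ann_below, 0L)
  expect_equal(res$n_unann_below, 5L)
  # one-sided tail P(X >= 3) = C(3,3) C(7,2) / C(10,5) = 1/12
  expect_equal(res$p_one_sided, choose(7, 2) / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(res$p_value, fisher_two_sided_oracle(3, 2, 0, 5),
               tolerance = 1e-12)
  expect_equal(res$direction, "up")
  expect_true(res$p_adj >= res$p_value)
})

test_that("a term annotating every gene is never enriched", {
  ranked <- tibble::tibble(gene_id = sprintf("g%02d", 1:20), stat = 20:1)
  map <- annotation_map(
    tibble::tibble(gene_id = ranked$gene_id, term_id = "ALL"),
    tibble::tibble(child = character(), parent = character())
  )
  res <- partition_scan(ranked, map, n_partitions = 5)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$odds_ratio == 1 | res$n_unann_above == 0))
})

test_that("terms absent from the list are skipped with a message", {
  ranked <- tibble::tibble(gene_id = c("a", "b"), stat = c(2, 1))
  map <- annotation_map(
    tibble::tibble(gene_id = "zzz", term_id = "T"),
    tibble::tibble(child = character(), parent = character())
  )
  expect_message(res <- partition_scan(ranked, map, cuts = 1), "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand case with distinct adjusted values: p_(i) * m / i, cummin from top
  expect_equal(bh_adjust(c(0.001, 0.02, 0.9)),
               c(0.003, 0.03, 0.9))
  set.seed(30)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))
    expect_true(all(bh_adjust(p) >= p))
  }
  # order preserved relative to input positions
  p <- c(0.5, 0.001, 0.2)
  expect_equal(order(bh_adjust(p)), order(p))
})

test_that("the scan is invariant to gene-id relabeling", {
  rl <- simulate_ranked_list(400, frac_up = 0.1, frac_down = 0.02, seed = 5)
  map <- annotation_map(rl$annotations, rl$dag)
  res1 <- partition_scan(rl$ranked, map, n_partitions = 7)

  relabel <- setNames(sprintf("x%05d", sample(400)), rl$ranked$gene_id)
  ranked2 <- rl$ranked
  ranked2$gene_id <- unname(relabel[ranked2$gene_id])
  ann2 <- rl$annotations
  ann2$gene_id <- unname(relabel[ann2$gene_id])
  res2 <- partition_scan(ranked2, annotation_map(ann2, rl$dag),
                         n_partitions = 7)
  expect_equal(res1$p_value, res2$p_value, tolerance = 1e-12)
  expect_equal(res1$n_ann_above, res2$n_ann_above)
})

test_that("an up-regulated block at realistic list size is flagged", {
  rl <- simulate_ranked_list(20000, block_term = "GO:0031430",
                             frac_up = 0.016, frac_down = 0.0069, seed = 6)
  res <- partition_scan(rl$ranked, annotation_map(rl$annotations, rl$dag),
                        n_partitions = 10, terms = "GO:0031430")
  best <- res[which.min(res$p_value), ]
  expect_lt(best$p_value, 0.001)
  expect_equal(best$direction, "up")
  expect_gt(best$pct_above, best$pct_below)
})

test_that("the M-band gene table ranks and annotates cleanly", {
  path <- system.file("extdata", "mband_genes.tsv", package = "sarcomorph")
  tab <- tibble::as_tibble(read.delim(path))
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$fold_change > 0))  # all up-regulated in IUGR
  ranked <- tibble::tibble(gene_id = tab$gene_id, stat = tab$fold_change)
  map <- propagate_annotations(annotation_map(
    tibble::tibble(gene_id = tab$gene_id, term_id = "GO:0031430"),
    mband_dag()
  ))
  ann <- map$annotations
  expect_true(all(vapply(tab$gene_id, function(g) {
    "GO:0030017" %in% ann$term_id[ann$gene_id == g]
  }, TRUE)))
  # highest fold change ranks first
  r <- ranked[order(-ranked$stat, ranked$gene_id), ]
  expect_equal(r$gene_id[1], "ENSOCUT00000009940")
})
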