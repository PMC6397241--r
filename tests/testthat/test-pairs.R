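test_that("pair construction deduplicates across queries", {
  net <- data.frame(suppressor = c("a", "b", "c"), query = "Q1")
  p <- build_pairs(net)
  expect_identical(nrow(p$interacting), 3L)
  expect_identical(nrow(p$sharing), 3L)
  expect_setequal(paste(p$sharing$gene1, p$sharing$gene2),
                  c("a b", "a c", "b c"))
  # a second query sharing b, c adds no new sharing pair
  net2 <- rbind(net, data.frame(suppressor = c("b", "c"), query = "Q2"))
  p2 <- build_pairs(net2)
  expect_identical(nrow(p2$sharing), 3L)
  expect_identical(nrow(p2$interacting), 5L)
  # single edge
  p1 <- build_pairs(data.frame(suppressor = "a", query = "Q1"))
  expect_identical(nrow(p1$interacting), 1L)
  expect_identical(nrow(p1$sharing), 0L)
  expect_error(build_pairs(data.frame(suppressor = "x", query = "x")),
               "self-edges")
  # no unordered pair appears twice
  expect_false(any(duplicated(paste(p2$interacting$gene1,
                                    p2$interacting$gene2))))
})

ann_toy <- function() {
  list(go = data.frame(gene_id = c("a", "b", "b", "c"),
                       term = c("ribosome", "ribosome", "mitochondrion",
                                "mitochondrion")),
       loc = data.frame(gene_id = c("a", "a", "b", "c", "c", "d"),
                        term = c("nucleus", "ER", "nucleus", "nucleus",
                                 "ER", "cytosol")),
       ppi = data.frame(gene1 = "a", gene2 = "c"))
}

test_that("predicates handle sharing, generic terms and indeterminacy", {
  ann <- ann_toy()
  pr <- function(g1, g2) data.frame(gene1 = g1, gene2 = g2)
  expect_true(evaluate_predicate(pr("a", "b"), "shared_go", ann))
  expect_false(evaluate_predicate(pr("a", "c"), "shared_go", ann))
  # gene with no GO terms: indeterminate
  expect_identical(evaluate_predicate(pr("a", "d"), "shared_go", ann), NA)
  # nucleus-only sharing does not count as co-localization
  expect_false(evaluate_predicate(pr("b", "c"), "colocalized", ann))
  expect_true(evaluate_predicate(pr("a", "c"), "colocalized", ann))
  expect_identical(evaluate_predicate(pr("a", "e"), "colocalized", ann),
                   NA)
  # physical interaction is never indeterminate, and order-symmetric
  expect_true(evaluate_predicate(pr("c", "a"), "ppi", ann))
  expect_false(evaluate_predicate(pr("a", "b"), "ppi", ann))
  expect_identical(evaluate_predicate(pr("b", "a"), "shared_go", ann),
                   evaluate_predicate(pr("a", "b"), "shared_go", ann))
  expect_error(evaluate_predicate(pr("a", "b"), "nope", ann), "predicate")
})

test_that("enrichment against an enumerated toy background is exact", {
  # 4 essential x 6 non-essential genes; PPI set = 6 of the 24 cross pairs
  ess <- paste0("E", 1:4); non <- paste0("N", 1:6)
  ppi <- data.frame(gene1 = rep("E1", 6), gene2 = non)
  ann <- list(ppi = ppi)
  obs <- data.frame(gene1 = rep("E1", 4), gene2 = non[1:4])
  rep <- enrichment(obs, list(type = "cross", set1 = ess, set2 = non),
                    "ppi", ann, n_perm = 4000, seed = 5)
  expect_identical(rep$B, 24L)
  expect_identical(rep$K, 6L)
  expect_equal(rep$expected_fraction, 0.25)
  expect_equal(rep$ratio, 4)
  expect_identical(rep$method, "exact-enumeration")
  expect_equal(rep$p_exact, phyper(3, 6, 18, 4, lower.tail = FALSE))
  expect_lt(abs(rep$p_value - rep$p_exact), 0.01)
  # predicate true for every pair: ratio 1, p 1
  ppi_all <- expand.grid(gene1 = ess, gene2 = non,
                         stringsAsFactors = FALSE)
  rep_all <- enrichment(obs, list(type = "cross", set1 = ess, set2 = non),
                        "ppi", list(ppi = ppi_all), n_perm = 500, seed = 1)
  expect_equal(rep_all$ratio, 1)
  expect_equal(rep_all$p_value, 1)
  # observed pair outside the background is rejected
  expect_error(enrichment(data.frame(gene1 = "E1", gene2 = "X9"),
                          list(type = "cross", set1 = ess, set2 = non),
                          "ppi", ann, n_perm = 10, seed = 1),
               "outside the background")
})

test_that("within-set backgrounds enumerate all unordered pairs", {
  genes <- paste0("g", 1:7)
  set.seed(3)
  terms <- data.frame(gene_id = sample(genes, 10, replace = TRUE),
                      term = sample(c("t1", "t2", "t3"), 10, replace = TRUE))
  # direct oracle over combn
  cmb <- utils::combn(genes, 2)
  oracle <- vapply(seq_len(ncol(cmb)), function(i)
    evaluate_predicate(data.frame(gene1 = cmb[1, i], gene2 = cmb[2, i]),
                       "shared_go", list(go = terms)), NA)
  ok <- which(!is.na(oracle))[1:5]  # observed pairs must be evaluable
  obs <- data.frame(gene1 = cmb[1, ok], gene2 = cmb[2, ok])
  rep <- enrichment(obs, list(type = "within", set = genes), "shared_go",
                    list(go = terms), n_perm = 200, seed = 2)
  expect_identical(rep$B, sum(!is.na(oracle)))
  expect_identical(rep$K, as.integer(sum(oracle, na.rm = TRUE)))
})

test_that("sampled backgrounds converge to the enumerated fraction", {
  set.seed(41)
  genes <- sprintf("g%03d", 1:80)
  terms <- data.frame(gene_id = rep(genes, 2),
                      term = sample(sprintf("t%02d", 1:12), 160,
                                    replace = TRUE))
  obs <- data.frame(gene1 = genes[1:10], gene2 = genes[21:30])
  exact <- enrichment(obs, list(type = "within", set = genes), "shared_go",
                      list(go = terms), n_perm = 100, seed = 7)
  sampled <- enrichment(obs, list(type = "within", set = genes),
                        "shared_go", list(go = terms), n_perm = 100,
                        seed = 7, max_enum = 100, sample_size = 20000)
  expect_identical(sampled$method, "sampled")
  f <- exact$expected_fraction
  se <- sqrt(f * (1 - f) / 20000)
  expect_lt(abs(sampled$expected_fraction - f), 4 * se)
})

test_that("planted GO-assortative networks show enrichment, null ones do not", {
  sig <- 0
  for (s in 1:10) {
    ann <- simulate_annotation_tables(sim_params(
      seed = 700 + s, n_screened = 30L, n_bypassable = 10L,
      n_nonessential = 120L, n_terms = 15L, go_odds = 5, mean_degree = 5,
      n_ppi = 100L))
    prs <- build_pairs(ann$network)
    rep <- enrichment(prs$interacting,
                      list(type = "cross", set1 = ann$screened,
                           set2 = ann$nonessential), "shared_go",
                      list(go = ann$terms), n_perm = 500, seed = s)
    sig <- sig + (rep$ratio > 1 && rep$p_value < 0.05)
  }
  expect_gte(sig, 8)
})
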