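mk_catalog <- function(members_list, features = NULL) {
  mem <- data.frame(
    complex_id = rep(names(members_list), lengths(members_list)),
    gene_id = unlist(members_list, use.names = FALSE), queried = TRUE,
    stringsAsFactors = FALSE)
  complex_catalog(mem, features)
}

test_that("complexes are classified by their queried subunits", {
  cat <- mk_catalog(list(c1 = c("a", "b"), c2 = c("c", "d", "e"),
                         c3 = c("f", "g"), c4 = "h"))
  cls <- classify_complexes(cat, c("a", "b", "c"))
  expect_identical(cls$category[cls$complex_id == "c1"], "bypassable")
  expect_identical(cls$category[cls$complex_id == "c2"], "mixed")
  expect_identical(cls$category[cls$complex_id == "c3"], "non_bypassable")
  # single-subunit complexes are ineligible
  expect_true(is.na(cls$category[cls$complex_id == "c4"]))
  expect_false(cls$eligible[cls$complex_id == "c4"])
})

test_that("permutation expectations match exhaustive enumeration", {
  # two disjoint 2-gene complexes, 2 bypassable among 4 genes: the 6 equally
  # likely assignments give expected counts 1/3, 4/3, 1/3
  cat <- mk_catalog(list(c1 = c("g1", "g2"), c2 = c("g3", "g4")))
  exhaustive <- function(cat, genes, b) {
    sets <- utils::combn(genes, b, simplify = FALSE)
    counts <- vapply(sets, function(s) {
      cls <- classify_complexes(cat, s)
      c(sum(cls$category == "bypassable", na.rm = TRUE),
        sum(cls$category == "non_bypassable", na.rm = TRUE),
        sum(cls$category == "mixed", na.rm = TRUE))
    }, numeric(3))
    rowMeans(counts)
  }
  exact <- exhaustive(cat, paste0("g", 1:4), 2)
  expect_equal(exact, c(1 / 3, 1 / 3, 4 / 3))
  pr <- permute_shared_bypassability(cat, c("g1", "g2"), n_perm = 20000,
                                     seed = 3)
  got <- setNames(pr$summary$expected, pr$summary$category)
  se <- sqrt(2 / 3) / sqrt(20000)  # category counts are bounded by 2
  expect_lt(abs(got[["bypassable"]] - 1 / 3), 3 * se)
  expect_lt(abs(got[["non_bypassable"]] - 1 / 3), 3 * se)
  expect_lt(abs(got[["mixed"]] - 4 / 3), 3 * se)
  # observed counts equal the unpermuted classification
  expect_equal(pr$summary$observed[pr$summary$category == "bypassable"], 1)
  # a larger random universe, checked against enumeration as well
  set.seed(8)
  cat2 <- mk_catalog(list(c1 = c("h1", "h2", "h3"), c2 = c("h4", "h5"),
                          c3 = c("h2", "h6", "h7")))
  exact2 <- exhaustive(cat2, paste0("h", 1:7), 3)
  pr2 <- permute_shared_bypassability(cat2, c("h1", "h2", "h6"),
                                      n_perm = 50000, seed = 4)
  got2 <- setNames(pr2$summary$expected, pr2$summary$category)
  for (cc in c("bypassable", "non_bypassable", "mixed"))
    expect_lt(abs(got2[[cc]] - exact2[[match(cc, c("bypassable",
                                                   "non_bypassable",
                                                   "mixed"))]]),
              3 * sqrt(3) / sqrt(50000))
})

test_that("degenerate permutations behave sensibly", {
  cat <- mk_catalog(list(c1 = c("a", "b"), c2 = c("c", "d")))
  pr <- permute_shared_bypassability(cat, c("a", "b", "c", "d"),
                                     n_perm = 50, seed = 1)
  expect_equal(pr$summary$expected, as.numeric(pr$summary$observed))
  expect_true(all(pr$summary$p_value == 1))
  expect_error(permute_shared_bypassability(cat, letters[1:4], n_perm = 10,
                                            seed = 1, n_bypassable = 9),
               "exceeds")
})

test_that("feature screening reports the AUC as U/(n1 n2)", {
  feats <- data.frame(complex_id = sprintf("c%d", 1:10),
                      perfect = c(6:10, 1:5) + 0,
                      noisy = rnorm(10))
  cat <- mk_catalog(setNames(lapply(1:10, function(i)
    sprintf("g%d_%d", i, 1:2)), sprintf("c%d", 1:10)), feats)
  byp <- unlist(lapply(1:5, function(i) sprintf("g%d_%d", i, 1:2)))
  cls <- classify_complexes(cat, byp)
  res <- feature_screen(cat, cls)
  expect_identical(res$auc[res$feature == "perfect"], 1)
  # brute-force pairwise oracle on random data
  set.seed(91)
  for (i in 1:50) {
    x <- rnorm(6); y <- rnorm(9)
    mw <- mann_whitney_feature(x, y)
    auc_oracle <- mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
    expect_equal(mw$U / (6 * 9), auc_oracle, tolerance = 1e-12)
  }
})

test_that("average-linkage clustering reproduces hand-computed merges", {
  # 1-d points 0, 1, 5, 7: UPGMA merge heights 1, 2, 5.5
  feats <- data.frame(complex_id = c("A", "B", "C", "D"),
                      f1 = c(0, 1, 5, 7))
  cat <- mk_catalog(list(A = c("a1", "a2"), B = c("b1", "b2"),
                         C = c("c1", "c2"), D = c("d1", "d2")), feats)
  cl <- cluster_complexes(cat, standardize = FALSE)
  expect_equal(cl$hclust$height, c(1, 2, 5.5))
  # identical feature vectors merge first at height zero
  feats2 <- data.frame(complex_id = c("A", "B", "C"), f1 = c(2, 2, 9),
                       f2 = c(1, 1, 4))
  cat2 <- mk_catalog(list(A = "x1", B = "x2", C = "x3"), feats2)
  cl2 <- cluster_complexes(cat2, standardize = FALSE)
  expect_equal(cl2$hclust$height[1], 0)
  expect_setequal(-cl2$hclust$merge[1, ], c(1, 2))
  # invariance to row and feature order
  perm <- c(3, 1, 4, 2)
  feats3 <- feats[perm, c("complex_id", "f1")]
  cat3 <- mk_catalog(list(C = "z1", A = "z2", D = "z3", B = "z4")[
    order(c("C", "A", "D", "B")[1:4])], feats3)
  cl3 <- cluster_complexes(cat3, standardize = FALSE)
  expect_equal(sort(cl3$hclust$height), sort(cl$hclust$height))
  expect_error(cluster_complexes(cat, "nope"), "unknown feature")
})

test_that("the lowest containing node predicts bypassable complexes", {
  feats <- data.frame(complex_id = c("A", "B", "C", "D", "E"),
                      f1 = c(0, 0.5, 1, 10, 11))
  cat <- mk_catalog(setNames(as.list(paste0("g", 1:5)),
                             c("A", "B", "C", "D", "E")), feats)
  cl <- cluster_complexes(cat, standardize = FALSE)
  # A and C first share a node once B has joined: B is the prediction
  pred <- predict_bypassable_cluster(cl, c("A", "C"))
  expect_setequal(pred$predicted, "B")
  # all leaves known: root selected, nothing predicted
  pred_all <- predict_bypassable_cluster(cl, c("A", "B", "C", "D", "E"))
  expect_length(pred_all$predicted, 0)
  # single leaf: its nearest sibling subtree
  pred_one <- predict_bypassable_cluster(cl, "D")
  expect_setequal(pred_one$predicted, "E")
  expect_error(predict_bypassable_cluster(cl, "Z"), "absent")
})

test_that("a planted feature signature recovers held-out complexes", {
  recovered <- 0; total <- 0
  for (s in 1:20) {
    set.seed(600 + s)
    n_byp <- 6; n_other <- 10
    X <- rbind(matrix(rnorm(n_byp * 4, mean = 3), n_byp),
               matrix(rnorm(n_other * 4), n_other))
    feats <- data.frame(complex_id = sprintf("c%02d", 1:16))
    for (j in 1:4) feats[[paste0("f", j)]] <- X[, j]
    cat <- mk_catalog(setNames(as.list(sprintf("g%02d", 1:16)),
                               feats$complex_id), feats)
    cl <- cluster_complexes(cat)
    known <- sprintf("c%02d", 1:4)       # 4 of the 6 planted
    held_out <- sprintf("c%02d", 5:6)
    pred <- predict_bypassable_cluster(cl, known)
    recovered <- recovered + sum(held_out %in% pred$predicted)
    total <- total + length(held_out)
  }
  expect_gte(recovered / total, 0.8)
})
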