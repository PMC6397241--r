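mk_ins <- function(pos, reads, sample = "S1", chrom = "chr1",
                   query = "q1") {
  data.frame(chrom = chrom, position = as.integer(pos), strand = "+",
             read_count = as.integer(reads), sample_id = sample,
             query_gene_id = query, stringsAsFactors = FALSE)
}

test_that("deduplication keeps the higher-read insertion within 3 bp", {
  t1 <- mk_ins(c(100, 102), c(5, 9))
  expect_identical(dedup_insertions(t1)$position, 102L)
  # distance exactly 3 is outside the rule
  t2 <- mk_ins(c(100, 103), c(5, 9))
  expect_identical(dedup_insertions(t2)$position, c(100L, 103L))
  # identical positions in different samples of the same query both survive
  t3 <- rbind(mk_ins(100, 5, "S1"), mk_ins(100, 7, "S2"))
  expect_identical(nrow(dedup_insertions(t3)), 2L)
  # read-count tie keeps the leftmost
  t4 <- mk_ins(c(100, 101), c(5, 5))
  expect_identical(dedup_insertions(t4)$position, 100L)
  # chain collapse: the retained record replaces the anchor
  t5 <- mk_ins(c(100, 102, 104), c(5, 9, 5))
  expect_identical(dedup_insertions(t5)$position, 102L)
  expect_identical(nrow(dedup_insertions(mk_ins(1, 1)[0, ])), 0L)
})

test_that("deduplication is idempotent and enforces 3-bp spacing", {
  set.seed(42)
  for (i in 1:20) {
    tb <- mk_ins(sample(1:200, 60, replace = TRUE),
                 sample(1:50, 60, replace = TRUE),
                 sample(c("S1", "S2"), 60, replace = TRUE))
    d1 <- dedup_insertions(tb)
    expect_identical(dedup_insertions(d1), d1)
    for (s in unique(d1$sample_id)) {
      pos <- sort(d1$position[d1$sample_id == s])
      if (length(pos) > 1) expect_true(all(diff(pos) >= 3L))
    }
  }
})

test_that("region partition tiles each chromosome exactly", {
  g <- toy_genome()
  g$genes <- data.frame(gene_id = "g1", chrom = "chrT", start = 200L,
                        end = 500L, strand = "+", is_essential = TRUE,
                        is_query = FALSE)
  g$chromosomes <- c(chrT = strrep("A", 1000))
  g$ttaa_sites <- list(chrT = integer(0))
  r <- partition_regions(g)
  expect_identical(r$start, c(0L, 200L, 500L))
  expect_identical(r$end, c(200L, 500L, 1000L))
  expect_identical(r$kind, c("intergenic", "ORF", "intergenic"))
  # gene abutting position 0: no leading zero-length region
  g$genes$start <- 0L; g$genes$end <- 300L
  r0 <- partition_regions(g)
  expect_identical(r0$kind, c("ORF", "intergenic"))
  # two interior genes give 5 regions
  g$genes <- rbind(g$genes, g$genes)
  g$genes$gene_id <- c("g1", "g2")
  g$genes$start <- c(200L, 600L); g$genes$end <- c(400L, 800L)
  expect_identical(nrow(partition_regions(g)), 5L)
  # overlap is an error naming the pair
  g$genes$start <- c(200L, 300L); g$genes$end <- c(400L, 500L)
  expect_error(partition_regions(g), "g1.*g2")
})

test_that("partition of a simulated genome is exact and conserved", {
  g <- simulate_genome(fast_params(seed = 3))
  r <- partition_regions(g)
  for (chrom in names(g$chromosomes)) {
    rc <- r[r$chrom == chrom, ]
    rc <- rc[order(rc$start), ]
    expect_identical(rc$start[1], 0L)
    expect_identical(rc$end[nrow(rc)], nchar(g$chromosomes[[chrom]]))
    expect_true(all(rc$start[-1] == rc$end[-nrow(rc)]))
  }
  orf <- r[r$kind == "ORF", ]
  expect_setequal(orf$region_id, g$genes$gene_id)
})

test_that("G statistic matches the closed form and a brute-force oracle", {
  # observed equals expected
  r0 <- region_gtest(10, 100, 1000, 10000)
  expect_equal(r0$G, 0)
  expect_equal(r0$p_value, 1)
  # frozen worked example
  r1 <- region_gtest(30, 100, 1000, 10000)
  expect_equal(r1$G, 2 * (30 * log(3) + 970 * log(970 / 990)),
               tolerance = 1e-12)
  expect_equal(r1$G, 26.32353, tolerance = 1e-6)
  expect_equal(r1$p_value, 2.887498e-07, tolerance = 1e-6)
  # zero-cell convention
  r2 <- region_gtest(0, 100, 1000, 10000)
  expect_equal(r2$G, 2 * 1000 * log(1000 / 990), tolerance = 1e-12)
  # degenerate: the whole genome is one region
  r3 <- region_gtest(5, 100, 10, 100)
  expect_true(r3$degenerate)
  expect_true(is.na(r3$G))
  # oracle equivalence on random tuples
  set.seed(99)
  for (i in 1:1000) {
    N_pot <- sample(100:10000, 1)
    T_sites <- sample.int(N_pot - 1, 1)
    N_obs <- sample(1:5000, 1)
    O <- rbinom(1, N_obs, T_sites / N_pot)
    g <- region_gtest(O, T_sites, N_obs, N_pot)
    E <- N_obs * T_sites / N_pot
    t1 <- if (O == 0) 0 else O * log(O / E)
    t2 <- if (N_obs - O == 0) 0 else (N_obs - O) * log((N_obs - O) /
                                                         (N_obs - E))
    G_ref <- max(0, 2 * (t1 + t2))
    expect_equal(g$G, G_ref, tolerance = 1e-10)
    expect_equal(g$p_value, pchisq(G_ref, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("G increases monotonically in O above the expectation", {
  O <- 11:400
  G <- region_gtest(O, 100, 1000, 10000)$G
  expect_true(all(diff(G) > 0))
})

test_that("candidate calling conserves counts and honours thresholds", {
  p <- fast_params(seed = 17, n_insertions = 800L)
  g <- simulate_genome(p)
  sup <- median_length_gene(g)
  tb <- simulate_tboe_screen(g, sup, p)
  res <- call_tboe_candidates(tb, g)
  expect_identical(sum(res$O), attr(res, "n_dedup"))
  expect_identical(sum(res$T_sites), sum(lengths(g$ttaa_sites)))
  expect_true(all(res$q_value >= res$p_value, na.rm = TRUE))
  expect_true(all(res$kind[res$candidate] == "ORF"))
  expect_identical(res$region_id[1], sup)
  expect_error(call_tboe_candidates(tb[0, ], g), "no insertions")
})

test_that("a single targeted ORF is the unique candidate", {
  g <- simulate_genome(fast_params(seed = 23))
  gene <- median_length_gene(g)
  gi <- g$genes[g$genes$gene_id == gene, ]
  sites <- g$ttaa_sites[[gi$chrom]]
  inside <- sites[sites >= gi$start & sites < gi$end]
  expect_gt(length(inside), 0)
  tb <- mk_ins(rep(inside, length.out = 40), rep(10, 40), chrom = gi$chrom)
  tb$position <- as.integer(tb$position)
  res <- call_tboe_candidates(tb, g)
  expect_identical(res$region_id[res$candidate], gene)
})
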