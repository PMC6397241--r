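# toy_genome gene gplus: CDS ATG GCT TGG AAA CCC GGG TTT CTC TAC TAA
# at chrT [10, 40), + strand; gminus carries the same CDS on - strand at
# [50, 80); gintron splits the CDS with a GT..AG intron at chrU [25, 45).

snp <- function(chrom, pos, ref, alt) list(chrom = chrom, pos = pos,
                                           ref = ref, alt = alt)

test_that("variant effects are classified per the standard genetic code", {
  g <- toy_genome()
  expect_identical(classify_effect(snp("chrT", 5, "A", "G"), g),
                   "intergenic")
  # codon position 3 of ATG: ATG -> ATA is Met -> Ile
  expect_identical(classify_effect(snp("chrT", 12, "G", "A"), g),
                   "missense")
  # TGG -> TGA (codon 3, interior): stop gain
  expect_identical(classify_effect(snp("chrT", 18, "G", "A"), g),
                   "stop_gain")
  # GGG -> GGA: synonymous (Gly)
  expect_identical(classify_effect(snp("chrT", 27, "G", "A"), g),
                   "synonymous")
  # terminal TAA -> TAC: stop loss
  expect_identical(classify_effect(snp("chrT", 39, "A", "C"), g),
                   "stop_loss")
  # reference mismatch is an error
  expect_error(classify_effect(snp("chrT", 12, "C", "A"), g), "mismatch")
})

test_that("minus-strand and intron-containing genes classify correctly", {
  g <- toy_genome()
  # gminus occupies [50, 80); its last genome base (79) is the CDS start.
  # Genome position 77 is CDS position 2 (the G of ATG, complement C).
  expect_identical(boescan:::genome_base(g, "chrT", 77), "C")
  expect_identical(classify_effect(snp("chrT", 77, "C", "T"), g),
                   "missense")  # ATG -> ATA on the coding strand
  # genome position 71 is coding position 8 (TGG codon; -> TGA stop gain)
  expect_identical(classify_effect(snp("chrT", 71, "C", "T"), g),
                   "stop_gain")
  # intron of gintron spans [25, 45): GT..AG
  expect_identical(classify_effect(snp("chrU", 25, "G", "A"), g),
                   "splice_site")
  expect_identical(classify_effect(snp("chrU", 44, "G", "A"), g),
                   "splice_site")
  expect_identical(classify_effect(snp("chrU", 43, "A", "T"), g),
                   "splice_site")
  expect_identical(classify_effect(snp("chrU", 30, "C", "T"), g),
                   "intronic")
  # exon 2 of gintron: CDS continues across the junction
  expect_identical(classify_effect(snp("chrU", 46, "G", "A"), g),
                   classify_effect(snp("chrT", 26, "G", "A"), g))
})

test_that("effect classes are invariant under reverse-complementation", {
  g <- simulate_genome(fast_params(seed = 19))
  # build the mirrored genome: reverse-complement sequences, flip strands
  # and reflect all coordinates
  g2 <- g
  for (chrom in names(g$chromosomes)) {
    L <- nchar(g$chromosomes[[chrom]])
    g2$chromosomes[[chrom]] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(g$chromosomes[[chrom]])))
    sel <- g2$genes$chrom == chrom
    s <- g2$genes$start[sel]; e <- g2$genes$end[sel]
    g2$genes$start[sel] <- L - e; g2$genes$end[sel] <- L - s
    g2$genes$strand[sel] <- ifelse(g2$genes$strand[sel] == "+", "-", "+")
    gene_chrom <- g$genes$chrom[match(g2$exons$gene_id, g$genes$gene_id)]
    esel <- gene_chrom == chrom
    es <- g2$exons$start[esel]; ee <- g2$exons$end[esel]
    g2$exons$start[esel] <- L - ee; g2$exons$end[esel] <- L - es
    g2$ttaa_sites[[chrom]] <- find_ttaa_sites(g2$chromosomes[[chrom]])
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(7)
  checked <- 0
  for (i in 1:200) {
    chrom <- sample(names(g$chromosomes), 1)
    L <- nchar(g$chromosomes[[chrom]])
    pos <- sample.int(L, 1) - 1L
    ref <- boescan:::genome_base(g, chrom, pos)
    if (!ref %in% names(comp)) next
    alt <- sample(setdiff(names(comp), ref), 1)
    e1 <- classify_effect(snp(chrom, pos, ref, alt), g)
    e2 <- classify_effect(snp(chrom, L - 1L - pos, comp[[ref]],
                              comp[[alt]]), g2)
    expect_identical(e2, e1)
    checked <- checked + 1
  }
  expect_gt(checked, 150)
})

toy_snps <- function() {
  # seven records exercising each rule once; query gene at chr2:[0, 2000)
  data.frame(
    id = paste0("S", 1:7),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2", "chr1"),
    pos = c(2100000L, 2110000L, 2120000L, 2130000L, 2140000L, 202000L,
            2150000L),
    quality = c(250, 80, 250, 250, 250, 250, 250),
    alt_reads = c(30L, 30L, 1L, 30L, 30L, 30L, 30L),
    ref_allele_fraction = c(0.02, 0.02, 0.02, 0.45, 0.02, 0.02, 0.02),
    effect = c("missense", "missense", "missense", "missense",
               "synonymous", "missense", "missense"),
    is_background = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("the five-rule candidate filter keeps exactly the clean SNP", {
  cfg <- cboe_filter_config("chr2:0-2000")
  res <- filter_candidates(toy_snps(), cfg)
  expect_identical(res$candidates$id, "S1")
  expect_identical(unname(res$tally),
                   c(1L, 1L, 1L, 1L, 1L, 1L))
  expect_identical(sum(res$tally) + nrow(res$candidates), 7L)
  # empty input passes through
  res0 <- filter_candidates(toy_snps()[0, ], cfg)
  expect_identical(nrow(res0$candidates), 0L)
  expect_identical(sum(res0$tally), 0L)
  # the filter is per-record: duplicates both survive
  dup <- rbind(toy_snps()[1, ], toy_snps()[1, ])
  expect_identical(nrow(filter_candidates(dup, cfg)$candidates), 2L)
})

test_that("the literal conjunction reading keeps single-condition failures", {
  snps <- toy_snps()[2:3, ]  # S2 fails quality only, S3 fails reads only
  strict <- filter_candidates(snps, cboe_filter_config("chr2:0-2000"))
  expect_identical(nrow(strict$candidates), 0L)
  literal <- filter_candidates(snps, cboe_filter_config("chr2:0-2000",
                                                        literal_and = TRUE))
  expect_identical(literal$candidates$id, c("S2", "S3"))
})

test_that("relaxing any threshold never shrinks the survivor set", {
  set.seed(55)
  for (i in 1:10) {
    n <- 40
    snps <- data.frame(
      id = seq_len(n), chrom = sample(c("chr1", "chr2"), n, TRUE),
      pos = sample.int(3000000L, n),
      quality = runif(n, 0, 400), alt_reads = sample(0:40, n, TRUE),
      ref_allele_fraction = runif(n),
      effect = sample(c("missense", "synonymous", "intergenic",
                        "splice_site"), n, TRUE),
      is_background = runif(n) < 0.3, stringsAsFactors = FALSE)
    base <- cboe_filter_config("chr2:1000000-1002000")
    got <- filter_candidates(snps, base)$candidates$id
    relaxed <- list(
      cboe_filter_config("chr2:1000000-1002000", min_quality = 50),
      cboe_filter_config("chr2:1000000-1002000", min_alt_reads = 1),
      cboe_filter_config("chr2:1000000-1002000", linkage_window_bp = 1e5),
      cboe_filter_config("chr2:1000000-1002000", max_ref_fraction = 0.5))
    for (cfg in relaxed)
      expect_true(all(got %in% filter_candidates(snps, cfg)$candidates$id))
  }
})
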