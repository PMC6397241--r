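# Shared fixtures built in code.

# Hand-crafted two-chromosome genome with known gene structures:
#   chrT (+ strand gene, single exon, CDS at [10, 40)):
#     ATG GCT TGG AAA CCC GGG TTT CTC TAC TAA
#   chrT (- strand gene at [50, 80)): same CDS on the minus strand
#   chrU (+ strand gene at [10, 60) with intron [25, 45), GT..AG):
#     exon1 [10,25) + exon2 [45,60), CDS = ATG GCT TGG AAA CCC GGG TTT CTC
#     TAC TAA split after 15 nt
toy_genome <- function() {
  cds <- "ATGGCTTGGAAACCCGGGTTTCTCTACTAA"
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  pad <- function(n) strrep("A", n)
  chrT <- paste0(pad(10), cds, pad(10), rc(cds), pad(20))
  intron <- paste0("GT", strrep("C", 16), "AG")
  chrU <- paste0(pad(10), substr(cds, 1, 15), intron, substr(cds, 16, 30),
                 pad(40))
  stopifnot(nchar(chrT) == 100, nchar(chrU) == 100)
  genes <- data.frame(
    gene_id = c("gplus", "gminus", "gintron"),
    chrom = c("chrT", "chrT", "chrU"),
    start = c(10L, 50L, 10L), end = c(40L, 80L, 60L),
    strand = c("+", "-", "+"),
    is_essential = c(TRUE, FALSE, FALSE),
    is_query = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gplus", "gminus", "gintron", "gintron"),
    start = c(10L, 50L, 10L, 45L), end = c(40L, 80L, 25L, 60L))
  chroms <- c(chrT = chrT, chrU = chrU)
  structure(list(chromosomes = chroms, genes = genes, exons = exons,
                 ttaa_sites = lapply(chroms, find_ttaa_sites),
                 seed = 0L, params = NULL),
            class = "boe_genome")
}

# the representative planted suppressor used in recovery studies: the
# non-query gene whose length is closest to the median gene length
median_length_gene <- function(genome) {
  cand <- genome$genes[!genome$genes$is_query, ]
  len <- cand$end - cand$start
  cand$gene_id[which.min(abs(len - stats::median(len)))]
}

# small parameter set for fast simulations in unit tests
fast_params <- function(seed, ...) {
  sim_params(seed = seed, chrom_lengths = c(chrA = 60000, chrB = 40000),
             n_genes = 12L, n_insertions = 300L, ...)
}
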