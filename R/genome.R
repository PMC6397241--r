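#' @importFrom stats rbinom rgeom rnorm rpois runif rmultinom rlnorm sd
#'   median setNames complete.cases
NULL

COMP <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chars <- function(x) rev(unname(COMP[x]))

# uniform draw from the 61 sense codons
sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulate a toy genome with gene models and TTAA target sites
#'
#' Generates random chromosome sequences at the requested GC content, places
#' non-overlapping protein-coding gene models (ATG start, TAA stop, interior
#' sense codons; a configurable fraction carry one GT..AG intron), and
#' enumerates every TTAA tetranucleotide as a potential transposon target
#' site. Coordinates are 0-based half-open internally.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `boe_genome`: a list with `chromosomes` (named
#'   character vector of sequences), `genes` (data.frame: gene_id, chrom,
#'   start, end, strand, is_essential, is_query), `exons` (data.frame:
#'   gene_id, start, end), `ttaa_sites` (named list of 0-based motif start
#'   positions per chromosome) and `seed`.
#' @examples
#' g <- simulate_genome(sim_params(seed = 1, chrom_lengths = c(chrA = 20000),
#'                                 n_genes = 4))
#' head(g$genes)
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "boe_sim_params"))
  set.seed(params$seed)
  lens <- params$chrom_lengths
  if (is.null(names(lens)) || any(names(lens) == ""))
    names(lens) <- paste0("chr", seq_along(lens))
  gc <- params$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chrom_chars <- lapply(lens, function(L)
    sample(names(base_prob), L, replace = TRUE, prob = base_prob))

  n_genes <- params$n_genes
  sense <- sense_codons()
  # weight codons by the background base composition so coding sequence
  # honours gc_content (start/stop codons are fixed and negligible)
  codon_w <- vapply(strsplit(sense, ""), function(b) prod(base_prob[b]), 0)
  if (all(codon_w == 0))
    stop("no sense codon is compatible with the requested gc_content")
  genes <- vector("list", n_genes)
  exons <- vector("list", n_genes)
  placed <- lapply(lens, function(L) matrix(numeric(0), ncol = 2))
  min_gap <- 50L
  tries <- 0L
  max_tries <- 500L * max(1L, n_genes)
  i <- 1L
  while (i <= n_genes) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("gene placement failed: could not place ", n_genes,
           " non-overlapping genes of the requested lengths on ",
           sum(lens), " bp after ", max_tries, " attempts")
    rng <- params$gene_length_range
    cds_len <- 3L * sample(seq(rng[1] %/% 3L, rng[2] %/% 3L), 1L)
    has_intron <- runif(1) < params$frac_intron_genes
    intron_len <- if (has_intron) params$intron_length else 0L
    gene_len <- cds_len + intron_len
    chrom <- sample(names(lens), 1L, prob = lens)
    L <- lens[[chrom]]
    if (L - gene_len - 1L < 1L) next
    start <- sample.int(L - gene_len - 1L, 1L)
    iv <- placed[[chrom]]
    if (nrow(iv) && any(start < iv[, 2] + min_gap &
                        start + gene_len + min_gap > iv[, 1])) next
    strand <- sample(c("+", "-"), 1L)
    codons <- c("ATG",
                sample(sense, cds_len / 3L - 2L, replace = TRUE,
                       prob = codon_w),
                "TAA")
    cds_chars <- unlist(strsplit(codons, ""), use.names = FALSE)
    if (has_intron) {
      split_at <- sample(seq(3L, cds_len - 3L), 1L)
      intron <- c("G", "T",
                  sample(names(base_prob), intron_len - 4L, replace = TRUE,
                         prob = base_prob),
                  "A", "G")
      gene_chars <- c(cds_chars[seq_len(split_at)], intron,
                      cds_chars[seq(split_at + 1L, cds_len)])
      ex_coding <- rbind(c(0L, split_at),
                        c(split_at + intron_len, gene_len))
    } else {
      gene_chars <- cds_chars
      ex_coding <- rbind(c(0L, gene_len))
    }
    # map coding-strand exon intervals to genome coordinates
    if (strand == "+") {
      ex_genome <- cbind(start + ex_coding[, 1], start + ex_coding[, 2])
      seg <- gene_chars
    } else {
      ex_genome <- cbind(start + gene_len - ex_coding[, 2],
                         start + gene_len - ex_coding[, 1])
      seg <- revcomp_chars(gene_chars)
    }
    ex_genome <- ex_genome[order(ex_genome[, 1]), , drop = FALSE]
    chrom_chars[[chrom]][seq(start + 1L, start + gene_len)] <- seg
    placed[[chrom]] <- rbind(placed[[chrom]], c(start, start + gene_len))
    gid <- sprintf("gene%03d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = chrom, start = start,
                             end = start + gene_len, strand = strand,
                             stringsAsFactors = FALSE)
    exons[[i]] <- data.frame(gene_id = gid, start = ex_genome[, 1],
                             end = ex_genome[, 2])
    i <- i + 1L
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)
  genes$is_essential <- runif(n_genes) < params$frac_essential
  genes$is_query <- genes$is_essential & (runif(n_genes) < params$frac_query)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL

  chromosomes <- vapply(chrom_chars, paste, collapse = "", FUN.VALUE = "")
  ttaa <- lapply(chromosomes, find_ttaa_sites)
  structure(list(chromosomes = chromosomes, genes = genes, exons = exons,
                 ttaa_sites = ttaa, seed = params$seed, params = params),
            class = "boe_genome")
}

#' Enumerate TTAA motif start positions in a sequence
#'
#' @param seq a single nucleotide string.
#' @return integer vector of 0-based motif start positions.
#' @export
find_ttaa_sites <- function(seq) {
  m <- Biostrings::matchPattern("TTAA", Biostrings::DNAString(seq))
  as.integer(Biostrings::start(m)) - 1L
}

#' @export
print.boe_genome <- function(x, ...) {
  cat("boe_genome: ", length(x$chromosomes), " chromosome(s), ",
      sum(nchar(x$chromosomes)), " bp, ", nrow(x$genes), " genes, ",
      sum(lengths(x$ttaa_sites)), " TTAA sites (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

# genome base(s) at 0-based positions (single chromosome)
genome_base <- function(genome, chrom, pos) {
  seq <- genome$chromosomes[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  substring(seq, pos + 1L, pos + 1L)
}

# coding-strand CDS sequence of a gene, as a character vector of bases
gene_cds_chars <- function(genome, gene_id) {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  seq <- genome$chromosomes[[g$chrom]]
  pieces <- substring(seq, ex$start + 1L, ex$end)
  chars <- unlist(strsplit(pieces, ""), use.names = FALSE)
  if (g$strand == "-") chars <- revcomp_chars(chars)
  chars
}

# internal consistency checks; used by tests and run_pipeline
validate_genome <- function(genome) {
  stopifnot(inherits(genome, "boe_genome"))
  for (chrom in names(genome$chromosomes)) {
    expected <- find_ttaa_sites(genome$chromosomes[[chrom]])
    if (!identical(expected, genome$ttaa_sites[[chrom]]))
      stop("TTAA site list inconsistent with sequence on ", chrom)
  }
  g <- genome$genes
  lens <- nchar(genome$chromosomes)
  if (any(g$start < 0 | g$end > lens[g$chrom]))
    stop("gene interval outside chromosome bounds")
  for (chrom in unique(g$chrom)) {
    gi <- g[g$chrom == chrom, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) > 1L && any(gi$start[-1] < gi$end[-nrow(gi)]))
      stop("overlapping genes on ", chrom)
  }
  invisible(TRUE)
}
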