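#' Classify the effect of a single-nucleotide variant on toy gene models
#'
#' Minimal, strand-aware effect prediction on the package's toy gene models:
#' a variant is `intergenic` outside all genes; inside a gene it is
#' `splice_site` when within the first or last 2 nt of an intron, `intronic`
#' elsewhere in an intron, and otherwise the affected codon is translated
#' with the standard genetic code to give `synonymous`, `missense`,
#' `stop_gain` (sense to stop) or `stop_loss` (stop to sense). For minus
#' strand genes the codon is read on the reverse complement.
#'
#' @param snp list or one-row data.frame with `chrom`, `pos` (0-based),
#'   `ref`, `alt`.
#' @param genome a [simulate_genome()] result (or any `boe_genome`).
#' @return one of "intergenic", "intronic", "splice_site", "synonymous",
#'   "missense", "stop_gain", "stop_loss".
#' @export
classify_effect <- function(snp, genome) {
  stopifnot(inherits(genome, "boe_genome"))
  chrom <- as.character(snp$chrom); pos <- as.integer(snp$pos)
  ref <- toupper(as.character(snp$ref)); alt <- toupper(as.character(snp$alt))
  if (!chrom %in% names(genome$chromosomes))
    stop("unknown chromosome: ", chrom)
  if (pos < 0 || pos >= nchar(genome$chromosomes[[chrom]]))
    stop("position outside chromosome bounds: ", chrom, ":", pos)
  if (ref == alt) stop("ref and alt alleles are identical")
  gbase <- genome_base(genome, chrom, pos)
  if (gbase != ref)
    stop("reference allele mismatch at ", chrom, ":", pos,
         " (genome has ", gbase, ", record says ", ref, ")")
  g <- genome$genes
  hit <- which(g$chrom == chrom & g$start <= pos & pos < g$end)
  if (!length(hit)) return("intergenic")
  gene <- g[hit[1], ]
  ex <- genome$exons[genome$exons$gene_id == gene$gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  in_exon <- which(ex$start <= pos & pos < ex$end)
  if (!length(in_exon)) {
    # inside an intron: gaps between consecutive exons
    for (j in seq_len(nrow(ex) - 1L)) {
      istart <- ex$end[j]; iend <- ex$start[j + 1L]
      if (pos >= istart && pos < iend) {
        if (pos - istart < 2L || iend - pos <= 2L) return("splice_site")
        return("intronic")
      }
    }
    stop("internal error: position in gene but in no exon or intron")
  }
  j <- in_exon[1]
  widths <- ex$end - ex$start
  fwd <- (if (j > 1L) sum(widths[seq_len(j - 1L)]) else 0L) + (pos - ex$start[j])
  cds <- gene_cds_chars(genome, gene$gene_id)
  cds_pos <- if (gene$strand == "+") fwd else length(cds) - 1L - fwd
  ref_c <- if (gene$strand == "+") ref else unname(COMP[ref])
  alt_c <- if (gene$strand == "+") alt else unname(COMP[alt])
  if (cds[cds_pos + 1L] != ref_c)
    stop("internal error: CDS base disagrees with genome")
  codon_idx <- cds_pos %/% 3L
  if (3L * codon_idx + 3L > length(cds))
    stop("incomplete terminal codon in gene ", gene$gene_id)
  codon <- cds[(3L * codon_idx + 1L):(3L * codon_idx + 3L)]
  alt_codon <- codon
  alt_codon[cds_pos %% 3L + 1L] <- alt_c
  gc_tab <- Biostrings::GENETIC_CODE
  aa_ref <- gc_tab[[paste(codon, collapse = "")]]
  aa_alt <- gc_tab[[paste(alt_codon, collapse = "")]]
  if (aa_ref == "*" && aa_alt == "*") return("synonymous")
  if (aa_ref == "*") return("stop_loss")
  if (aa_alt == "*") return("stop_gain")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

#' Configuration for the BSA-seq candidate SNP filter
#'
#' Thresholds for [filter_candidates()]. Defaults follow the screening
#' procedure the package implements: discard variants with quality score
#' below 100 or fewer than 2 alternate-supporting reads, variants in the
#' compiled background list, variants linked to the query gene (within
#' 500 kb on the same chromosome), variants whose effect class is not a
#' candidate class (missense, stop gain/loss, splice site), and variants
#' with a reference-allele read fraction of 10% or more.
#'
#' The quality/read-support discard rule is applied disjunctively (a variant
#' must have quality >= `min_quality` AND >= `min_alt_reads` alternate reads
#' to survive). Set `literal_and = TRUE` to discard only variants failing
#' both thresholds simultaneously.
#'
#' @param min_quality minimum variant quality score.
#' @param min_alt_reads minimum alternate-supporting reads.
#' @param linkage_window_bp exclusion window around the query gene (bp).
#' @param max_ref_fraction maximum (exclusive) reference-allele fraction.
#' @param allowed_effects candidate effect classes.
#' @param query_locus `list(chrom=, start=, end=)` or "chrom:start-end"
#'   (0-based half-open) locating the query gene.
#' @param background optional data.frame with `chrom`, `pos` of background
#'   SNPs; if `NULL`, a logical `is_background` column on the input is used.
#' @param literal_and apply the quality/read rule as a literal conjunction.
#' @return a `cboe_filter_config` list.
#' @export
cboe_filter_config <- function(query_locus, min_quality = 100,
                               min_alt_reads = 2,
                               linkage_window_bp = 500000,
                               max_ref_fraction = 0.10,
                               allowed_effects = c("missense", "stop_gain",
                                                   "stop_loss", "splice_site"),
                               background = NULL, literal_and = FALSE) {
  if (is.character(query_locus) && length(query_locus) == 1L) {
    m <- regmatches(query_locus,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", query_locus))[[1]]
    if (length(m) != 4L) stop("query_locus must be 'chrom:start-end'")
    query_locus <- list(chrom = m[2], start = as.integer(m[3]),
                        end = as.integer(m[4]))
  }
  stopifnot(min_quality > 0, min_alt_reads > 0, linkage_window_bp >= 0,
            max_ref_fraction > 0, query_locus$start <= query_locus$end)
  structure(list(min_quality = min_quality, min_alt_reads = min_alt_reads,
                 linkage_window_bp = linkage_window_bp,
                 max_ref_fraction = max_ref_fraction,
                 allowed_effects = allowed_effects,
                 query_locus = query_locus, background = background,
                 literal_and = literal_and),
            class = "cboe_filter_config")
}

#' Filter SNPs to candidate suppressor mutations
#'
#' Applies the five candidate rules of the BSA-seq analysis in order:
#' quality / alternate-read support, background list, linkage to the query
#' gene, effect class, and reference-allele fraction. Distance to the query
#' gene is the minimum base-pair distance to the gene interval; variants on
#' other chromosomes are never considered linked. Each rejected record is
#' tallied under the first rule it fails.
#'
#' @param snps data.frame of SNP records (as from [simulate_bsa_seq()] or
#'   [read_snp_vcf()]): needs `chrom`, `pos`, `quality`, `alt_reads`,
#'   `ref_allele_fraction`, `effect`; `is_background` is used when no
#'   background table is configured.
#' @param config a [cboe_filter_config()].
#' @param genome optional `boe_genome`; required to compute missing `effect`
#'   values via [classify_effect()].
#' @return list with `candidates` (surviving rows), `tally` (named rejection
#'   counts per rule) and `n_input`.
#' @export
filter_candidates <- function(snps, config, genome = NULL) {
  stopifnot(inherits(config, "cboe_filter_config"))
  rules <- c("quality", "alt_reads", "background", "linked", "effect",
             "ref_fraction")
  tally <- setNames(integer(length(rules)), rules)
  if (nrow(snps) == 0L)
    return(list(candidates = snps, tally = tally, n_input = 0L))
  if (is.null(snps$effect) || anyNA(snps$effect)) {
    if (is.null(genome))
      stop("effect classes missing and no genome supplied to compute them")
    need <- if (is.null(snps$effect)) seq_len(nrow(snps)) else which(is.na(snps$effect))
    snps$effect[need] <- vapply(need, function(i)
      classify_effect(snps[i, ], genome), "")
  }
  if (is.null(config$background)) {
    is_bg <- if (is.null(snps$is_background)) rep(FALSE, nrow(snps))
             else snps$is_background
  } else {
    key <- paste(snps$chrom, snps$pos)
    is_bg <- key %in% paste(config$background$chrom, config$background$pos)
  }
  q <- config$query_locus
  dist <- ifelse(snps$chrom != q$chrom, Inf,
                 pmax(0, pmax(q$start - snps$pos, snps$pos - (q$end - 1L))))
  fail_qual <- snps$quality < config$min_quality
  fail_alt <- snps$alt_reads < config$min_alt_reads
  fail_support <- if (config$literal_and) fail_qual & fail_alt
                  else fail_qual | fail_alt
  checks <- list(
    quality = fail_support & fail_qual,
    alt_reads = fail_support & !fail_qual,
    background = is_bg,
    linked = dist < config$linkage_window_bp,
    effect = !(snps$effect %in% config$allowed_effects),
    ref_fraction = snps$ref_allele_fraction >= config$max_ref_fraction
  )
  first_fail <- rep(NA_character_, nrow(snps))
  for (r in rules)
    first_fail[is.na(first_fail) & checks[[r]]] <- r
  tally_tab <- table(factor(first_fail, levels = rules))
  tally[rules] <- as.integer(tally_tab)
  list(candidates = snps[is.na(first_fail), , drop = FALSE],
       tally = tally, n_input = nrow(snps))
}
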