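#' Haldane map function
#'
#' Recombinant fraction for a map distance in Morgans under the Haldane
#' (no-interference) model, `r = (1 - exp(-2 d)) / 2`. Used by
#' [simulate_bsa_seq()] to set the expected reference-allele fraction of a
#' SNP linked to the causal suppressor locus in a backcross pool: `r(0) = 0`
#' at the causal site, rising monotonically to 0.5 for unlinked markers.
#'
#' @param d map distance in Morgans (non-negative).
#' @return recombinant fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(c(0, 0.5, Inf))
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}

#' Simulate a transposon insertion screen
#'
#' Draws mapped transposon insertion events over the genome's TTAA target
#' sites. Sites inside the ORFs of `true_suppressors` are drawn with weight
#' `enrichment_fold`; all other sites have weight 1. Per-insertion read
#' counts are geometric with mean `insertion_read_mean`, and each event is
#' assigned to one of `n_samples` independent screen samples.
#'
#' @param genome a [simulate_genome()] result.
#' @param true_suppressors character vector of gene ids acting as planted
#'   suppressors (may be empty).
#' @param params a [sim_params()] object.
#' @param query_gene_id id recorded on every record (the screened essential
#'   gene); defaults to the first query gene in the genome.
#' @return an insertion table: data.frame with columns chrom, position
#'   (0-based TTAA start), strand, read_count, sample_id, query_gene_id.
#' @export
simulate_tboe_screen <- function(genome, true_suppressors = character(),
                                 params = sim_params(),
                                 query_gene_id = NULL) {
  stopifnot(inherits(genome, "boe_genome"))
  bad <- setdiff(true_suppressors, genome$genes$gene_id)
  if (length(bad))
    stop("true_suppressors not in genome: ", paste(bad, collapse = ", "))
  sites <- data.frame(
    chrom = rep(names(genome$ttaa_sites), lengths(genome$ttaa_sites)),
    position = unlist(genome$ttaa_sites, use.names = FALSE))
  if (nrow(sites) == 0L) stop("genome has no TTAA sites")
  if (is.null(query_gene_id)) {
    q <- genome$genes$gene_id[genome$genes$is_query]
    query_gene_id <- if (length(q)) q[1] else NA_character_
  }
  set.seed(params$seed)
  n <- params$n_insertions
  if (n == 0L) {
    out <- sites[0, ]
    out$strand <- character(0); out$read_count <- integer(0)
    out$sample_id <- character(0); out$query_gene_id <- character(0)
    return(out)
  }
  w <- rep(1, nrow(sites))
  sup <- genome$genes[genome$genes$gene_id %in% true_suppressors, ,
                      drop = FALSE]
  if (nrow(sup)) {
    for (k in seq_len(nrow(sup))) {
      hit <- sites$chrom == sup$chrom[k] & sites$position >= sup$start[k] &
        sites$position < sup$end[k]
      w[hit] <- params$enrichment_fold
    }
  }
  idx <- sample.int(nrow(sites), n, replace = TRUE, prob = w)
  out <- sites[idx, , drop = FALSE]
  out$strand <- sample(c("+", "-"), n, replace = TRUE)
  # geometric with mean m: successes before failure, p = 1/m, shifted to >= 1
  p <- 1 / params$insertion_read_mean
  out$read_count <- rgeom(n, p) + 1L
  out$sample_id <- sample(sprintf("S%d", seq_len(params$n_samples)), n,
                          replace = TRUE)
  out$query_gene_id <- query_gene_id
  rownames(out) <- NULL
  out
}

#' Simulate an overexpression-library sequencing screen
#'
#' Plasmid input abundances are log-normal. The pooled input control is a
#' multinomial draw at `control_depth`; each of `n_screens` selection samples
#' is a multinomial draw at `sequencing_depth` from abundances multiplied by
#' `selection_fold` for the planted suppressor plasmids. Counts are then
#' split between N-terminal and C-terminal sequencing reads by a binomial
#' with probability `end_split`.
#'
#' @param library_size number of plasmids in the library.
#' @param true_suppressors plasmid ids (or integer indices) planted as
#'   suppressors.
#' @param params a [sim_params()] object (`n_screens` must be >= 2).
#' @return an object of class `orfseq_counts`: list with integer matrices
#'   `N`, `C` (plasmids x screens), vectors `N_control`, `C_control`, and
#'   `plasmid_id`, `screen_id`.
#' @export
simulate_opboe_screen <- function(library_size, true_suppressors = character(),
                                  params = sim_params()) {
  stopifnot(library_size >= 1)
  if (params$selection_fold <= 0) stop("selection_fold must be > 0")
  if (params$n_screens < 2L) stop("n_screens must be >= 2")
  set.seed(params$seed)
  plasmid_id <- sprintf("P%04d", seq_len(library_size))
  if (is.numeric(true_suppressors)) true_suppressors <- plasmid_id[true_suppressors]
  bad <- setdiff(true_suppressors, plasmid_id)
  if (length(bad)) stop("unknown suppressor plasmid(s): ",
                        paste(bad, collapse = ", "))
  abund <- rlnorm(library_size, meanlog = 0, sdlog = params$abundance_sdlog)
  is_sup <- plasmid_id %in% true_suppressors

  draw <- function(weights, depth) {
    if (depth == 0) return(integer(length(weights)))
    as.integer(rmultinom(1, size = depth, prob = weights / sum(weights)))
  }
  split_ends <- function(total) {
    n_end <- rbinom(length(total), total, params$end_split)
    cbind(N = n_end, C = total - n_end)
  }
  ctl <- split_ends(draw(abund, params$control_depth))
  screens <- sprintf("screen%d", seq_len(params$n_screens))
  N <- C <- matrix(0L, library_size, params$n_screens,
                   dimnames = list(plasmid_id, screens))
  sel_w <- abund * ifelse(is_sup, params$selection_fold, 1)
  for (s in seq_len(params$n_screens)) {
    sc <- split_ends(draw(sel_w, params$sequencing_depth))
    N[, s] <- sc[, "N"]; C[, s] <- sc[, "C"]
  }
  structure(list(N = N, C = C, N_control = setNames(ctl[, "N"], plasmid_id),
                 C_control = setNames(ctl[, "C"], plasmid_id),
                 plasmid_id = plasmid_id, screen_id = screens,
                 true_suppressors = true_suppressors, seed = params$seed),
            class = "orfseq_counts")
}

#' @export
print.orfseq_counts <- function(x, ...) {
  cat("orfseq_counts: ", length(x$plasmid_id), " plasmids x ",
      length(x$screen_id), " screens (+ pooled control), seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Simulate backcross-pool sequencing of a point-mutant suppressor
#'
#' Emulates bulk segregant analysis: progeny of a backcross selected for the
#' suppression phenotype are pooled and sequenced. Background SNPs are placed
#' uniformly over the genome. A SNP at physical distance `b` bp from the
#' causal site on the same chromosome has expected reference-allele fraction
#' equal to the Haldane recombinant fraction `haldane_r(b * recombination_rate)`;
#' unlinked SNPs have expectation 0.5 and the causal SNP itself 0. Observed
#' reference-supporting read counts are binomial at `snp_depth`. Quality
#' scores, alternate-read supports and background-list membership are drawn
#' so configurable fractions of background SNPs fail the corresponding
#' candidate filters; effect classes come from [classify_effect()].
#'
#' @param genome a [simulate_genome()] result.
#' @param causal_position list(chrom=, pos=) or "chrom:pos" (0-based) of the
#'   causal suppressor SNP.
#' @param query_gene_id the screened essential gene (must be in the genome).
#' @param params a [sim_params()] object (`snp_depth` must be > 0).
#' @param causal_alt alternate allele of the causal SNP; if `NULL`, an
#'   allele whose effect class is missense / stop gain / stop loss / splice
#'   site is chosen automatically.
#' @return data.frame of SNP records: chrom, pos (0-based), ref, alt,
#'   quality, ref_reads, alt_reads, ref_allele_fraction, effect,
#'   is_background, is_causal.
#' @export
simulate_bsa_seq <- function(genome, causal_position, query_gene_id,
                             params = sim_params(), causal_alt = NULL) {
  stopifnot(inherits(genome, "boe_genome"))
  if (is.character(causal_position) && length(causal_position) == 1L) {
    parts <- strsplit(causal_position, ":", fixed = TRUE)[[1]]
    causal_position <- list(chrom = parts[1], pos = as.integer(parts[2]))
  }
  cchrom <- causal_position$chrom; cpos <- as.integer(causal_position$pos)
  if (!cchrom %in% names(genome$chromosomes))
    stop("causal chromosome not in genome: ", cchrom)
  if (!query_gene_id %in% genome$genes$gene_id)
    stop("query gene not in genome: ", query_gene_id)
  depth <- params$snp_depth
  if (depth <= 0) stop("snp_depth must be > 0")
  set.seed(params$seed)

  lens <- nchar(genome$chromosomes)
  nb <- params$n_background_snps
  chrom <- sample(names(lens), nb, replace = TRUE, prob = lens)
  pos <- vapply(chrom, function(ch) sample.int(lens[[ch]] - 4L, 1L), 1L)
  keep <- !(chrom == cchrom & pos == cpos)
  chrom <- chrom[keep]; pos <- pos[keep]

  snps <- data.frame(chrom = c(cchrom, chrom), pos = c(cpos, pos),
                     stringsAsFactors = FALSE)
  snps$is_causal <- c(TRUE, rep(FALSE, length(pos)))
  snps$ref <- mapply(function(ch, p) genome_base(genome, ch, p),
                     snps$chrom, snps$pos)
  if (any(!snps$ref %in% names(COMP)))
    stop("reference base outside ACGT at a simulated position")
  pick_alt <- function(ref) sample(setdiff(names(COMP), ref), 1L)
  snps$alt <- vapply(snps$ref, pick_alt, "")
  if (is.null(causal_alt)) {
    wanted <- c("missense", "stop_gain", "stop_loss", "splice_site")
    found <- NA_character_
    for (a in setdiff(names(COMP), snps$ref[1])) {
      eff <- classify_effect(list(chrom = cchrom, pos = cpos,
                                  ref = snps$ref[1], alt = a), genome)
      if (eff %in% wanted) { found <- a; break }
    }
    if (is.na(found))
      stop("no alternate allele at the causal position yields a candidate ",
           "effect class (missense/stop/splice); choose a CDS position")
    snps$alt[1] <- found
  } else snps$alt[1] <- causal_alt

  d_bp <- ifelse(snps$chrom == cchrom, abs(snps$pos - cpos), Inf)
  expect <- haldane_r(d_bp * params$recombination_rate)
  expect[1] <- 0
  snps$ref_reads <- rbinom(nrow(snps), depth, expect)
  snps$alt_reads <- depth - snps$ref_reads

  n <- nrow(snps)
  low_q <- runif(n) < params$frac_low_quality
  snps$quality <- ifelse(low_q, runif(n, 0, 99.9), runif(n, 150, 2000))
  low_alt <- runif(n) < params$frac_low_altreads
  snps$alt_reads[low_alt] <- sample(0:1, sum(low_alt), replace = TRUE)
  snps$ref_reads[low_alt] <- depth - snps$alt_reads[low_alt]
  snps$is_background <- runif(n) < params$frac_background_list
  # the causal record itself always has clean support and is not background
  snps$quality[1] <- runif(1, 500, 2000)
  snps$ref_reads[1] <- rbinom(1, depth, 0)
  snps$alt_reads[1] <- depth - snps$ref_reads[1]
  snps$is_background[1] <- FALSE
  snps$ref_allele_fraction <- snps$ref_reads / depth
  snps$effect <- vapply(seq_len(n), function(i)
    classify_effect(list(chrom = snps$chrom[i], pos = snps$pos[i],
                         ref = snps$ref[i], alt = snps$alt[i]), genome), "")
  snps[order(snps$chrom, snps$pos),
       c("chrom", "pos", "ref", "alt", "quality", "ref_reads", "alt_reads",
         "ref_allele_fraction", "effect", "is_background", "is_causal")] ->
    out
  rownames(out) <- NULL
  out
}
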