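#' Simulation parameters for synthetic BOE screens
#'
#' Central parameter object consumed by all `simulate_*()` generators. Every
#' source of randomness flows from `seed`; rerunning any generator with the
#' same parameters yields byte-identical outputs.
#'
#' Defaults describe the study conditions the generators emulate: a ~500-kb
#' toy genome (two chromosomes) standing in for a yeast chromosome arm, a
#' transposon screen of 2000 mapped insertions with 50-fold target-site
#' enrichment inside true suppressor ORFs, a 500-plasmid overexpression
#' library screened in 3 replicates at depth 1e5 with 30-fold selection of
#' true suppressors, and a backcross-pool sequencing experiment at 50x depth
#' with 200 background SNPs. The recombination rate (Morgans per bp) is
#' scaled so that the toy genome carries a map length comparable, per base,
#' to compressing a ~2000-cM yeast map onto a ~500-kb sequence; linkage then
#' decays over tens of kb as it does over Mb-scale windows in the real
#' genome.
#'
#' @param seed integer seed; mandatory, recorded in every output header.
#' @param ... overrides for any default listed in Details; unknown names are
#'   rejected.
#'
#' @section Parameters:
#' \describe{
#'   \item{chrom_lengths}{named integer vector of chromosome lengths (bp).}
#'   \item{gc_content}{fraction of G+C in simulated sequence.}
#'   \item{n_genes, gene_length_range, frac_intron_genes, intron_length}{gene
#'     model placement controls; CDS lengths are multiples of 3.}
#'   \item{frac_essential, frac_query}{fraction of genes flagged essential,
#'     and of essential genes flagged as screened query genes.}
#'   \item{n_insertions, enrichment_fold, insertion_read_mean, n_samples}{
#'     transposon screen: number of mapped insertions, weight multiplier for
#'     TTAA sites inside true-suppressor ORFs, mean of the geometric
#'     per-insertion read count, number of independent screen samples.}
#'   \item{n_screens, selection_fold, sequencing_depth, control_depth,
#'     abundance_sdlog, end_split}{overexpression screen: replicate screens,
#'     abundance multiplier for true suppressors under selection, multinomial
#'     read depth per screen and for the pooled input control, log-normal
#'     sdlog of plasmid input abundances, binomial probability that a read
#'     comes from the N-terminal end.}
#'   \item{snp_depth, n_background_snps, recombination_rate, frac_low_quality,
#'     frac_low_altreads, frac_background_list}{backcross-pool sequencing:
#'     per-SNP depth, background SNP count, Morgans per bp, and the fractions
#'     of background SNPs drawn with sub-threshold quality, with 0-1
#'     alternate-supporting reads, or present in the compiled background
#'     list.}
#'   \item{n_screened, n_bypassable, n_nonessential, n_terms, n_loc_terms,
#'     n_complexes, complex_size_range, complex_assort, feature_shift,
#'     slow_spore_lor, ortholog_p_byp, ortholog_p_nonbyp, p_no_ortholog,
#'     go_odds, mean_degree, n_ppi}{annotation-table generator: universe
#'     sizes, planted effect sizes (standardised feature shift for bypassable
#'     genes, log-odds of slow spore lethality, ortholog-dispensability
#'     probabilities, GO-assortativity odds multiplier for network edges,
#'     probability that a complex is bypassability-coherent).}
#' }
#'
#' @return an object of class `boe_sim_params` (a validated list).
#' @examples
#' p <- sim_params(seed = 7, n_insertions = 500)
#' p$n_insertions
#' @export
sim_params <- function(seed = 1L, ...) {
  defaults <- list(
    seed = 1L,
    # genome
    chrom_lengths = c(chrI = 300000L, chrII = 200000L),
    gc_content = 0.36,
    n_genes = 60L,
    gene_length_range = c(300L, 2400L),
    frac_intron_genes = 0.3,
    intron_length = 60L,
    frac_essential = 0.4,
    frac_query = 0.5,
    # transposon screen
    n_insertions = 2000L,
    enrichment_fold = 50,
    insertion_read_mean = 20,
    n_samples = 2L,
    # overexpression screen
    n_screens = 3L,
    selection_fold = 30,
    sequencing_depth = 1e5,
    control_depth = 1.8e6,  # pooled control of 18 input samples
    abundance_sdlog = 1,
    end_split = 0.5,
    # backcross-pool sequencing
    snp_depth = 50L,
    n_background_snps = 200L,
    recombination_rate = 4e-5,
    frac_low_quality = 0.1,
    frac_low_altreads = 0.05,
    frac_background_list = 0.5,
    # annotation tables
    n_screened = 142L,
    n_bypassable = 38L,
    n_nonessential = 3578L,
    n_terms = 40L,
    n_loc_terms = 8L,
    n_complexes = 20L,
    complex_size_range = c(2L, 4L),
    complex_assort = 0.8,
    feature_shift = 1,
    slow_spore_lor = 1.5,
    ortholog_p_byp = 0.77,
    ortholog_p_nonbyp = 0.14,
    p_no_ortholog = 0.13,
    go_odds = 3,
    mean_degree = 7,
    n_ppi = 3000L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == ""))
      stop("unknown simulation parameter(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  defaults$seed <- seed
  p <- defaults
  stopifnot(length(p$seed) == 1L, is.finite(p$seed))
  p$seed <- as.integer(p$seed)
  # YAML configs deliver named vectors as lists
  p$chrom_lengths <- unlist(p$chrom_lengths)
  if (any(p$chrom_lengths < 1000L))
    stop("chromosome lengths must be >= 1 kb")
  for (f in c("gc_content", "frac_intron_genes", "frac_essential",
              "frac_query", "end_split", "frac_low_quality",
              "frac_low_altreads", "frac_background_list", "complex_assort",
              "ortholog_p_byp", "ortholog_p_nonbyp", "p_no_ortholog")) {
    v <- p[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(f, " must be a fraction in [0, 1]")
  }
  for (f in c("enrichment_fold", "insertion_read_mean", "selection_fold",
              "recombination_rate", "go_odds", "feature_shift"))
    if (!is.numeric(p[[f]]) || p[[f]] < 0) stop(f, " must be non-negative")
  if (p$n_bypassable > p$n_screened)
    stop("n_bypassable cannot exceed n_screened")
  structure(p, class = "boe_sim_params")
}

#' @export
print.boe_sim_params <- function(x, ...) {
  cat("BOE simulation parameters (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", length(x$chrom_lengths), " chromosome(s), ",
      sum(x$chrom_lengths), " bp, ", x$n_genes, " genes\n", sep = "")
  cat("  T-BOE : ", x$n_insertions, " insertions, fold ", x$enrichment_fold,
      "\n  OP-BOE: ", x$n_screens, " screens, fold ", x$selection_fold,
      ", depth ", format(x$sequencing_depth, scientific = FALSE),
      "\n  C-BOE : depth ", x$snp_depth, ", ", x$n_background_snps,
      " background SNPs\n", sep = "")
  invisible(x)
}

# one-line "key=value;..." rendering used in output file headers
format_params_header <- function(params, fields) {
  vals <- lapply(params[fields], function(v) paste(format(v), collapse = ","))
  paste(sprintf("%s=%s", fields, unlist(vals)), collapse = "; ")
}
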