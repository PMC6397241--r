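#' Simulate gene feature, complex, annotation and network tables
#'
#' Generates the downstream-analysis inputs with configurable planted
#' structure: bypassability labels optionally coherent within protein
#' complexes (`complex_assort`), continuous gene features shifted by
#' `feature_shift` standard deviations in bypassable genes (sign per
#' feature: features tracking lower gene importance rise, expression-level
#' features fall), slow spore lethality with log-odds `slow_spore_lor`,
#' ortholog dispensability probabilities per bypassability class, and a
#' suppressor network whose edges prefer GO-term-sharing partners with odds
#' multiplier `go_odds`. Setting `complex_assort = 0`, `feature_shift = 0`,
#' `slow_spore_lor = 0`, equal ortholog probabilities and `go_odds = 1`
#' yields a fully null dataset for calibration.
#'
#' @param params a [sim_params()] object.
#' @return list with `features` (per screened gene), `terms` (gene_id,
#'   term), `localization` (gene_id, term), `ppi` (gene1, gene2),
#'   `complexes` (a [complex_catalog()] with per-complex median features),
#'   `network` (suppressor, query, type), plus `screened`, `nonessential`,
#'   `bypassable` gene-id vectors and `seed`.
#' @export
simulate_annotation_tables <- function(params = sim_params()) {
  stopifnot(inherits(params, "boe_sim_params"))
  set.seed(params$seed)
  screened <- sprintf("ess%04d", seq_len(params$n_screened))
  nonessential <- sprintf("non%04d", seq_len(params$n_nonessential))
  p_byp <- params$n_bypassable / params$n_screened

  # complex membership over screened genes (all queried)
  sizes <- sample(seq(params$complex_size_range[1],
                      params$complex_size_range[2]),
                  params$n_complexes, replace = TRUE)
  if (any(sizes > length(screened)))
    stop("complex size exceeds the number of screened genes")
  members <- lapply(sizes, function(s) sample(screened, s))
  mem_df <- data.frame(
    complex_id = rep(sprintf("cpx%03d", seq_along(members)), sizes),
    gene_id = unlist(members), queried = TRUE, stringsAsFactors = FALSE)

  # bypassability: complex-coherent labels with probability complex_assort
  byp <- setNames(rep(NA, length(screened)), screened)
  for (cx in sample(seq_along(members))) {
    g <- members[[cx]]
    if (runif(1) < params$complex_assort) {
      lab <- runif(1) < p_byp
      byp[g][is.na(byp[g])] <- lab
    } else {
      free <- g[is.na(byp[g])]
      byp[free] <- runif(length(free)) < p_byp
    }
  }
  byp[is.na(byp)] <- runif(sum(is.na(byp))) < p_byp
  bypassable <- screened[byp]

  # per-gene features: direction encodes lower importance for bypassable
  dirs <- c(evolutionary_rate = +1, n_species_with_ortholog = -1,
            codon_adaptation_index = -1, tRNA_adaptation_index = -1,
            hermes_insertion_density = +1, mRNA_abundance = -1,
            protein_abundance = -1, protein_degradation_rate = +1)
  feats <- data.frame(gene_id = screened, screened = TRUE,
                      bypassable = unname(byp), stringsAsFactors = FALSE)
  for (f in names(dirs))
    feats[[f]] <- rnorm(length(screened)) +
      dirs[[f]] * params$feature_shift * feats$bypassable
  p_slow <- stats::plogis(stats::qlogis(0.25) +
                            params$slow_spore_lor * feats$bypassable)
  feats$slow_spore_lethality <- runif(length(screened)) < p_slow
  p_non <- ifelse(feats$bypassable, params$ortholog_p_byp,
                  params$ortholog_p_nonbyp)
  u <- runif(length(screened))
  feats$sc_ortholog_status <- ifelse(
    u < params$p_no_ortholog, "none",
    ifelse(runif(length(screened)) < p_non, "non-essential", "essential"))

  all_genes <- c(screened, nonessential)
  term_ids <- sprintf("T%02d", seq_len(params$n_terms))
  k_terms <- sample(1:3, length(all_genes), replace = TRUE)
  terms <- data.frame(
    gene_id = rep(all_genes, k_terms),
    term = unlist(lapply(k_terms, sample, x = term_ids)),
    stringsAsFactors = FALSE)
  terms <- unique(terms)

  loc_ids <- c("nucleus", "cytosol",
               c("mitochondrion", "ER", "golgi", "vacuole", "membrane",
                 "nucleolus", "spindle", "cell_tip")[
                   seq_len(max(0L, params$n_loc_terms - 2L))])
  loc_rows <- lapply(all_genes, function(g) {
    if (runif(1) < 0.1) return(NULL)  # unannotated gene
    got <- c(if (runif(1) < 0.5) "nucleus", if (runif(1) < 0.5) "cytosol",
             sample(setdiff(loc_ids, c("nucleus", "cytosol")),
                    sample(0:2, 1)))
    if (!length(got)) got <- sample(loc_ids, 1)
    data.frame(gene_id = g, term = got, stringsAsFactors = FALSE)
  })
  localization <- do.call(rbind, loc_rows)

  ppi <- data.frame(gene1 = sample(all_genes, params$n_ppi, replace = TRUE),
                    gene2 = sample(all_genes, params$n_ppi, replace = TRUE),
                    stringsAsFactors = FALSE)
  ppi <- unique(ppi[ppi$gene1 != ppi$gene2, ])

  # suppressor network: bypassable queries, non-essential suppressors,
  # GO-assortative partner choice
  A <- matrix(FALSE, length(all_genes), length(term_ids),
              dimnames = list(all_genes, term_ids))
  A[cbind(match(terms$gene_id, all_genes),
          match(terms$term, term_ids))] <- TRUE
  edges <- list()
  types <- c("T-BOE-deletion", "T-BOE-insertion", "C-BOE", "OP-BOE")
  for (q in bypassable) {
    deg <- 1L + rpois(1, max(0, params$mean_degree - 1))
    shares <- as.vector(A[nonessential, , drop = FALSE] %*% A[q, ]) > 0
    w <- ifelse(shares, params$go_odds, 1)
    sup <- sample(nonessential, min(deg, length(nonessential)), prob = w)
    edges[[q]] <- data.frame(
      suppressor = sup, query = q,
      type = sample(types, length(sup), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  network <- do.call(rbind, edges)
  rownames(network) <- NULL

  cx_feats <- data.frame(complex_id = unique(mem_df$complex_id),
                         stringsAsFactors = FALSE)
  for (f in names(dirs))
    cx_feats[[f]] <- vapply(cx_feats$complex_id, function(cx) {
      g <- mem_df$gene_id[mem_df$complex_id == cx]
      median(feats[[f]][match(g, feats$gene_id)])
    }, 0)

  list(features = feats, terms = terms, localization = localization,
       ppi = ppi, complexes = complex_catalog(mem_df, cx_feats),
       network = network, screened = screened,
       nonessential = nonessential, bypassable = bypassable,
       seed = params$seed)
}
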