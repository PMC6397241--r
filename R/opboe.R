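#' Per-end log2 control/selection read ratio
#'
#' Depth-normalised log2 ratio of pooled-control to selection reads for one
#' sequenced ORF end, with +1 pseudocounts:
#' `log2((control_reads + 1) / (sample_reads + 1) * total_sample /
#' total_control)`. Because the control sits in the numerator, plasmids
#' enriched under selection get negative ratios.
#'
#' @param sample_reads,control_reads per-plasmid read counts for this end.
#' @param total_sample,total_control per-end library totals for the
#'   selection sample and the pooled control.
#' @return the log2 ratio (vectorised).
#' @examples
#' end_ratio(199, 99, 2e6, 1e6)  # 0
#' @export
end_ratio <- function(sample_reads, control_reads, total_sample,
                      total_control) {
  if (any(total_sample == 0) || any(total_control == 0))
    stop("per-end totals must be positive")
  log2((control_reads + 1) / (sample_reads + 1) * total_sample /
         total_control)
}

#' Read-weighted average of the two end ratios
#'
#' `(N_ratio * N_reads + C_ratio * C_reads) / (N_reads + C_reads)`; when a
#' plasmid has zero reads at both ends in a screen the unweighted mean of
#' the two ratios is returned.
#'
#' @param N_ratio,C_ratio per-end log2 ratios.
#' @param N_reads,C_reads per-end selection read counts (the weights).
#' @return the weighted-average ratio (vectorised).
#' @export
wa_ratio <- function(N_ratio, C_ratio, N_reads, C_reads) {
  stopifnot(all(N_reads >= 0), all(C_reads >= 0))
  tot <- N_reads + C_reads
  ifelse(tot == 0, (N_ratio + C_ratio) / 2,
         (N_ratio * N_reads + C_ratio * C_reads) / tot)
}

#' Consistency-gated BOE-score from per-screen WA ratios
#'
#' mu is the mean and sigma the sample (n-1) standard deviation of the
#' per-screen WA ratios. The consistency score is 0 when `|mu/sigma| < 1`
#' and `1 - 1/|mu/sigma|` otherwise, so the BOE-score `C_score * mu` is
#' zeroed whenever the mean is within one standard deviation of zero. A zero
#' sigma is treated as the limit: `C_score` 1 when mu is nonzero, 0 when mu
#' is 0.
#'
#' @param wa_ratios numeric vector of per-screen WA ratios (>= 2 screens).
#' @param force allow a single screen (mu is the value, sigma NA, C_score 1).
#' @return list with `mu`, `sigma`, `C_score`, `boe_score`, `n_screens`.
#' @examples
#' boe_score(c(-3.0, -2.5, -3.5))$boe_score  # -2.5
#' @export
boe_score <- function(wa_ratios, force = FALSE) {
  n <- length(wa_ratios)
  if (n < 2L && !force)
    stop("need >= 2 screens to score (or set force = TRUE)")
  mu <- mean(wa_ratios)
  sigma <- if (n >= 2L) sd(wa_ratios) else NA_real_
  if (n < 2L) {
    cs <- 1
  } else if (sigma == 0) {
    cs <- if (mu != 0) 1 else 0
  } else {
    ratio <- abs(mu / sigma)
    cs <- if (ratio < 1) 0 else 1 - 1 / ratio
  }
  list(mu = mu, sigma = sigma, C_score = cs, boe_score = cs * mu,
       n_screens = n)
}

#' Score and rank all plasmids of an overexpression screen
#'
#' Computes per-screen N- and C-end ratios (per-screen selection totals,
#' pooled-control totals), the read-weighted WA ratio per screen, and the
#' consistency-gated BOE-score per plasmid. Plasmids are ranked by ascending
#' BOE-score: selection-enriched plasmids (candidate suppressors) have the
#' most negative scores because the control is in the ratio numerator. Ties
#' are broken by plasmid id.
#'
#' A per-plasmid two-sided p-value for "no abundance change under
#' selection" is attached as a calibration diagnostic: pooling a plasmid's
#' reads over screens and ends, its selection count given the
#' selection-plus-control total is binomial with proportion equal to the
#' depth share of the selection libraries under the null (the plasmid's
#' unknown input abundance cancels in this conditioning). The normal
#' approximation with continuity correction is used. This p-value is not
#' the selection statistic - candidates are called from BOE-scores.
#'
#' @param counts an `orfseq_counts` object (see [simulate_opboe_screen()]
#'   and [read_orfseq_counts()]).
#' @param force score even when fewer than 2 screens are present.
#' @return data.frame with plasmid_id, per-screen WA ratios (wa.screen
#'   columns), mu, sigma, C_score, boe_score, p_value and rank, sorted by
#'   rank.
#' @export
rank_opboe <- function(counts, force = FALSE) {
  stopifnot(inherits(counts, "orfseq_counts"))
  if (length(counts$plasmid_id) < 1L) stop("no plasmids to score")
  miss <- is.na(counts$N_control[counts$plasmid_id]) |
    is.na(counts$C_control[counts$plasmid_id])
  if (any(miss))
    stop("missing control counts for plasmid(s): ",
         paste(counts$plasmid_id[miss], collapse = ", "))
  S <- length(counts$screen_id)
  if (S < 2L && !force) stop("need >= 2 screens (or set force = TRUE)")
  tot_Nc <- sum(counts$N_control); tot_Cc <- sum(counts$C_control)
  wa <- matrix(NA_real_, length(counts$plasmid_id), S,
               dimnames = list(counts$plasmid_id, counts$screen_id))
  for (s in seq_len(S)) {
    Nr <- counts$N[, s]; Cr <- counts$C[, s]
    nr <- end_ratio(Nr, counts$N_control, sum(Nr), tot_Nc)
    cr <- end_ratio(Cr, counts$C_control, sum(Cr), tot_Cc)
    wa[, s] <- wa_ratio(nr, cr, Nr, Cr)
  }
  scores <- apply(wa, 1L, boe_score, force = force)
  # conditional binomial diagnostic: pooled selection reads vs the depth
  # share of the selection libraries
  X <- rowSums(counts$N) + rowSums(counts$C)
  tot_sel <- sum(X)
  ctl <- counts$N_control + counts$C_control
  n_pair <- X + ctl
  p0 <- tot_sel / (tot_sel + tot_Nc + tot_Cc)
  z <- (abs(X - n_pair * p0) - 0.5) / sqrt(pmax(1e-12, n_pair * p0 *
                                                  (1 - p0)))
  p_binom <- pmin(1, 2 * stats::pnorm(-pmax(0, z)))
  res <- data.frame(plasmid_id = counts$plasmid_id,
                    mu = vapply(scores, `[[`, 0, "mu"),
                    sigma = vapply(scores, `[[`, 0, "sigma"),
                    C_score = vapply(scores, `[[`, 0, "C_score"),
                    boe_score = vapply(scores, `[[`, 0, "boe_score"),
                    p_value = p_binom,
                    stringsAsFactors = FALSE)
  colnames(wa) <- paste0("wa.", colnames(wa))
  res <- cbind(res, wa)
  res <- res[order(res$boe_score, res$plasmid_id), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
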