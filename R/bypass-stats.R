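#' Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test conditioning on both margins. The one-sided
#' p-value is the upper tail of the a-cell ("greater") or its lower tail
#' ("less"); the two-sided p-value is the sum of all point probabilities not
#' exceeding the observed one (point-probability convention, with a 1e-7
#' relative tolerance for floating-point ties). The odds ratio reported is
#' the sample odds ratio `ad/bc` (0 or Inf at zero cells), not the
#' conditional MLE.
#'
#' @param table 2x2 matrix, or a length-4 vector `c(a, b, c, d)` read
#'   row-wise.
#' @param sided "two", "greater" or "less".
#' @return list with `odds_ratio`, `p_value` and the table counts.
#' @examples
#' fisher_exact_2x2(c(7, 31, 0, 104), sided = "greater")$p_value
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == 2L))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  } else {
    stopifnot(length(table) == 4L)
    a <- table[1]; b <- table[2]; c <- table[3]; d <- table[4]
  }
  if (any(c(a, b, c, d) < 0)) stop("negative counts in 2x2 table")
  if (a + b + c + d < 1) stop("empty 2x2 table")
  m <- a + b        # row-1 margin
  n <- c + d        # row-2 margin
  k <- a + c        # column-1 margin
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- switch(sided,
    greater = sum(dens[support >= a]),
    less = sum(dens[support <= a]),
    two = sum(dens[dens <= obs * (1 + 1e-7)]))
  p <- min(1, p)
  or <- if (b == 0 || c == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else (a * d) / (b * c)
  list(odds_ratio = or, p_value = p, a = a, b = b, c = c, d = d)
}

#' GO-slim term enrichment by Fisher's exact test
#'
#' One 2x2 Fisher test per term: foreground genes with / without the term
#' versus the remaining background genes with / without it, with
#' Benjamini-Hochberg q-values across terms. Terms annotating no background
#' gene are skipped.
#'
#' @param foreground,background character vectors of gene ids
#'   (`foreground` must be a subset of `background`).
#' @param term_map data.frame with columns `gene_id` and `term`.
#' @param sided sidedness of the per-term Fisher test; enrichment
#'   ("greater") by default.
#' @return data.frame, one row per tested term, with the 2x2 counts,
#'   odds_ratio, p_value and q_value, sorted by ascending p.
#' @export
go_slim_enrichment <- function(foreground, background, term_map,
                               sided = "greater") {
  if (length(foreground) == 0L) stop("empty foreground gene set")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  stopifnot(all(c("gene_id", "term") %in% names(term_map)))
  term_map <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- unique(term_map$term)
  n_fg <- length(unique(foreground))
  rest <- setdiff(background, foreground)
  n_rest <- length(rest)
  rows <- lapply(terms, function(tm) {
    genes <- unique(term_map$gene_id[term_map$term == tm])
    a <- sum(genes %in% foreground)
    cc <- sum(genes %in% rest)
    if (a + cc == 0L) return(NULL)
    ft <- fisher_exact_2x2(c(a, n_fg - a, cc, n_rest - cc), sided = sided)
    data.frame(term = tm, fg_with = a, fg_without = n_fg - a, bg_with = cc,
               bg_without = n_rest - cc, odds_ratio = ft$odds_ratio,
               p_value = ft$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(term = character(), fg_with = integer(),
                      fg_without = integer(), bg_with = integer(),
                      bg_without = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric()))
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  res
}

#' Two-sided Mann-Whitney U comparison of a feature between groups
#'
#' Exact enumeration when both groups together hold at most 20 observations
#' without ties, otherwise the normal approximation with tie and continuity
#' corrections (the standard behaviour of [stats::wilcox.test()]). Missing
#' values are dropped, with the dropped counts reported. When every value in
#' both groups is identical the comparison is degenerate and p = 1.
#'
#' @param values_A,values_B numeric vectors (each with at least one
#'   non-missing value).
#' @return list with `U` (number of (A, B) pairs with A > B, plus half-ties),
#'   `p_value`, `n_A`, `n_B`, `dropped_A`, `dropped_B`.
#' @export
mann_whitney_feature <- function(values_A, values_B) {
  dropped_A <- sum(is.na(values_A)); dropped_B <- sum(is.na(values_B))
  a <- values_A[!is.na(values_A)]; b <- values_B[!is.na(values_B)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p_value = 1,
                n_A = length(a), n_B = length(b),
                dropped_A = dropped_A, dropped_B = dropped_B))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       n_A = length(a), n_B = length(b),
       dropped_A = dropped_A, dropped_B = dropped_B)
}

#' Re-run an association test within a stratum of genes
#'
#' Controls for a confounder (e.g. gene importance) by restricting a test to
#' genes passing a stratum filter, requiring genes on both sides of the
#' bypassability split inside the stratum.
#'
#' @param table a gene-feature data.frame with a logical `bypassable`
#'   column.
#' @param stratum_filter logical vector along `table`, or a function of the
#'   table returning one.
#' @param test_fun function taking the (subsetted) table and returning the
#'   test result (e.g. a wrapper around [mann_whitney_feature()] or
#'   [fisher_exact_2x2()]).
#' @return list with `result` (the test output on the stratum), `n_stratum`,
#'   `n_bypassable`, `n_non_bypassable`.
#' @export
stratified_retest <- function(table, stratum_filter, test_fun) {
  keep <- if (is.function(stratum_filter)) stratum_filter(table)
          else stratum_filter
  stopifnot(is.logical(keep), length(keep) == nrow(table))
  keep[is.na(keep)] <- FALSE
  sub <- table[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty stratum")
  nb <- sum(sub$bypassable); nn <- sum(!sub$bypassable)
  if (nb == 0L || nn == 0L)
    stop("stratum has genes on only one side of the bypassability split (",
         nb, " bypassable, ", nn, " non-bypassable)")
  list(result = test_fun(sub), n_stratum = nrow(sub), n_bypassable = nb,
       n_non_bypassable = nn)
}
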