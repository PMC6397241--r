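pair_key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")

#' Build interacting and interactor-sharing gene pairs from a BOE network
#'
#' Interacting pairs are the distinct (query, suppressor) edges taken as
#' unordered gene pairs. Interactor-sharing pairs are unordered pairs of
#' suppressors that suppress at least one common query; a pair shared by
#' several queries is counted once.
#'
#' @param network data.frame of directed edges with columns `suppressor`,
#'   `query` (and optionally `type`).
#' @return list with data.frames `interacting` and `sharing`, each with
#'   columns `gene1`, `gene2` (gene1 < gene2).
#' @export
build_pairs <- function(network) {
  stopifnot(all(c("suppressor", "query") %in% names(network)))
  if (any(network$suppressor == network$query))
    stop("self-edges in network (suppressor == query)")
  mk <- function(g1, g2) {
    if (!length(g1))
      return(data.frame(gene1 = character(), gene2 = character()))
    df <- unique(data.frame(gene1 = pmin(g1, g2), gene2 = pmax(g1, g2),
                            stringsAsFactors = FALSE))
    df[order(df$gene1, df$gene2), , drop = FALSE]
  }
  interacting <- mk(network$query, network$suppressor)
  sh1 <- character(0); sh2 <- character(0)
  for (q in unique(network$query)) {
    sup <- sort(unique(network$suppressor[network$query == q]))
    if (length(sup) >= 2L) {
      cmb <- utils::combn(sup, 2L)
      sh1 <- c(sh1, cmb[1, ]); sh2 <- c(sh2, cmb[2, ])
    }
  }
  sharing <- mk(sh1, sh2)
  rownames(interacting) <- rownames(sharing) <- NULL
  list(interacting = interacting, sharing = sharing)
}

# precompute fast structures for predicate evaluation over a gene universe
predicate_context <- function(universe, annotations,
                              generic_loc = c("nucleus", "cytosol")) {
  inc <- function(map) {
    map <- map[map$gene_id %in% universe, , drop = FALSE]
    terms <- sort(unique(map$term))
    A <- matrix(FALSE, length(universe), length(terms),
                dimnames = list(universe, terms))
    if (nrow(map)) A[cbind(match(map$gene_id, universe),
                           match(map$term, terms))] <- TRUE
    A
  }
  ctx <- list(universe = universe, generic_loc = generic_loc)
  if (!is.null(annotations$go)) ctx$go <- inc(annotations$go)
  if (!is.null(annotations$loc)) ctx$loc <- inc(annotations$loc)
  if (!is.null(annotations$ppi))
    ctx$ppi <- unique(pair_key(annotations$ppi[[1]], annotations$ppi[[2]]))
  ctx
}

# vectorised predicate over index pairs into ctx$universe
eval_predicate_idx <- function(i, j, predicate, ctx) {
  if (predicate == "shared_go") {
    A <- ctx$go
    annotated <- rowSums(A) > 0
    res <- rowSums(A[i, , drop = FALSE] & A[j, , drop = FALSE]) > 0
    res[!annotated[i] | !annotated[j]] <- NA
    return(res)
  }
  if (predicate == "colocalized") {
    A <- ctx$loc
    annotated <- rowSums(A) > 0
    specific <- !colnames(A) %in% ctx$generic_loc
    shared_specific <- rowSums(A[i, specific, drop = FALSE] &
                                 A[j, specific, drop = FALSE]) > 0
    res <- shared_specific
    res[!annotated[i] | !annotated[j]] <- NA
    return(res)
  }
  if (predicate == "ppi") {
    g1 <- ctx$universe[i]; g2 <- ctx$universe[j]
    return(pair_key(g1, g2) %in% ctx$ppi)
  }
  stop("unknown predicate: ", predicate)
}

#' Evaluate a functional-similarity predicate for gene pairs
#'
#' `shared_go` is true when the two genes share at least one GO-slim term
#' and indeterminate (NA) when either gene has no terms. `colocalized` is
#' true when the genes share at least one subcellular localization other
#' than the two generic compartments (nucleus, cytosol); a pair sharing
#' only those is false, and a pair with an unannotated gene is NA. `ppi` is
#' true when the unordered pair is in the physical-interaction set and is
#' never indeterminate.
#'
#' @param pairs data.frame with `gene1`, `gene2`.
#' @param predicate one of "shared_go", "colocalized", "ppi".
#' @param annotations list with data.frames `go` (gene_id, term), `loc`
#'   (gene_id, term) and `ppi` (two gene columns), as needed.
#' @return logical vector (with NA for indeterminate pairs).
#' @export
evaluate_predicate <- function(pairs, predicate, annotations) {
  universe <- sort(unique(c(pairs$gene1, pairs$gene2,
                            annotations$go$gene_id,
                            annotations$loc$gene_id)))
  ctx <- predicate_context(universe, annotations)
  unname(eval_predicate_idx(match(pairs$gene1, universe),
                            match(pairs$gene2, universe), predicate, ctx))
}

# enumerate (or sample) the background and count evaluable/positive pairs
background_counts <- function(background, predicate, ctx, max_enum,
                              sample_size) {
  if (background$type == "cross") {
    s1 <- match(background$set1, ctx$universe)
    s2 <- match(background$set2, ctx$universe)
    B_total <- length(s1) * length(s2)
    gen <- function(rows) {
      i1 <- ((rows - 1L) %% length(s1)) + 1L
      i2 <- ((rows - 1L) %/% length(s1)) + 1L
      list(i = s1[i1], j = s2[i2])
    }
  } else if (background$type == "within") {
    s <- match(background$set, ctx$universe)
    n <- length(s)
    B_total <- n * (n - 1) / 2
    gen <- function(rows) {
      # row-wise enumeration of i < j from a linear index
      i <- n - 1 - floor((sqrt(4 * n * (n - 1) - 8 * rows + 1) - 1) / 2)
      off <- rows - (i - 1) * n + (i - 1) * i / 2
      list(i = s[i], j = s[i + off])
    }
  } else stop("unknown background type: ", background$type)
  if (anyNA(c(background$set1, background$set2, background$set)))
    stop("background contains genes outside the annotation universe")
  if (B_total < 1) stop("empty background")
  enumerated <- B_total <= max_enum
  rows <- if (enumerated) seq_len(B_total)
          else ceiling(runif(sample_size) * B_total)
  K <- 0L; B_eval <- 0L
  for (chunk in split(rows, ceiling(seq_along(rows) / 2e5))) {
    ij <- gen(chunk)
    v <- eval_predicate_idx(ij$i, ij$j, predicate, ctx)
    K <- K + sum(v, na.rm = TRUE)
    B_eval <- B_eval + sum(!is.na(v))
  }
  list(K = K, B_eval = B_eval, B_total = B_total, enumerated = enumerated)
}

#' Enrichment of a functional-similarity predicate among observed pairs
#'
#' Compares the fraction of observed pairs satisfying a predicate with the
#' fraction among all background pairs. The background is enumerated
#' exhaustively when it holds at most `max_enum` pairs and sampled
#' uniformly otherwise; indeterminate pairs are removed from both numerator
#' and denominator. The permutation p-value draws `n_perm` random sets of
#' the observed size from the evaluable background (the positive count of
#' such a draw is hypergeometric) with an add-one correction; the exact
#' hypergeometric tail is reported alongside when the background was
#' enumerated.
#'
#' @param pairs data.frame of observed pairs (`gene1`, `gene2`).
#' @param background `list(type = "cross", set1 =, set2 =)` for all
#'   combinations between two gene sets, or `list(type = "within", set =)`
#'   for all unordered pairs inside one set.
#' @param predicate one of "shared_go", "colocalized", "ppi".
#' @param annotations as in [evaluate_predicate()].
#' @param n_perm Monte Carlo draws for the p-value.
#' @param seed integer seed.
#' @param max_enum largest background enumerated exhaustively.
#' @param sample_size pairs sampled when the background is too large.
#' @param randomized also report `p_randomized`, a randomized version of the
#'   permutation p-value (ties enter with uniform weight) that is exactly
#'   uniform under the null despite the discreteness of the positive count;
#'   used for calibration diagnostics.
#' @return an `enrichment_report` list: predicate, m (evaluable observed
#'   pairs), k (positives), B (evaluable background), K (background
#'   positives), expected_fraction, observed_fraction, ratio, p_value,
#'   p_exact, method, n_perm, seed.
#' @export
enrichment <- function(pairs, background, predicate, annotations,
                       n_perm = 10000, seed = 1, max_enum = 1e7,
                       sample_size = 1e5, randomized = FALSE) {
  set.seed(as.integer(seed))
  bg_genes <- unique(c(background$set1, background$set2, background$set))
  universe <- sort(unique(c(pairs$gene1, pairs$gene2, bg_genes,
                            annotations$go$gene_id,
                            annotations$loc$gene_id)))
  ctx <- predicate_context(universe, annotations)
  in_bg <- if (background$type == "cross") {
    (pairs$gene1 %in% background$set1 & pairs$gene2 %in% background$set2) |
      (pairs$gene2 %in% background$set1 & pairs$gene1 %in% background$set2)
  } else {
    pairs$gene1 %in% background$set & pairs$gene2 %in% background$set
  }
  if (any(!in_bg))
    stop(sum(!in_bg), " observed pair(s) outside the background universe")
  obs <- eval_predicate_idx(match(pairs$gene1, universe),
                            match(pairs$gene2, universe), predicate, ctx)
  m <- sum(!is.na(obs)); k <- sum(obs, na.rm = TRUE)
  if (m == 0L) stop("no evaluable observed pairs")
  bc <- background_counts(background, predicate, ctx, max_enum, sample_size)
  if (bc$B_eval == 0L) stop("zero evaluable background pairs")
  exp_frac <- bc$K / bc$B_eval
  ratio <- (k / m) / exp_frac
  if (bc$enumerated) {
    draws <- stats::rhyper(n_perm, bc$K, bc$B_eval - bc$K, min(m, bc$B_eval))
    p_exact <- stats::phyper(k - 1, bc$K, bc$B_eval - bc$K,
                             min(m, bc$B_eval), lower.tail = FALSE)
  } else {
    draws <- stats::rbinom(n_perm, m, exp_frac)
    p_exact <- NA_real_
  }
  p <- (sum(draws >= k) + 1) / (n_perm + 1)
  p_rand <- if (randomized)
    (sum(draws > k) + runif(1) * (sum(draws == k) + 1)) / (n_perm + 1)
  else NA_real_
  structure(list(predicate = predicate, p_randomized = p_rand,
                 m = m, k = k, B = bc$B_eval,
                 K = bc$K, expected_fraction = exp_frac,
                 observed_fraction = k / m, ratio = ratio, p_value = p,
                 p_exact = p_exact,
                 method = if (bc$enumerated) "exact-enumeration"
                          else "sampled",
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf(
    "%s: %d/%d observed (%.3f) vs %d/%d background (%.4f); ratio %.2f, p %.3g (%s)\n",
    x$predicate, x$k, x$m, x$observed_fraction, x$K, x$B,
    x$expected_fraction, x$ratio, x$p_value, x$method))
  invisible(x)
}
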