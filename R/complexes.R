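#' Build a protein complex catalog
#'
#' @param members data.frame with columns `complex_id`, `gene_id` and
#'   logical `queried` (whether the subunit is encoded by a screened query
#'   gene).
#' @param features optional data.frame of per-complex feature values with a
#'   `complex_id` column; remaining columns must be numeric.
#' @return an object of class `complex_catalog`.
#' @export
complex_catalog <- function(members, features = NULL) {
  stopifnot(all(c("complex_id", "gene_id", "queried") %in% names(members)))
  if (!is.logical(members$queried)) stop("`queried` must be logical")
  if (!is.null(features)) {
    stopifnot("complex_id" %in% names(features))
    num <- setdiff(names(features), "complex_id")
    if (!all(vapply(features[num], is.numeric, TRUE)))
      stop("all feature columns must be numeric")
  }
  structure(list(members = members, features = features),
            class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat("complex_catalog: ", length(unique(x$members$complex_id)),
      " complexes, ", length(unique(x$members$gene_id)), " genes",
      if (!is.null(x$features))
        paste0(", ", ncol(x$features) - 1L, " features"), "\n", sep = "")
  invisible(x)
}

#' Classify complexes by the bypassability of their queried subunits
#'
#' A complex with at least two queried subunits is `bypassable` when all of
#' them are bypassable, `non_bypassable` when none is, and `mixed`
#' otherwise. Complexes with fewer than two queried subunits are ineligible
#' and excluded (category NA, with the reason recorded).
#'
#' @param catalog a [complex_catalog()].
#' @param bypassable_set character vector of bypassable gene ids.
#' @return data.frame with complex_id, n_queried, n_bypassable, eligible,
#'   category.
#' @export
classify_complexes <- function(catalog, bypassable_set) {
  stopifnot(inherits(catalog, "complex_catalog"))
  mem <- catalog$members[catalog$members$queried, , drop = FALSE]
  ids <- unique(catalog$members$complex_id)
  n_q <- vapply(ids, function(cx)
    length(unique(mem$gene_id[mem$complex_id == cx])), 1L)
  n_b <- vapply(ids, function(cx)
    sum(unique(mem$gene_id[mem$complex_id == cx]) %in% bypassable_set), 1L)
  eligible <- n_q >= 2L
  category <- rep(NA_character_, length(ids))
  category[eligible & n_b == n_q] <- "bypassable"
  category[eligible & n_b == 0L] <- "non_bypassable"
  category[eligible & n_b > 0L & n_b < n_q] <- "mixed"
  data.frame(complex_id = ids, n_queried = n_q, n_bypassable = n_b,
             eligible = eligible,
             reason = ifelse(eligible, NA_character_,
                             "fewer than 2 queried subunits"),
             category = category, stringsAsFactors = FALSE, row.names = NULL)
}

# queried-membership incidence matrix over eligible complexes
queried_incidence <- function(catalog) {
  mem <- unique(catalog$members[catalog$members$queried,
                                c("complex_id", "gene_id")])
  tab <- table(mem$complex_id, mem$gene_id) > 0
  M <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  M[rowSums(M) >= 2L, , drop = FALSE]
}

#' Permutation test for shared bypassability within complexes
#'
#' Holds complex membership fixed and redraws which genes are bypassable:
#' each permutation assigns the observed number of bypassable genes
#' uniformly without replacement among the queried genes of the eligible
#' complexes (a gene keeps one label across all complexes it belongs to),
#' then reclassifies the complexes. Expected counts are permutation means;
#' p-values are one-sided with an add-one correction, in the direction of
#' the observed deviation by default.
#'
#' @param catalog a [complex_catalog()].
#' @param bypassable_set bypassable gene ids.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail "auto" (direction of observed deviation), "ge" or "le".
#' @param n_bypassable optionally override the number of bypassable labels
#'   drawn per permutation (defaults to the observed count in the universe).
#' @param randomized also report a randomized p-value per category
#'   (`p_randomized`): ties between permuted and observed counts enter with
#'   a uniform weight, which makes the p-value exactly uniform under the
#'   null despite the discreteness of the counts. Intended for calibration
#'   diagnostics; the add-one p-value remains the reported test result.
#' @return an object of class `boe_permutation`: data.frame `summary` with
#'   observed, expected and p per category, plus `n_perm`, `seed`,
#'   `universe_size`, `n_bypassable`.
#' @export
permute_shared_bypassability <- function(catalog, bypassable_set,
                                         n_perm = 1000, seed = 1,
                                         tail = c("auto", "ge", "le"),
                                         n_bypassable = NULL,
                                         randomized = FALSE) {
  tail <- match.arg(tail)
  stopifnot(n_perm >= 1)
  M <- queried_incidence(catalog)
  if (!nrow(M)) stop("no eligible complexes (>= 2 queried subunits)")
  genes <- colnames(M)
  b <- if (is.null(n_bypassable)) sum(genes %in% bypassable_set)
       else as.integer(n_bypassable)
  if (b > length(genes))
    stop("bypassable count (", b, ") exceeds the gene universe (",
         length(genes), ")")
  n_q <- rowSums(M)
  count_cats <- function(byp_vec) {
    s <- as.vector(M %*% byp_vec)
    c(bypassable = sum(s == n_q), non_bypassable = sum(s == 0),
      mixed = sum(s > 0 & s < n_q))
  }
  obs <- count_cats(as.numeric(genes %in% bypassable_set))
  set.seed(as.integer(seed))
  perm <- matrix(0, length(genes), n_perm)
  for (j in seq_len(n_perm))
    perm[sample.int(length(genes), b), j] <- 1
  S <- M %*% perm
  perm_counts <- rbind(
    bypassable = colSums(S == n_q),
    non_bypassable = colSums(S == 0),
    mixed = colSums(S > 0 & S < n_q))
  expected <- rowMeans(perm_counts)
  p <- p_rand <- dir <- setNames(numeric(3), names(obs))
  for (cat in names(obs)) {
    use_ge <- switch(tail, ge = TRUE, le = FALSE,
                     auto = obs[[cat]] >= expected[[cat]])
    strict <- if (use_ge) sum(perm_counts[cat, ] > obs[[cat]])
              else sum(perm_counts[cat, ] < obs[[cat]])
    ties <- sum(perm_counts[cat, ] == obs[[cat]])
    p[cat] <- (strict + ties + 1) / (n_perm + 1)
    p_rand[cat] <- (strict + runif(1) * (ties + 1)) / (n_perm + 1)
    dir[cat] <- if (use_ge) 1 else -1
  }
  summary <- data.frame(category = names(obs), observed = unname(obs),
                        expected = unname(expected), p_value = unname(p),
                        tail = ifelse(dir > 0, "ge", "le"),
                        stringsAsFactors = FALSE)
  if (randomized) summary$p_randomized <- unname(p_rand)
  structure(list(
    summary = summary,
    n_perm = n_perm, seed = as.integer(seed),
    universe_size = length(genes), n_bypassable = b),
    class = "boe_permutation")
}

#' @export
print.boe_permutation <- function(x, ...) {
  cat("Shared-bypassability permutation test (", x$n_perm,
      " permutations, ", x$universe_size, " genes, ", x$n_bypassable,
      " bypassable)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Screen complex features for power to separate bypassable from
#' non-bypassable complexes
#'
#' For every numeric feature, compares bypassable against non-bypassable
#' complexes (mixed complexes are excluded) with a two-sided rank-sum test
#' and reports the ROC AUC computed from the rank statistic as
#' `U / (n1 * n2)`, with bypassable complexes as the positive class.
#' Features missing for all complexes are skipped with a warning.
#'
#' @param catalog a [complex_catalog()] with features.
#' @param classification output of [classify_complexes()].
#' @return data.frame with feature, n_bypassable, n_non_bypassable,
#'   p_value, auc and predictive (p < 0.05), sorted by p.
#' @export
feature_screen <- function(catalog, classification) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (is.null(catalog$features)) stop("catalog has no feature table")
  feats <- catalog$features
  cls <- classification[match(feats$complex_id, classification$complex_id),
                        "category"]
  pos <- cls == "bypassable" & !is.na(cls)
  neg <- cls == "non_bypassable" & !is.na(cls)
  if (sum(pos) < 2L || sum(neg) < 2L)
    stop("need >= 2 bypassable and >= 2 non-bypassable complexes")
  rows <- list()
  for (f in setdiff(names(feats), "complex_id")) {
    x <- feats[[f]][pos]; y <- feats[[f]][neg]
    if (all(is.na(x)) || all(is.na(y))) {
      warning("feature skipped (all missing in a group): ", f)
      next
    }
    mw <- mann_whitney_feature(x, y)
    rows[[f]] <- data.frame(feature = f, n_bypassable = mw$n_A,
                            n_non_bypassable = mw$n_B, U = mw$U,
                            p_value = mw$p_value,
                            auc = mw$U / (mw$n_A * mw$n_B),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$predictive <- res$p_value < 0.05
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  res
}

#' Hierarchically cluster complexes on selected features
#'
#' Median-imputes missing feature values, z-scores each feature (optional),
#' and performs average-linkage (UPGMA) agglomerative clustering on
#' Euclidean distances.
#'
#' @param catalog a [complex_catalog()] with features.
#' @param selected_features feature names to use (default all).
#' @param k,h optional flat-cluster count or cut height for
#'   [stats::cutree()].
#' @param standardize z-score features before clustering.
#' @return list of class `complex_clustering` with `hclust`, `labels`
#'   (flat assignments or NULL), and the processed `matrix`.
#' @export
cluster_complexes <- function(catalog, selected_features = NULL, k = NULL,
                              h = NULL, standardize = TRUE) {
  stopifnot(inherits(catalog, "complex_catalog"))
  if (is.null(catalog$features)) stop("catalog has no feature table")
  feats <- catalog$features
  if (is.null(selected_features))
    selected_features <- setdiff(names(feats), "complex_id")
  missing_f <- setdiff(selected_features, names(feats))
  if (length(missing_f))
    stop("unknown feature(s): ", paste(missing_f, collapse = ", "))
  if (length(selected_features) < 1L) stop("need >= 1 feature")
  X <- as.matrix(feats[selected_features])
  rownames(X) <- feats$complex_id
  if (nrow(X) < 2L) stop("need >= 2 complexes to cluster")
  for (j in seq_len(ncol(X))) {
    col <- X[, j]
    if (all(is.na(col)))
      stop("feature has no observed values: ", selected_features[j])
    col[is.na(col)] <- median(col, na.rm = TRUE)
    if (standardize) {
      s <- sd(col)
      col <- if (s > 0) (col - mean(col)) / s else col - mean(col)
    }
    X[, j] <- col
  }
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "average")
  labels <- NULL
  if (!is.null(k) || !is.null(h))
    labels <- stats::cutree(hc, k = k, h = h)
  structure(list(hclust = hc, labels = labels, matrix = X),
            class = "complex_clustering")
}

#' Predict bypassable complexes from a dendrogram
#'
#' Finds the lowest internal node of the dendrogram whose leaves contain
#' every known bypassable complex; the node's remaining leaves are the
#' predicted bypassable complexes, tagged with the node merge height.
#'
#' @param clustering a [cluster_complexes()] result (or a bare `hclust`).
#' @param known character vector of known bypassable complex ids (leaf
#'   labels; non-empty, all present in the tree).
#' @return list with `predicted` (character), `node_height`, `node_leaves`.
#' @export
predict_bypassable_cluster <- function(clustering, known) {
  hc <- if (inherits(clustering, "complex_clustering")) clustering$hclust
        else clustering
  stopifnot(inherits(hc, "hclust"), length(known) >= 1L)
  absent <- setdiff(known, hc$labels)
  if (length(absent))
    stop("known complex(es) absent from tree: ",
         paste(absent, collapse = ", "))
  n <- length(hc$labels)
  node_leaves <- vector("list", nrow(hc$merge))
  target <- match(known, hc$labels)
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    leaves <- unlist(lapply(kids, function(kk)
      if (kk < 0) -kk else node_leaves[[kk]]))
    node_leaves[[i]] <- leaves
    if (all(target %in% leaves)) {
      others <- setdiff(leaves, target)
      return(list(predicted = hc$labels[others],
                  node_height = hc$height[i],
                  node_leaves = hc$labels[leaves]))
    }
  }
  stop("internal error: no containing node found")  # unreachable
}
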