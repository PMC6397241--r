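#' Deduplicate transposon insertion records
#'
#' Within each (sample, chromosome) group, insertions closer than 3 bp are
#' treated as one event and the record with the higher read count is kept
#' (ties keep the leftmost). The sweep is a greedy left-to-right pass over
#' position-sorted records in which the retained record replaces the current
#' anchor, so chains of nearby insertions collapse deterministically.
#' Identical positions in different samples are retained: they are
#' independent events.
#'
#' @param table an insertion table (see [simulate_tboe_screen()]).
#' @return the deduplicated table, sorted by sample, chromosome, position.
#' @export
dedup_insertions <- function(table) {
  if (nrow(table) == 0L) return(table)
  o <- order(table$sample_id, table$chrom, table$position)
  table <- table[o, , drop = FALSE]
  grp <- paste(table$sample_id, table$chrom, sep = "\r")
  keep <- logical(nrow(table))
  for (idx in split(seq_len(nrow(table)), grp)) {
    anchor <- idx[1]
    keep[anchor] <- TRUE
    for (k in idx[-1]) {
      if (table$position[k] - table$position[anchor] < 3L) {
        if (table$read_count[k] > table$read_count[anchor]) {
          keep[anchor] <- FALSE
          keep[k] <- TRUE
          anchor <- k
        }
      } else {
        keep[k] <- TRUE
        anchor <- k
      }
    }
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a genome into ORF and intergenic regions
#'
#' Tiles every chromosome exactly: ORF regions equal gene intervals and
#' intergenic regions fill the gaps, including chromosome ends. Zero-length
#' regions are omitted.
#'
#' @param genome a `boe_genome`.
#' @return data.frame with region_id, chrom, start, end (0-based half-open),
#'   kind ("ORF" or "intergenic") and gene_id (NA for intergenic regions).
#' @export
partition_regions <- function(genome) {
  stopifnot(inherits(genome, "boe_genome"))
  out <- list()
  for (chrom in names(genome$chromosomes)) {
    L <- nchar(genome$chromosomes[[chrom]])
    g <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1L) {
      ov <- which(g$start[-1] < g$end[-nrow(g)])
      if (length(ov))
        stop("overlapping genes on ", chrom, ": ", g$gene_id[ov[1]],
             " and ", g$gene_id[ov[1] + 1L])
    }
    bounds <- c(0L, rbind(g$start, g$end), L)
    ig <- 0L
    for (j in seq_len(length(bounds) - 1L)) {
      s <- bounds[j]; e <- bounds[j + 1L]
      if (e <= s) next
      is_orf <- j %% 2L == 0L  # even segments are gene intervals
      if (is_orf) {
        gid <- g$gene_id[j %/% 2L]
        out[[length(out) + 1L]] <- data.frame(
          region_id = gid, chrom = chrom, start = s, end = e,
          kind = "ORF", gene_id = gid, stringsAsFactors = FALSE)
      } else {
        ig <- ig + 1L
        out[[length(out) + 1L]] <- data.frame(
          region_id = sprintf("%s_ig%03d", chrom, ig), chrom = chrom,
          start = s, end = e, kind = "intergenic", gene_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-cell goodness-of-fit G-test for insertion enrichment
#'
#' Compares the observed number of insertions in a region against the
#' expectation proportional to its share of TTAA target sites:
#' `E = N_obs * T / N_pot`, `G = 2 * (O * ln(O/E) + (N_obs - O) *
#' ln((N_obs - O)/(N_obs - E)))` with the convention `0 * ln(0/x) = 0`,
#' referred to the upper tail of a chi-square with 1 df. The degenerate case
#' `T == N_pot` with `O < N_obs` (expected count zero outside the region) is
#' flagged rather than returned as an infinite statistic.
#'
#' @param O observed insertions in the region.
#' @param T_sites TTAA sites in the region.
#' @param N_obs total observed insertions.
#' @param N_pot total TTAA sites.
#' @return list with `G`, `p_value` and `degenerate` (all vectorised).
#' @examples
#' region_gtest(30, 100, 1000, 10000)
#' @export
region_gtest <- function(O, T_sites, N_obs, N_pot) {
  n <- max(length(O), length(T_sites), length(N_obs), length(N_pot))
  O <- rep_len(O, n); T_sites <- rep_len(T_sites, n)
  N_obs <- rep_len(N_obs, n); N_pot <- rep_len(N_pot, n)
  stopifnot(all(O >= 0), all(O <= N_obs), all(T_sites >= 1),
            all(T_sites <= N_pot), all(N_obs >= 1))
  E <- N_obs * T_sites / N_pot
  degenerate <- T_sites == N_pot & O < N_obs
  term <- function(obs, exp) ifelse(obs == 0, 0, obs * log(obs / exp))
  G <- 2 * (term(O, E) + term(N_obs - O, N_obs - E))
  G[degenerate] <- NA_real_
  # guard tiny negative values from floating point when O == E
  G <- pmax(G, 0)
  p <- stats::pchisq(G, df = 1, lower.tail = FALSE)
  list(G = G, p_value = p, degenerate = degenerate)
}

# count events with 0-based positions falling in each region of one genome
count_in_regions <- function(regions, chrom, pos) {
  counts <- integer(nrow(regions))
  for (ch in unique(regions$chrom)) {
    r <- which(regions$chrom == ch)
    idx <- which(chrom == ch)
    if (!length(idx)) next
    # regions tile the chromosome, so findInterval on starts is exact
    hit <- findInterval(pos[idx], regions$start[r])
    tab <- tabulate(hit, nbins = length(r))
    counts[r] <- counts[r] + tab
  }
  counts
}

#' Call candidate suppressor regions from an insertion table
#'
#' Deduplicates insertions, partitions the genome into ORF and intergenic
#' regions, counts observed insertions and TTAA target sites per region,
#' applies the per-region G-test and Benjamini-Hochberg correction across
#' all regions, and flags candidate ORFs.
#'
#' @param table insertion table (deduplication is always applied; the
#'   operation is idempotent).
#' @param genome a `boe_genome`.
#' @param alpha BH-adjusted significance threshold for candidates.
#' @param min_insertions minimum observed insertions for a candidate.
#' @param samples optional character vector restricting to given sample ids
#'   before pooling (by default all samples of the query are pooled).
#' @return data.frame of per-region results (region_id, kind, O, T_sites,
#'   N_obs, N_pot, E, G, p_value, q_value, enriched, candidate), sorted by
#'   ascending p then descending O, with the deduplicated insertion count in
#'   attribute `n_dedup`.
#' @export
call_tboe_candidates <- function(table, genome, alpha = 0.05,
                                 min_insertions = 2, samples = NULL) {
  stopifnot(inherits(genome, "boe_genome"))
  if (!is.null(samples)) table <- table[table$sample_id %in% samples, ,
                                        drop = FALSE]
  table <- dedup_insertions(table)
  if (nrow(table) == 0L) stop("no insertions after deduplication")
  regions <- partition_regions(genome)
  O <- count_in_regions(regions, table$chrom, table$position)
  ttaa_chrom <- rep(names(genome$ttaa_sites), lengths(genome$ttaa_sites))
  ttaa_pos <- unlist(genome$ttaa_sites, use.names = FALSE)
  T_sites <- count_in_regions(regions, ttaa_chrom, ttaa_pos)
  N_obs <- sum(O); N_pot <- sum(T_sites)
  res <- regions[, c("region_id", "chrom", "start", "end", "kind", "gene_id")]
  res$O <- O
  res$T_sites <- T_sites
  res$N_obs <- N_obs
  res$N_pot <- N_pot
  res$E <- N_obs * T_sites / N_pot
  testable <- T_sites >= 1
  res$G <- res$p_value <- NA_real_
  if (any(testable)) {
    gt <- region_gtest(O[testable], T_sites[testable], N_obs, N_pot)
    res$G[testable] <- gt$G
    res$p_value[testable] <- gt$p_value
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$O > res$E
  res$candidate <- res$kind == "ORF" & res$enriched &
    !is.na(res$q_value) & res$q_value <= alpha & res$O >= min_insertions
  res <- res[order(res$p_value, -res$O), ]
  rownames(res) <- NULL
  attr(res, "n_dedup") <- nrow(table)
  res
}
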