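# Generates the synthetic fixture tables under inst/extdata.
# Gene/complex/suppressor identities are invented; only the tallies are
# meaningful (38/142 bypassable; 7-gene mitochondrial-translation term wholly
# bypassable; 124-gene ortholog cross-tab 24/31 vs 13/93; 20 complexes
# classifying 5 bypassable / 11 non-bypassable / 4 mixed; 263 network edges
# from 157 suppressors).
set.seed(20260929)

hdr <- function(con, what)
  writeLines(c(paste0("# boescan synthetic fixture: ", what),
               "# generated by scratch/make_fixtures.R (fixed seed)"), con)

out <- function(df, name, what) {
  path <- file.path("inst/extdata", paste0("fixture_", name,
                                           "_synthetic.tsv"))
  con <- file(path, "w"); on.exit(close(con))
  hdr(con, what)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  message(path, ": ", nrow(df), " rows")
}

# --- gene table: 142 screened, 38 bypassable, 124 one-to-one orthologs ----
genes <- sprintf("q%03d", 1:142)
byp <- c(rep(TRUE, 38), rep(FALSE, 104))
# one-to-one ortholog subset: 31 bypassable, 93 non-bypassable
one2one <- c(rep(TRUE, 31), rep(FALSE, 7),      # bypassable block
             rep(TRUE, 93), rep(FALSE, 11))     # non-bypassable block
# ortholog dispensability among the one-to-one subset: 24/31 and 13/93
status <- rep("none", 142)
status[1:31] <- c(rep("non-essential", 24), rep("essential", 7))
status[39:131] <- c(rep("non-essential", 13), rep("essential", 80))
gene_df <- data.frame(gene_id = genes, screened = TRUE, bypassable = byp,
                      sc_one_to_one = one2one, sc_ortholog_status = status)
stopifnot(sum(gene_df$bypassable) == 38,
          sum(gene_df$sc_one_to_one) == 124,
          sum(gene_df$sc_one_to_one & gene_df$bypassable) == 31,
          sum(gene_df$sc_one_to_one & gene_df$bypassable &
                gene_df$sc_ortholog_status == "non-essential") == 24,
          sum(gene_df$sc_one_to_one & !gene_df$bypassable &
                gene_df$sc_ortholog_status == "non-essential") == 13)
out(gene_df, "genes", "142 screened genes, 38 bypassable")

# --- GO-slim term map: mito-translation term = 7 bypassable genes ---------
mito <- data.frame(gene_id = genes[1:7], term = "mitochondrial_translation")
other_terms <- sprintf("term_%02d", 1:12)
filler <- data.frame(gene_id = sample(genes, 320, replace = TRUE),
                     term = sample(other_terms, 320, replace = TRUE))
terms <- unique(rbind(mito, filler))
stopifnot(identical(sort(terms$gene_id[terms$term ==
                                         "mitochondrial_translation"]),
                    sort(genes[1:7])))
out(terms, "terms", "GO-slim map; mitochondrial_translation = 7 bypassable")

# --- suppressor network: 263 edges, 38 queries, 157 suppressors -----------
sup <- sprintf("s%03d", 1:157)
qset <- genes[1:38]
q_edge <- c(qset, sample(qset, 263 - 38, replace = TRUE))
s_edge <- c(sup, sample(sup, 263 - 157, replace = TRUE))
s_edge <- sample(s_edge)  # decouple suppressor order from query order
net <- data.frame(suppressor = s_edge, query = q_edge,
                  type = sample(c("T-BOE-deletion", "T-BOE-insertion",
                                  "C-BOE", "OP-BOE"), 263, replace = TRUE,
                                prob = c(0.3, 0.15, 0.15, 0.4)))
net <- net[order(net$query, net$suppressor), ]
# edges must be distinct (query, suppressor) pairs
while (any(dup <- duplicated(net[c("query", "suppressor")]))) {
  net$suppressor[dup] <- sample(sup, sum(dup), replace = TRUE)
}
net <- net[order(net$query, net$suppressor), ]
stopifnot(nrow(net) == 263, length(unique(net$query)) == 38,
          length(unique(net$suppressor)) == 157,
          !any(duplicated(net[c("query", "suppressor")])))
out(net, "network", "263 suppressor->query edges, 38 queries bypassed")

# --- complex catalog: 20 eligible complexes -> 5 / 11 / 4 -----------------
plan <- c(rep("bypassable", 5), rep("non_bypassable", 11), rep("mixed", 4))
byp_pool <- setdiff(genes[1:38], genes[1:7])   # keep mito genes aside
non_pool <- genes[39:142]
rows <- list()
for (i in seq_along(plan)) {
  n_q <- sample(2:4, 1)
  memb <- switch(plan[i],
    bypassable = { x <- byp_pool[1:n_q]; byp_pool <- byp_pool[-(1:n_q)]; x },
    non_bypassable = { x <- non_pool[1:n_q]; non_pool <- non_pool[-(1:n_q)]; x },
    mixed = {
      nb <- max(1, n_q - 2)
      x <- c(byp_pool[1:nb], non_pool[1:(n_q - nb)])
      byp_pool <- byp_pool[-(1:nb)]; non_pool <- non_pool[-(1:(n_q - nb))]
      x
    })
  rows[[i]] <- data.frame(complex_id = sprintf("cpx%02d", i),
                          gene_id = memb, queried = TRUE)
}
cpx <- do.call(rbind, rows)
out(cpx, "complex_members", "20 complexes: 5 bypassable / 11 non / 4 mixed")
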