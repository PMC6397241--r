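#' Choose a causal SNP site with a desired effect class inside a gene
#'
#' Scans the exonic positions of a gene for the first (position, alternate
#' allele) combination whose [classify_effect()] class matches `wanted`.
#' Used to plant a causal suppressor mutation for backcross-pool
#' simulations.
#'
#' @param genome a `boe_genome`.
#' @param gene_id target gene.
#' @param wanted desired effect class.
#' @return list with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @export
pick_causal_site <- function(genome, gene_id, wanted = "missense") {
  g <- genome$genes[genome$genes$gene_id == gene_id, ]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id)
  ex <- genome$exons[genome$exons$gene_id == gene_id, , drop = FALSE]
  pos_all <- unlist(mapply(seq, ex$start, ex$end - 1L, SIMPLIFY = FALSE))
  # skip start/stop codons at either end of the gene interval
  pos_all <- pos_all[pos_all > g$start + 3L & pos_all < g$end - 4L]
  for (p in pos_all) {
    ref <- genome_base(genome, g$chrom, p)
    for (a in setdiff(names(COMP), ref)) {
      eff <- classify_effect(list(chrom = g$chrom, pos = p, ref = ref,
                                  alt = a), genome)
      if (eff == wanted)
        return(list(chrom = g$chrom, pos = p, ref = ref, alt = a))
    }
  }
  stop("no position in ", gene_id, " yields effect class ", wanted)
}

default_pipeline_config <- function() {
  list(outdir = "boescan_out", seed = 1L,
       stages = c("simulate", "tboe", "opboe", "cboe"),
       sim = list(), tboe = list(alpha = 0.05, min_insertions = 2),
       opboe = list(), cboe = list(), stats = list(),
       complexes = list(n_perm = 1000), pairs = list(n_perm = 1000))
}

#' Run the screening pipeline on synthetic data
#'
#' Executes the requested stages in dependency order: `simulate` writes the
#' toy genome (FASTA + GFF3), a transposon insertion table, overexpression
#' screen counts and a backcross-pool VCF with one planted suppressor per
#' screen type; `tboe`, `opboe` and `cboe` run the corresponding callers on
#' those outputs; `stats`, `complexes` and `pairs` run the downstream
#' analyses on simulated annotation tables. Every output carries a header
#' with version and seed, and a JSON manifest with per-file MD5 checksums
#' plus a resolved-config YAML are written next to the outputs; rerunning
#' the same configuration reproduces identical checksums.
#'
#' @param config a named list (or path to a YAML file) overriding the
#'   defaults: `outdir`, `seed`, `stages`, and per-stage parameter blocks
#'   `sim`, `tboe`, `opboe`, `cboe`, `stats`, `complexes`, `pairs`. Unknown
#'   keys are rejected.
#' @return invisibly, the manifest (named list of output paths and
#'   checksums).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_pipeline_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  known_stages <- c("simulate", "tboe", "opboe", "cboe", "stats",
                    "complexes", "pairs")
  bad_stage <- setdiff(cfg$stages, known_stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outdir <- cfg$outdir
  seed <- as.integer(cfg$seed)
  files <- character(0)
  log_msg <- function(...) message("[boescan] ", ...)
  path <- function(f) file.path(outdir, f)
  add <- function(f) files <<- c(files, f)

  params <- do.call(sim_params, c(list(seed = seed), cfg$sim))
  genome <- tboe_table <- op_counts <- snps <- NULL
  planted <- list()

  if ("simulate" %in% cfg$stages) {
    genome <- simulate_genome(params)
    validate_genome(genome)
    write_genome(genome, path("genome.fa"), path("genes.gff3"))
    add(path("genome.fa")); add(path("genes.gff3"))
    non_query <- genome$genes$gene_id[!genome$genes$is_query]
    query <- genome$genes$gene_id[genome$genes$is_query][1]
    planted$tboe <- non_query[1]
    tboe_table <- simulate_tboe_screen(genome, planted$tboe, params,
                                       query_gene_id = query)
    write_insertions_bed(tboe_table, path("insertions.bed"), seed = seed)
    add(path("insertions.bed"))
    planted$opboe <- sprintf("P%04d", 1:3)
    op_counts <- simulate_opboe_screen(500L, planted$opboe, params)
    write_orfseq_counts(op_counts, path("orfseq_counts.tsv"), seed = seed)
    add(path("orfseq_counts.tsv"))
    qg <- genome$genes[genome$genes$gene_id == query, ]
    other_chrom <- genome$genes$chrom != qg$chrom &
      !genome$genes$is_query
    sup_gene <- genome$genes$gene_id[other_chrom][1]
    if (is.na(sup_gene)) sup_gene <- non_query[2]
    site <- pick_causal_site(genome, sup_gene)
    planted$cboe <- list(gene = sup_gene, site = site)
    snps <- simulate_bsa_seq(genome, site[c("chrom", "pos")], query,
                             params, causal_alt = site$alt)
    write_snp_vcf(snps, path("snps.vcf"), seed = seed)
    add(path("snps.vcf"))
    log_msg("simulate: ", nrow(tboe_table), " insertions, ",
            length(op_counts$plasmid_id), " plasmids, ", nrow(snps),
            " SNPs (seed ", seed, ")")
  }
  need_sim <- function(stage) {
    if (is.null(genome))
      stop("stage '", stage, "' requires upstream stage 'simulate'")
  }
  if ("tboe" %in% cfg$stages) {
    need_sim("tboe")
    res <- call_tboe_candidates(tboe_table, genome,
                                alpha = cfg$tboe$alpha,
                                min_insertions = cfg$tboe$min_insertions)
    write_boe_table(res, path("tboe_regions.tsv"), seed = seed)
    write_boe_table(res[res$candidate, ], path("tboe_candidates.tsv"),
                    seed = seed)
    add(path("tboe_regions.tsv")); add(path("tboe_candidates.tsv"))
    log_msg("tboe: ", sum(res$candidate), " candidate region(s)")
  }
  if ("opboe" %in% cfg$stages) {
    need_sim("opboe")
    sc <- rank_opboe(op_counts)
    write_boe_table(sc, path("opboe_scores.tsv"), seed = seed)
    add(path("opboe_scores.tsv"))
    log_msg("opboe: ", sum(sc$boe_score < 0), " plasmids with negative ",
            "BOE-score")
  }
  if ("cboe" %in% cfg$stages) {
    need_sim("cboe")
    qg <- genome$genes[genome$genes$is_query, ][1, ]
    fc <- cboe_filter_config(list(chrom = qg$chrom, start = qg$start,
                                  end = qg$end))
    res <- filter_candidates(snps, fc, genome)
    write_snp_vcf(res$candidates, path("cboe_candidates.vcf"), seed = seed)
    write_boe_table(data.frame(rule = names(res$tally),
                               rejected = as.integer(res$tally)),
                    path("cboe_tally.tsv"), seed = seed)
    add(path("cboe_candidates.vcf")); add(path("cboe_tally.tsv"))
    log_msg("cboe: ", nrow(res$candidates), " candidate SNP(s)")
  }
  ann <- NULL
  if (any(c("stats", "complexes", "pairs") %in% cfg$stages))
    ann <- simulate_annotation_tables(params)
  if ("stats" %in% cfg$stages) {
    byp <- ann$features$gene_id[ann$features$bypassable]
    go <- go_slim_enrichment(byp, ann$features$gene_id, ann$terms)
    write_boe_table(go, path("go_enrichment.tsv"), seed = seed)
    add(path("go_enrichment.tsv"))
    log_msg("stats: ", sum(go$q_value <= 0.05), " enriched term(s)")
  }
  if ("complexes" %in% cfg$stages) {
    cls <- classify_complexes(ann$complexes, ann$bypassable)
    perm <- permute_shared_bypassability(ann$complexes, ann$bypassable,
                                         n_perm = cfg$complexes$n_perm,
                                         seed = seed)
    write_boe_table(cls, path("complex_classes.tsv"), seed = seed)
    write_boe_table(perm$summary, path("complex_permutation.tsv"),
                    seed = seed)
    add(path("complex_classes.tsv")); add(path("complex_permutation.tsv"))
    log_msg("complexes: ",
            paste(perm$summary$observed, collapse = "/"),
            " observed per category")
  }
  if ("pairs" %in% cfg$stages) {
    prs <- build_pairs(ann$network)
    ann_list <- list(go = ann$terms, loc = ann$localization, ppi = ann$ppi)
    rep1 <- enrichment(prs$interacting,
                       list(type = "cross", set1 = ann$screened,
                            set2 = ann$nonessential),
                       "shared_go", ann_list, n_perm = cfg$pairs$n_perm,
                       seed = seed)
    out <- data.frame(pair_class = "interacting", predicate = "shared_go",
                      m = rep1$m, k = rep1$k, ratio = rep1$ratio,
                      p_value = rep1$p_value, method = rep1$method)
    write_boe_table(out, path("pair_enrichment.tsv"), seed = seed)
    add(path("pair_enrichment.tsv"))
    log_msg("pairs: shared-GO ratio ", round(rep1$ratio, 2))
  }

  yaml::write_yaml(cfg, path("config_resolved.yaml"))
  manifest <- list(version = pkg_version(), seed = seed,
                   stages = cfg$stages,
                   config = path("config_resolved.yaml"),
                   files = lapply(setNames(files, basename(files)),
                                  function(f)
                                    list(path = f,
                                         md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
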