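pkg_version <- function() {
  as.character(utils::packageVersion("boescan"))
}

header_lines <- function(seed = NULL, params = NULL) {
  c(paste0("# boescan v", pkg_version()),
    if (!is.null(seed)) paste0("# seed=", seed),
    if (!is.null(params)) paste0("# params: ", params))
}

#' Write a data frame as a commented TSV
#'
#' All tabular outputs share this format: `#`-prefixed header lines
#' recording the tool version, seed and resolved parameters, then a
#' tab-separated table with a column-name row.
#'
#' @param x data.frame.
#' @param path output path.
#' @param seed,params optional header metadata.
#' @export
write_boe_table <- function(x, path, seed = NULL, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(seed, params), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# schema registry: required columns and their coercions / checks
boe_schemas <- list(
  insertions = list(chrom = "character", position = "integer",
                    strand = "character", read_count = "integer",
                    sample_id = "character", query_gene_id = "character"),
  orfseq = list(plasmid_id = "character", screen_id = "character",
                end = "character", reads = "integer"),
  features = list(gene_id = "character", screened = "logical",
                  bypassable = "logical"),
  terms = list(gene_id = "character", term = "character"),
  network = list(suppressor = "character", query = "character",
                 type = "character"),
  complex_members = list(complex_id = "character", gene_id = "character",
                         queried = "logical"),
  ppi = list(gene1 = "character", gene2 = "character"),
  snps = list(chrom = "character", pos = "integer", ref = "character",
              alt = "character", quality = "numeric",
              ref_reads = "integer", alt_reads = "integer",
              ref_allele_fraction = "numeric", effect = "character")
)

#' Read and validate a tabular input
#'
#' Reads a `#`-commented TSV and validates it against one of the package's
#' named schemas (column presence, type coercion, basic range checks),
#' reporting the offending column and row on failure.
#'
#' @param path file path.
#' @param schema one of `r paste(names(boe_schemas), collapse = ", ")`.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- boe_schemas[[schema]]
  if (is.null(sch)) stop("unknown schema: ", schema)
  x <- utils::read.delim(path, comment.char = "#", sep = "\t",
                         stringsAsFactors = FALSE)
  miss <- setdiff(names(sch), names(x))
  if (length(miss))
    stop("schema '", schema, "': missing column(s) ",
         paste(miss, collapse = ", "), " in ", path)
  for (col in names(sch)) {
    coerce <- switch(sch[[col]], character = as.character,
                     integer = as.integer, numeric = as.numeric,
                     logical = as.logical)
    v <- suppressWarnings(coerce(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]))
    if (length(bad))
      stop("schema '", schema, "': column '", col, "' row ", bad[1],
           " is not ", sch[[col]])
    x[[col]] <- v
  }
  neg_cols <- intersect(c("position", "read_count", "reads", "pos",
                          "quality", "ref_reads", "alt_reads"), names(sch))
  for (col in neg_cols) {
    bad <- which(!is.na(x[[col]]) & x[[col]] < 0)
    if (length(bad))
      stop("schema '", schema, "': column '", col, "' row ", bad[1],
           " is negative")
  }
  if ("ref_allele_fraction" %in% names(sch)) {
    bad <- which(x$ref_allele_fraction < 0 | x$ref_allele_fraction > 1)
    if (length(bad))
      stop("schema 'snps': column 'ref_allele_fraction' row ", bad[1],
           " outside [0, 1]")
  }
  x
}

#' Write a genome as FASTA and GFF3
#'
#' Gene models are written as `gene` features (attributes `essential`,
#' `query`) with `exon` children; GFF3 coordinates are 1-based closed,
#' converted from the package's internal 0-based half-open intervals at
#' this boundary.
#'
#' @param genome a `boe_genome`.
#' @param fasta,gff3 output paths.
#' @export
write_genome <- function(genome, fasta, gff3) {
  stopifnot(inherits(genome, "boe_genome"))
  dna <- Biostrings::DNAStringSet(genome$chromosomes)
  Biostrings::writeXStringSet(dna, fasta)
  g <- genome$genes
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id,
    essential = ifelse(g$is_essential, "1", "0"),
    query = ifelse(g$is_query, "1", "0"))
  ex <- genome$exons
  ex_strand <- g$strand[match(ex$gene_id, g$gene_id)]
  ex_chrom <- g$chrom[match(ex$gene_id, g$gene_id)]
  exon_gr <- GenomicRanges::GRanges(
    ex_chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex_strand,
    type = "exon", ID = NA_character_, essential = NA_character_,
    query = NA_character_)
  S4Vectors::mcols(exon_gr)$Parent <- ex$gene_id
  S4Vectors::mcols(gene_gr)$Parent <- NA_character_
  rtracklayer::export(c(gene_gr, exon_gr), gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Read a genome from FASTA and GFF3
#'
#' Inverse of [write_genome()]; TTAA sites are re-enumerated from the
#' sequence. GFF3 1-based closed coordinates become 0-based half-open.
#'
#' @param fasta,gff3 input paths.
#' @return a `boe_genome`.
#' @export
read_genome <- function(fasta, gff3) {
  dna <- Biostrings::readDNAStringSet(fasta)
  chromosomes <- setNames(as.character(dna),
                          sub("\\s.*$", "", names(dna)))
  gr <- rtracklayer::import(gff3, format = "gff3")
  is_gene <- gr$type == "gene"
  gg <- gr[is_gene]
  genes <- data.frame(
    gene_id = as.character(gg$ID),
    chrom = as.character(GenomicRanges::seqnames(gg)),
    start = GenomicRanges::start(gg) - 1L,
    end = GenomicRanges::end(gg),
    strand = as.character(GenomicRanges::strand(gg)),
    is_essential = as.character(gg$essential) == "1",
    is_query = as.character(gg$query) == "1", stringsAsFactors = FALSE)
  ge <- gr[gr$type == "exon"]
  parent <- vapply(as.list(ge$Parent), function(p)
    as.character(p)[1], "")
  exons <- data.frame(gene_id = parent,
                      start = GenomicRanges::start(ge) - 1L,
                      end = GenomicRanges::end(ge))
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  structure(list(chromosomes = chromosomes, genes = genes, exons = exons,
                 ttaa_sites = lapply(chromosomes, find_ttaa_sites),
                 seed = NA_integer_, params = NULL),
            class = "boe_genome")
}

#' Write an insertion table as BED6+2
#'
#' Columns: chrom, start (0-based), end = start + 4 (the TTAA motif), name
#' = sample id, score = read count, strand, sample_id, query_gene_id.
#'
#' @param table insertion table.
#' @param path output path.
#' @param seed,params optional header metadata.
#' @export
write_insertions_bed <- function(table, path, seed = NULL, params = NULL) {
  bed <- data.frame(chrom = table$chrom, start = table$position,
                    end = table$position + 4L, name = table$sample_id,
                    score = table$read_count, strand = table$strand,
                    sample_id = table$sample_id,
                    query_gene_id = table$query_gene_id)
  write_boe_table(bed, path, seed = seed, params = params)
}

#' Read a BED6+2 insertion table
#' @param path input path.
#' @return insertion table data.frame.
#' @export
read_insertions_bed <- function(path) {
  x <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "score", "strand", "sample_id",
            "query_gene_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("BED insertion table missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(chrom = x$chrom, position = as.integer(x$start),
                    strand = x$strand, read_count = as.integer(x$score),
                    sample_id = x$sample_id,
                    query_gene_id = x$query_gene_id,
                    stringsAsFactors = FALSE)
  read_table_validate_insertions(out)
}

read_table_validate_insertions <- function(out) {
  if (any(out$read_count < 1)) stop("read_count must be >= 1")
  out
}

#' Write SNP records as minimal VCF v4.2
#'
#' QUAL carries the quality score; INFO carries `RO` (reference-supporting
#' reads), `AO` (alternate-supporting reads) and `EFF` (effect class).
#' Positions convert from internal 0-based to VCF 1-based.
#'
#' @param snps SNP data.frame (see [simulate_bsa_seq()]).
#' @param path output path.
#' @param seed optional header metadata.
#' @export
write_snp_vcf <- function(snps, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=boescan_v", pkg_version()),
               if (!is.null(seed)) paste0("##boescan_seed=", seed),
               "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference-supporting reads\">",
               "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate-supporting reads\">",
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    info <- sprintf("RO=%d;AO=%d;EFF=%s", snps$ref_reads, snps$alt_reads,
                    snps$effect)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s", snps$chrom,
                       snps$pos + 1L, snps$ref, snps$alt,
                       format(snps$quality, trim = TRUE), info), con)
  }
  invisible(path)
}

#' Read a minimal VCF of SNP records
#'
#' @param path VCF path (QUAL column and INFO keys RO/AO required; EFF
#'   optional).
#' @return SNP data.frame with 0-based `pos` and `ref_allele_fraction`
#'   computed from RO/(RO+AO).
#' @export
read_snp_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ro <- suppressWarnings(as.integer(vcfR::extract.info(v, "RO")))
  ao <- suppressWarnings(as.integer(vcfR::extract.info(v, "AO")))
  if (anyNA(ro)) stop("VCF missing INFO key RO on some records")
  if (anyNA(ao)) stop("VCF missing INFO key AO on some records")
  eff <- vcfR::extract.info(v, "EFF")
  data.frame(chrom = fix[, "CHROM"],
             pos = as.integer(fix[, "POS"]) - 1L,
             ref = fix[, "REF"], alt = fix[, "ALT"],
             quality = as.numeric(fix[, "QUAL"]),
             ref_reads = ro, alt_reads = ao,
             ref_allele_fraction = ro / pmax(1L, ro + ao),
             effect = if (is.null(eff)) NA_character_ else eff,
             stringsAsFactors = FALSE)
}

#' Write ORF-seq counts in long format
#' @param counts an `orfseq_counts` object.
#' @param path output path.
#' @param seed optional header metadata.
#' @export
write_orfseq_counts <- function(counts, path, seed = NULL) {
  stopifnot(inherits(counts, "orfseq_counts"))
  long <- function(mat, screen) data.frame(
    plasmid_id = rep(counts$plasmid_id, 2L),
    screen_id = screen,
    end = rep(c("N", "C"), each = length(counts$plasmid_id)),
    reads = c(mat$N, mat$C))
  blocks <- lapply(seq_along(counts$screen_id), function(s)
    long(list(N = counts$N[, s], C = counts$C[, s]), counts$screen_id[s]))
  blocks[[length(blocks) + 1L]] <-
    long(list(N = counts$N_control, C = counts$C_control), "control")
  write_boe_table(do.call(rbind, blocks), path, seed = seed)
}

#' Read long-format ORF-seq counts
#'
#' Expects columns plasmid_id, screen_id (with "control" for the pooled
#' input), end (N|C), reads.
#'
#' @param path input path.
#' @return an `orfseq_counts` object.
#' @export
read_orfseq_counts <- function(path) {
  x <- read_table(path, "orfseq")
  if (!all(x$end %in% c("N", "C")))
    stop("orfseq 'end' column must be N or C")
  plasmids <- sort(unique(x$plasmid_id))
  screens <- setdiff(unique(x$screen_id), "control")
  if (!"control" %in% x$screen_id)
    stop("orfseq table has no control rows")
  get <- function(screen, end) {
    sub <- x[x$screen_id == screen & x$end == end, ]
    v <- setNames(rep(NA_integer_, length(plasmids)), plasmids)
    v[sub$plasmid_id] <- sub$reads
    v[is.na(v)] <- 0L
    v
  }
  N <- vapply(screens, get, integer(length(plasmids)), end = "N")
  C <- vapply(screens, get, integer(length(plasmids)), end = "C")
  dimnames(N) <- dimnames(C) <- list(plasmids, screens)
  structure(list(N = N, C = C, N_control = get("control", "N"),
                 C_control = get("control", "C"), plasmid_id = plasmids,
                 screen_id = screens, seed = NA_integer_),
            class = "orfseq_counts")
}

#' Load a packaged synthetic fixture table
#'
#' The packaged fixtures transcribe the headline tallies of a chromosome-arm
#' bypass-of-essentiality dataset into fully synthetic tables (gene ids and
#' memberships are generated, only the tallies are real): a suppressor
#' network over 142 screened genes of which 38 have suppressors, a GO-slim
#' term map whose mitochondrial-translation term covers 7 bypassable genes,
#' an ortholog table with the 24/31 vs 13/93 dispensability split, and a
#' 20-complex catalog classifying 5/11/4.
#'
#' @param name one of "network", "genes", "terms", "complex_members".
#' @return data.frame.
#' @export
boe_fixture <- function(name = c("network", "genes", "terms",
                                 "complex_members")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("fixture_", name, "_synthetic.tsv"),
                      package = "boescan", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
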