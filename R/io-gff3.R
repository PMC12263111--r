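# GFF3 reading/writing. On disk GFF3 is 1-based inclusive; internally the
# package is 0-based half-open, so start0 = start - 1, end0 = end.
#
# Annotation pipelines differ in how they mark gene biotypes; a "dialect"
# names the attribute that carries it. Ab-initio predictors (Augustus)
# emit only protein-coding genes and usually no biotype attribute at all.

gff3_dialects <- list(
  ensembl  = list(biotype_attr = "biotype"),
  ncbi     = list(biotype_attr = "gene_biotype"),
  augustus = list(biotype_attr = NULL),
  generic  = list(biotype_attr = "biotype")
)

#' Read protein-coding gene models from a GFF3 file
#'
#' Parses gene / mRNA (or transcript) / exon features, keeps only
#' protein-coding genes, and converts coordinates to the package-internal
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param dialect one of `"ensembl"`, `"ncbi"`, `"augustus"`, `"generic"`,
#'   controlling which attribute names the gene biotype. Genes without a
#'   biotype attribute are assumed protein-coding (the ab-initio case).
#' @param species,label identifiers stored on the result.
#' @return an `AnnotationSet`.
#' @export
parse_gff3 <- function(path, dialect = "generic",
                       species = NA_character_, label = NA_character_) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  dia <- gff3_dialects[[match.arg(dialect, names(gff3_dialects))]]
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g, stringsAsFactors = FALSE)
  first_parent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1L]] else NA_character_, "")

  genes <- g[g$type == "gene", , drop = FALSE]
  battr <- dia$biotype_attr
  biotype <- if (!is.null(battr) && battr %in% names(genes))
    as.character(genes[[battr]]) else rep(NA_character_, nrow(genes))
  biotype[is.na(biotype)] <- "protein_coding"
  gene_tab <- data.frame(gene_id = as.character(genes$ID),
                         biotype = biotype, stringsAsFactors = FALSE)
  coding <- gene_tab$gene_id[gene_tab$biotype == "protein_coding"]

  tx <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_gene <- setNames(first_parent(tx$Parent), as.character(tx$ID))
  tx_keep <- names(tx_gene)[tx_gene %in% coding]

  ex <- g[g$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) stop_data("GFF3 has no exon features: ", path)
  # an exon may name several parent transcripts; expand
  np <- lengths(ex$Parent)
  if (any(np == 0L)) stop_data("exon without Parent attribute in ", path)
  idx <- rep(seq_len(nrow(ex)), np)
  parent <- unlist(ex$Parent, use.names = FALSE)
  unknown <- setdiff(unique(parent), names(tx_gene))
  if (length(unknown))
    stop_data("exon with unknown Parent transcript: ",
              paste(head(unknown, 5L), collapse = ", "))
  keep <- parent %in% tx_keep
  exons <- data.frame(
    gene_id = unname(tx_gene[parent[keep]]),
    transcript_id = parent[keep],
    chrom = as.character(ex$seqid[idx[keep]]),
    strand = as.character(ex$strand[idx[keep]]),
    start = as.integer(ex$start[idx[keep]]) - 1L,
    end = as.integer(ex$end[idx[keep]]),
    stringsAsFactors = FALSE)
  if (any(!exons$strand %in% c("+", "-")))
    stop_data("exon with missing strand in ", path)
  chk <- unique(exons[c("transcript_id", "strand")])
  if (anyDuplicated(chk$transcript_id))
    stop_data("mixed strands within a transcript in ", path)
  annotation_set(exons, label = label, species = species,
                 biotypes = gene_tab[gene_tab$gene_id %in% coding, ])
}

#' Write an AnnotationSet to GFF3
#'
#' Emits gene, mRNA and exon features with `ID`/`Parent` linkage and a
#' `biotype=protein_coding` attribute, converting back to 1-based
#' inclusive coordinates, so [parse_gff3()] reproduces the input exactly.
#'
#' @param x an `AnnotationSet`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(x, path) {
  ex <- x$exons
  src <- ifelse(is.na(x$label), "orthoqc", x$label)
  tx <- unique(ex[c("gene_id", "transcript_id", "chrom", "strand")])
  tspan <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(d)
    data.frame(transcript_id = d$transcript_id[1L],
               start = min(d$start), end = max(d$end))))
  tx <- merge(tx, tspan, by = "transcript_id")
  gspan <- do.call(rbind, lapply(split(tx, tx$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               strand = d$strand[1L],
               start = min(d$start), end = max(d$end))))
  fmt <- function(chrom, type, start0, end0, strand, attrs)
    paste(chrom, src, type, start0 + 1L, end0, ".", strand, ".", attrs,
          sep = "\t")
  lines <- c(
    "##gff-version 3",
    fmt(gspan$chrom, "gene", gspan$start, gspan$end, gspan$strand,
        paste0("ID=", gspan$gene_id, ";biotype=protein_coding")),
    fmt(tx$chrom, "mRNA", tx$start, tx$end, tx$strand,
        paste0("ID=", tx$transcript_id, ";Parent=", tx$gene_id)),
    fmt(ex$chrom, "exon", ex$start, ex$end, ex$strand,
        paste0("Parent=", ex$transcript_id)))
  writeLines(lines, path)
  invisible(path)
}
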