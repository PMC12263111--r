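# Internal data model for gene models and proteomes.
#
# Coordinates are 0-based half-open everywhere inside the package;
# conversion to/from the 1-based inclusive GFF3 convention happens only in
# the GFF3 reader/writer. This keeps interval arithmetic (intron chains,
# overlaps, splits) free of off-by-one cases.

#' Construct a transcript model
#'
#' @param id transcript identifier.
#' @param gene_id parent gene identifier.
#' @param chrom chromosome / sequence identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (start, end) of exon intervals in
#'   0-based half-open coordinates. Exons are sorted by start and must be
#'   pairwise non-overlapping.
#' @return an object of class `TranscriptModel`.
#' @export
transcript_model <- function(id, gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop_data("transcript '", id, "' has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] >= exons[, 2L]))
    stop_data("transcript '", id, "' has an empty or inverted exon")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop_data("transcript '", id, "' has overlapping exons")
  if (!strand %in% c("+", "-"))
    stop_data("transcript '", id, "' has invalid strand '", strand, "'")
  structure(list(id = id, gene_id = gene_id, chrom = chrom,
                 strand = strand, exons = exons),
            class = "TranscriptModel")
}

#' Construct an annotation set
#'
#' An annotation set holds the protein-coding gene models of one species
#' from one annotation source, stored as a flat exon table for vectorised
#' processing.
#'
#' @param exons data frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open exon intervals).
#' @param label annotation-source name.
#' @param species species identifier.
#' @param biotypes optional data frame with columns `gene_id`, `biotype`;
#'   defaults to `protein_coding` for every gene.
#' @return an object of class `AnnotationSet`.
#' @export
annotation_set <- function(exons, label = NA_character_,
                           species = NA_character_, biotypes = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop_data("exon table must have columns: ", paste(need, collapse = ", "))
  exons <- exons[need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$start < 0L) || any(exons$start >= exons$end))
    stop_data("exon intervals must satisfy 0 <= start < end")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # one chrom+strand per transcript, one chrom per gene
  chk <- unique(exons[c("transcript_id", "chrom", "strand")])
  if (anyDuplicated(chk$transcript_id))
    stop_data("mixed chrom/strand within a transcript")
  gchk <- unique(exons[c("gene_id", "chrom")])
  if (anyDuplicated(gchk$gene_id))
    stop_data("gene with transcripts on multiple chromosomes")
  tmap <- unique(exons[c("gene_id", "transcript_id")])
  if (anyDuplicated(tmap$transcript_id))
    stop_data("transcript id assigned to multiple genes")
  if (is.null(biotypes)) {
    gid <- unique(exons$gene_id)
    biotypes <- data.frame(gene_id = gid,
                           biotype = rep("protein_coding", length(gid)),
                           stringsAsFactors = FALSE)
  }
  structure(list(label = label, species = species, exons = exons,
                 genes = biotypes),
            class = "AnnotationSet")
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat("AnnotationSet '", x$label, "' (", x$species, "): ",
      length(unique(x$exons$gene_id)), " genes, ",
      length(unique(x$exons$transcript_id)), " transcripts\n", sep = "")
  invisible(x)
}

#' Number of genes in an annotation set
#' @param x an `AnnotationSet`.
#' @return integer gene count.
#' @export
n_genes <- function(x) length(unique(x$exons$gene_id))

# Extract one TranscriptModel from the exon table.
get_transcript <- function(x, transcript_id) {
  rows <- x$exons[x$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop_data("unknown transcript '", transcript_id, "'")
  transcript_model(transcript_id, rows$gene_id[1L], rows$chrom[1L],
                   rows$strand[1L], cbind(rows$start, rows$end))
}

# All transcripts of an annotation set as a list of TranscriptModel.
all_transcripts <- function(x) {
  split_rows <- split(seq_len(nrow(x$exons)), x$exons$transcript_id)
  lapply(split_rows, function(i) {
    rows <- x$exons[i, , drop = FALSE]
    transcript_model(rows$transcript_id[1L], rows$gene_id[1L],
                     rows$chrom[1L], rows$strand[1L],
                     cbind(rows$start, rows$end))
  })
}

#' Construct a proteome
#'
#' @param id character vector of protein identifiers (unique).
#' @param gene_id parent gene identifier per protein.
#' @param species species identifier (single value or per-protein vector).
#' @param sequence amino-acid sequences (letters of the 20 standard amino
#'   acids plus `X` and `*`).
#' @param canonical logical canonical-isoform flags; at most one canonical
#'   protein per gene.
#' @param label annotation-source name.
#' @return a data frame of class `Proteome` with columns `id`, `gene_id`,
#'   `species`, `sequence`, `canonical`.
#' @export
proteome <- function(id, gene_id, species, sequence,
                     canonical = FALSE, label = NA_character_) {
  if (anyDuplicated(id))
    stop_data("duplicate protein ids: ",
              paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(nchar(sequence) == 0L)) stop_data("empty protein sequence")
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", sequence)
  if (any(bad))
    stop_data("invalid amino-acid letters in: ",
              paste(head(id[bad], 5L), collapse = ", "))
  df <- data.frame(id = id, gene_id = gene_id,
                   species = rep_len(species, length(id)),
                   sequence = sequence,
                   canonical = rep_len(canonical, length(id)),
                   stringsAsFactors = FALSE)
  can <- df[df$canonical, ]
  if (anyDuplicated(can$gene_id))
    stop_data("more than one canonical protein for a gene")
  attr(df, "label") <- label
  class(df) <- c("Proteome", "data.frame")
  df
}

#' Protein lengths of a proteome
#'
#' Residue counts excluding a trailing stop symbol `*` if present.
#'
#' @param x a `Proteome`.
#' @param canonical_only count only canonical proteins.
#' @return named integer vector of lengths.
#' @export
protein_lengths <- function(x, canonical_only = FALSE) {
  df <- if (canonical_only) x[x$canonical, , drop = FALSE] else x
  setNames(nchar(sub("\\*$", "", df$sequence)), df$id)
}
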