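# FASTA reading/writing via Biostrings.

#' Read a protein FASTA file into a Proteome
#'
#' The record id is the first whitespace-delimited token of the header.
#' The parent gene id is extracted from the header with `gene_pattern`
#' (first capture group); records whose header does not match fall back to
#' `gene_id = id`, which is appropriate for one-protein-per-gene files
#' such as canonicalized proteomes.
#'
#' @param path FASTA file.
#' @param species species identifier to assign.
#' @param label annotation-source name.
#' @param gene_pattern regular expression with one capture group locating
#'   the gene id in the header; default matches a `gene=<id>` token.
#' @return a `Proteome`; all canonical flags are `FALSE` until
#'   [select_canonical_longest()] is applied.
#' @export
parse_fasta <- function(path, species = NA_character_,
                        label = NA_character_,
                        gene_pattern = "(?:^|\\s)gene=(\\S+)") {
  if (!file.exists(path)) stop_data("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop_data("duplicate FASTA headers: ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(Biostrings::width(aa) == 0L))
    stop_data("empty sequence for: ",
              paste(ids[Biostrings::width(aa) == 0L], collapse = ", "))
  m <- regmatches(headers, regexec(gene_pattern, headers, perl = TRUE))
  gene_id <- vapply(seq_along(m), function(i) {
    if (length(m[[i]]) >= 2L) m[[i]][2L] else ids[i]
  }, "")
  proteome(id = ids, gene_id = gene_id, species = species,
           sequence = as.character(aa), canonical = FALSE, label = label)
}

#' Write a Proteome to FASTA
#'
#' Headers carry the protein id and, when it differs from the id, a
#' `gene=<gene_id>` token that [parse_fasta()] recovers; sequences are
#' written on a single line so the round trip is byte-identical.
#'
#' @param x a `Proteome`.
#' @param path output file.
#' @param canonical_only write only canonical proteins.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, canonical_only = FALSE) {
  df <- if (canonical_only) x[x$canonical, , drop = FALSE] else x
  hdr <- ifelse(df$gene_id == df$id, df$id,
                paste0(df$id, " gene=", df$gene_id))
  writeLines(paste0(">", hdr, "\n", df$sequence), path, sep = "\n")
  invisible(path)
}
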