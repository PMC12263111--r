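# Gene-model agreement between two annotations of the same assembly.
#
# Two transcripts are a "complete match" when they sit on the same chrom
# and strand and have identical intron chains; the outer boundaries of
# the first and last exon are free (annotations rarely agree on UTR
# extent). Mono-exonic transcripts have an empty intron chain, so for a
# mono-exonic pair we additionally require the exons to overlap; a
# mono-exonic transcript never matches a multi-exonic one.

#' Intron chain of a transcript
#'
#' Introns are the gaps between consecutive exons, in 0-based half-open
#' coordinates. A mono-exonic transcript has an empty chain (its span is
#' still recorded).
#'
#' @param transcript a `TranscriptModel`.
#' @return an object of class `IntronChain`: list with `chrom`, `strand`,
#'   `introns` (two-column matrix) and `span` (first exon start, last exon
#'   end).
#' @export
intron_chain <- function(transcript) {
  ex <- transcript$exons
  n <- nrow(ex)
  introns <- if (n > 1L)
    cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
  else
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  structure(list(chrom = transcript$chrom, strand = transcript$strand,
                 introns = introns,
                 span = c(ex[1L, 1L], ex[n, 2L])),
            class = "IntronChain")
}

# String signature of a multi-exonic transcript's intron chain; NA for
# mono-exonic transcripts (their matching needs interval overlap, not
# equality).
chain_signature <- function(chrom, strand, introns) {
  if (nrow(introns) == 0L) return(NA_character_)
  paste(chrom, strand, paste(introns[, 1L], introns[, 2L],
                             sep = "-", collapse = ","), sep = "|")
}

#' Classify the match between two transcript models
#'
#' @param query,ref `TranscriptModel` objects from annotations of the same
#'   assembly.
#' @return `"complete"` or `"no_match"`. The relation is symmetric.
#' @export
classify_match <- function(query, ref) {
  if (query$chrom != ref$chrom || query$strand != ref$strand)
    return("no_match")
  cq <- intron_chain(query); cr <- intron_chain(ref)
  nq <- nrow(cq$introns); nr <- nrow(cr$introns)
  if (nq != nr) return("no_match")
  if (nq == 0L) {
    # mono-exonic pair: any shared base counts
    ok <- cq$span[1L] < cr$span[2L] && cr$span[1L] < cq$span[2L]
    return(if (ok) "complete" else "no_match")
  }
  if (all(cq$introns == cr$introns)) "complete" else "no_match"
}

# Per-annotation transcript summary used by the vectorised matcher.
transcript_table <- function(x) {
  ex <- x$exons
  idx <- split(seq_len(nrow(ex)), ex$transcript_id)
  do.call(rbind, lapply(idx, function(i) {
    rows <- ex[i, , drop = FALSE]
    n <- nrow(rows)
    introns <- if (n > 1L) cbind(rows$end[-n], rows$start[-1L])
               else matrix(integer(), ncol = 2L)
    data.frame(transcript_id = rows$transcript_id[1L],
               gene_id = rows$gene_id[1L],
               chrom = rows$chrom[1L], strand = rows$strand[1L],
               mono = n == 1L,
               sig = chain_signature(rows$chrom[1L], rows$strand[1L],
                                     introns),
               span_start = min(rows$start), span_end = max(rows$end),
               stringsAsFactors = FALSE)
  }))
}

#' Gene-level agreement between two annotations
#'
#' A gene of `A` is *matched* when any of its transcripts is a complete
#' match to any transcript of any gene of `B`, and symmetrically for `B`.
#' One-to-many matches count every gene involved on both sides. The
#' Jaccard index is
#' `ji = (|matched_A| + |matched_B|) / (n_A + n_B)`,
#' the fraction of all genes involved in a complete match; it is 1 when
#' the two annotations agree gene-for-gene and 0 when nothing matches.
#'
#' @param A,B `AnnotationSet` objects describing the same species and
#'   assembly (query and reference respectively).
#' @return an object of class `AgreementStats`: list with `n_query`,
#'   `n_ref`, `matched_query`, `matched_ref` (character vectors of gene
#'   ids) and `ji`.
#' @export
gene_agreement <- function(A, B) {
  nq <- n_genes(A); nr <- n_genes(B)
  if (nq == 0L || nr == 0L) {
    warning("empty annotation set; Jaccard index defined as 0")
    return(structure(list(n_query = nq, n_ref = nr,
                          matched_query = character(),
                          matched_ref = character(), ji = 0),
                     class = "AgreementStats"))
  }
  ta <- transcript_table(A); tb <- transcript_table(B)

  # multi-exonic: exact intron-chain signature equality
  ma <- ta[!ta$mono, , drop = FALSE]; mb <- tb[!tb$mono, , drop = FALSE]
  shared <- intersect(ma$sig, mb$sig)
  genes_a <- unique(ma$gene_id[ma$sig %in% shared])
  genes_b <- unique(mb$gene_id[mb$sig %in% shared])

  # mono-exonic: overlap on the same chrom+strand
  sa <- ta[ta$mono, , drop = FALSE]; sb <- tb[tb$mono, , drop = FALSE]
  if (nrow(sa) && nrow(sb)) {
    key_a <- paste(sa$chrom, sa$strand)
    key_b <- paste(sb$chrom, sb$strand)
    for (key in intersect(key_a, key_b)) {
      da <- sa[key_a == key, , drop = FALSE]
      db <- sb[key_b == key, , drop = FALSE]
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(da$span_start + 1L, da$span_end),
        IRanges::IRanges(db$span_start + 1L, db$span_end))
      genes_a <- union(genes_a, da$gene_id[S4Vectors::queryHits(ov)])
      genes_b <- union(genes_b, db$gene_id[S4Vectors::subjectHits(ov)])
    }
  }
  structure(list(n_query = nq, n_ref = nr,
                 matched_query = sort(genes_a),
                 matched_ref = sort(genes_b),
                 ji = (length(genes_a) + length(genes_b)) / (nq + nr)),
            class = "AgreementStats")
}

#' @export
print.AgreementStats <- function(x, ...) {
  cat(sprintf(
    "AgreementStats: %d/%d query and %d/%d reference genes matched; ji = %.4f\n",
    length(x$matched_query), x$n_query,
    length(x$matched_ref), x$n_ref, x$ji))
  invisible(x)
}

#' Pairwise agreement across annotation methods
#'
#' For every pair of methods sharing a species, [gene_agreement()] is run
#' twice with query and reference roles exchanged and the two Jaccard
#' indexes averaged. (With the symmetric complete-match criterion the two
#' directions coincide; both are still computed and reported.)
#'
#' @param sets list of `AnnotationSet` objects; each must carry its
#'   `label` (method) and `species`.
#' @return list with `per_species` (one row per species and method pair:
#'   `species`, `method_pair`, `n_query`, `n_ref`, `matched_query`,
#'   `matched_ref`, `ji_dir1`, `ji_dir2`, `ji_mean`) and `medians` (per
#'   method pair median of `ji_mean`).
#' @export
pairwise_agreement <- function(sets) {
  lab <- vapply(sets, function(s) s$label, "")
  spc <- vapply(sets, function(s) s$species, "")
  if (anyDuplicated(paste(lab, spc)))
    stop_data("duplicate (method, species) annotation set")
  rows <- list()
  for (sp in unique(spc)) {
    here <- which(spc == sp)
    if (length(here) < 2L) {
      warning("species '", sp, "' present in only one method; skipped")
      next
    }
    here <- here[order(lab[here])]
    for (i in seq_along(here)) for (j in seq_along(here)) {
      if (i >= j) next
      A <- sets[[here[i]]]; B <- sets[[here[j]]]
      d1 <- gene_agreement(A, B)
      d2 <- gene_agreement(B, A)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp,
        method_pair = paste(A$label, B$label, sep = ":"),
        n_query = d1$n_query, n_ref = d1$n_ref,
        matched_query = length(d1$matched_query),
        matched_ref = length(d1$matched_ref),
        ji_dir1 = d1$ji, ji_dir2 = d2$ji,
        ji_mean = (d1$ji + d2$ji) / 2,
        stringsAsFactors = FALSE)
    }
  }
  per_species <- do.call(rbind, rows) %||%
    data.frame(species = character(), method_pair = character())
  medians <- if (nrow(per_species)) {
    agg <- aggregate(ji_mean ~ method_pair, per_species, median)
    names(agg)[2L] <- "median_ji"
    agg
  } else data.frame(method_pair = character(), median_ji = numeric())
  list(per_species = per_species, medians = medians)
}
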