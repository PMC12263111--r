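# Ortholog proportions, canonical-isoform selection and HOG quality
# metrics (counts, sizes, completeness, phyletic patterns).

#' Flag the longest isoform of each gene as canonical
#'
#' Per gene, the longest protein becomes the canonical isoform; length
#' ties break to the lexicographically smallest protein id. Genes not
#' listed in the splice map keep their proteins grouped by the proteome's
#' own `gene_id` column (a gene with a single protein keeps it as
#' canonical).
#'
#' @param proteome a `Proteome`.
#' @param splice optional `SpliceMap` from [parse_splice()]; when given,
#'   its isoform lists override the proteome's gene grouping.
#' @return the proteome with updated `gene_id` (if a splice map was used)
#'   and exactly one canonical protein per gene.
#' @export
select_canonical_longest <- function(proteome, splice = NULL) {
  if (!is.null(splice)) {
    unknown <- setdiff(unlist(splice), proteome$id)
    if (length(unknown))
      stop_data("splice isoforms absent from proteome: ",
                paste(head(unknown, 5L), collapse = ", "))
    for (g in names(splice))
      proteome$gene_id[proteome$id %in% splice[[g]]] <- g
  }
  len <- protein_lengths(proteome)
  ord <- order(proteome$gene_id, -len, proteome$id)
  first <- !duplicated(proteome$gene_id[ord])
  canonical <- logical(nrow(proteome))
  canonical[ord[first]] <- TRUE
  proteome$canonical <- canonical
  if (any(tapply(canonical, proteome$gene_id, sum) != 1L))
    stop_data("gene left without a canonical isoform")
  proteome
}

#' Proportion of canonical proteins with at least one ortholog
#'
#' The denominator is the canonical proteins of the proteome ("one gene,
#' one protein"); the numerator counts those appearing in at least one
#' ortholog pair. Canonical proteins in no pair are the proteome's
#' singletons.
#'
#' @param proteome a canonicalized `Proteome` (one species).
#' @param pairs an `OrthologPairs` set. Every pair id that belongs to this
#'   proteome's species must resolve to a canonical protein; ids of other
#'   species are ignored (declare them via `other_ids` to enable full
#'   validation).
#' @param other_ids protein ids of the other species' proteomes; when
#'   given, pair ids resolving to neither side raise an error.
#' @return an object of class `OrthologProportion`: list with `species`,
#'   `n_canonical`, `n_with_ortholog`, `proportion` and `singletons`.
#' @export
ortholog_proportion <- function(proteome, pairs, other_ids = NULL) {
  can <- proteome$id[proteome$canonical]
  if (length(can) == 0L) stop_data("proteome has no canonical proteins")
  pair_ids <- unique(c(pairs$id1, pairs$id2))
  own <- pair_ids[pair_ids %in% proteome$id]
  bad <- setdiff(own, can)
  if (length(bad))
    stop_data("pair ids are non-canonical proteins: ",
              paste(head(bad, 5L), collapse = ", "))
  if (!is.null(other_ids)) {
    unknown <- setdiff(pair_ids, c(proteome$id, other_ids))
    if (length(unknown))
      stop_data("pair ids not found in any proteome: ",
                paste(head(unknown, 5L), collapse = ", "))
  }
  with_orth <- intersect(can, pair_ids)
  structure(list(species = proteome$species[1L],
                 n_canonical = length(can),
                 n_with_ortholog = length(with_orth),
                 proportion = length(with_orth) / length(can),
                 singletons = sort(setdiff(can, with_orth))),
            class = "OrthologProportion")
}

#' Ortholog proportions for a set of proteomes
#'
#' Validates that every pair id resolves to a canonical protein of one of
#' the proteomes, then computes [ortholog_proportion()] per species.
#'
#' @param proteomes named list of canonicalized `Proteome` objects.
#' @param pairs an `OrthologPairs` set.
#' @return data frame with one row per species (`species`, `n_canonical`,
#'   `n_with_ortholog`, `proportion`); the per-species
#'   `OrthologProportion` objects are attached as attribute `"details"`.
#' @export
ortholog_proportions <- function(proteomes, pairs) {
  all_ids <- unlist(lapply(proteomes, `[[`, "id"), use.names = FALSE)
  res <- lapply(proteomes, function(p)
    ortholog_proportion(p, pairs, other_ids = setdiff(all_ids, p$id)))
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(species = r$species, n_canonical = r$n_canonical,
               n_with_ortholog = r$n_with_ortholog,
               proportion = r$proportion, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "details") <- res
  df
}

#' rootHOG counts and size distribution
#'
#' The size of a rootHOG is its total member (gene) count across species;
#' within-species duplicates contribute their copy number.
#'
#' @param hogs a `HOGCollection`.
#' @return list with `n_roothogs`, `sizes` (integer vector, one per
#'   rootHOG) and `size_distribution` (table of sizes).
#' @export
hog_sizes <- function(hogs) {
  sizes <- as.integer(rowSums(hogs$profile))
  names(sizes) <- rownames(hogs$profile)
  list(n_roothogs = length(sizes), sizes = sizes,
       size_distribution = table(sizes))
}

#' Completeness of a HOG at its taxonomic level
#'
#' The fraction of the level clade's species represented by at least one
#' gene in the HOG.
#'
#' @param hog a HOG node (element of `HOGCollection$roothogs`) or a named
#'   copy-count vector together with `level`.
#' @param tree the species tree ([parse_newick()]).
#' @param level clade label; defaults to the HOG's own level.
#' @return completeness ratio in `(0, 1]`.
#' @export
hog_completeness <- function(hog, tree, level = NULL) {
  if (is.list(hog) && !is.null(hog$members)) {
    present <- unique(hog$members$species)
    level <- level %||% hog$level
  } else {
    present <- names(hog)[hog >= 1L]
  }
  if (is.null(level) || is.na(level))
    stop_data("HOG has no taxonomic level")
  clade <- clade_species(tree, level)
  outside <- setdiff(present, clade)
  if (length(outside))
    stop_data("HOG members outside its level clade: ",
              paste(outside, collapse = ", "))
  length(intersect(present, clade)) / length(clade)
}

#' Completeness of every rootHOG in a collection
#'
#' @param hogs a `HOGCollection` whose rootHOGs carry levels.
#' @param tree the species tree.
#' @return named numeric vector of completeness ratios.
#' @export
hog_completeness_all <- function(hogs, tree) {
  vapply(hogs$roothogs, function(h) hog_completeness(h, tree),
         numeric(1L)) |>
    setNames(vapply(hogs$roothogs, `[[`, "", "id"))
}

#' Define a phyletic pattern
#'
#' @param ... named expected copy counts, e.g. `spA = 2, spB = 0`; use the
#'   wildcard `"*"` for "any count".
#' @param others default for unnamed species: a count, or `"*"` (default).
#' @param species optional full species vector to expand `others` over.
#' @return a named vector of class `PhyleticPattern` (`NA` = wildcard).
#' @export
phyletic_pattern <- function(..., others = "*", species = NULL) {
  given <- c(...)
  pat <- if (!is.null(species)) {
    base <- rep(if (identical(others, "*")) NA_integer_
                else as.integer(others), length(species))
    names(base) <- species
    base
  } else setNames(integer(0), character(0))
  for (nm in names(given)) {
    v <- given[[nm]]
    pat[nm] <- if (identical(v, "*")) NA_integer_ else as.integer(v)
  }
  structure(pat, class = "PhyleticPattern")
}

#' Count rootHOGs matching a phyletic pattern
#'
#' A rootHOG matches when its profile equals the pattern exactly on every
#' non-wildcard species; species absent from a HOG count as 0 copies.
#'
#' @param hogs a `HOGCollection`.
#' @param pattern a `PhyleticPattern` (named vector; `NA` = wildcard).
#' @return integer count.
#' @export
count_pattern <- function(hogs, pattern) {
  unknown <- setdiff(names(pattern), hogs$species)
  if (length(unknown))
    stop_data("pattern species not in the dataset: ",
              paste(unknown, collapse = ", "))
  fixed <- names(pattern)[!is.na(pattern)]
  if (length(fixed) == 0L) return(nrow(hogs$profile))
  sub <- hogs$profile[, fixed, drop = FALSE]
  target <- matrix(unclass(pattern)[fixed], nrow = nrow(sub),
                   ncol = length(fixed), byrow = TRUE)
  sum(rowSums(sub == target) == length(fixed))
}
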