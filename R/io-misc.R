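# Newick species trees, OMA-style .splice files, pairwise-ortholog TSVs
# and phyletic-profile TSVs.

#' Read a rooted, node-labeled species tree
#'
#' Leaf labels are species identifiers; internal labels name clades
#' (taxonomic levels). Unlabeled internal nodes get deterministic
#' auto-labels `node1`, `node2`, ... (preorder) with a warning, so
#' taxonomy-derived trees without full labeling still load.
#'
#' @param path a Newick file, or a Newick string ending in `";"`.
#' @return an [ape::phylo] tree with unique leaf and internal labels.
#' @export
parse_newick <- function(path) {
  tree <- if (grepl(";\\s*$", path) && !file.exists(path))
    ape::read.tree(text = path)
  else if (file.exists(path)) ape::read.tree(path)
  else stop_data("no such file: ", path)
  if (is.null(tree)) stop_data("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop_data("duplicate leaf labels: ",
              paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                    collapse = ", "))
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  missing <- is.na(lab) | lab == ""
  if (any(missing)) {
    warning(sum(missing), " unlabeled internal node(s) auto-labeled")
    lab[missing] <- paste0("node", which(missing))
  }
  if (anyDuplicated(lab)) stop_data("duplicate internal node labels")
  tree$node.label <- lab
  tree
}

#' Species below a named clade of a species tree
#'
#' @param tree a species tree from [parse_newick()].
#' @param label an internal node (clade) label, or a leaf label (then the
#'   single species is returned).
#' @return character vector of species identifiers in the clade.
#' @export
clade_species <- function(tree, label) {
  if (label %in% tree$tip.label) return(label)
  i <- match(label, tree$node.label)
  if (is.na(i)) stop_data("no clade labeled '", label, "' in species tree")
  node <- length(tree$tip.label) + i
  ape::extract.clade(tree, node)$tip.label
}

# Label of the most recent common ancestor clade of a species set.
mrca_label <- function(tree, species) {
  species <- unique(species)
  if (length(species) == 1L) return(species)
  node <- ape::getMRCA(tree, species)
  tree$node.label[node - length(tree$tip.label)]
}

#' Read an OMA-style .splice isoform map
#'
#' One gene per line, isoform protein ids separated by `delim`. Entries
#' are named by gene id: taken from the proteome when given, otherwise the
#' longest common prefix of the isoform ids (trimmed of trailing
#' separators) with a line-number fallback.
#'
#' @param path text file.
#' @param delim isoform delimiter (default `";"`).
#' @param proteome optional `Proteome` used to resolve and validate gene
#'   ids (every listed isoform must exist; lists must be disjoint).
#' @return named list of character vectors (class `SpliceMap`).
#' @export
parse_splice <- function(path, delim = ";", proteome = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  iso <- lapply(strsplit(lines, delim, fixed = TRUE), trimws)
  all_ids <- unlist(iso)
  if (anyDuplicated(all_ids))
    stop_data("isoform listed under more than one gene: ",
              paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  common_prefix <- function(v) {
    if (length(v) == 1L) return(v)
    chars <- strsplit(v, "")
    n <- min(lengths(chars))
    k <- 0L
    while (k < n && length(unique(vapply(chars, `[[`, "", k + 1L))) == 1L)
      k <- k + 1L
    sub("[._-]+$", "", substr(v[1L], 1L, k))
  }
  if (!is.null(proteome)) {
    unknown <- setdiff(all_ids, proteome$id)
    if (length(unknown))
      stop_data("splice isoforms absent from proteome: ",
                paste(head(unknown, 5L), collapse = ", "))
    nm <- vapply(iso, function(v)
      unique(proteome$gene_id[match(v, proteome$id)])[1L], "")
  } else {
    nm <- vapply(iso, common_prefix, "")
    nm[!nzchar(nm)] <- paste0("gene", which(!nzchar(nm)))
  }
  structure(setNames(iso, nm), class = "SpliceMap")
}

#' Construct a set of pairwise orthologs
#'
#' Pairs are unordered, deduplicated, and stored with `id1 < id2`;
#' self-pairs are rejected.
#'
#' @param id1,id2 character vectors of protein identifiers.
#' @return a data frame of class `OrthologPairs` with columns `id1`, `id2`.
#' @export
ortholog_pairs <- function(id1 = character(), id2 = character()) {
  if (any(id1 == id2)) stop_data("self-pair in ortholog pairs")
  a <- pmin(id1, id2); b <- pmax(id1, id2)
  df <- unique(data.frame(id1 = a, id2 = b, stringsAsFactors = FALSE))
  df <- df[order(df$id1, df$id2), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("OrthologPairs", "data.frame")
  df
}

#' Read a pairwise-ortholog TSV
#'
#' Expects two protein-id columns (further columns ignored); the column
#' positions are configurable because pairwise-ortholog exports differ
#' between tools. Reading a file concatenated with itself yields the same
#' set (set semantics).
#'
#' @param path TSV file; lines starting with `#` are skipped.
#' @param id_cols integer positions of the two id columns.
#' @param species_of optional named character vector mapping protein id to
#'   species; when given, within-species pairs raise an error naming the
#'   offending line.
#' @return an `OrthologPairs` set.
#' @export
parse_pairwise <- function(path, id_cols = c(1L, 2L), species_of = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) return(ortholog_pairs())
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (any(lengths(fields) < max(id_cols)))
    stop_data("line with fewer than ", max(id_cols), " columns")
  a <- vapply(fields, `[[`, "", id_cols[1L])
  b <- vapply(fields, `[[`, "", id_cols[2L])
  if (!is.null(species_of)) {
    same <- !is.na(species_of[a]) & !is.na(species_of[b]) &
      species_of[a] == species_of[b]
    if (any(same))
      stop_data("within-species pair at line ",
                paste(which(keep)[same], collapse = ", "))
  }
  ortholog_pairs(a, b)
}

#' Write pairwise orthologs to TSV
#' @param pairs an `OrthologPairs` set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pairwise <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a phyletic-profile TSV into a profile-only HOG collection
#'
#' Header row: a HOG-id column followed by one column per species; cells
#' are gene copy counts. The resulting collection has profiles but no
#' nested group structure (empty membership), which suffices for
#' pattern-count and size metrics based on profiles.
#'
#' @param path TSV file with header.
#' @return a `HOGCollection` whose `roothogs` carry ids only.
#' @export
parse_profile_tsv <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_data("profile TSV needs id + species columns")
  ids <- as.character(tab[[1L]])
  species <- colnames(tab)[-1L]
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stop_data("negative copy count in profile TSV")
  roothogs <- lapply(seq_along(ids), function(i)
    hog_node(ids[i], NA_character_, "ortholog",
             data.frame(id = character(), species = character())))
  out <- hog_collection(roothogs, species = species)
  out$profile <- counts
  rownames(out$profile) <- ids
  out
}

#' Write the phyletic profile of a HOG collection to TSV
#' @param hogs a `HOGCollection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(hogs, path) {
  df <- data.frame(HOG = rownames(hogs$profile), hogs$profile,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
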