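# Hierarchical orthologous groups (HOGs) and OrthoXML I/O.
#
# A HOG node is a plain list: id, level (taxonomic-range label; NA for
# paralog nodes), type ("ortholog" or "paralog"), members (data frame of
# protein id + species for every extant gene below the node) and children
# (list of nested HOG nodes). A HOGCollection holds the root-level HOGs
# plus the per-rootHOG phyletic profile (species x copy-count matrix).

hog_node <- function(id, level, type, members, children = list()) {
  list(id = id, level = level, type = type,
       members = members, children = children)
}

#' Assemble a HOG collection
#'
#' @param roothogs list of root-level HOG nodes.
#' @param species optional character vector fixing the species (profile
#'   columns); defaults to the species observed in the members.
#' @return an object of class `HOGCollection` with elements `roothogs`,
#'   `species` and `profile` (integer matrix, one row per rootHOG).
#' @export
hog_collection <- function(roothogs, species = NULL) {
  if (is.null(species))
    species <- sort(unique(unlist(lapply(roothogs,
                                         function(h) h$members$species))))
  profile <- matrix(0L, nrow = length(roothogs), ncol = length(species),
                    dimnames = list(vapply(roothogs, `[[`, "", "id"),
                                    species))
  for (i in seq_along(roothogs)) {
    tab <- table(roothogs[[i]]$members$species)
    profile[i, names(tab)] <- as.integer(tab)
  }
  structure(list(roothogs = roothogs, species = species, profile = profile),
            class = "HOGCollection")
}

#' @export
print.HOGCollection <- function(x, ...) {
  cat("HOGCollection:", length(x$roothogs), "rootHOGs over",
      length(x$species), "species\n")
  invisible(x)
}

#' Read hierarchical orthologous groups from OrthoXML
#'
#' Supports the standard nesting of `orthologGroup` / `paralogGroup`
#' elements with `geneRef` members and a `TaxRange` property giving the
#' taxonomic level of each ortholog group.
#'
#' @param path OrthoXML file.
#' @return a `HOGCollection`.
#' @export
parse_orthoxml <- function(path) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(o = xml2::xml_ns(doc)[[1]])
  gene_nodes <- xml2::xml_find_all(doc, ".//o:species//o:gene", ns)
  sp_of_gene <- xml2::xml_attr(
    xml2::xml_find_first(gene_nodes, "ancestor::o:species", ns), "name")
  gid <- xml2::xml_attr(gene_nodes, "id")
  prot <- xml2::xml_attr(gene_nodes, "protId")
  if (anyDuplicated(gid)) stop_data("duplicate gene ids in OrthoXML")
  lut <- data.frame(gid = gid, prot = prot, species = sp_of_gene,
                    stringsAsFactors = FALSE)
  rownames(lut) <- lut$gid

  counter <- new.env(); counter$k <- 0L
  parse_group <- function(node, type) {
    id <- xml2::xml_attr(node, "id")
    if (is.na(id)) {
      counter$k <- counter$k + 1L
      id <- sprintf("HOG:%04d", counter$k)
    }
    level <- NA_character_
    kids <- xml2::xml_children(node)
    children <- list()
    members <- list()
    for (k in kids) {
      nm <- xml2::xml_name(k)
      if (nm == "property") {
        if (identical(xml2::xml_attr(k, "name"), "TaxRange"))
          level <- xml2::xml_attr(k, "value")
      } else if (nm == "geneRef") {
        ref <- xml2::xml_attr(k, "id")
        if (!ref %in% lut$gid)
          stop_data("geneRef to unknown gene id '", ref, "'")
        members[[length(members) + 1L]] <-
          data.frame(id = lut[ref, "prot"], species = lut[ref, "species"],
                     stringsAsFactors = FALSE)
      } else if (nm %in% c("orthologGroup", "paralogGroup")) {
        child <- parse_group(k, if (nm == "orthologGroup") "ortholog"
                                else "paralog")
        children[[length(children) + 1L]] <- child
        members[[length(members) + 1L]] <- child$members
      }
    }
    hog_node(id, level, type,
             do.call(rbind, members) %||%
               data.frame(id = character(), species = character()),
             children)
  }
  groups <- xml2::xml_find_all(doc, "./o:groups/o:orthologGroup", ns)
  hog_collection(lapply(groups, parse_group, type = "ortholog"))
}

#' Write a HOG collection to OrthoXML
#'
#' Inverse of [parse_orthoxml()]: emits per-species gene cross-references
#' and the nested `orthologGroup`/`paralogGroup` structure with `TaxRange`
#' properties. Profiles and membership survive the round trip unchanged.
#'
#' @param hogs a `HOGCollection`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_orthoxml <- function(hogs, path) {
  members <- unique(do.call(rbind, lapply(hogs$roothogs, `[[`, "members")))
  members <- members[order(members$species, members$id), , drop = FALSE]
  gid <- setNames(as.character(seq_len(nrow(members))), members$id)

  doc <- xml2::xml_new_root(
    "orthoXML", xmlns = "http://orthoXML.org/2011/", version = "0.3",
    origin = "orthoqc", originVersion = "0.1.0")
  for (sp in unique(members$species)) {
    spn <- xml2::xml_add_child(doc, "species", name = sp, NCBITaxId = "0")
    db <- xml2::xml_add_child(spn, "database", name = "orthoqc",
                              version = "0")
    gn <- xml2::xml_add_child(db, "genes")
    rows <- members[members$species == sp, , drop = FALSE]
    for (i in seq_len(nrow(rows)))
      xml2::xml_add_child(gn, "gene", id = gid[[rows$id[i]]],
                          protId = rows$id[i])
  }
  grp <- xml2::xml_add_child(doc, "groups")
  emit <- function(parent, node) {
    el <- xml2::xml_add_child(
      parent,
      if (node$type == "paralog") "paralogGroup" else "orthologGroup",
      id = node$id)
    if (!is.na(node$level))
      xml2::xml_add_child(el, "property", name = "TaxRange",
                          value = node$level)
    child_members <- unlist(lapply(node$children,
                                   function(c) c$members$id))
    own <- setdiff(node$members$id, child_members)
    for (m in own) xml2::xml_add_child(el, "geneRef", id = gid[[m]])
    for (c in node$children) emit(el, c)
  }
  for (h in hogs$roothogs) emit(grp, h)
  xml2::write_xml(doc, path)
  invisible(path)
}
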