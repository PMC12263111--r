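# Gene-family simulator with ground-truth orthology.
#
# Families are born as single genes at the species-tree root and evolve
# down the tree: along every branch each extant copy duplicates as a
# Poisson process (birth rate) and is killed by a loss process (death
# rate), both per unit branch length; optional whole-genome duplications
# double every surviving copy at the stem of a named clade, the extra
# copy retained with a stated probability. Speciation nodes copy all
# lineages into both children. Two extant genes are true orthologs iff
# the last common ancestor in their family tree is a speciation node.
#
# Sequences evolve root-to-tip by i.i.d. site substitutions with lengths
# preserved, so any length signal in the perturbed data comes from the
# perturbation operators alone. Each (family|gene|operation) has its own
# RNG substream: adding families never changes existing ones, and raising
# a perturbation probability only grows the affected gene set.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default species tree for simulations
#'
#' A random rooted binary tree with leaves `sp01..spNN`, internal nodes
#' labeled `clade<k>` (root included), and edge lengths drawn uniformly
#' on `[0.1, 1]` then rescaled so the deepest leaf sits at depth 1. The
#' lower bound keeps internal edges long enough to carry phylogenetic
#' signal at desk-scale sequence lengths.
#'
#' @param n_species number of leaves.
#' @param seed RNG seed (its own substream; independent of family seeds).
#' @return an [ape::phylo] tree with branch lengths and node labels.
#' @export
default_species_tree <- function(n_species = 20L, seed = 1L) {
  with_seed(substream_seed(seed, "speciestree"), {
    tr <- ape::rtree(n_species)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth
    tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
    tr$node.label <- paste0("clade", seq_len(tr$Nnode))
    tr
  })
}

#' Simulation configuration
#'
#' @param species_tree rooted species tree with branch lengths and node
#'   labels; default [default_species_tree()] on `n_species` leaves.
#' @param n_species leaf count for the default tree.
#' @param n_families number of gene families.
#' @param birth_rate gene duplication rate per copy per unit branch
#'   length.
#' @param death_rate gene loss rate per copy per unit branch length.
#' @param wgd_events named numeric vector: clade (or species) label ->
#'   retention probability; a whole-genome duplication is placed on the
#'   branch entering that node.
#' @param root_length_median,root_length_sigma discretized lognormal
#'   parameters of the family root protein length (amino acids).
#' @param substitution_rate amino-acid substitutions per site per unit
#'   branch length.
#' @param miss_prob probability that a true gene is missed entirely by
#'   the perturbed annotation.
#' @param frag_prob probability that a true gene model is fragmented.
#' @param n_fragments number of fragments a fragmented gene is split
#'   into (cut points uniform on interior residues).
#' @param spurious_rate expected spurious gene models per true gene.
#' @param spurious_length_median,spurious_length_sigma lognormal
#'   parameters of spurious protein lengths (short by default).
#' @param boundary_jitter maximal absolute shift (bp) applied to the
#'   outer boundaries of terminal exons of kept gene models.
#' @param overlap_threshold tau in (0, 1]: a fragment keeps its parent's
#'   ortholog pairs iff its length is at least tau times the parent
#'   length (annotation-sensitive inference emulation).
#' @param seed global RNG seed; all substreams derive from it.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(species_tree = NULL, n_species = 20L,
                              n_families = 100L,
                              birth_rate = 0.1, death_rate = 0.1,
                              wgd_events = numeric(),
                              root_length_median = 300,
                              root_length_sigma = 0.4,
                              substitution_rate = 0.3,
                              miss_prob = 0, frag_prob = 0,
                              n_fragments = 2L,
                              spurious_rate = 0,
                              spurious_length_median = 120,
                              spurious_length_sigma = 0.5,
                              boundary_jitter = 0L,
                              overlap_threshold = 0.6,
                              seed = 1L) {
  if (birth_rate < 0 || death_rate < 0) stop_data("rates must be >= 0")
  probs <- c(miss_prob, frag_prob, spurious_rate = NULL)
  if (any(c(miss_prob, frag_prob) < 0 | c(miss_prob, frag_prob) > 1))
    stop_data("probabilities must lie in [0, 1]")
  if (any(wgd_events < 0 | wgd_events > 1))
    stop_data("WGD retention probabilities must lie in [0, 1]")
  if (overlap_threshold <= 0 || overlap_threshold > 1)
    stop_data("overlap_threshold must lie in (0, 1]")
  if (n_fragments < 2L) stop_data("n_fragments must be >= 2")
  if (is.null(species_tree))
    species_tree <- default_species_tree(n_species, seed)
  if (is.null(species_tree$edge.length))
    stop_data("species tree needs branch lengths")
  if (is.null(species_tree$node.label))
    stop_data("species tree needs internal node labels")
  structure(list(species_tree = species_tree,
                 n_families = as.integer(n_families),
                 birth_rate = birth_rate, death_rate = death_rate,
                 wgd_events = wgd_events,
                 root_length_median = root_length_median,
                 root_length_sigma = root_length_sigma,
                 substitution_rate = substitution_rate,
                 miss_prob = miss_prob, frag_prob = frag_prob,
                 n_fragments = as.integer(n_fragments),
                 spurious_rate = spurious_rate,
                 spurious_length_median = spurious_length_median,
                 spurious_length_sigma = spurious_length_sigma,
                 boundary_jitter = as.integer(boundary_jitter),
                 overlap_threshold = overlap_threshold,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# ---- family birth-death simulation -----------------------------------

node_label_of <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node]
  else tree$node.label[node - ntip]
}

# Simulate one family down the species tree; returns the family-tree root
# node (list) or NULL if the family went extinct.
sim_family_tree <- function(tree, cfg, fam_label, counter) {
  ntip <- length(tree$tip.label)
  kids_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen_of <- setNames(tree$edge.length, tree$edge[, 2L])
  b <- cfg$birth_rate; d <- cfg$death_rate

  new_gene <- function(tip, t) {
    counter$k <- counter$k + 1L
    list(type = "extant",
         species = tree$tip.label[tip],
         gene_id = sprintf("%s_%s_g%03d", tree$tip.label[tip],
                           fam_label, counter$k),
         t = t, children = list())
  }

  at_node <- function(node, t) {
    if (node <= ntip) return(new_gene(node, t))
    subs <- list()
    for (child in kids_of[[as.character(node)]]) {
      s <- into_branch(child, t)
      if (!is.null(s)) subs[[length(subs) + 1L]] <- s
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) return(subs[[1L]])
    list(type = "speciation", clade = node_label_of(tree, node),
         t = t, children = subs)
  }

  lineage <- function(child, t, rem) {
    rate <- b + d
    dt <- if (rate > 0) rexp(1L, rate) else Inf
    if (dt >= rem) return(at_node(child, t + rem))
    t2 <- t + dt
    if (runif(1L) < d / rate) return(NULL)  # loss
    c1 <- lineage(child, t2, rem - dt)
    c2 <- lineage(child, t2, rem - dt)
    alive <- Filter(Negate(is.null), list(c1, c2))
    if (length(alive) == 0L) return(NULL)
    if (length(alive) == 1L) return(alive[[1L]])
    list(type = "duplication", t = t2, children = alive)
  }

  into_branch <- function(child, t0) {
    rem <- elen_of[[as.character(child)]]
    lab <- node_label_of(tree, child)
    ret <- cfg$wgd_events[lab]
    if (length(ret) == 1L && !is.na(ret)) {
      # WGD at this clade's stem: original plus a retained extra copy
      keep_extra <- runif(1L) < ret
      c1 <- lineage(child, t0, rem)
      c2 <- if (keep_extra) lineage(child, t0, rem) else NULL
      alive <- Filter(Negate(is.null), list(c1, c2))
      if (length(alive) == 0L) return(NULL)
      if (length(alive) == 1L) return(alive[[1L]])
      return(list(type = "duplication", t = t0, children = alive))
    }
    lineage(child, t0, rem)
  }

  at_node(ntip + 1L, 0)
}

extant_below <- function(node) {
  if (node$type == "extant")
    return(data.frame(id = node$gene_id, species = node$species,
                      t = node$t, stringsAsFactors = FALSE))
  do.call(rbind, lapply(node$children, extant_below))
}

#' Simulate gene families along the species tree
#'
#' Families that go fully extinct are regenerated from a fresh substream
#' (up to 50 attempts each, then an error), so the configured family
#' count is always delivered.
#'
#' @param config a `SimulationConfig`.
#' @return an object of class `SimulatedTruth`: list with `config`,
#'   `species_tree`, `families` (named list of family trees) and `genes`
#'   (data frame: `gene_id`, `species`, `family`).
#' @export
simulate_families <- function(config) {
  tree <- config$species_tree
  families <- vector("list", config$n_families)
  names(families) <- sprintf("f%03d", seq_len(config$n_families))
  for (i in seq_len(config$n_families)) {
    fam <- names(families)[i]
    root <- NULL
    for (attempt in seq_len(50L)) {
      counter <- new.env(); counter$k <- 0L
      root <- with_seed(substream_seed(config$seed, "family", fam, attempt),
                        sim_family_tree(tree, config, fam, counter))
      if (!is.null(root)) break
    }
    if (is.null(root))
      stop_data("family ", fam, " went extinct in 50 attempts; ",
                "lower the death rate")
    families[[i]] <- root
  }
  genes <- do.call(rbind, lapply(names(families), function(fam) {
    df <- extant_below(families[[fam]])
    df$family <- fam
    df
  }))
  names(genes)[names(genes) == "id"] <- "gene_id"
  genes$t <- NULL
  rownames(genes) <- NULL
  structure(list(config = config, species_tree = tree,
                 families = families, genes = genes),
            class = "SimulatedTruth")
}

#' @export
print.SimulatedTruth <- function(x, ...) {
  cat("SimulatedTruth:", length(x$families), "families,",
      nrow(x$genes), "extant genes in",
      length(unique(x$genes$species)), "species\n")
  invisible(x)
}

# ---- ground-truth orthology ------------------------------------------

#' Ground-truth ortholog pairs and HOGs of a simulation
#'
#' Pairs are all cross-species extant gene pairs whose family-tree last
#' common ancestor is a speciation node. HOGs mirror the family trees:
#' speciation nodes become nested ortholog groups labeled with the
#' species-tree clade where they occurred, duplication nodes become
#' paralog splits. Single-gene families yield no HOG. The level of a
#' duplication-rooted HOG is the MRCA clade of its member species.
#'
#' @param truth a `SimulatedTruth`.
#' @return list with `pairs` (`OrthologPairs`) and `hogs`
#'   (`HOGCollection` over all species of the tree).
#' @export
true_orthology <- function(truth) {
  tree <- truth$species_tree
  pair_acc <- list()
  collect_pairs <- function(node) {
    if (node$type == "extant")
      return(extant_below(node))
    leaves <- lapply(node$children, collect_pairs)
    if (node$type == "speciation") {
      for (i in seq_along(leaves)) for (j in seq_along(leaves)) {
        if (i >= j) next
        a <- leaves[[i]]; b <- leaves[[j]]
        grid <- expand.grid(x = seq_len(nrow(a)), y = seq_len(nrow(b)))
        keep <- a$species[grid$x] != b$species[grid$y]
        if (any(keep))
          pair_acc[[length(pair_acc) + 1L]] <<-
            data.frame(id1 = a$id[grid$x[keep]],
                       id2 = b$id[grid$y[keep]],
                       stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, leaves)
  }

  hogs <- list()
  conv <- function(node, id) {
    members <- extant_below(node)[c("id", "species")]
    internal_children <- Filter(function(c) c$type != "extant",
                                node$children)
    children <- lapply(seq_along(internal_children), function(k)
      conv(internal_children[[k]], paste0(id, ".", k)))
    level <- if (node$type == "speciation") node$clade else NA_character_
    hog_node(id, level,
             if (node$type == "speciation") "ortholog" else "paralog",
             members, children)
  }
  for (fam in names(truth$families)) {
    root <- truth$families[[fam]]
    if (root$type == "extant") next
    h <- conv(root, sprintf("HOG:%s", fam))
    if (is.na(h$level))
      h$level <- mrca_label(tree, h$members$species)
    hogs[[length(hogs) + 1L]] <- h
  }
  for (fam in names(truth$families)) collect_pairs(truth$families[[fam]])
  pairs <- if (length(pair_acc))
    ortholog_pairs(unlist(lapply(pair_acc, `[[`, "id1")),
                   unlist(lapply(pair_acc, `[[`, "id2")))
  else ortholog_pairs()
  list(pairs = pairs,
       hogs = hog_collection(hogs, species = tree$tip.label))
}

# ---- sequences and toy gene models -----------------------------------

mutate_seq <- function(aa_vec, dt, rate) {
  if (rate <= 0 || dt <= 0) return(aa_vec)
  p <- 1 - exp(-rate * dt)
  hit <- which(runif(length(aa_vec)) < p)
  for (i in hit) aa_vec[i] <- sample(setdiff(AA20, aa_vec[i]), 1L)
  aa_vec
}

# Deterministic toy gene model: k near-equal exons separated by 200 bp
# introns; genes placed left to right with 1 kb gaps on one chromosome.
make_gene_models <- function(gene_ids, aa_lengths, species, label) {
  offset <- 0L
  rows <- list()
  for (i in seq_along(gene_ids)) {
    cds <- 3L * aa_lengths[i]
    k <- min(10L, 1L + aa_lengths[i] %/% 150L)
    base <- cds %/% k
    lens <- rep(base, k) + c(rep(1L, cds %% k), rep(0L, k - cds %% k))
    starts <- offset + cumsum(c(0L, head(lens, -1L) + 200L))
    rows[[i]] <- data.frame(
      gene_id = gene_ids[i],
      transcript_id = paste0(gene_ids[i], ".t1"),
      chrom = "chr1", strand = "+",
      start = starts, end = starts + lens,
      stringsAsFactors = FALSE)
    offset <- max(rows[[i]]$end) + 1000L
  }
  annotation_set(do.call(rbind, rows) %||%
                   data.frame(gene_id = character(),
                              transcript_id = character(),
                              chrom = character(), strand = character(),
                              start = integer(), end = integer()),
                 label = label, species = species)
}

#' Evolve protein sequences and toy gene models for a simulation
#'
#' Each family draws a root length from a discretized lognormal and a
#' uniform-random root sequence, then substitutes sites independently
#' down the family tree at the configured rate (lengths are preserved, so
#' length effects in downstream metrics are attributable to annotation
#' perturbations only). Every extant gene receives a deterministic toy
#' gene model on a synthetic chromosome.
#'
#' @param truth a `SimulatedTruth`.
#' @param config the `SimulationConfig` (defaults to `truth$config`).
#' @return list with `proteomes` (named list of `Proteome`, one per
#'   species, all proteins canonical) and `annotations` (named list of
#'   `AnnotationSet`).
#' @export
evolve_sequences <- function(truth, config = truth$config) {
  rate <- config$substitution_rate
  seq_env <- new.env()
  walk <- function(node, aa_vec, t_parent) {
    aa_vec <- mutate_seq(aa_vec, node$t - t_parent, rate)
    if (node$type == "extant") {
      assign(node$gene_id, paste(aa_vec, collapse = ""), envir = seq_env)
    } else {
      for (c in node$children) walk(c, aa_vec, node$t)
    }
  }
  for (fam in names(truth$families)) {
    with_seed(substream_seed(config$seed, "seq", fam), {
      L <- max(50L, as.integer(round(rlnorm(
        1L, log(config$root_length_median), config$root_length_sigma))))
      walk(truth$families[[fam]], sample(AA20, L, replace = TRUE), 0)
    })
  }
  species <- sort(unique(truth$genes$species))
  proteomes <- list(); annotations <- list()
  for (sp in species) {
    ids <- sort(truth$genes$gene_id[truth$genes$species == sp])
    seqs <- vapply(ids, get, "", envir = seq_env)
    proteomes[[sp]] <- proteome(ids, ids, sp, unname(seqs),
                                canonical = TRUE, label = "simulated")
    annotations[[sp]] <- make_gene_models(ids, nchar(seqs), sp,
                                          "simulated")
  }
  list(proteomes = proteomes, annotations = annotations)
}
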