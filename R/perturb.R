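# Annotation perturbation and annotation-sensitive "observed" orthology.
#
# The perturbation layer emulates the failure modes of real structural
# annotation: genes missed outright, gene models fragmented into several
# short models, spurious (mostly short) gene models with no evolutionary
# history, and jitter of the outer terminal-exon boundaries. Every
# perturbed gene is recorded in a ledger, so measured error fractions can
# be compared to the configured probabilities.

# Split an exon chain (0-based half-open matrix-like data frame) at a CDS
# nucleotide offset; returns list(left, right) exon data frames.
split_exon_chain <- function(exons, cut_nt) {
  lens <- exons$end - exons$start
  cum <- cumsum(lens)
  if (cut_nt <= 0L || cut_nt >= sum(lens))
    stop_data("cut outside coding region")
  e <- which(cum >= cut_nt)[1L]
  before <- if (e > 1L) cum[e - 1L] else 0L
  off <- cut_nt - before
  if (off == lens[e]) {
    left <- exons[seq_len(e), , drop = FALSE]
    right <- exons[seq(e + 1L, nrow(exons)), , drop = FALSE]
  } else {
    left <- exons[seq_len(e), , drop = FALSE]
    left$end[e] <- left$start[e] + off
    right <- exons[seq(e, nrow(exons)), , drop = FALSE]
    right$start[1L] <- exons$start[e] + off
  }
  list(left = left, right = right)
}

# Distinct interior cut points (residues) for splitting a protein of
# length L into n fragments; u supplies the first n-1 uniforms, more are
# drawn from the current stream if rounding collides.
interior_cuts <- function(L, n, u) {
  cuts <- unique(pmin(L - 1L, pmax(1L, as.integer(ceiling(u * (L - 1L))))))
  guard <- 0L
  while (length(cuts) < n - 1L && guard < 100L) {
    extra <- runif(1L)
    cuts <- unique(c(cuts, pmin(L - 1L, pmax(1L, as.integer(
      ceiling(extra * (L - 1L)))))))
    guard <- guard + 1L
  }
  if (length(cuts) < n - 1L)
    stop_data("cannot place ", n - 1L, " distinct cuts in length ", L)
  sort(cuts)
}

#' Perturb a simulated annotation
#'
#' Independently per true gene (its own RNG substream, so raising a
#' probability only grows the affected gene set): the gene is *missed*
#' with `miss_prob`, else *fragmented* with `frag_prob` (protein split at
#' uniform interior cut points into `n_fragments` pieces, the gene model
#' split at the corresponding coding positions), else *kept* with its
#' terminal-exon outer boundaries jittered by up to `boundary_jitter`
#' bp. Spurious gene models (no family membership, short lognormal
#' lengths) are injected per species with a Poisson count of mean
#' `spurious_rate` times the species' true gene count.
#'
#' @param dataset output of [evolve_sequences()] (`proteomes` +
#'   `annotations`).
#' @param truth the `SimulatedTruth`.
#' @param config the `SimulationConfig` (defaults to `truth$config`).
#' @return an object of class `PerturbedAnnotation`: list with
#'   `proteomes`, `annotations` (both per species, every protein
#'   canonical) and `ledger` (data frame: `gene_id`, `species`, `family`,
#'   `status` in kept/missed/fragmented/spurious, `parent_length`,
#'   `new_ids` semicolon-separated).
#' @export
perturb_annotation <- function(dataset, truth, config = truth$config) {
  J <- config$boundary_jitter
  proteomes <- list(); annotations <- list(); ledger <- list()
  for (sp in names(dataset$proteomes)) {
    prot <- dataset$proteomes[[sp]]
    ann <- dataset$annotations[[sp]]
    out_prot <- list(); out_exons <- list()
    for (i in seq_len(nrow(prot))) {
      gid <- prot$id[i]
      seq <- prot$sequence[i]
      L <- nchar(seq)
      fam <- truth$genes$family[match(gid, truth$genes$gene_id)]
      exons <- ann$exons[ann$exons$gene_id == gid, , drop = FALSE]
      res <- with_seed(substream_seed(config$seed, "perturb", gid), {
        u_miss <- runif(1L); u_frag <- runif(1L)
        u_cut <- runif(config$n_fragments - 1L)
        jit <- as.integer(round(runif(2L, -J, J)))
        if (u_miss < config$miss_prob) {
          list(status = "missed", ids = character(),
               seqs = character(), exons = NULL)
        } else if (u_frag < config$frag_prob) {
          cuts <- interior_cuts(L, config$n_fragments, u_cut)
          bounds <- c(0L, cuts, L)
          ids <- paste0(gid, "_fr", seq_len(length(bounds) - 1L))
          seqs <- substring(seq, head(bounds, -1L) + 1L, bounds[-1L])
          pieces <- list(); rest <- exons
          for (cut in cuts) {
            halves <- split_exon_chain(rest, 3L * cut -
                                         3L * (bounds[match(cut, cuts)]))
            pieces[[length(pieces) + 1L]] <- halves$left
            rest <- halves$right
          }
          pieces[[length(pieces) + 1L]] <- rest
          for (k in seq_along(pieces)) {
            pieces[[k]]$gene_id <- ids[k]
            pieces[[k]]$transcript_id <- paste0(ids[k], ".t1")
          }
          list(status = "fragmented", ids = ids, seqs = seqs,
               exons = do.call(rbind, pieces))
        } else {
          ex <- exons
          n <- nrow(ex)
          ex$start[1L] <- max(0L, min(ex$end[1L] - 1L,
                                      ex$start[1L] + jit[1L]))
          ex$end[n] <- max(ex$start[n] + 1L, ex$end[n] + jit[2L])
          list(status = "kept", ids = gid, seqs = seq, exons = ex)
        }
      })
      ledger[[length(ledger) + 1L]] <- data.frame(
        gene_id = gid, species = sp, family = fam, status = res$status,
        parent_length = L, new_ids = paste(res$ids, collapse = ";"),
        stringsAsFactors = FALSE)
      if (length(res$ids)) {
        out_prot[[length(out_prot) + 1L]] <-
          data.frame(id = res$ids, sequence = res$seqs,
                     stringsAsFactors = FALSE)
        out_exons[[length(out_exons) + 1L]] <- res$exons
      }
    }
    # spurious gene models, appended beyond the chromosome end
    n_true <- nrow(prot)
    spur <- with_seed(substream_seed(config$seed, "spurious", sp), {
      K <- qpois(runif(1L), config$spurious_rate * n_true)
      if (K == 0L) NULL else {
        lens <- pmax(30L, as.integer(round(rlnorm(
          K, log(config$spurious_length_median),
          config$spurious_length_sigma))))
        data.frame(
          id = sprintf("%s_spur%03d", sp, seq_len(K)),
          sequence = vapply(lens, function(l)
            paste(sample(AA20, l, replace = TRUE), collapse = ""), ""),
          stringsAsFactors = FALSE)
      }
    })
    if (!is.null(spur)) {
      out_prot[[length(out_prot) + 1L]] <- spur
      offset <- if (length(out_exons))
        max(vapply(out_exons, function(e) max(e$end), 0L)) + 1000L
      else 0L
      spur_models <- make_gene_models(spur$id, nchar(spur$sequence),
                                      sp, "perturbed")
      spur_models$exons$start <- spur_models$exons$start + offset
      spur_models$exons$end <- spur_models$exons$end + offset
      out_exons[[length(out_exons) + 1L]] <- spur_models$exons
      ledger[[length(ledger) + 1L]] <- data.frame(
        gene_id = spur$id, species = sp, family = NA_character_,
        status = "spurious", parent_length = nchar(spur$sequence),
        new_ids = spur$id, stringsAsFactors = FALSE)
    }
    pr <- do.call(rbind, out_prot)
    proteomes[[sp]] <- proteome(pr$id, pr$id, sp, pr$sequence,
                                canonical = TRUE, label = "perturbed")
    annotations[[sp]] <- annotation_set(do.call(rbind, out_exons),
                                        label = "perturbed", species = sp)
  }
  led <- do.call(rbind, ledger)
  rownames(led) <- NULL
  structure(list(proteomes = proteomes, annotations = annotations,
                 ledger = led),
            class = "PerturbedAnnotation")
}

# Surviving representatives per true gene that keep the parent's ortholog
# pairs: the gene itself if kept, fragments of length >= tau * parent.
passing_representatives <- function(ledger, perturbed_proteomes, tau) {
  lens <- unlist(unname(lapply(perturbed_proteomes, protein_lengths)))
  reps <- list()
  for (i in seq_len(nrow(ledger))) {
    row <- ledger[i, ]
    if (row$status == "kept") {
      reps[[row$gene_id]] <- row$gene_id
    } else if (row$status == "fragmented") {
      ids <- strsplit(row$new_ids, ";", fixed = TRUE)[[1L]]
      ok <- ids[lens[ids] >= tau * row$parent_length]
      if (length(ok)) reps[[row$gene_id]] <- ok
    }
  }
  reps
}

#' Ortholog pairs as an annotation-sensitive inferrer would observe them
#'
#' Emulates the effect of annotation errors on orthology inference:
#' intact genes inherit all their true pairs; a fragment inherits its
#' parent's pairs iff its length is at least `overlap_threshold` times
#' the parent length (short fragments fail the aligner's overlap
#' criterion); missed genes contribute nothing; spurious genes get no
#' pairs.
#'
#' @param perturbed a `PerturbedAnnotation`.
#' @param truth the `SimulatedTruth`.
#' @param config the `SimulationConfig` (defaults to `truth$config`).
#' @param true_pairs optional precomputed [true_orthology()] pairs.
#' @return an `OrthologPairs` set over the perturbed protein ids.
#' @export
observed_orthology <- function(perturbed, truth, config = truth$config,
                               true_pairs = NULL) {
  if (is.null(true_pairs)) true_pairs <- true_orthology(truth)$pairs
  reps <- passing_representatives(perturbed$ledger, perturbed$proteomes,
                                  config$overlap_threshold)
  n1 <- lengths(reps[true_pairs$id1])
  n2 <- lengths(reps[true_pairs$id2])
  keep <- which(n1 > 0L & n2 > 0L)
  if (length(keep) == 0L) return(ortholog_pairs())
  id1 <- unlist(lapply(keep, function(i)
    rep(reps[[true_pairs$id1[i]]], each = n2[i])))
  id2 <- unlist(lapply(keep, function(i)
    rep(reps[[true_pairs$id2[i]]], times = n1[i])))
  ortholog_pairs(id1, id2)
}

#' Observed HOGs under annotation perturbation
#'
#' Builds the rootHOGs an orthology pipeline would report from the
#' perturbed annotation. Per family, members whose proteins keep their
#' ortholog pairs (intact genes and fragments passing the overlap
#' threshold) form the family's main HOG; fragments failing the
#' threshold lose homology to full-length members but still match each
#' other, so when they span at least two species they form a separate,
#' incomplete "split" rootHOG of gene fragments. Spurious genes join no
#' HOG. A group needs at least two members in at least two species to
#' count as a rootHOG; levels are the MRCA clade of the member species.
#'
#' @param perturbed a `PerturbedAnnotation`.
#' @param truth the `SimulatedTruth`.
#' @param config the `SimulationConfig` (defaults to `truth$config`).
#' @return a `HOGCollection` over all species of the species tree.
#' @export
observed_hogs <- function(perturbed, truth, config = truth$config) {
  tree <- truth$species_tree
  tau <- config$overlap_threshold
  lens <- unlist(unname(lapply(perturbed$proteomes, protein_lengths)))
  led <- perturbed$ledger[!is.na(perturbed$ledger$family), , drop = FALSE]
  hogs <- list()
  for (fam in unique(led$family)) {
    rows <- led[led$family == fam, , drop = FALSE]
    main <- list(); frag <- list()
    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      if (row$status == "kept") {
        main[[length(main) + 1L]] <-
          data.frame(id = row$gene_id, species = row$species,
                     stringsAsFactors = FALSE)
      } else if (row$status == "fragmented") {
        ids <- strsplit(row$new_ids, ";", fixed = TRUE)[[1L]]
        pass <- lens[ids] >= tau * row$parent_length
        if (any(pass))
          main[[length(main) + 1L]] <-
            data.frame(id = ids[pass], species = row$species,
                       stringsAsFactors = FALSE)
        if (any(!pass))
          frag[[length(frag) + 1L]] <-
            data.frame(id = ids[!pass], species = row$species,
                       stringsAsFactors = FALSE)
      }
    }
    add_group <- function(members, id) {
      if (is.null(members)) return()
      if (nrow(members) < 2L || length(unique(members$species)) < 2L)
        return()
      hogs[[length(hogs) + 1L]] <<- hog_node(
        id, mrca_label(tree, members$species), "ortholog", members)
    }
    add_group(do.call(rbind, main), sprintf("HOG:%s", fam))
    add_group(do.call(rbind, frag), sprintf("HOG:%s.frag", fam))
  }
  hog_collection(hogs, species = tree$tip.label)
}

#' Run a full simulation: truth, sequences, perturbation, observations
#'
#' Convenience wrapper chaining [simulate_families()],
#' [true_orthology()], [evolve_sequences()], [perturb_annotation()],
#' [observed_orthology()] and [observed_hogs()].
#'
#' @param config a `SimulationConfig`.
#' @return an object of class `SimulatedDataset` with elements `truth`,
#'   `true_pairs`, `true_hogs`, `clean` (unperturbed proteomes +
#'   annotations), `perturbed`, `observed_pairs`, `observed_hogs`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_families(config)
  to <- true_orthology(truth)
  clean <- evolve_sequences(truth, config)
  perturbed <- perturb_annotation(clean, truth, config)
  structure(list(truth = truth,
                 true_pairs = to$pairs, true_hogs = to$hogs,
                 clean = clean, perturbed = perturbed,
                 observed_pairs = observed_orthology(
                   perturbed, truth, config, true_pairs = to$pairs),
                 observed_hogs = observed_hogs(perturbed, truth, config)),
            class = "SimulatedDataset")
}
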