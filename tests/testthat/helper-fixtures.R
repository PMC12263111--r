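# Fixture builders and independent brute-force oracles used across tests.

# Shorthand transcript: exons given as c(s1, e1, s2, e2, ...), 0-based
# half-open.
tx <- function(id, gene, exons, chrom = "c1", strand = "+") {
  transcript_model(id, gene, chrom, strand,
                   matrix(exons, ncol = 2, byrow = TRUE))
}

# Annotation set from a list of TranscriptModel.
ann_from_tx <- function(transcripts, label = "m", species = "spX") {
  exons <- do.call(rbind, lapply(transcripts, function(t)
    data.frame(gene_id = t$gene_id, transcript_id = t$id,
               chrom = t$chrom, strand = t$strand,
               start = t$exons[, 1], end = t$exons[, 2],
               stringsAsFactors = FALSE)))
  annotation_set(exons, label = label, species = species)
}

# Random toy annotation pair sharing some gene structures: B contains a
# perturbed copy of A (terminal-boundary shifts keep matches, splice-site
# shifts and gene drops/additions break them).
random_annotation_pair <- function(n_genes = 10, seed = 1) {
  set.seed(seed)
  make_gene <- function(g, chrom) {
    k <- sample(1:4, 1)
    starts <- cumsum(c(sample(0:500, 1), rep(0, k - 1))) +
      cumsum(c(0, rep(300, k - 1))) * 0 # placeholder
    # build exons left to right with random lengths and gaps
    pos <- sample(0:1000, 1)
    ex <- matrix(0L, k, 2)
    for (i in seq_len(k)) {
      len <- sample(50:200, 1)
      ex[i, ] <- c(pos, pos + len)
      pos <- pos + len + sample(60:300, 1)
    }
    lapply(seq_len(sample(1:2, 1)), function(t)
      tx(sprintf("%s.t%d", g, t), g, t(ex) |> as.vector(),
         chrom = chrom, strand = sample(c("+", "-"), 1)))
  }
  genes_a <- paste0("ga", seq_len(n_genes))
  chroms <- sample(c("c1", "c2"), n_genes, replace = TRUE)
  txa <- unlist(lapply(seq_len(n_genes), function(i)
    make_gene(genes_a[i], chroms[i])), recursive = FALSE)
  # B: copy of a random subset with random perturbation
  txb <- list()
  for (i in seq_len(n_genes)) {
    action <- sample(c("copy", "shift_terminal", "shift_splice", "drop"),
                     1, prob = c(0.35, 0.25, 0.25, 0.15))
    if (action == "drop") next
    src <- txa[vapply(txa, function(t) t$gene_id == genes_a[i], TRUE)]
    for (t in src) {
      ex <- t$exons
      if (action == "shift_terminal") {
        ex[1, 1] <- max(0, ex[1, 1] - sample(1:40, 1))
        ex[nrow(ex), 2] <- ex[nrow(ex), 2] + sample(1:40, 1)
      } else if (action == "shift_splice" && nrow(ex) > 1) {
        j <- sample(nrow(ex) - 1, 1)
        ex[j, 2] <- ex[j, 2] + sample(1:10, 1)  # stays left of next start
      }
      id <- sub("^ga", "gb", t$id)
      txb[[length(txb) + 1L]] <-
        transcript_model(id, sub("^ga", "gb", t$gene_id),
                         t$chrom, t$strand, ex)
    }
  }
  # a few B-only genes
  for (j in seq_len(sample(0:3, 1))) {
    g <- paste0("gbx", j)
    txb <- c(txb, make_gene(g, sample(c("c1", "c2"), 1)))
  }
  if (length(txb) == 0L) txb <- make_gene("gbx0", "c1")
  list(A = ann_from_tx(txa, label = "A"),
       B = ann_from_tx(txb, label = "B"))
}

# Oracle: all-pairs transcript comparison for gene agreement.
bf_agreement <- function(A, B) {
  ta <- orthoqc:::all_transcripts(A)
  tb <- orthoqc:::all_transcripts(B)
  mq <- character(); mr <- character()
  for (q in ta) for (r in tb)
    if (classify_match(q, r) == "complete") {
      mq <- union(mq, q$gene_id)
      mr <- union(mr, r$gene_id)
    }
  list(matched_query = sort(mq), matched_ref = sort(mr))
}

# Oracle: KS statistic as explicit sup over pooled sample points.
bf_ks <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), 0)))
}

# Small HOG collection built in code: profiles only need members.
toy_hogs <- function(profiles, species, levels = NULL) {
  hogs <- lapply(seq_along(profiles), function(i) {
    counts <- profiles[[i]]
    members <- do.call(rbind, lapply(names(counts)[counts > 0],
      function(sp) data.frame(
        id = sprintf("h%d_%s_%d", i, sp, seq_len(counts[[sp]])),
        species = sp, stringsAsFactors = FALSE)))
    orthoqc:::hog_node(sprintf("HOG:%04d", i),
                       if (is.null(levels)) NA_character_ else levels[i],
                       "ortholog", members)
  })
  hog_collection(hogs, species = species)
}

# Proteome of n single-isoform genes with given lengths.
toy_proteome <- function(ids, lengths, species = "spA",
                         canonical = TRUE) {
  proteome(ids, ids, species,
           vapply(lengths, function(l) strrep("A", l), ""),
           canonical = canonical)
}
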