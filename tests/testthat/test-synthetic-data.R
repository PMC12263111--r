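# Family-tree node helpers for hand-built ground-truth cases.
nd <- function(type, children, t = 0, clade = NULL) {
  list(type = type, clade = clade, t = t, children = children)
}
leaf <- function(id, species, t = 1) {
  list(type = "extant", species = species, gene_id = id, t = t,
       children = list())
}

test_that("orthology is defined by speciation-node LCAs", {
  tree <- parse_newick("((A:1,B:1)AB:1,C:2)Root;")
  # duplication on the branch into AB, before the A/B split
  fam <- nd("speciation", clade = "Root", t = 0, children = list(
    nd("duplication", t = 0.5, children = list(
      nd("speciation", clade = "AB", t = 1, children = list(
        leaf("A1", "A", 2), leaf("B1", "B", 2))),
      nd("speciation", clade = "AB", t = 1, children = list(
        leaf("A2", "A", 2), leaf("B2", "B", 2))))),
    leaf("C1", "C", 2)))
  truth <- structure(list(species_tree = tree,
                          families = list(f001 = fam)),
                     class = "SimulatedTruth")
  to <- true_orthology(truth)
  got <- paste(to$pairs$id1, to$pairs$id2)
  expect_setequal(got, c("A1 B1", "A2 B2", "A1 C1", "A2 C1",
                         "B1 C1", "B2 C1"))
  # ohnolog pairs across the duplication are absent
  expect_false(any(got %in% c("A1 B2", "A2 B1", "A1 A2", "B1 B2")))
  # HOG: one rootHOG at Root with a nested paralog split
  expect_equal(length(to$hogs$roothogs), 1L)
  expect_equal(to$hogs$roothogs[[1]]$level, "Root")
  expect_equal(to$hogs$profile[1, ], c(A = 2L, B = 2L, C = 1L))
  expect_equal(to$hogs$roothogs[[1]]$children[[1]]$type, "paralog")
})

test_that("zero birth/death rates give strict 1:1 families", {
  cfg <- simulation_config(n_species = 10, n_families = 25,
                           birth_rate = 0, death_rate = 0, seed = 2)
  truth <- simulate_families(cfg)
  expect_equal(nrow(truth$genes), 250L)
  to <- true_orthology(truth)
  expect_true(all(to$hogs$profile == 1L))
  expect_equal(count_pattern(to$hogs,
                             phyletic_pattern(others = 1L,
                                              species = to$hogs$species)),
               25L)
  comp <- hog_completeness_all(to$hogs, cfg$species_tree)
  expect_true(all(comp == 1))
})

test_that("a high death rate empties most families of no species but errors out when everything dies", {
  cfg <- simulation_config(n_species = 6, n_families = 5,
                           birth_rate = 0, death_rate = 50, seed = 2)
  expect_error(simulate_families(cfg), "extinct")
})

test_that("WGD at a clade stem with full retention doubles that clade", {
  tree <- parse_newick("((A:1,B:1)AB:1,C:2)Root;")
  cfg <- simulation_config(species_tree = tree, n_families = 12,
                           birth_rate = 0, death_rate = 0,
                           wgd_events = c(AB = 1.0), seed = 6)
  truth <- simulate_families(cfg)
  to <- true_orthology(truth)
  expect_true(all(to$hogs$profile[, "A"] == 2L))
  expect_true(all(to$hogs$profile[, "B"] == 2L))
  expect_true(all(to$hogs$profile[, "C"] == 1L))
  pat <- phyletic_pattern(A = 2L, B = 2L, C = 1L)
  expect_equal(count_pattern(to$hogs, pat), 12L)
})

test_that("zero substitution rate leaves family members identical", {
  cfg <- simulation_config(n_species = 6, n_families = 8,
                           birth_rate = 0.05, death_rate = 0,
                           substitution_rate = 0, seed = 9)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  all_seq <- do.call(rbind, lapply(ds$proteomes, function(p)
    p[c("id", "sequence")]))
  fam_of <- setNames(truth$genes$family, truth$genes$gene_id)
  for (fam in unique(fam_of)) {
    seqs <- all_seq$sequence[fam_of[all_seq$id] == fam]
    expect_equal(length(unique(seqs)), 1L, label = fam)
  }
})

test_that("species median lengths track the configured root median", {
  cfg <- simulation_config(n_species = 8, n_families = 300,
                           birth_rate = 0, death_rate = 0,
                           substitution_rate = 0.1,
                           root_length_median = 300, seed = 12)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  for (p in ds$proteomes) {
    med <- median_length(protein_lengths(p))
    expect_lt(abs(med - 300) / 300, 0.1)
  }
})

test_that("emitted gene models self-match through a GFF3 round trip", {
  cfg <- simulation_config(n_species = 4, n_families = 10,
                           birth_rate = 0.1, death_rate = 0, seed = 4)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ds$annotations[[1]], f)
  back <- parse_gff3(f, species = ds$annotations[[1]]$species)
  expect_equal(gene_agreement(back, ds$annotations[[1]])$ji, 1)
})

test_that("zero perturbation is the identity", {
  cfg <- simulation_config(n_species = 6, n_families = 12,
                           birth_rate = 0.05, death_rate = 0.05,
                           substitution_rate = 0.2, seed = 14)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  pert <- perturb_annotation(ds, truth, cfg)
  expect_true(all(pert$ledger$status == "kept"))
  expect_equal(sum(vapply(pert$proteomes, nrow, 0L)), nrow(truth$genes))
  to <- true_orthology(truth)
  obs <- observed_orthology(pert, truth, cfg, true_pairs = to$pairs)
  expect_equal(obs, to$pairs)
  # gene models are untouched at zero jitter
  expect_equal(pert$annotations[[1]]$exons, ds$annotations[[1]]$exons)
})

test_that("measured perturbation fractions match configured probabilities", {
  cfg <- simulation_config(n_species = 10, n_families = 60,
                           birth_rate = 0, death_rate = 0,
                           substitution_rate = 0,
                           miss_prob = 0.2, frag_prob = 0.25,
                           spurious_rate = 0.3, seed = 15)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  pert <- perturb_annotation(ds, truth, cfg)
  n <- nrow(truth$genes)
  tab <- table(factor(pert$ledger$status,
                      c("kept", "missed", "fragmented", "spurious")))
  sd3 <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(tab[["missed"]] / n - 0.2), sd3(0.2))
  # fragmentation applies to genes that were not missed
  expect_lt(abs(tab[["fragmented"]] / n - 0.8 * 0.25), sd3(0.2))
  expect_lt(abs(tab[["spurious"]] / n - 0.3), 3 * sqrt(0.3 / n))
})

test_that("fragment boundaries preserve the protein and the coding length", {
  cfg <- simulation_config(n_species = 4, n_families = 15,
                           birth_rate = 0, death_rate = 0,
                           substitution_rate = 0, frag_prob = 1,
                           n_fragments = 3, seed = 16)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  pert <- perturb_annotation(ds, truth, cfg)
  led <- pert$ledger[pert$ledger$status == "fragmented", ]
  seqs <- do.call(rbind, lapply(ds$proteomes, function(p)
    p[c("id", "sequence")]))
  pseqs <- do.call(rbind, lapply(pert$proteomes, function(p)
    p[c("id", "sequence")]))
  for (i in seq_len(nrow(led))) {
    ids <- strsplit(led$new_ids[i], ";")[[1]]
    joined <- paste(pseqs$sequence[match(ids, pseqs$id)], collapse = "")
    expect_equal(joined, seqs$sequence[seqs$id == led$gene_id[i]])
    ex <- pert$annotations[[led$species[i]]]$exons
    for (k in seq_along(ids)) {
      rows <- ex[ex$gene_id == ids[k], ]
      expect_equal(sum(rows$end - rows$start),
                   3L * nchar(pseqs$sequence[pseqs$id == ids[k]]))
    }
  }
})

test_that("an overlap threshold of 1 makes every fragment a singleton", {
  cfg <- simulation_config(n_species = 6, n_families = 10,
                           birth_rate = 0, death_rate = 0,
                           substitution_rate = 0, frag_prob = 1,
                           overlap_threshold = 1, seed = 17)
  truth <- simulate_families(cfg)
  ds <- evolve_sequences(truth, cfg)
  pert <- perturb_annotation(ds, truth, cfg)
  obs <- observed_orthology(pert, truth, cfg)
  expect_equal(nrow(obs), 0L)
})

test_that("spurious short genes drag the median length down", {
  cfg0 <- simulation_config(n_species = 5, n_families = 40,
                            birth_rate = 0, death_rate = 0,
                            substitution_rate = 0, seed = 18)
  cfg1 <- simulation_config(n_species = 5, n_families = 40,
                            birth_rate = 0, death_rate = 0,
                            substitution_rate = 0, spurious_rate = 0.5,
                            seed = 18)
  truth <- simulate_families(cfg0)
  ds <- evolve_sequences(truth, cfg0)
  p0 <- perturb_annotation(ds, truth, cfg0)
  p1 <- perturb_annotation(ds, truth, cfg1)
  m0 <- median_length(unlist(lapply(p0$proteomes, protein_lengths)))
  m1 <- median_length(unlist(lapply(p1$proteomes, protein_lengths)))
  expect_lt(m1, m0)
})

test_that("raising frag_prob under coupled streams never raises the proportion", {
  base <- function(f) simulation_config(
    n_species = 8, n_families = 30, birth_rate = 0, death_rate = 0,
    substitution_rate = 0, frag_prob = f, seed = 19)
  truth <- simulate_families(base(0))
  ds <- evolve_sequences(truth, base(0))
  to <- true_orthology(truth)
  props <- vapply(c(0, 0.15, 0.3), function(f) {
    cfg <- base(f)
    pert <- perturb_annotation(ds, truth, cfg)
    obs <- observed_orthology(pert, truth, cfg, true_pairs = to$pairs)
    pr <- ortholog_proportions(pert$proteomes, obs)
    sum(pr$n_with_ortholog) / sum(pr$n_canonical)
  }, 0)
  expect_true(all(diff(props) <= 1e-12))
})

test_that("simulated true HOGs round-trip through OrthoXML", {
  cfg <- simulation_config(n_species = 6, n_families = 10,
                           birth_rate = 0.15, death_rate = 0.1, seed = 20)
  truth <- simulate_families(cfg)
  to <- true_orthology(truth)
  f <- withr::local_tempfile(fileext = ".orthoxml")
  write_orthoxml(to$hogs, f)
  back <- parse_orthoxml(f)
  expect_equal(back$profile[rownames(to$hogs$profile),
                            colnames(to$hogs$profile)],
               to$hogs$profile)
  m1 <- lapply(to$hogs$roothogs, function(h) sort(h$members$id))
  m2 <- lapply(back$roothogs, function(h) sort(h$members$id))
  names(m1) <- vapply(to$hogs$roothogs, `[[`, "", "id")
  names(m2) <- vapply(back$roothogs, `[[`, "", "id")
  expect_equal(m2[names(m1)], m1)
})
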