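test_that("intron chains are the gaps between consecutive exons", {
  ic <- intron_chain(tx("t1", "g1", c(0, 100, 200, 300)))
  expect_equal(unname(ic$introns[1, ]), c(100L, 200L))
  expect_equal(nrow(ic$introns), 1L)

  mono <- intron_chain(tx("t2", "g2", c(0, 300)))
  expect_equal(nrow(mono$introns), 0L)
  expect_equal(unname(mono$span), c(0L, 300L))

  three <- intron_chain(tx("t3", "g3", c(0, 10, 20, 30, 50, 80)))
  expect_equal(nrow(three$introns), 2L)
  expect_true(all(diff(three$introns[, 1]) > 0))
})

test_that("complete match requires identical intron chains with free outer ends", {
  a <- tx("t1", "g1", c(0, 100, 200, 300, 400, 500))
  expect_equal(classify_match(a, a), "complete")

  # terminal exon extended beyond the reference: still complete
  ext <- tx("t2", "g2", c(0, 100, 200, 300, 400, 550))
  expect_equal(classify_match(a, ext), "complete")
  lead <- tx("t2b", "g2", c(0, 100, 200, 300, 400, 500))
  lead$exons[1, 1] <- 0L
  expect_equal(classify_match(a, lead), "complete")

  # one internal splice site shifted by 1 bp: no match
  shift <- tx("t3", "g3", c(0, 101, 200, 300, 400, 500))
  expect_equal(classify_match(a, shift), "no_match")

  expect_equal(classify_match(a, tx("t4", "g4", c(0, 100, 200, 300, 400, 500),
                                    chrom = "c2")), "no_match")
  expect_equal(classify_match(a, tx("t5", "g5", c(0, 100, 200, 300, 400, 500),
                                    strand = "-")), "no_match")
})

test_that("mono-exonic matching needs overlap; mono never matches multi", {
  m1 <- tx("t1", "g1", c(0, 300))
  m2 <- tx("t2", "g2", c(250, 600))
  m3 <- tx("t3", "g3", c(300, 600))
  multi <- tx("t4", "g4", c(0, 100, 200, 300))
  expect_equal(classify_match(m1, m2), "complete")
  expect_equal(classify_match(m1, m3), "no_match")  # adjacent, no shared base
  expect_equal(classify_match(m1, multi), "no_match")
})

test_that("classify_match is symmetric on random transcript pairs", {
  pair <- random_annotation_pair(n_genes = 8, seed = 5)
  ta <- orthoqc:::all_transcripts(pair$A)
  tb <- orthoqc:::all_transcripts(pair$B)
  for (q in ta[seq_len(min(10, length(ta)))])
    for (r in tb[seq_len(min(10, length(tb)))])
      expect_identical(classify_match(q, r), classify_match(r, q))
})

test_that("self-agreement gives ji = 1 and disjoint annotations give 0", {
  txs <- lapply(1:10, function(i)
    tx(sprintf("t%d", i), sprintf("g%d", i),
       c(i * 1000, i * 1000 + 100, i * 1000 + 200, i * 1000 + 300)))
  A <- ann_from_tx(txs)
  expect_equal(gene_agreement(A, A)$ji, 1)

  B <- ann_from_tx(lapply(txs, function(t) {
    t2 <- t
    t2$exons <- t$exons + 37L  # shifts every splice site
    transcript_model(paste0(t$id, "b"), paste0(t$gene_id, "b"),
                     t$chrom, t$strand, t2$exons)
  }))
  expect_equal(gene_agreement(A, B)$ji, 0)
})

test_that("one-to-many matches count every gene involved", {
  # 4 genes each side; two A genes share the intron chain of one B gene
  shared <- c(0, 100, 200, 300)
  A <- ann_from_tx(list(
    tx("a1.t", "a1", shared),
    tx("a2.t", "a2", c(0, 100, 200, 350)),  # same introns, longer end
    tx("a3.t", "a3", c(5000, 5100, 5300, 5400)),
    tx("a4.t", "a4", c(7000, 7100))))
  B <- ann_from_tx(list(
    tx("b1.t", "b1", shared),
    tx("b2.t", "b2", c(9000, 9100, 9200, 9300)),
    tx("b3.t", "b3", c(11000, 11200, 11300, 11500)),
    tx("b4.t", "b4", c(13000, 13100))))
  st <- gene_agreement(A, B)
  expect_setequal(st$matched_query, c("a1", "a2"))
  expect_equal(st$matched_ref, "b1")
  expect_equal(st$ji, (2 + 1) / 8)
})

test_that("empty annotation yields ji 0 with a warning", {
  A <- ann_from_tx(list(tx("t1", "g1", c(0, 100))))
  E <- suppressWarnings(annotation_set(
    data.frame(gene_id = character(), transcript_id = character(),
               chrom = character(), strand = character(),
               start = integer(), end = integer())))
  expect_warning(st <- gene_agreement(A, E), "empty")
  expect_equal(st$ji, 0)
})

test_that("removing a gene's only matching transcript cannot raise ji", {
  pair <- random_annotation_pair(n_genes = 12, seed = 9)
  st <- gene_agreement(pair$A, pair$B)
  if (length(st$matched_query) > 0) {
    g <- st$matched_query[1]
    A2 <- pair$A
    A2$exons <- A2$exons[A2$exons$gene_id != g, ]
    # dropping the matched gene entirely removes it from both counts
    st2 <- gene_agreement(annotation_set(A2$exons, A2$label, A2$species),
                          pair$B)
    expect_lte(st2$ji, st$ji + 1e-12)
  }
})

test_that("gene_agreement equals all-pairs brute force on random fixtures", {
  for (seed in 1:20) {
    pair <- random_annotation_pair(n_genes = sample(3:15, 1), seed = seed)
    st <- gene_agreement(pair$A, pair$B)
    bf <- bf_agreement(pair$A, pair$B)
    expect_identical(st$matched_query, bf$matched_query,
                     label = paste("query seed", seed))
    expect_identical(st$matched_ref, bf$matched_ref,
                     label = paste("ref seed", seed))
  }
})

test_that("pairwise agreement averages the two directions per method pair", {
  mk <- function(label, sp, txs) {
    a <- ann_from_tx(txs, label = label, species = sp)
    a
  }
  shared <- c(0, 100, 200, 300)
  m1 <- mk("m1", "spA", list(tx("x1.t", "x1", shared),
                             tx("x2.t", "x2", c(900, 1000))))
  m2 <- mk("m2", "spA", list(tx("y1.t", "y1", shared),
                             tx("y2.t", "y2", c(5000, 5100, 5200, 5300))))
  m3 <- mk("m3", "spA", list(tx("z1.t", "z1", c(70, 100, 200, 330))))
  res <- pairwise_agreement(list(m1, m2, m3))
  expect_equal(nrow(res$per_species), 3L)  # three method pairs
  expect_setequal(res$per_species$method_pair,
                  c("m1:m2", "m1:m3", "m2:m3"))
  expect_equal(res$per_species$ji_mean,
               (res$per_species$ji_dir1 + res$per_species$ji_dir2) / 2)
  # m1:m3 share the intron chain of x1/z1 -> ji = (1+1)/(2+1)
  expect_equal(res$per_species$ji_mean[res$per_species$method_pair == "m1:m3"],
               2 / 3)
  expect_equal(nrow(res$medians), 3L)
})

test_that("species present in only one method is skipped with a warning", {
  a <- ann_from_tx(list(tx("t", "g", c(0, 100))), label = "m1",
                   species = "spA")
  b <- ann_from_tx(list(tx("t", "g", c(0, 100))), label = "m2",
                   species = "spB")
  w <- capture_warnings(res <- pairwise_agreement(list(a, b)))
  expect_true(all(grepl("only one method", w)))
  expect_equal(nrow(res$per_species), 0L)
})
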