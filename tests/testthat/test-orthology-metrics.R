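test_that("canonical selection keeps the longest isoform with id tie-break", {
  p <- proteome(c("g1a", "g1b", "g2a"), c("g1", "g1", "g2"), "spA",
                c(strrep("A", 100), strrep("A", 250), strrep("A", 80)))
  can <- select_canonical_longest(p)
  expect_equal(can$id[can$canonical], c("g1b", "g2a"))

  tie <- proteome(c("g1b", "g1a"), c("g1", "g1"), "spA",
                  c(strrep("A", 100), strrep("A", 100)))
  can2 <- select_canonical_longest(tie)
  expect_equal(can2$id[can2$canonical], "g1a")
})

test_that("splice maps regroup isoforms and missing isoforms error", {
  p <- proteome(c("x1", "x2", "y1"), c("x1", "x2", "y1"), "spA",
                c(strrep("A", 10), strrep("A", 20), strrep("A", 5)))
  f <- withr::local_tempfile()
  writeLines("x1;x2", f)
  sm <- parse_splice(f, proteome = p)
  can <- select_canonical_longest(p, sm)
  expect_equal(can$gene_id[can$id == "x1"], can$gene_id[can$id == "x2"])
  expect_equal(can$id[can$canonical], c("x2", "y1"))

  writeLines("x1;zz", f)
  expect_error(parse_splice(f, proteome = p), "absent")
})

test_that("proteome without a splice map keeps single proteins canonical", {
  p <- proteome(paste0("p", 1:3), paste0("g", 1:3), "spA",
                rep(strrep("A", 50), 3))
  can <- select_canonical_longest(p)
  expect_true(all(can$canonical))
})

test_that("ortholog proportion counts canonical proteins in pairs", {
  p <- select_canonical_longest(toy_proteome(paste0("p", 1:5),
                                             rep(100, 5)))
  pairs <- ortholog_pairs(paste0("p", 1:4), paste0("q", 1:4))
  op <- ortholog_proportion(p, pairs)
  expect_equal(op$proportion, 0.8)
  expect_equal(op$singletons, "p5")
  expect_equal(op$n_with_ortholog + length(op$singletons), op$n_canonical)

  empty <- ortholog_proportion(p, ortholog_pairs())
  expect_equal(empty$proportion, 0)
  expect_equal(length(empty$singletons), 5L)
})

test_that("proportion uses canonical isoforms only", {
  # 10 genes x 2 isoforms; canonical = the longer (suffix "b")
  ids <- c(paste0("g", 1:10, "a"), paste0("g", 1:10, "b"))
  p <- proteome(ids, rep(paste0("g", 1:10), 2), "spA",
                c(rep(strrep("A", 50), 10), rep(strrep("A", 99), 10)))
  p <- select_canonical_longest(p)
  pairs <- ortholog_pairs(paste0("g", 1:7, "b"), paste0("z", 1:7))
  op <- ortholog_proportion(p, pairs)
  expect_equal(op$n_canonical, 10L)
  expect_equal(op$proportion, 0.7)
  # a pair naming a non-canonical isoform is a data error
  bad <- ortholog_pairs("g1a", "z9")
  expect_error(ortholog_proportion(p, bad), "non-canonical")
})

test_that("proportion is invariant to pair duplication and order", {
  p <- select_canonical_longest(toy_proteome(paste0("p", 1:6),
                                             rep(80, 6)))
  a <- c("p1", "p2", "p3"); b <- c("q1", "q2", "q3")
  p1 <- ortholog_proportion(p, ortholog_pairs(a, b))
  p2 <- ortholog_proportion(p, ortholog_pairs(c(rev(b), a), c(rev(a), b)))
  expect_equal(p1$proportion, p2$proportion)
  expect_equal(p1$singletons, p2$singletons)
})

test_that("unresolvable pair ids are reported", {
  p <- select_canonical_longest(toy_proteome("p1", 100))
  q <- select_canonical_longest(toy_proteome("q1", 100, species = "spB"))
  expect_error(
    ortholog_proportions(list(spA = p, spB = q),
                         ortholog_pairs("p1", "nosuch")),
    "not found")
})

test_that("rootHOG sizes count genes, nested members once", {
  h <- toy_hogs(list(c(s1 = 1, s2 = 1), c(s1 = 2), c(s1 = 10, s2 = 10)),
                species = c("s1", "s2"))
  hs <- hog_sizes(h)
  expect_equal(hs$n_roothogs, 3L)
  expect_equal(sort(unname(hs$sizes)), c(2L, 2L, 20L))
  expect_equal(as.integer(hs$size_distribution[c("2", "20")]), c(2L, 1L))

  empty <- hog_collection(list(), species = c("s1", "s2"))
  expect_equal(hog_sizes(empty)$n_roothogs, 0L)

  # one rootHOG holding two disjoint child HOGs of 3 members each
  kids <- lapply(1:2, function(k) orthoqc:::hog_node(
    paste0("H1.", k), NA, "ortholog",
    data.frame(id = paste0("m", k, 1:3),
               species = paste0("s", 1:3))))
  root <- orthoqc:::hog_node("H1", "root", "ortholog",
                             do.call(rbind, lapply(kids, `[[`, "members")),
                             children = kids)
  h2 <- hog_collection(list(root), species = paste0("s", 1:3))
  expect_equal(hog_sizes(h2)$n_roothogs, 1L)
  expect_equal(unname(hog_sizes(h2)$sizes), 6L)
})

test_that("HOG completeness divides present species by the level clade", {
  tree <- parse_newick("((A,B)AB,C)Root;")
  h_ab <- orthoqc:::hog_node("H1", "AB", "ortholog",
                             data.frame(id = "a1", species = "A"))
  expect_equal(hog_completeness(h_ab, tree), 0.5)
  h_root <- orthoqc:::hog_node("H2", "Root", "ortholog",
                               data.frame(id = c("a1", "b1", "c1"),
                                          species = c("A", "B", "C")))
  expect_equal(hog_completeness(h_root, tree), 1)
  h10 <- setNames(c(rep(1L, 7), rep(0L, 3)), paste0("s", 1:10))
  big <- parse_newick(paste0("(", paste(paste0("s", 1:10), collapse = ","),
                             ")Root;"))
  expect_equal(hog_completeness(h10, big, level = "Root"), 0.7)
  expect_error(hog_completeness(h_ab, tree, level = "nope"), "no clade")
})

test_that("phyletic pattern counts match profiles exactly", {
  species <- c("s1", "s2", "s3")
  h <- toy_hogs(c(replicate(3, c(s1 = 1, s2 = 1, s3 = 1), simplify = FALSE),
                  replicate(2, c(s1 = 2, s2 = 0, s3 = 1), simplify = FALSE),
                  list(c(s1 = 1, s2 = 2, s3 = 1),
                       c(s1 = 0, s2 = 1, s3 = 1),
                       c(s1 = 3, s2 = 3, s3 = 3))),
                species = species)
  strict <- phyletic_pattern(others = 1L, species = species)
  expect_equal(count_pattern(h, strict), 3L)
  # duplicated-in-s1, absent-in-s2 pattern (the WGD-polyploid analogue)
  pat <- phyletic_pattern(s1 = 2L, s2 = 0L, others = 1L, species = species)
  expect_equal(count_pattern(h, pat), 2L)
  wild <- phyletic_pattern(others = "*", species = species)
  expect_equal(count_pattern(h, wild), 8L)
  expect_error(count_pattern(h, phyletic_pattern(s9 = 1L)), "not in the dataset")
})

test_that("counts over an exhaustive pattern partition sum to n_roothogs", {
  set.seed(4)
  species <- c("s1", "s2")
  profs <- replicate(30, setNames(sample(0:2, 2, replace = TRUE), species),
                     simplify = FALSE)
  profs <- lapply(profs, function(p) { if (sum(p) == 0) p["s1"] <- 1L; p })
  h <- toy_hogs(profs, species = species)
  total <- sum(vapply(0:2, function(k1) sum(vapply(0:2, function(k2)
    count_pattern(h, phyletic_pattern(s1 = k1, s2 = k2)), 0L)), 0L))
  expect_equal(total, hog_sizes(h)$n_roothogs)
})

test_that("adding a species-disjoint rootHOG leaves other metrics unchanged", {
  species <- c("s1", "s2", "s3", "s4")
  h <- toy_hogs(list(c(s1 = 1, s2 = 1)), species = species)
  h2 <- toy_hogs(list(c(s1 = 1, s2 = 1), c(s3 = 1, s4 = 2)),
                 species = species)
  expect_equal(h2$profile[1, ], h$profile[1, ])
  expect_equal(unname(hog_sizes(h2)$sizes[1]), unname(hog_sizes(h)$sizes[1]))
  pat <- phyletic_pattern(s1 = 1L, s2 = 1L, s3 = 0L, s4 = 0L)
  expect_equal(count_pattern(h, pat), count_pattern(h2, pat))
})
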