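test_that("the seven-group amino-acid map is a partition with known sizes", {
  red <- proteinReduction()
  expect_identical(red@nGroups, 7L)
  expect_length(red@map, 20L)
  sizes <- as.integer(table(red@map))
  expect_identical(sort(sizes, decreasing = TRUE), c(4L, 4L, 4L, 3L, 2L, 2L, 1L))
  # spot-checks from the published grouping
  expect_identical(unname(reduceSequence("VGA", red)), c(0L, 0L, 0L))
  expect_identical(unname(reduceSequence("C", red)), 6L)
  expect_identical(unname(reduceSequence("W", red)),
                   unname(reduceSequence("H", red)))  # Trp sits with His group
})

test_that("structure reductions collapse as declared", {
  expect_identical(unname(reduceSequence("..((", rnaStructureReduction())),
                   c(0L, 0L, 1L, 1L))
  expect_identical(unname(reduceSequence("HEC", proteinStructureReduction())),
                   c(0L, 1L, 2L))
  expect_error(reduceSequence("..x", rnaStructureReduction()), "position 3")
})

test_that("k-mer frequencies match hand-computed small cases", {
  red <- rnaReduction()
  # single-symbol string: all mass on the A-homopolymer in every block
  v <- kmerFrequencies(reduceSequence("AAAA", red), kmerSpec(4, 1, 4))
  expect_length(v, 340L)
  nm <- kmerNames(kmerSpec(4, 1, 4), c("A", "C", "G", "T"))
  expect_identical(unname(v[nm == "A"]), 1)
  expect_identical(unname(v[nm == "AA"]), 1)
  expect_identical(unname(v[nm == "AAAA"]), 1)
  expect_identical(sum(v > 0), 4L)

  # ACGT, k = 1..2
  v2 <- kmerFrequencies(reduceSequence("ACGT", red), kmerSpec(4, 1, 2))
  nm2 <- kmerNames(kmerSpec(4, 1, 2), c("A", "C", "G", "T"))
  expect_equal(unname(v2[1:4]), rep(0.25, 4))
  expect_equal(unname(v2[nm2 %in% c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(v2[5:20]), 1)

  # strings shorter than k give an all-zero block
  v3 <- kmerFrequencies(reduceSequence("ACG", red), kmerSpec(4, 4, 4))
  expect_identical(unname(v3), numeric(256))
  expect_error(kmerFrequencies(integer(0), kmerSpec(4, 1, 2)), "empty")
})

test_that("k-mer frequencies equal the enumerate-and-count oracle", {
  set.seed(11)
  cases <- list(list(sym = c("A", "C", "G", "T"), red = rnaReduction(), kMax = 4L),
                list(sym = as.character(1:7), red = NULL, kMax = 3L),
                list(sym = c("u", "p"), red = NULL, kMax = 4L),
                list(sym = c("H", "E", "C"), red = NULL, kMax = 3L))
  for (cs in cases) {
    A <- length(cs$sym)
    spec <- kmerSpec(A, 1L, cs$kMax)
    for (i in 1:50) {
      L <- sample(cs$kMax:30, 1)
      chars <- sample(cs$sym, L, replace = TRUE)
      s <- paste(chars, collapse = "")
      groups <- match(chars, cs$sym) - 1L
      got <- kmerFrequencies(groups, spec)
      expect_equal(got, naiveKmerFrequencies(s, cs$sym, 1L, cs$kMax),
                   tolerance = 1e-12)
      # per-k normalization: every block with L >= k sums to 1
      off <- 0L
      for (k in 1:cs$kMax) {
        blk <- got[(off + 1):(off + A^k)]
        if (L >= k) expect_equal(sum(blk), 1, tolerance = 1e-9)
        off <- off + A^k
      }
    }
  }
})

test_that("1-mer blocks are shuffle-invariant, higher-k blocks are not", {
  set.seed(3)
  s <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  sh <- sample(s)
  spec <- kmerSpec(4, 1, 4)
  v1 <- kmerFrequencies(match(s, c("A", "C", "G", "T")) - 1L, spec)
  v2 <- kmerFrequencies(match(sh, c("A", "C", "G", "T")) - 1L, spec)
  expect_equal(v1[1:4], v2[1:4], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(v1[21:340], v2[21:340], tolerance = 1e-6)))
})

test_that("encoder dimensionalities and block layout are exact", {
  expect_identical(sum(featureLayout("rna", FALSE)$length), 340L)
  expect_identical(sum(featureLayout("rna", TRUE)$length), 370L)
  expect_identical(sum(featureLayout("protein", FALSE)$length), 399L)
  expect_identical(sum(featureLayout("protein", TRUE)$length), 438L)
  lr <- featureLayout("rna", TRUE)
  expect_identical(lr$length[lr$block == "seq" & lr$k == 4], 256L)
  expect_identical(sum(lr$length[lr$block == "struct"]), 30L)
  lp <- featureLayout("protein", TRUE)
  expect_identical(lp$length[lp$block == "seq" & lp$k == 3], 343L)
  expect_identical(sum(lp$length[lp$block == "struct"]), 39L)
})

test_that("encodeRNA / encodeProtein enforce their contracts", {
  expect_length(encodeRNA(strrep("ACGT", 15)), 340L)
  expect_length(encodeRNA(strrep("ACGT", 15), strrep(".", 60)), 370L)
  expect_length(encodeProtein("MKVLAWGRETCYHNQDSIFP"), 399L)
  expect_length(encodeProtein("MKVLAWGRETCYHNQDSIFP",
                              paste0(strrep("HEC", 6), "HH")), 438L)
  expect_error(encodeRNA(strrep("A", 50), strrep(".", 49)),
               "structure length")
  # an all-Cys protein concentrates mass on the Cys group in every block
  v <- encodeProtein("CCCC")
  expect_identical(unname(v["seq_7"]), 1)
  expect_identical(unname(v["seq_777"]), 1)
})

test_that("encodeDataset is deterministic and shape-correct", {
  ds <- tinyDataset()
  enc <- encodeDataset(ds, withStructure = TRUE)
  expect_identical(nPairs(enc), 4L)
  expect_identical(dim(featureMatrix(enc, "rna")), c(4L, 370L))
  expect_identical(dim(featureMatrix(enc, "protein")), c(4L, 438L))
  enc2 <- encodeDataset(ds, withStructure = TRUE)
  expect_identical(featureMatrix(enc, "rna"), featureMatrix(enc2, "rna"))
  expect_identical(featureMatrix(enc, "protein"), featureMatrix(enc2, "protein"))
  # all feature values are frequencies
  expect_true(all(featureMatrix(enc, "rna") >= 0 &
                  featureMatrix(enc, "rna") <= 1))
  # sequence-only mode
  encS <- encodeDataset(ds, withStructure = FALSE)
  expect_identical(ncol(featureMatrix(encS, "rna")), 340L)
  expect_identical(ncol(featureMatrix(encS, "protein")), 399L)
  # structure requested but absent
  expect_error(encodeDataset(tinyDataset(withStructures = FALSE), TRUE),
               "no structure stores")
})
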