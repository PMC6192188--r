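test_that("readAlignment parses FASTA, uppercases and validates", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtacgtaa", ">b", "ACGTACGTAC",
               ">c", "ACGTACGTAG"), f)
  aln <- readAlignment(f)
  expect_length(aln, 3)
  expect_equal(unique(Biostrings::width(aln)), 10)
  expect_equal(as.character(aln[["a"]]), "ACGTACGTAA")

  writeLines(c(">a", "ACGTACGTAA", ">b", "ACGTACGTACG"), f)
  expect_error(readAlignment(f), "unequal lengths")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f)
  expect_error(readAlignment(f), "duplicate")
  writeLines(character(0), f)
  expect_error(readAlignment(f))
})

test_that("fixture alignment has the published dimensions", {
  fx <- makePaperFixture("cpDNA")
  aln <- readAlignment(fx$alignmentFile)
  expect_length(aln, 253)
  expect_equal(unique(Biostrings::width(aln)), 1531)
})

test_that("DMS coordinates convert to decimal degrees", {
  expect_equal(parseDms("29°18′36″N"), 29 + 18 / 60 + 36 / 3600,
               tolerance = 1e-12)
  expect_equal(parseDms("97°00′59″E"), 97 + 59 / 3600,
               tolerance = 1e-12)
  expect_equal(parseDms("29.31"), 29.31)         # decimal passthrough
  expect_equal(parseDms("-12.5"), -12.5)
  expect_equal(parseDms("10°30′00″S"), -10.5)
  # malformed seconds >= 60 as printed in field tables: arithmetic + warning
  expect_warning(v <- parseDms("31°48′79″"), "60")
  expect_equal(v, 31 + 48 / 60 + 79 / 3600, tolerance = 1e-12)
})

test_that("readPopulationMap validates and flags", {
  fx <- makePaperFixture("cpDNA")
  pm <- suppressWarnings(readPopulationMap(fx$popmapFile))
  expect_length(popNames(pm), 16)
  expect_equal(nrow(pm@individuals), 253)

  f <- tempfile(fileext = ".tsv")
  writeLines(c("individual\tpopulation\tlat\tlon",
               "i1\tA\t29.1\t97.1", "i1\tA\t29.1\t97.1"), f)
  expect_error(readPopulationMap(f), "mapped twice")
  writeLines(c("individual\tpopulation\tlat\tlon",
               "i1\tA\t29.1\t97.1", "i2\tA\t29.1\t97.1"), f)
  aln <- Biostrings::DNAStringSet(c(i1 = "ACGT"))
  expect_warning(readPopulationMap(f, aln), "absent from alignment")
})

test_that("collapseHaplotypes recovers published haplotype structure", {
  fx <- makePaperFixture("cpDNA")
  ch <- collapseHaplotypes(fx$alignment)
  expect_length(ch$hapSeq, 6)
  expect_length(ch$segSites, 7)
  expect_equal(max(ch$distMat), 6)

  fi <- makePaperFixture("ITS")
  ci <- collapseHaplotypes(fi$alignment, hapPrefix = "R")
  expect_length(ci$hapSeq, 6)
  expect_length(ci$segSites, 4)
  # gap columns are excluded before ribotype definition
  expect_false(any(grepl("-", ci$hapSeq)))
})

test_that("identical sequences collapse to one haplotype", {
  aln <- Biostrings::DNAStringSet(rep("ACGTACGT", 4))
  names(aln) <- paste0("s", 1:4)
  ch <- collapseHaplotypes(aln)
  expect_length(ch$hapSeq, 1)
  expect_length(ch$segSites, 0)
  expect_equal(dim(ch$distMat), c(1L, 1L))
})

test_that("haplotype partition matches brute-force string comparison", {
  set.seed(11)
  for (rep in 1:10) {
    mat <- matrix(sample(c("A", "C", "G", "T"), 100, TRUE,
                         prob = c(0.4, 0.3, 0.2, 0.1)), 5, 20)
    rownames(mat) <- paste0("s", 1:5)
    seqs <- apply(mat, 1, paste, collapse = "")
    aln <- Biostrings::DNAStringSet(seqs)
    names(aln) <- names(seqs)
    ch <- collapseHaplotypes(aln)
    ours <- as.integer(factor(ch$assignment,
                              levels = unique(ch$assignment)))
    expect_equal(ours, bruteHapPartition(seqs))
  }
})

test_that("record order changes labels but not the partition", {
  fx <- makePaperFixture("cpDNA")
  aln <- fx$alignment
  set.seed(5)
  perm <- sample(length(aln))
  ch1 <- collapseHaplotypes(aln)
  ch2 <- collapseHaplotypes(aln[perm])
  # same partition of individuals
  p1 <- split(names(ch1$assignment), ch1$assignment)
  p2 <- split(names(ch2$assignment), ch2$assignment)
  expect_setequal(unname(lapply(p1, sort)), unname(lapply(p2, sort)))
  # same multiset of pairwise distances
  expect_equal(sort(ch1$distMat[upper.tri(ch1$distMat)]),
               sort(ch2$distMat[upper.tri(ch2$distMat)]))
})

test_that("distances are a Hamming metric under exclude_columns", {
  set.seed(21)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), 160, TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.15, 0.05)), 8, 20)
    rownames(mat) <- paste0("s", 1:8)
    if (!any(apply(mat, 2, function(col)
      all(col %in% c("A", "C", "G", "T"))))) next
    ch <- collapseHaplotypes(Biostrings::DNAStringSet(
      structure(apply(mat, 1, paste, collapse = ""),
                names = rownames(mat))))
    d <- ch$distMat
    k <- nrow(d)
    expect_true(all(d <= length(ch$segSites) + 1e-12) ||
                  length(ch$segSites) == 0)
    for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k))
      expect_lte(d[i, j], d[i, l] + d[l, j])
  }
})

test_that("tabulation reproduces published per-population counts", {
  fx <- makePaperFixture("cpDNA")
  cn <- hapCounts(fx$table)
  expect_equal(cn["ML", c("H5", "H4", "H2")],
               c(H5 = 3L, H4 = 16L, H2 = 1L))
  expect_equal(sum(cn["ML", ]), 20L)
  expect_equal(sum(cn), 253L)
  # 13 populations fixed for a single haplotype
  expect_equal(sum(rowSums(cn > 0) == 1), 13L)
  expect_equal(rowSums(cn), sampleSizes(fx$table))
})

test_that("single-population tabulation gives a one-row matrix", {
  aln <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGT", c = "AGGT"))
  pm <- new("PopulationMap",
    individuals = data.frame(individual = c("a", "b", "c"),
                             population = "X"),
    populations = data.frame(population = "X", lat = 30, lon = 90,
                             elevation = NA_real_))
  tbl <- tabulateByPopulation(collapseHaplotypes(aln), pm)
  expect_equal(nrow(hapCounts(tbl)), 1L)
  expect_equal(sum(hapCounts(tbl)), 3L)
})

test_that("haplotype table writers round-trip", {
  fx <- makePaperFixture("cpDNA")
  f <- tempfile()
  writeHaplotypeTable(fx$table, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$N, unname(sampleSizes(fx$table)))
  expect_equal(as.matrix(back[, -(1:2)]),
               unname(hapCounts(fx$table)), ignore_attr = TRUE)
  writeDistMatrix(fx$table, f)
  dm <- read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(dm[, -1]), unname(hapDist(fx$table)),
               ignore_attr = TRUE)
  writeHapFasta(fx$table, f)
  expect_length(Biostrings::readDNAStringSet(f), 6)
})
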