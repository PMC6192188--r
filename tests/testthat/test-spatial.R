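test_that("two fixed populations give FST = 1, 100% among populations", {
  cnt <- matrix(c(2L, 0L, 0L, 2L), 2, 2,
                dimnames = list(c("a", "b"), c("A", "B")))
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = dimnames(cnt)[c(2, 2)])
  am <- amova(haplotypeTableFromCounts(cnt, d), nPerm = 0)
  expect_equal(unname(am@phi["FST"]), 1)
  expect_equal(am@table$PV[1], 100)
})

test_that("monomorphic data flags Phi as undefined", {
  cnt <- matrix(c(3L, 4L), 2, 1,
                dimnames = list(c("a", "b"), "H1"))
  d <- matrix(0, 1, 1, dimnames = list("H1", "H1"))
  am <- amova(haplotypeTableFromCounts(cnt, d), nPerm = 0)
  expect_true(any(grepl("zero total variance", am@flags)))
  expect_true(is.na(am@phi["FST"]))
  expect_equal(am@table$SS[1:2], c(0, 0))
})

test_that("AMOVA equals the brute-force oracle (grouped and ungrouped)", {
  set.seed(61)
  for (rep in 1:8) {
    tbl <- randomHapTable(nPops = 4, nHaps = 4, lambda = 2)
    cn <- hapCounts(tbl)
    iv <- indVectorsFromCounts(cn)
    am <- amova(tbl, nPerm = 0)
    br <- bruteAmova(iv$hap, iv$pop, hapDist(tbl))
    expect_equal(am@table$SS[1:2], br$ss, tolerance = 1e-9)
    expect_equal(am@table$VC[1:2], br$vc, tolerance = 1e-9)
    expect_equal(unname(am@phi["FST"]), br$fst, tolerance = 1e-9)

    g <- c(1L, 1L, 2L, 2L)
    names(g) <- rownames(cn)
    am2 <- amova(tbl, groups = g, nPerm = 0)
    br2 <- bruteAmova(iv$hap, iv$pop, hapDist(tbl), gOfPop = g)
    expect_equal(am2@table$VC[1:3], br2$vc, tolerance = 1e-9)
    expect_equal(unname(am2@phi), c(br2$fct, br2$fsc, br2$fst),
                 tolerance = 1e-9)
  }
})

test_that("AMOVA invariants hold on random grouped instances", {
  set.seed(62)
  for (rep in 1:10) {
    tbl <- randomHapTable(nPops = 6, nHaps = 5)
    g <- sample(1:3, 6, replace = TRUE)
    if (length(unique(g)) < 2) next
    names(g) <- popNames(tbl)
    am <- amova(tbl, groups = g, nPerm = 0)
    expect_equal(sum(am@table$PV[1:3]), 100, tolerance = 1e-6)
    expect_equal(sum(am@table$df[1:3]), sum(sampleSizes(tbl)) - 1)
    phi <- am@phi
    if (all(is.finite(phi)))
      expect_equal(1 - phi[["FST"]],
                   (1 - phi[["FSC"]]) * (1 - phi[["FCT"]]),
                   tolerance = 1e-9)
  }
})

test_that("binary distances reduce AMOVA to the frequency-based form", {
  set.seed(63)
  tbl <- randomHapTable(nPops = 4, nHaps = 5)
  k <- ncol(hapCounts(tbl))
  d01 <- matrix(1, k, k); diag(d01) <- 0
  dimnames(d01) <- dimnames(hapDist(tbl))
  tbl01 <- haplotypeTableFromCounts(hapCounts(tbl), d01)
  iv <- indVectorsFromCounts(hapCounts(tbl))
  br <- bruteAmova(iv$hap, iv$pop, d01)  # indicator distances
  am <- amova(tbl01, nPerm = 0)
  expect_equal(unname(am@phi["FST"]), br$fst, tolerance = 1e-9)
})

test_that("SAMOVA trivial and exhaustive cases", {
  # 2 populations, K = 2: the unique partition, FCT = grouped AMOVA FCT
  set.seed(71)
  tbl <- randomHapTable(nPops = 2, nHaps = 3, withCoords = TRUE)
  sv <- samova(tbl, k = 2, nStarts = 2, nProposals = 50, seed = 4)
  expect_setequal(unname(sv@partition), 1:2)
  g <- stats::setNames(1:2, popNames(tbl))
  am <- amova(tbl, groups = g, nPerm = 0)
  expect_equal(sv@fct, unname(am@phi["FCT"]), tolerance = 1e-12)

  # K = P: each population its own group, FCT equals ungrouped FST
  tbl6 <- randomHapTable(nPops = 6, nHaps = 4, withCoords = TRUE)
  svP <- samova(tbl6, k = 6, seed = 1)
  amU <- amova(tbl6, nPerm = 0)
  expect_equal(svP@fct, unname(amU@phi["FST"]), tolerance = 1e-9)
})

test_that("annealer is deterministic given the seed", {
  set.seed(72)
  tbl <- randomHapTable(nPops = 6, nHaps = 4, withCoords = TRUE)
  a <- samova(tbl, k = 3, nStarts = 3, nProposals = 300, seed = 9)
  b <- samova(tbl, k = 3, nStarts = 3, nProposals = 300, seed = 9)
  expect_identical(a@partition, b@partition)
  expect_identical(a@fct, b@fct)
})

test_that("fixture SAMOVA at K = 4 isolates ML and pairs DD-1/DD-2", {
  fx <- makePaperFixture("cpDNA")
  sv <- samova(fx$table, k = 4, nStarts = 8, nProposals = 1500,
               seed = 7)
  p <- sv@partition
  expect_equal(sum(p == p[["ML"]]), 1)            # ML alone
  expect_equal(p[["DD-1"]], p[["DD-2"]])          # DD-1 with DD-2
  expect_equal(p[["JCL"]], p[["SJL-1"]])
  expect_equal(p[["JCL"]], p[["SJL-2"]])
})

test_that("fctPlateau selects the levelling-off K", {
  expect_equal(fctPlateau(c(0.5, 0.7, 0.9, 0.901, 0.902, 0.9),
                          k = 2:7), 4)
  expect_warning(sel <- fctPlateau(c(0.1, 0.3, 0.5, 0.7), k = 2:5),
                 "no plateau")
  expect_equal(sel, 5)
  expect_equal(fctPlateau(rep(0.4, 5), k = 2:6), 2)
})

test_that("great-circle distances are correct and symmetric", {
  expect_equal(greatCircleKm(30, 90, 30, 90), 0)
  expect_equal(greatCircleKm(0, 0, 0, 180), 6371 * pi,
               tolerance = 1e-9)
  set.seed(81)
  for (rep in 1:10) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_equal(greatCircleKm(a[1], a[2], b[1], b[2]),
                 greatCircleKm(b[1], b[2], a[1], a[2]))
  }
  # cross-check against an established geodesic library
  skip_if_not_installed("geosphere")
  expect_equal(greatCircleKm(29.31, 97.02, 31.93, 98.93),
               geosphere::distHaversine(c(97.02, 29.31),
                                        c(98.93, 31.93),
                                        r = 6371) ,
               tolerance = 1e-6)
})

test_that("Mantel test: perfect correlation and contract errors", {
  set.seed(91)
  pts <- data.frame(lat = runif(6, 25, 35), lon = runif(6, 85, 100))
  geo <- outer(1:6, 1:6, function(i, j)
    greatCircleKm(pts$lat[i], pts$lon[i], pts$lat[j], pts$lon[j]))
  mt <- mantelTest(geo, geo, nPerm = 99, seed = 1)
  expect_equal(mt@r, 1, tolerance = 1e-12)
  expect_error(mantelTest(geo[1:3, 1:3], geo[1:3, 1:3]),
               "at least 4")
  expect_error(mantelTest(matrix(0, 6, 6), geo), "zero-variance")
})

test_that("fixture shows no isolation by distance", {
  fx <- makePaperFixture("cpDNA")
  gen <- pairwisePhiST(fx$table)
  geo <- geoDistMatrix(fx$table)
  mt <- mantelTest(gen, geo, nPerm = 1000, seed = 17)
  expect_gt(mt@pValue, 0.05)
})

test_that("Mantel p-values are approximately uniform under the null", {
  set.seed(92)
  p <- vapply(1:300, function(b) {
    a <- matrix(0, 6, 6); a[upper.tri(a)] <- runif(15); a <- a + t(a)
    g <- matrix(0, 6, 6); g[upper.tri(g)] <- runif(15); g <- g + t(g)
    mantelTest(a, g, nPerm = 99, seed = b)@pValue
  }, numeric(1))
  expect_equal(mean(p <= 0.05), 0.05, tolerance = 0.5)
  expect_lt(abs(mean(p <= 0.05) - 0.05), 0.035)
  expect_gt(mean(p), 0.4); expect_lt(mean(p), 0.6)
})
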