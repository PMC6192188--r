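test_that("mismatch histogram: exact pair counting", {
  # all identical
  cnt <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("a", "b"), "H1"))
  d0 <- matrix(0, 1, 1, dimnames = list("H1", "H1"))
  h <- mismatchHistogram(haplotypeTableFromCounts(cnt, d0))
  expect_equal(unname(h), 1)
  expect_equal(names(h), "0")

  # two haplotypes 50/50 with d = 3, n = 100: exact combinatorics
  cnt2 <- matrix(c(50L, 50L), 1, 2,
                 dimnames = list("p", c("H1", "H2")))
  d3 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("H1", "H2"), c("H1", "H2")))
  h2 <- mismatchHistogram(haplotypeTableFromCounts(cnt2, d3))
  expect_equal(unname(h2[c("0", "3")]),
               c(2 * choose(50, 2), 50 * 50) / choose(100, 2))
  expect_equal(sum(h2), 1)
})

test_that("fixture mismatch distribution is unimodal", {
  fx <- makePaperFixture("cpDNA")
  h <- mismatchHistogram(fx$table)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # single mode: frequencies rise to the mode then fall
  dh <- diff(h)
  expect_lte(sum(diff(sign(dh)[sign(dh) != 0]) != 0), 1)
})

test_that("sudden-expansion model probabilities are a distribution", {
  for (pars in list(c(3, 1, 100), c(0.5, 0.2, 5), c(10, 0.01, 50),
                    c(0, 2, 2))) {
    f <- expectedMismatch(0:3000, pars[1], pars[2], pars[3])
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-6)
  }
})

test_that("model matches numerical integration of the coalescent mixture", {
  Fnum <- function(i, tau, th0, th1) {
    f <- function(t) ifelse(t < tau, exp(-t / th1) / th1,
                            exp(-tau / th1) * exp(-(t - tau) / th0) / th0)
    sapply(i, function(ii)
      integrate(function(t) dpois(ii, t) * f(t), 0, Inf,
                rel.tol = 1e-12, subdivisions = 2000L)$value)
  }
  for (pars in list(c(3, 1, 100), c(0.5, 0.2, 5), c(7, 0.05, 20))) {
    expect_equal(expectedMismatch(0:25, pars[1], pars[2], pars[3]),
                 Fnum(0:25, pars[1], pars[2], pars[3]),
                 tolerance = 1e-9)
  }
})

test_that("fit recovers exact model histograms (self-consistency)", {
  h <- expectedMismatch(0:50, 3, 1, 100)
  names(h) <- 0:50
  fit <- fitSuddenExpansion(h)
  expect_lte(fit@ssd, 1e-10)
  expect_equal(fit@tau, 3, tolerance = 1e-3)
  expect_equal(fit@theta0, 1, tolerance = 1e-3)
  expect_equal(fit@theta1, 100, tolerance = 1e-1)
})

test_that("degenerate histograms give tau = 0", {
  fit <- fitSuddenExpansion(c(`0` = 1))
  expect_equal(fit@tau, 0)
  expect_true(any(grepl("degenerate", fit@flags)))
})

test_that("raggedness follows the stated convention", {
  # two adjacent classes 0.5/0.5 at classes 1 and 2:
  # (F1-F0)^2 + (F2-F1)^2 + (0-F2)^2 = 0.25 + 0 + 0.25
  expect_equal(raggedness(c(`1` = 0.5, `2` = 0.5)), 0.5)
  # smooth decay is less ragged than the same masses permuted
  smooth <- 0.5^(1:6); smooth <- smooth / sum(smooth)
  names(smooth) <- 0:5
  rough <- smooth[c(4, 1, 5, 2, 6, 3)]
  names(rough) <- 0:5
  expect_lt(raggedness(smooth), raggedness(rough))
  # independent reimplementation on random histograms
  set.seed(101)
  for (rep in 1:100) {
    k <- sample(3:9, 1)
    f <- runif(k); f <- f / sum(f)
    cls <- sort(sample(0:12, k))
    names(f) <- cls
    expect_equal(raggedness(f), raggednessOracle(f, cls),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D: construction zero, fixture sign, oracle equality", {
  n <- 30
  a1 <- sum(1 / seq_len(n - 1))
  expect_equal(unname(tajimasD(n, 11, 11 / a1)["D"]), 0,
               tolerance = 1e-9)

  fx <- makePaperFixture("cpDNA")
  nt <- neutralityTests(fx$table)
  expect_lt(nt@d, 0)    # expansion-like excess of rare haplotypes
  expect_equal(nt@s, 7L)
  expect_equal(nt@n, 253L)

  set.seed(103)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    S <- sample(1:50, 1)
    khat <- runif(1, 0, S)
    expect_equal(unname(tajimasD(n, S, khat)["D"]),
                 tajimaOracle(n, S, khat), tolerance = 1e-12)
  }
  expect_error(tajimasD(3, 5, 1), "n >= 4")
  expect_error(tajimasD(30, 0, 1), "S = 0")
})

test_that("Tajima's D beta p-value is sane", {
  # D = 0 is central: p near 1; strongly negative D: small p
  n <- 50; a1 <- sum(1 / seq_len(n - 1))
  p0 <- unname(tajimasD(n, 20, 20 / a1)["p"])
  expect_gt(p0, 0.5)
  pneg <- unname(tajimasD(n, 20, 0.2)["p"])
  expect_lt(pneg, 0.05)
})

test_that("Ewens distribution and Fu's Fs against exact Stirling numbers", {
  expect_equal(sum(ewensAlleleDist(10, 2)), 1, tolerance = 1e-12)
  # n = 5, theta = 1: |S(5,k)| = 24, 50, 35, 10, 1; rising fact = 120
  st <- c(24, 50, 35, 10, 1)
  expect_equal(ewensAlleleDist(5, 1), st / 120, tolerance = 1e-12)
  # S' = P(K >= 2) = 1 - 24/120 = 0.8; Fs = ln(0.8/0.2) = ln 4
  fs <- fusFs(5, 2, 1)
  expect_equal(unname(fs["Sprime"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(fs["Fs"]), log(4), tolerance = 1e-12)
  # theta -> 0 with k0 > 1: S' -> 0 and Fs diverges to -Inf
  expect_lt(unname(fusFs(5, 2, 1e-9)["Fs"]), -15)
  expect_lt(unname(fusFs(5, 2, 1e-300)["Fs"]), -600)
  # large-n stability (species-scale sample)
  expect_true(is.finite(fusFs(253, 6, 0.977)["Fs"]))
})

test_that("expansion time conversion and scaling laws", {
  est <- expansionTime(tau = 1.488, mu = 2e-9, k = 1531, g = 10)
  expect_equal(est@u, 2e-9 * 1531 * 10)
  expect_equal(est@tYears, 1.488 / (2 * est@u) * 10,
               tolerance = 1e-12)
  expect_equal(est@tYears, 2.43e5, tolerance = 0.01)
  expect_equal(expansionTime(0, 2e-9, 1531, 10)@tYears, 0)
  # doubling mu halves t exactly
  expect_equal(expansionTime(1.5, 4e-9, 1531, 10)@tYears * 2,
               expansionTime(1.5, 2e-9, 1531, 10)@tYears,
               tolerance = 1e-12)
  expect_error(expansionTime(1, -1e-9, 1531, 10), "positive")
})

test_that("strict-clock divergence estimate", {
  expect_equal(strictClockDivergence(0, mu = 2e-9), 0)
  expect_equal(strictClockDivergence(0.004, mu = 2e-9), 1e6)
  # linear in the net distance
  expect_equal(strictClockDivergence(0.008, mu = 2e-9),
               2 * strictClockDivergence(0.004, mu = 2e-9))
  expect_warning(T <- strictClockDivergence(mu = 2e-9, dBetween = 0.001,
                                            dWithin1 = 0.004),
                 "clamped")
  expect_equal(T, 0)
})

test_that("parametric bootstrap does not reject the fixture expansion fit", {
  fx <- makePaperFixture("cpDNA")
  fit <- fitSuddenExpansion(mismatchHistogram(fx$table))
  expect_error(bootstrapGof(fit, 253, nBoot = 0), "positive")
  bg <- bootstrapGof(fit, 253, nBoot = 60, seed = 5)
  expect_gt(bg@pSsd, 0.05)
  expect_gt(bg@pRag, 0.05)
  expect_true(bg@pSsd >= 1 / 61 && bg@pSsd <= 1)
})

test_that("neutralityTests handles monomorphic input", {
  cnt <- matrix(c(5L, 5L), 2, 1, dimnames = list(c("a", "b"), "H1"))
  d0 <- matrix(0, 1, 1, dimnames = list("H1", "H1"))
  nt <- neutralityTests(haplotypeTableFromCounts(cnt, d0))
  expect_true(is.na(nt@d))
  expect_true(any(grepl("S = 0", nt@flags)))
})
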