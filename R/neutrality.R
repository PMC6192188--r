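#' Tajima's D
#'
#' The standardized difference between the mean pairwise difference
#' estimate of theta and Watterson's segregating-sites estimate,
#' D = (k - S/a1) / sqrt(e1 S + e2 S (S-1)), with the classic a1, a2,
#' b1, b2, c1, c2, e1, e2 coefficients. Significantly negative D
#' indicates an excess of rare variants, as after a population
#' expansion. The p-value uses the beta-distribution approximation of
#' the null (two-sided).
#'
#' @param n sample size (>= 4).
#' @param S number of segregating sites (>= 1).
#' @param kHat observed mean number of pairwise differences.
#' @return named numeric vector \code{c(D = , p = )}.
#' @export
tajimasD <- function(n, S, kHat) {
  if (n < 4) stop("need n >= 4")
  if (S < 1) stop("D undefined with S = 0")
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (kHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  # beta approximation on [Dmin, Dmax] with mean 0, variance 1
  dmin <- (2 / n - 1 / a1) / sqrt(e2)
  dmax <- ((n + 1) / (2 * n) - 1 / a1) / sqrt(e2)
  alpha <- -(1 + dmin * dmax) * dmax / (dmax - dmin)
  beta <- (1 + dmin * dmax) * dmin / (dmax - dmin)
  # Tajima's density is ~ (Dmax-D)^(alpha-1) (D-Dmin)^(beta-1), i.e.
  # (D-Dmin)/(Dmax-Dmin) ~ Beta(shape1 = beta, shape2 = alpha)
  z <- (D - dmin) / (dmax - dmin)
  F <- stats::pbeta(min(max(z, 0), 1), beta, alpha)
  c(D = D, p = 2 * min(F, 1 - F))
}

#' Ewens sampling distribution of the number of alleles
#'
#' P(K = k | theta, n) = |S(n,k)| theta^k / (theta)_(n), with unsigned
#' Stirling numbers of the first kind and rising factorial
#' (theta)_(n); computed by a log-space recursion so it is stable for
#' large n.
#'
#' @param n sample size.
#' @param theta scaled mutation rate.
#' @return numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewensAlleleDist <- function(n, theta) {
  if (theta <= 0) stop("theta must be positive")
  ls <- .logStirling1(n)
  lp <- ls + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1)))
  exp(lp)
}

# log unsigned Stirling numbers of the first kind |S(n, k)|, k = 1..n
.logStirling1 <- function(n) {
  cur <- 0  # n = 1: |S(1,1)| = 1
  if (n == 1) return(cur)
  for (m in 2:n) {
    prev <- cur
    cur <- numeric(m)
    # k = 1: (m-1)! ; k = m: 1
    cur[1] <- log(m - 1) + prev[1]
    cur[m] <- 0
    if (m > 2) {
      k <- 2:(m - 1)
      a <- prev[k - 1]                       # |S(m-1, k-1)|
      b <- log(m - 1) + prev[k]              # (m-1) |S(m-1, k)|
      mx <- pmax(a, b)
      cur[k] <- mx + log1p(exp(pmin(a, b) - mx))
    }
  }
  cur
}

#' Fu's Fs
#'
#' Fs = ln(S'/(1 - S')) with S' = P(K >= k0 | theta, n) under the
#' Ewens sampling distribution, where k0 is the observed number of
#' haplotypes and theta is estimated by the mean pairwise difference.
#' Large negative Fs (an excess of haplotypes over the neutral
#' expectation) indicates population expansion. A significance
#' p-value, if requested, is estimated by coalescent simulation at the
#' observed theta: p = P(Fs_sim <= Fs_obs) with the add-one
#' convention; the conventional 5 percent significance level
#' corresponds to p < 0.02 (noted in \code{flags} of
#' \code{\link{neutralityTests}}).
#'
#' @param n sample size (>= 2).
#' @param k0 observed number of distinct haplotypes (>= 1).
#' @param thetaPi mean pairwise difference estimate of theta (> 0).
#' @return named numeric vector \code{c(Fs = , Sprime = )}; Fs is
#'   +/-Inf when S' reaches 1 or 0 numerically.
#' @export
fusFs <- function(n, k0, thetaPi) {
  if (n < 2 || k0 < 1) stop("need n >= 2 and k0 >= 1")
  if (thetaPi <= 0) stop("thetaPi must be positive")
  p <- ewensAlleleDist(n, thetaPi)
  sp <- sum(p[k0:n])
  sp <- min(max(sp, 0), 1)
  fs <- if (sp == 0) -Inf else if (sp == 1) Inf else log(sp / (1 - sp))
  c(Fs = fs, Sprime = sp)
}

#' Neutrality tests for a haplotype table
#'
#' Computes Tajima's D (with its beta-approximation p-value) and Fu's
#' Fs from pooled haplotype counts, segregating sites and the mean
#' pairwise difference. The Fs p-value is estimated by coalescent
#' simulation when \code{nSim > 0}.
#'
#' @param tbl a \linkS4class{HaplotypeTable}.
#' @param haplotypes optional subset of haplotype ids to pool.
#' @param nSim coalescent replicates for the Fs p-value (0 = skip).
#' @param seed integer seed for the simulation p-value.
#' @return a \linkS4class{NeutralityResult}.
#' @export
neutralityTests <- function(tbl, haplotypes = NULL, nSim = 0L,
                            seed = 1L) {
  cn <- colSums(hapCounts(tbl))
  d <- hapDist(tbl)
  if (!is.null(haplotypes)) {
    cn <- cn[haplotypes]
    d <- d[haplotypes, haplotypes, drop = FALSE]
  }
  n <- sum(cn)
  flags <- character(0)
  # segregating sites among the pooled sequences
  S <- if (is.null(haplotypes)) length(segSites(tbl)) else {
    keep <- cn > 0
    sum(apply(do.call(rbind,
      strsplit(hapSeqs(tbl)[names(cn)[keep]], "")), 2,
      function(col) length(unique(col)) > 1))
  }
  p <- cn / n
  kHat <- n / (n - 1) * drop(p %*% d %*% p)
  if (S == 0) {
    return(new("NeutralityResult", d = NA_real_, pD = NA_real_,
               fs = NA_real_, pFs = NA_real_, n = as.integer(n),
               s = 0L, kHat = kHat,
               flags = "S = 0: D and Fs undefined"))
  }
  td <- tajimasD(n, S, kHat)
  fsv <- fusFs(n, sum(cn > 0), kHat)
  pFs <- NA_real_
  if (nSim > 0 && is.finite(fsv["Fs"])) {
    set.seed(seed)
    seeds <- sample.int(2147483646L, nSim)
    fsSim <- vapply(seq_len(nSim), function(b) {
      pd <- simulateSuddenExpansion(n, L = 100000L, tau = 0,
                                    theta0 = kHat, theta1 = kHat,
                                    seed = seeds[b],
                                    returnWhat = "pairDiffs")
      kk <- attr(pd, "nHaplotypes")
      th <- mean(pd)
      if (th <= 0) return(Inf)
      unname(fusFs(n, kk, th)["Fs"])
    }, numeric(1))
    pFs <- (1 + sum(fsSim <= fsv["Fs"] + 1e-12)) / (nSim + 1)
  }
  if (!is.finite(fsv["Fs"]))
    flags <- c(flags, "S' numerically 0 or 1: Fs infinite")
  new("NeutralityResult", d = unname(td["D"]), pD = unname(td["p"]),
      fs = unname(fsv["Fs"]), pFs = pFs, n = as.integer(n),
      s = as.integer(S), kHat = kHat, flags = flags)
}
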