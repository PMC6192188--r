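#' Gene (haplotype) diversity
#'
#' Unbiased gene diversity h = n/(n-1) * (1 - sum p_i^2): the
#' probability that two sequences drawn without replacement carry
#' different haplotypes. The standard deviation follows Nei's (1987,
#' eq. 8.12) variance formula.
#'
#' @param counts non-negative haplotype counts for one sampling unit.
#' @return named numeric vector \code{c(h = , sd = )}.
#' @export
#' @examples
#' geneDiversity(c(3, 16, 1))["h"]   # 0.353 after rounding
geneDiversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("analysis error: need at least 2 sequences")
  p <- counts / n
  s2 <- sum(p^2)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  c(h = h, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity
#'
#' Unbiased mean number of pairwise differences per site,
#' pi = n/(n-1) * sum_{i != j} p_i p_j d_ij / L, computed from haplotype
#' counts and the haplotype substitution-distance matrix. The standard
#' deviation uses the no-recombination variance approximation
#' (Nei 1987, eq. 10.7).
#'
#' @param counts haplotype counts for one sampling unit (aligned with
#'   the rows of \code{distMat}).
#' @param distMat symmetric haplotype distance matrix.
#' @param L sequence length in bp.
#' @return named numeric vector \code{c(pi = , sd = )}.
#' @export
nucleotideDiversity <- function(counts, distMat, L) {
  n <- sum(counts)
  if (n < 2) stop("analysis error: need at least 2 sequences")
  if (L <= 0) stop("L must be positive")
  distMat <- as.matrix(distMat)
  p <- counts / n
  pik <- n / (n - 1) * drop(p %*% distMat %*% p)  # per sequence
  pi <- pik / L
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  c(pi = pi, sd = sqrt(max(v, 0)))
}

#' Per-population and species-level diversity table
#'
#' One row per population plus a pooled \code{Total} row, with sample
#' size, number of haplotypes, gene diversity h (SD) and nucleotide
#' diversity pi (SD).
#'
#' @param tbl a \linkS4class{HaplotypeTable}.
#' @return a data.frame.
#' @export
diversityTable <- function(tbl) {
  cn <- hapCounts(tbl)
  d <- hapDist(tbl)
  L <- tbl@L
  one <- function(x) {
    n <- sum(x)
    if (n < 2) return(c(n = n, k = sum(x > 0), h = NA, hSd = NA,
                        pi = NA, piSd = NA))
    g <- geneDiversity(x)
    p <- nucleotideDiversity(x, d, L)
    c(n = n, k = sum(x > 0), h = g["h"], hSd = g["sd"],
      pi = p["pi"], piSd = p["sd"])
  }
  rows <- rbind(t(apply(cn, 1, one)), Total = one(colSums(cn)))
  out <- data.frame(population = rownames(rows), rows,
                    row.names = NULL, check.names = FALSE)
  names(out) <- c("population", "n", "haplotypes", "h", "hSd",
                  "pi", "piSd")
  out
}

# internal: Pons-Petit style components from a count matrix and distances.
# hs is the unweighted mean of per-population unbiased diversities;
# ht uses unweighted mean haplotype frequencies with the Nei-Chesser
# harmonic-mean correction (htUncorrected omits the correction).
# vs/vt are the distance-weighted analogues built with the same
# corrections, so NST == GST exactly when all off-diagonal d are equal.
.permutComponents <- function(cn, d) {
  P <- nrow(cn)
  nk <- rowSums(cn)
  freq <- cn / nk
  nharm <- P / sum(1 / nk)
  unb <- nk / (nk - 1)

  hk <- unb * (1 - rowSums(freq^2))
  hs <- mean(hk)
  pbar <- colMeans(freq)
  htUnc <- 1 - sum(pbar^2)
  ht <- htUnc + hs / (nharm * P)

  vk <- unb * rowSums(freq * (freq %*% d))
  vs <- mean(vk)
  vtUnc <- drop(pbar %*% d %*% pbar)
  vt <- vtUnc + vs / (nharm * P)

  list(hs = hs, ht = ht, htUnc = htUnc,
       vs = vs, vt = vt, vtUnc = vtUnc)
}

#' Pons-Petit differentiation statistics (HS, HT, GST; vS, vT, NST)
#'
#' HS is the unweighted mean over populations of the per-population
#' unbiased gene diversity; HT is estimated from the unweighted mean
#' haplotype frequencies with the Nei-Chesser harmonic-mean sample-size
#' correction (the uncorrected form is also reported); GST = 1 - HS/HT.
#' vS, vT and NST = 1 - vS/vT are the analogues in which haplotype
#' identity/non-identity is replaced by the substitution distance
#' d_ij, so that NST exceeds GST when closely related haplotypes tend
#' to co-occur in the same populations (phylogeographic structure).
#'
#' @param tbl a \linkS4class{HaplotypeTable} with at least two
#'   populations of at least two sequences each.
#' @param htEstimator \code{"nei_chesser"} (default) or
#'   \code{"uncorrected"}: which HT/vT variant GST and NST are built on.
#' @return a \linkS4class{DifferentiationResult} (p-value NA until
#'   \code{\link{nstGstTest}} is run).
#' @export
permutStatistics <- function(tbl,
                             htEstimator = c("nei_chesser",
                                             "uncorrected")) {
  htEstimator <- match.arg(htEstimator)
  cn <- hapCounts(tbl)
  if (nrow(cn) < 2) stop("analysis error: need at least 2 populations")
  if (any(rowSums(cn) < 2))
    stop("analysis error: every population needs at least 2 sequences")
  comp <- .permutComponents(cn, hapDist(tbl))
  flags <- character(0)
  ht <- if (htEstimator == "nei_chesser") comp$ht else comp$htUnc
  vt <- if (htEstimator == "nei_chesser") comp$vt else comp$vtUnc
  gst <- if (ht > 0) 1 - comp$hs / ht else {
    flags <- c(flags, "HT = 0: GST undefined"); NA_real_
  }
  nst <- if (vt > 0) 1 - comp$vs / vt else {
    flags <- c(flags, "vT = 0: NST undefined"); NA_real_
  }
  new("DifferentiationResult", hs = comp$hs, ht = comp$ht,
      htUncorrected = comp$htUnc, gst = gst, vs = comp$vs,
      vt = vt, vtUncorrected = comp$vtUnc, nst = nst,
      pValue = NA_real_, nPerm = 0L, seed = NA_integer_,
      flags = flags)
}

#' Permutation test for phylogeographic structure (NST > GST)
#'
#' The null distribution is built by randomly relabelling haplotype
#' identities on the distance matrix (joint permutation of its rows and
#' columns) and recomputing NST - GST each time; GST itself is
#' invariant under the relabelling. The one-sided p-value uses the
#' add-one convention p = (1 + #\{perm >= observed\}) / (B + 1).
#'
#' @inheritParams permutStatistics
#' @param nPerm number of permutations (B), default 1000.
#' @param seed integer seed for reproducibility.
#' @return a \linkS4class{DifferentiationResult} with \code{pValue},
#'   \code{nPerm} and \code{seed} filled in.
#' @export
nstGstTest <- function(tbl, nPerm = 1000L, seed = 1L,
                       htEstimator = c("nei_chesser", "uncorrected")) {
  htEstimator <- match.arg(htEstimator)
  res <- permutStatistics(tbl, htEstimator)
  d <- hapDist(tbl)
  k <- nrow(d)
  if (k < 2) stop("test undefined with fewer than 2 haplotypes")
  if (is.na(res@nst) || is.na(res@gst)) return(res)
  obs <- res@nst - res@gst
  cn <- hapCounts(tbl)
  pick <- function(vt, vs) if (vt > 0) 1 - vs / vt else NA_real_
  set.seed(seed)
  stat <- vapply(seq_len(nPerm), function(b) {
    idx <- sample.int(k)
    comp <- .permutComponents(cn, d[idx, idx, drop = FALSE])
    vt <- if (htEstimator == "nei_chesser") comp$vt else comp$vtUnc
    nst <- pick(vt, comp$vs)
    gst <- 1 - comp$hs /
      (if (htEstimator == "nei_chesser") comp$ht else comp$htUnc)
    nst - gst
  }, numeric(1))
  stat <- stat[!is.na(stat)]
  res@pValue <- (1 + sum(stat >= obs - 1e-12)) / (length(stat) + 1)
  res@nPerm <- as.integer(nPerm)
  res@seed <- as.integer(seed)
  res
}
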