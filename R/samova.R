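#' Spatial AMOVA: search for the K-group partition maximizing FCT
#'
#' Searches partitions of populations into K groups for the one that
#' maximizes the among-group Phi-statistic FCT of the three-level
#' AMOVA. Initialization is geographic: K seed populations are drawn at
#' random and every other population joins its nearest seed by
#' great-circle distance, which encourages (but does not enforce)
#' geographically adjacent groups. Search is simulated annealing over
#' single-population moves between groups (a move is valid only if the
#' donor group stays non-empty), with Metropolis acceptance on the FCT
#' change and geometric cooling; the best partition over all restarts
#' is returned. With the same seed and schedule the result is
#' deterministic.
#'
#' @param tbl a \linkS4class{HaplotypeTable} whose population map has
#'   coordinates for every population.
#' @param k number of groups, 2 <= k <= number of populations.
#' @param nStarts number of annealing restarts (default 100).
#' @param nProposals proposals per restart (default 10000).
#' @param coolingFactor geometric cooling multiplier applied every 100
#'   proposals (default 0.95).
#' @param initTemp initial temperature; \code{NULL} (default)
#'   calibrates it from early proposals so roughly half of them accept.
#' @param seed integer seed.
#' @return a \linkS4class{SamovaResult}.
#' @export
samova <- function(tbl, k, nStarts = 100L, nProposals = 10000L,
                   coolingFactor = 0.95, initTemp = NULL, seed = 1L) {
  cn <- hapCounts(tbl)
  P <- nrow(cn)
  if (k > P) stop("input error: K exceeds the number of populations")
  if (k < 2) stop("input error: K must be at least 2")
  pd <- tbl@popmap@populations
  pd <- pd[match(rownames(cn), pd$population), ]
  if (any(!stats::complete.cases(pd[, c("lat", "lon")])))
    stop("all populations need coordinates for SAMOVA")
  np <- rowSums(cn)
  M <- .pairSumMatrix(cn, hapDist(tbl))
  geo <- outer(seq_len(P), seq_len(P), function(i, j)
    greatCircleKm(pd$lat[i], pd$lon[i], pd$lat[j], pd$lon[j]))

  fct <- function(g) {
    v <- .fctFromPartition(M, np, g)
    if (is.na(v)) -Inf else v
  }
  set.seed(seed)
  if (k == P) {
    g <- seq_len(P)
    return(new("SamovaResult", k = as.integer(k),
               partition = stats::setNames(g, rownames(cn)),
               fct = fct(g), trajectory = data.frame(),
               nStarts = 0L, seed = as.integer(seed)))
  }
  bestG <- NULL; bestF <- -Inf
  for (s in seq_len(nStarts)) {
    seeds <- sample.int(P, k)
    g <- apply(geo[, seeds, drop = FALSE], 1, which.min)
    g[seeds] <- seq_len(k)
    f <- fct(g)
    # temperature calibration: median |dF| of random proposals -> ~50%
    # early acceptance under exp(dF/T)
    temp <- initTemp
    if (is.null(temp)) {
      dfs <- replicate(50, {
        gp <- g
        mv <- sample.int(P, 1)
        if (sum(gp == gp[mv]) > 1) {
          gp[mv] <- sample(setdiff(seq_len(k), gp[mv]), 1)
          abs(fct(gp) - f)
        } else NA_real_
      })
      temp <- stats::median(dfs, na.rm = TRUE) / log(2)
      if (!is.finite(temp) || temp <= 0) temp <- 0.01
    }
    if (f > bestF) { bestF <- f; bestG <- g }
    for (i in seq_len(nProposals)) {
      mv <- sample.int(P, 1)
      if (sum(g == g[mv]) == 1) next  # donor group would empty
      gp <- g
      gp[mv] <- sample(setdiff(seq_len(k), g[mv]), 1)
      fp <- fct(gp)
      if (fp >= f || stats::runif(1) < exp((fp - f) / temp)) {
        g <- gp; f <- fp
        if (f > bestF) { bestF <- f; bestG <- g }
      }
      if (i %% 100 == 0) temp <- temp * coolingFactor
    }
  }
  # canonical group numbering (by first population in each group)
  bestG <- as.integer(factor(bestG, levels = unique(bestG)))
  new("SamovaResult", k = as.integer(k),
      partition = stats::setNames(bestG, rownames(cn)),
      fct = bestF, trajectory = data.frame(),
      nStarts = as.integer(nStarts), seed = as.integer(seed))
}

#' Scan SAMOVA over a range of K
#'
#' Runs \code{\link{samova}} for each K in \code{kRange} and stores the
#' FCT trajectory; \code{\link{fctPlateau}} can then select K.
#'
#' @inheritParams samova
#' @param kRange contiguous integer range of K values (default 2:10).
#' @return a \linkS4class{SamovaResult} for the plateau-selected K,
#'   with the full trajectory in \code{@trajectory}.
#' @export
samovaScan <- function(tbl, kRange = 2:10, nStarts = 100L,
                       nProposals = 10000L, coolingFactor = 0.95,
                       seed = 1L, tol = 0.01) {
  kRange <- kRange[kRange <= nrow(hapCounts(tbl))]
  fits <- lapply(seq_along(kRange), function(i)
    samova(tbl, kRange[i], nStarts = nStarts,
           nProposals = nProposals, coolingFactor = coolingFactor,
           seed = seed + i - 1L))
  traj <- data.frame(K = kRange,
                     fct = vapply(fits, function(f) f@fct, numeric(1)))
  kSel <- fctPlateau(traj$fct, kRange, tol = tol)
  out <- fits[[match(kSel, kRange)]]
  out@trajectory <- traj
  out
}

#' Select K at the FCT plateau
#'
#' Returns the smallest K whose FCT lies within a relative tolerance of
#' the maximum FCT attained at that or any larger K, i.e. the K where
#' the trajectory levels off. A strictly increasing trajectory with no
#' plateau returns the largest K with a warning.
#'
#' @param fct numeric vector of FCT values.
#' @param k integer vector of the corresponding (contiguous) K values.
#' @param tol relative tolerance, default 0.01 (1 percent).
#' @return the selected K.
#' @export
fctPlateau <- function(fct, k = seq_along(fct) + 1L, tol = 0.01) {
  stopifnot(length(fct) == length(k))
  runMax <- rev(cummax(rev(fct)))
  ok <- fct >= runMax * (1 - tol) - 1e-15
  sel <- k[which(ok)[1]]
  if (sel == max(k) && length(k) > 1 &&
      fct[length(fct)] > fct[length(fct) - 1] * (1 + tol))
    warning("FCT still increasing at the largest K; no plateau found")
  sel
}
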