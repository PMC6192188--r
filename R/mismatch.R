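#' Observed mismatch distribution
#'
#' Relative frequency of each pairwise difference count over all
#' N(N-1)/2 individual pairs, computed from haplotype counts and the
#' haplotype distance matrix. Individuals can be pooled across
#' populations or restricted to a subset of haplotypes (e.g. one clade).
#'
#' @param tbl a \linkS4class{HaplotypeTable}.
#' @param haplotypes optional character vector of haplotype ids to pool
#'   (default: all).
#' @return named numeric vector of relative frequencies for classes
#'   \code{0..max}; frequencies sum to 1.
#' @export
mismatchHistogram <- function(tbl, haplotypes = NULL) {
  cn <- colSums(hapCounts(tbl))
  d <- hapDist(tbl)
  if (!is.null(haplotypes)) {
    cn <- cn[haplotypes]
    d <- d[haplotypes, haplotypes, drop = FALSE]
  }
  .mismatchFromCounts(cn, d)
}

.mismatchFromCounts <- function(cn, d) {
  n <- sum(cn)
  if (n < 2) stop("need at least 2 individuals")
  maxd <- max(d)
  counts <- numeric(maxd + 1)
  counts[1] <- sum(choose(cn, 2))  # same-haplotype pairs
  k <- length(cn)
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    counts[d[i, j] + 1] <- counts[d[i, j] + 1] + cn[i] * cn[j]
  stats::setNames(counts / choose(n, 2), 0:maxd)
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Closed-form class probabilities for the stepwise (sudden) expansion
#' model: a population of mutation-scaled size theta0 grows
#' instantaneously to theta1 at tau units of mutational time before the
#' present. For a pair of sequences the coalescence-time density is
#' piecewise exponential and the number of differences is Poisson given
#' the coalescence time; integrating gives, with
#' \eqn{\hat F_i(\theta) = \theta^i/(1+\theta)^{i+1}} (the constant-size
#' geometric) and \eqn{a_m = 1 + 1/\theta_m},
#' \deqn{F_i = \hat F_i(\theta_1)\,[1 - P(\mathrm{Pois}(a_1\tau)\le i)]
#'  + \hat F_i(\theta_0)\, e^{-a_1\tau} \sum_{j=0}^{i}
#'   (a_0\tau)^j / j!.}
#' At tau = 0 this is the geometric with theta0; as tau grows it tends
#' to the geometric with theta1. The theta0 -> 0 limit (the classic
#' two-parameter form, mass e^{-a_1 tau} tau^i / i! in the second term)
#' is handled stably in log space.
#'
#' @param i integer vector of difference classes.
#' @param tau expansion age in mutational units (>= 0).
#' @param theta0,theta1 pre- and post-expansion scaled sizes (>= 0).
#' @return numeric vector of probabilities F_i.
#' @export
#' @examples
#' sum(expectedMismatch(0:400, tau = 3, theta0 = 1, theta1 = 20))  # ~1
expectedMismatch <- function(i, tau, theta0, theta1) {
  .suddenExpansionF(i, tau, theta0, theta1)
}

.geomMismatch <- function(i, th) {
  if (th <= 1e-12) as.numeric(i == 0) else
    exp(i * log(th) - (i + 1) * log1p(th))
}

.suddenExpansionF <- function(i, tau, theta0, theta1) {
  if (tau <= 0) return(.geomMismatch(i, theta0))
  th0 <- max(theta0, 1e-12)
  th1 <- max(theta1, 1e-12)
  a1 <- 1 + 1 / th1
  a0 <- 1 + 1 / th0
  term1 <- .geomMismatch(i, theta1) *
    stats::ppois(i, a1 * tau, lower.tail = FALSE)
  # log F_hat_i(theta0) + log( e^{-a1 tau} sum_{j<=i} (a0 tau)^j / j! )
  lF0 <- i * log(th0) - (i + 1) * log1p(th0)
  lsum <- vapply(i, function(ii) {
    lw <- (0:ii) * log(a0 * tau) - lgamma(1:(ii + 1))
    m <- max(lw)
    m + log(sum(exp(lw - m)))
  }, numeric(1))
  term1 + exp(lF0 - a1 * tau + lsum)
}

#' Harpending's raggedness index
#'
#' r = sum_{i=1}^{d+1} (F_i - F_{i-1})^2 over a histogram spanning
#' classes 0..d, with F_{d+1} = 0 (the empty class beyond the largest
#' difference). Smooth unimodal distributions give small r; ragged,
#' multimodal ones give large r.
#'
#' @param hist numeric vector of relative frequencies; names, if
#'   present, give the classes (default 0..length-1). The histogram is
#'   expanded to span 0..max(class), unlisted classes counting as 0.
#' @return the raggedness index.
#' @export
raggedness <- function(hist) {
  classes <- if (is.null(names(hist))) seq_along(hist) - 1L
             else as.integer(names(hist))
  full <- numeric(max(classes) + 1L)
  full[classes + 1L] <- hist
  sum(diff(c(full, 0))^2)
}

#' Fit the sudden-expansion model to a mismatch histogram
#'
#' Minimizes the sum of squared deviations SSD = sum_i (obs_i - F_i)^2
#' between the observed histogram and \code{\link{expectedMismatch}}
#' over (tau, theta0, theta1), by a coarse grid search refined with
#' derivative-free local optimization (nlminb, then a Nelder-Mead
#' polish). Bounds: tau in [0, 2 max class], theta0, theta1 >= 0; the
#' two thetas are swapped if the optimizer crosses theta1 < theta0.
#'
#' @param hist named numeric vector of observed relative frequencies
#'   (classes 0..max as names).
#' @param profileTheta1Inf fix theta1 at (effectively) infinity, the
#'   original two-parameter sudden-expansion form.
#' @return a \linkS4class{MismatchResult} (bootstrap p-values NA; see
#'   \code{\link{bootstrapGof}}).
#' @export
fitSuddenExpansion <- function(hist, profileTheta1Inf = FALSE) {
  classes <- if (is.null(names(hist))) seq_along(hist) - 1L
             else as.integer(names(hist))
  obs <- as.numeric(hist)
  if (length(obs) < 2 || sum(obs > 0) < 2) {
    return(new("MismatchResult",
               histogram = stats::setNames(obs, classes), tau = 0,
               theta0 = 0, theta1 = 0, ssd = 0, pSsd = NA_real_,
               raggedness = raggedness(hist), pRag = NA_real_,
               nBoot = 0L, seed = NA_integer_,
               flags = "degenerate single-class histogram: tau = 0"))
  }
  BIGTH1 <- 1e6
  ssdOf <- if (profileTheta1Inf)
    function(par) sum((obs - .suddenExpansionF(classes, par[1],
                                               par[2], BIGTH1))^2)
  else
    function(par) sum((obs - .suddenExpansionF(classes, par[1],
                                               par[2], par[3]))^2)
  maxc <- max(classes)
  meanD <- sum(classes * obs) / sum(obs)
  grid <- expand.grid(
    tau = unique(c(seq(0, 2 * maxc, length.out = 17), meanD)),
    theta0 = c(0, 0.1, 0.5, 1, 2, 5),
    theta1 = if (profileTheta1Inf) BIGTH1
             else c(0.5, 1, 2, 5, 10, 50, 200, 1000))
  npar <- if (profileTheta1Inf) 2L else 3L
  vals <- apply(grid[, seq_len(npar), drop = FALSE], 1, ssdOf)
  st <- as.numeric(grid[which.min(vals), seq_len(npar)])
  # theta1 is capped: beyond ~1e6 the expected histogram is flat in
  # theta1 and the parameter is unidentifiable
  upper <- c(2 * maxc, Inf, 1e6)[seq_len(npar)]
  fit <- stats::nlminb(st, ssdOf, lower = rep(0, npar),
                       upper = upper,
                       control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                      iter.max = 2000))
  nm <- stats::optim(fit$par, ssdOf, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-15,
                                    warn.1d.NelderMead = FALSE))
  par <- if (nm$value < fit$objective) nm$par else fit$par
  par <- pmax(par, 0)
  par[1] <- min(par[1], 2 * maxc)
  if (npar == 3) par[3] <- min(par[3], 1e6)
  if (profileTheta1Inf) par <- c(par, Inf)
  if (is.finite(par[3]) && par[3] < par[2]) par[2:3] <- sort(par[2:3])
  new("MismatchResult", histogram = stats::setNames(obs, classes),
      tau = par[1], theta0 = par[2], theta1 = par[3],
      ssd = ssdOf(par[seq_len(npar)]), pSsd = NA_real_,
      raggedness = raggedness(hist), pRag = NA_real_, nBoot = 0L,
      seed = NA_integer_, flags = character(0))
}

#' Parametric bootstrap goodness of fit for the sudden-expansion model
#'
#' Simulates B coalescent samples of the same size under the fitted
#' sudden-expansion parameters, refits the model to each simulated
#' mismatch histogram, and reports add-one p-values for the SSD and
#' raggedness statistics, p = (1 + #\{boot >= observed\}) / (B + 1).
#'
#' @param fit a \linkS4class{MismatchResult} from
#'   \code{\link{fitSuddenExpansion}}.
#' @param nIndividuals sample size for the simulations.
#' @param nBoot number of bootstrap replicates B (> 0).
#' @param seed integer seed.
#' @return the \linkS4class{MismatchResult} with \code{pSsd},
#'   \code{pRag}, \code{nBoot} and \code{seed} filled in.
#' @export
bootstrapGof <- function(fit, nIndividuals, nBoot = 1000L, seed = 1L) {
  if (nBoot < 1) stop("nBoot must be positive")
  set.seed(seed)
  seeds <- sample.int(2147483646L, nBoot)
  th1 <- if (is.finite(fit@theta1)) fit@theta1 else 1e6
  ssdB <- ragB <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    pd <- simulateSuddenExpansion(nIndividuals, L = 100000L,
                                  tau = fit@tau, theta0 = fit@theta0,
                                  theta1 = th1, seed = seeds[b],
                                  returnWhat = "pairDiffs")
    bf <- fitSuddenExpansion(.histFromPairDiffs(pd))
    ssdB[b] <- bf@ssd
    ragB[b] <- bf@raggedness
  }
  fit@pSsd <- (1 + sum(ssdB >= fit@ssd - 1e-15)) / (nBoot + 1)
  fit@pRag <- (1 + sum(ragB >= fit@raggedness - 1e-15)) / (nBoot + 1)
  fit@nBoot <- as.integer(nBoot)
  fit@seed <- as.integer(seed)
  fit
}

.histFromPairDiffs <- function(pd) {
  tab <- tabulate(pd + 1L, nbins = max(pd) + 1L)
  stats::setNames(tab / sum(tab), 0:max(pd))
}
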