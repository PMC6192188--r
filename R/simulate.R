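# Coalescent-style simulator: Kingman coalescent with island-model
# migration, piecewise-constant deme size, and infinite-sites mutation
# over L alignment columns.
#
# Scaling: theta is the mutation-scaled deme size (theta = 4*N*u with u
# the per-generation locus-wide rate), so the expected pairwise
# difference within a constant-size deme is theta. Time is measured in
# units of 1/(2u) generations; in those units a pair of lineages
# coalesces at rate 1/theta and each lineage mutates at rate 1/2, and a
# size change "tau before present" matches the tau of the mismatch
# sudden-expansion model.

# genealogy for lineages across demes; returns branches as a list of
# (length, leaf set) used to drop mutations
.coalesceGenealogy <- function(sampleSizes, theta1, theta0 = theta1,
                               tau = Inf, migration = 0) {
  D <- length(sampleSizes)
  n <- sum(sampleSizes)
  if (D > 1 && migration <= 0)
    stop("island model needs a positive migration rate")
  deme <- rep(seq_len(D), sampleSizes)
  sets <- as.list(seq_len(n))
  born <- rep(0, n)
  t <- 0
  branches <- vector("list", 2 * n)
  nb <- 0
  repeat {
    k <- length(sets)
    if (k == 1) break
    th <- if (t < tau) theta1 else theta0
    kd <- tabulate(deme, nbins = D)
    crate <- sum(choose(kd, 2)) / th
    mrate <- if (D > 1) k * migration else 0
    rate <- crate + mrate
    if (rate <= 0) stop("stuck genealogy: no possible events")
    dt <- stats::rexp(1, rate)
    if (t < tau && t + dt > tau) { t <- tau; next }  # epoch boundary
    t <- t + dt
    if (stats::runif(1) < crate / rate) {
      # coalescence: pick a deme weighted by its pair count
      dsel <- sample.int(D, 1, prob = choose(kd, 2))
      pair <- sample(which(deme == dsel), 2)
      for (x in pair) {
        nb <- nb + 1
        branches[[nb]] <- list(len = t - born[x], set = sets[[x]])
      }
      sets[[pair[1]]] <- c(sets[[pair[1]]], sets[[pair[2]]])
      born[pair[1]] <- t
      sets[[pair[2]]] <- NULL
      keep <- setdiff(seq_len(k), pair[2])
      deme <- deme[keep]
      born <- born[keep]
    } else {
      x <- sample.int(k, 1)
      deme[x] <- sample(setdiff(seq_len(D), deme[x]), 1)
    }
  }
  branches[seq_len(nb)]
}

# 0/1 genotype matrix (n x S) from a genealogy, infinite sites
.dropMutations <- function(branches, n) {
  lens <- vapply(branches, `[[`, numeric(1), "len")
  muts <- stats::rpois(length(lens), lens / 2)
  S <- sum(muts)
  G <- matrix(0L, n, S)
  col <- 0
  for (i in seq_along(branches)) {
    if (muts[i] > 0) for (j in seq_len(muts[i])) {
      col <- col + 1
      G[branches[[i]]$set, col] <- 1L
    }
  }
  G
}

.pairDiffsFromG <- function(G) {
  n <- nrow(G)
  if (ncol(G) == 0) {
    pd <- rep(0L, n * (n - 1) / 2)
  } else {
    Dm <- G %*% t(1 - G)
    Dm <- Dm + t(Dm)
    pd <- as.integer(Dm[lower.tri(Dm)])
  }
  attr(pd, "nHaplotypes") <-
    if (ncol(G) == 0) 1L else nrow(unique(G))
  attr(pd, "S") <- ncol(G)   # infinite sites: one column per mutation
  pd
}

# emit an aligned DNAStringSet: random ancestral bases, each mutation a
# distinct column with a different derived base
.sequencesFromG <- function(G, L, ids) {
  n <- nrow(G); S <- ncol(G)
  if (S > L) stop("more mutations than sites; increase L")
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  cols <- if (S > 0) sample.int(L, S) else integer(0)
  mat <- matrix(rep(anc, each = n), n, L)
  for (s in seq_len(S)) {
    der <- sample(setdiff(bases, anc[cols[s]]), 1)
    mat[G[, s] == 1L, cols[s]] <- der
  }
  seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(seqs) <- ids
  seqs
}

#' Simulate a multi-population dataset under the coalescent
#'
#' Kingman coalescent with island-model migration, optional sudden
#' expansion (scaled size theta0 before, theta1 after, switching tau
#' mutational units before the present), and infinite-sites mutation
#' over L alignment columns. Population coordinates are laid out on a
#' regular grid so spatial procedures can run on the output.
#'
#' @param nPops number of populations (demes).
#' @param sampleSizes per-population sample sizes (recycled).
#' @param theta mutation-scaled deme size (expected within-deme
#'   pairwise difference); 0 gives identical sequences.
#' @param migration per-lineage scaled migration rate (required > 0
#'   when nPops > 1).
#' @param expansion \code{NULL} for constant size, or
#'   \code{list(tau =, theta0 =)} for a sudden expansion.
#' @param L alignment length in bp.
#' @param seed integer seed; the output is reproducible bit-for-bit.
#' @return list with \code{alignment} (\code{DNAStringSet}) and
#'   \code{popmap} (\linkS4class{PopulationMap}).
#' @export
simulateDataset <- function(nPops = 1L, sampleSizes = 20L, theta = 1,
                            migration = 1, expansion = NULL,
                            L = 1000L, seed = 1L) {
  set.seed(seed)
  sampleSizes <- rep_len(sampleSizes, nPops)
  n <- sum(sampleSizes)
  tau <- if (is.null(expansion)) Inf else expansion$tau
  theta0 <- if (is.null(expansion)) theta else expansion$theta0
  if (theta <= 0) {
    G <- matrix(0L, n, 0)
  } else {
    br <- .coalesceGenealogy(sampleSizes, theta1 = theta,
                             theta0 = theta0, tau = tau,
                             migration = migration)
    G <- .dropMutations(br, n)
  }
  pops <- sprintf("P%02d", seq_len(nPops))
  popOf <- rep(pops, sampleSizes)
  ids <- paste0(popOf, "_", unlist(lapply(sampleSizes, seq_len)))
  aln <- .sequencesFromG(G, L, ids)
  side <- ceiling(sqrt(nPops))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side))[
    seq_len(nPops), ]
  pm <- new("PopulationMap",
    individuals = data.frame(individual = ids, population = popOf,
                             stringsAsFactors = FALSE),
    populations = data.frame(population = pops,
                             lat = 30 + grid$y, lon = 90 + grid$x,
                             elevation = NA_real_,
                             stringsAsFactors = FALSE))
  list(alignment = aln, popmap = pm)
}

#' Simulate a sample under the sudden-expansion model
#'
#' Single panmictic population whose scaled size switches from theta1
#' (present) to theta0 at tau mutational units before the present;
#' used by the mismatch parametric bootstrap and by parameter-recovery
#' tests. \code{tau = 0} (or \code{theta0 = theta1}) reduces to the
#' constant-size coalescent.
#'
#' @param n sample size.
#' @param L alignment length in bp.
#' @param tau expansion age in mutational units.
#' @param theta0,theta1 pre-/post-expansion scaled sizes.
#' @param seed integer seed.
#' @param returnWhat \code{"alignment"} for a \code{DNAStringSet},
#'   \code{"pairDiffs"} for the integer vector of pairwise differences
#'   (with attribute \code{nHaplotypes}), which skips sequence
#'   emission.
#' @return see \code{returnWhat}.
#' @export
simulateSuddenExpansion <- function(n, L = 1000L, tau, theta0, theta1,
                                    seed = 1L,
                                    returnWhat = c("alignment",
                                                   "pairDiffs")) {
  returnWhat <- match.arg(returnWhat)
  set.seed(seed)
  th0 <- max(theta0, 1e-12)
  th1 <- max(theta1, 1e-12)
  # tau = 0: the expansion is at the present, i.e. constant size theta0
  tauEff <- if (tau <= 0) Inf else tau
  if (tau <= 0) th1 <- th0
  br <- .coalesceGenealogy(n, theta1 = th1, theta0 = th0,
                           tau = tauEff)
  G <- .dropMutations(br, n)
  if (returnWhat == "pairDiffs") return(.pairDiffsFromG(G))
  .sequencesFromG(G, L, sprintf("ind%03d", seq_len(n)))
}
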