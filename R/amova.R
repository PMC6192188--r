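# Hierarchical analysis of molecular variance on squared inter-haplotype
# distances (Excoffier-style). The squared molecular distance between two
# individuals is the substitution count d_ij between the haplotypes they
# carry; sums of squares come from the pairwise-distance identity
# SS(set) = sum_{x<y} delta^2 / |set|.

# ordered pop-pair sums of delta^2: M[p,q] = sum_{x in p, y in q} delta^2
# (within-population unordered pair sum is diag(M)/2)
.pairSumMatrix <- function(cn, d) cn %*% d %*% t(cn)

# variance components for a grouped design from the pop-pair sum matrix
.amovaComponents <- function(M, np, gvec) {
  P <- length(np); N <- sum(np)
  gf <- factor(gvec)
  G <- nlevels(gf)
  ssdTotal <- sum(M) / 2 / N
  ssdWP <- sum(diag(M) / 2 / np)
  Ng <- as.vector(rowsum(np, gf))
  Mg <- rowsum(t(rowsum(M, gf)), gf)  # group-by-group pair sums
  ssdWG <- sum(diag(Mg) / 2 / Ng)
  ssAG <- ssdTotal - ssdWG
  ssAP <- ssdWG - ssdWP
  ssWP <- ssdWP
  dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
  sumsq <- as.vector(rowsum(np^2, gf)) / Ng
  Vc <- ssWP / dfWP
  if (dfAP > 0) {
    n1 <- (N - sum(sumsq)) / dfAP
    Vb <- (ssAP / dfAP - Vc) / n1
  } else {
    n1 <- NA_real_; Vb <- 0   # every population its own group
  }
  if (dfAG > 0) {
    n2 <- (sum(sumsq) - sum(np^2) / N) / dfAG
    n3 <- (N - sum(Ng^2) / N) / dfAG
    Va <- (ssAG / dfAG - Vc - n2 * Vb) / n3
  } else {
    Va <- NA_real_
  }
  list(ss = c(ssAG, ssAP, ssWP), df = c(dfAG, dfAP, dfWP),
       vc = c(Va, Vb, Vc), singletonOnly = dfAP == 0)
}

.fctFromPartition <- function(M, np, gvec) {
  cm <- .amovaComponents(M, np, gvec)
  tot <- sum(cm$vc)
  if (!is.finite(tot) || tot == 0) return(NA_real_)
  cm$vc[1] / tot
}

# counts matrix from individual-level hap/pop index vectors
.countsFromInd <- function(hap, pop, P, H)
  matrix(tabulate((hap - 1L) * P + pop, nbins = P * H), P, H)

#' Analysis of molecular variance (AMOVA)
#'
#' Decomposes molecular variance among groups of populations, among
#' populations within groups, and within populations (or, without
#' groups, among and within populations), using squared inter-haplotype
#' substitution distances. Phi-statistics are tested by the standard
#' per-statistic permutation schemes: individuals among populations
#' (FST), individuals among populations within groups (FSC), and whole
#' populations among groups (FCT), with the add-one p-value convention.
#'
#' @param tbl a \linkS4class{HaplotypeTable} with at least two
#'   populations.
#' @param groups optional named vector (population -> group) defining a
#'   partition of the populations; names must match \code{popNames(tbl)}.
#' @param nPerm number of permutations (0 to skip inference).
#' @param seed integer seed.
#' @return an \linkS4class{AmovaResult}.
#' @export
#' @examples
#' fx <- makePaperFixture("cpDNA")
#' am <- amova(fx$table, nPerm = 99)
#' am@phi["FST"]
amova <- function(tbl, groups = NULL, nPerm = 1000L, seed = 1L) {
  cn <- hapCounts(tbl)
  d <- hapDist(tbl)
  P <- nrow(cn); H <- ncol(cn)
  if (P < 2) stop("analysis error: need at least 2 populations")
  np <- rowSums(cn)
  N <- sum(np)
  pops <- rownames(cn)
  flags <- character(0)

  if (!is.null(groups)) {
    if (is.null(names(groups))) names(groups) <- pops
    if (!setequal(names(groups), pops))
      stop("groups must cover exactly the populations of the table")
    gvec <- as.integer(factor(groups[pops]))
    if (length(unique(gvec)) < 2)
      stop("analysis error: need at least 2 groups")
  } else gvec <- NULL

  # individual-level vectors for permutation schemes
  hap <- integer(0); pop <- integer(0)
  for (p in seq_len(P)) for (hh in seq_len(H)) {
    if (cn[p, hh] > 0) {
      hap <- c(hap, rep.int(hh, cn[p, hh]))
      pop <- c(pop, rep.int(p, cn[p, hh]))
    }
  }

  M <- .pairSumMatrix(cn, d)
  if (sum(M) == 0) flags <- c(flags, "zero total variance: Phi undefined")

  if (is.null(gvec)) {
    ssdTotal <- sum(M) / 2 / N
    ssdWP <- sum(diag(M) / 2 / np)
    ssAP <- ssdTotal - ssdWP
    dfAP <- P - 1; dfWP <- N - P
    Vc <- ssdWP / dfWP
    n0 <- (N - sum(np^2) / N) / dfAP
    Va <- (ssAP / dfAP - Vc) / n0
    tot <- Va + Vc
    fst <- if (is.finite(tot) && tot != 0) Va / tot else NA_real_
    tabl <- data.frame(
      source = c("Among populations", "Within populations", "Total"),
      df = c(dfAP, dfWP, dfAP + dfWP),
      SS = c(ssAP, ssdWP, ssdTotal),
      VC = c(Va, Vc, tot),
      PV = 100 * c(Va, Vc, tot) / tot)
    phi <- c(FST = fst)
    pv <- c(FST = NA_real_)
    if (nPerm > 0 && !is.na(fst)) {
      set.seed(seed)
      stat <- vapply(seq_len(nPerm), function(b) {
        hp <- hap[sample.int(N)]
        C2 <- .countsFromInd(hp, pop, P, H)
        M2 <- .pairSumMatrix(C2, d)
        Vc2 <- sum(diag(M2) / 2 / np) / dfWP
        Va2 <- ((sum(M2) / 2 / N - sum(diag(M2) / 2 / np)) / dfAP - Vc2) / n0
        t2 <- Va2 + Vc2
        if (t2 == 0) NA_real_ else Va2 / t2
      }, numeric(1))
      stat <- stat[!is.na(stat)]
      pv["FST"] <- (1 + sum(stat >= fst - 1e-12)) / (length(stat) + 1)
    }
    groupsOut <- integer(0)
  } else {
    cm <- .amovaComponents(M, np, gvec)
    Va <- cm$vc[1]; Vb <- cm$vc[2]; Vc <- cm$vc[3]
    tot <- sum(cm$vc)
    und <- !is.finite(tot) || tot == 0
    fct <- if (und) NA_real_ else Va / tot
    fst <- if (und) NA_real_ else (Va + Vb) / tot
    fsc <- if (!und && Vb + Vc != 0 && !cm$singletonOnly)
      Vb / (Vb + Vc) else NA_real_
    if (cm$singletonOnly)
      flags <- c(flags, "all groups are single populations: FSC undefined")
    tabl <- data.frame(
      source = c("Among groups", "Among populations within groups",
                 "Within populations", "Total"),
      df = c(cm$df, sum(cm$df)),
      SS = c(cm$ss, sum(cm$ss)),
      VC = c(cm$vc, tot),
      PV = 100 * c(cm$vc, tot) / tot)
    phi <- c(FCT = fct, FSC = fsc, FST = fst)
    pv <- c(FCT = NA_real_, FSC = NA_real_, FST = NA_real_)
    if (nPerm > 0 && !und) {
      set.seed(seed)
      G <- length(unique(gvec))
      # FCT: permute whole populations among groups
      statCT <- vapply(seq_len(nPerm), function(b)
        .fctFromPartition(M, np, gvec[sample.int(P)]), numeric(1))
      statCT <- statCT[!is.na(statCT)]
      pv["FCT"] <- (1 + sum(statCT >= fct - 1e-12)) / (length(statCT) + 1)
      # FSC: permute individuals among populations within groups
      if (!is.na(fsc)) {
        statSC <- vapply(seq_len(nPerm), function(b) {
          hp <- hap
          for (g in seq_len(G)) {
            sel <- which(gvec[pop] == g)
            hp[sel] <- hp[sel][sample.int(length(sel))]
          }
          C2 <- .countsFromInd(hp, pop, P, H)
          cm2 <- .amovaComponents(.pairSumMatrix(C2, d), np, gvec)
          den <- cm2$vc[2] + cm2$vc[3]
          if (den == 0) NA_real_ else cm2$vc[2] / den
        }, numeric(1))
        statSC <- statSC[!is.na(statSC)]
        pv["FSC"] <- (1 + sum(statSC >= fsc - 1e-12)) / (length(statSC) + 1)
      }
      # FST: permute individuals among all populations
      statST <- vapply(seq_len(nPerm), function(b) {
        hp <- hap[sample.int(N)]
        C2 <- .countsFromInd(hp, pop, P, H)
        cm2 <- .amovaComponents(.pairSumMatrix(C2, d), np, gvec)
        t2 <- sum(cm2$vc)
        if (!is.finite(t2) || t2 == 0) NA_real_ else
          (cm2$vc[1] + cm2$vc[2]) / t2
      }, numeric(1))
      statST <- statST[!is.na(statST)]
      pv["FST"] <- (1 + sum(statST >= fst - 1e-12)) / (length(statST) + 1)
    }
    groupsOut <- stats::setNames(gvec, pops)
  }
  new("AmovaResult", table = tabl, phi = phi, pValues = pv,
      groups = groupsOut, nPerm = as.integer(nPerm),
      seed = as.integer(seed), flags = flags)
}

#' Pairwise Phi-ST between populations
#'
#' Two-population AMOVA Phi-ST for every population pair, optionally
#' linearized as PhiST/(1 - PhiST) for isolation-by-distance analysis.
#'
#' @param tbl a \linkS4class{HaplotypeTable}.
#' @param linearize return PhiST/(1 - PhiST) (values of 1 give Inf).
#' @return symmetric matrix of pairwise distances (NA where undefined).
#' @export
pairwisePhiST <- function(tbl, linearize = FALSE) {
  cn <- hapCounts(tbl)
  d <- hapDist(tbl)
  P <- nrow(cn)
  out <- matrix(0, P, P, dimnames = list(rownames(cn), rownames(cn)))
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    sub <- cn[c(i, j), , drop = FALSE]
    np <- rowSums(sub); N <- sum(np)
    M <- .pairSumMatrix(sub, d)
    Vc <- sum(diag(M) / 2 / np) / (N - 2)
    n0 <- (N - sum(np^2) / N)
    Va <- ((sum(M) / 2 / N - sum(diag(M) / 2 / np)) - Vc) / n0
    tot <- Va + Vc
    # no molecular variance in the pair (both monomorphic for the same
    # haplotype): no differentiation, distance 0
    out[i, j] <- out[j, i] <- if (tot == 0) 0 else Va / tot
  }
  if (linearize) out <- out / (1 - out)
  diag(out) <- 0
  out
}
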