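# Independent brute-force oracles used to validate the implementation.

# haplotype partition by all-pairs string comparison on columns that
# are clean (A/C/G/T) in every sequence
bruteHapPartition <- function(seqs) {
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  sub <- mat[, keep, drop = FALSE]
  n <- nrow(sub)
  grp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (grp[i] == 0L) {
      nxt <- nxt + 1L
      grp[i] <- nxt
      if (i < n) for (j in (i + 1L):n)
        if (grp[j] == 0L && all(sub[i, ] == sub[j, ])) grp[j] <- nxt
    }
  }
  grp
}

# AMOVA from individual-level squared distances by explicit summation
# and the nested moment equations (independent of the package's
# count-matrix algebra). hap/pop are integer vectors per individual,
# gOfPop maps population index -> group index (NULL = two-level).
bruteAmova <- function(hap, pop, D, gOfPop = NULL) {
  N <- length(hap)
  delta2 <- function(x, y) D[hap[x], hap[y]]
  ssWithin <- function(members) {
    s <- 0
    if (length(members) > 1)
      for (a in seq_along(members)[-length(members)])
        for (b in (a + 1):length(members))
          s <- s + delta2(members[a], members[b])
    s / length(members)
  }
  P <- length(unique(pop))
  np <- as.vector(table(factor(pop, levels = seq_len(P))))
  ssdTot <- ssWithin(seq_len(N))
  ssdWP <- sum(vapply(seq_len(P), function(p)
    ssWithin(which(pop == p)), numeric(1)))
  if (is.null(gOfPop)) {
    ssAP <- ssdTot - ssdWP
    dfAP <- P - 1; dfWP <- N - P
    Vc <- ssdWP / dfWP
    n0 <- (N - sum(np^2) / N) / dfAP
    Va <- (ssAP / dfAP - Vc) / n0
    list(ss = c(ssAP, ssdWP), vc = c(Va, Vc),
         fst = Va / (Va + Vc))
  } else {
    G <- length(unique(gOfPop))
    gInd <- gOfPop[pop]
    ssdWG <- sum(vapply(seq_len(G), function(g)
      ssWithin(which(gInd == g)), numeric(1)))
    ssAG <- ssdTot - ssdWG
    ssAP <- ssdWG - ssdWP
    dfAG <- G - 1; dfAP <- P - G; dfWP <- N - P
    Vc <- ssdWP / dfWP
    Ng <- vapply(seq_len(G), function(g) sum(np[gOfPop == g]),
                 numeric(1))
    sq <- vapply(seq_len(G), function(g)
      sum(np[gOfPop == g]^2) / Ng[g], numeric(1))
    n1 <- (N - sum(sq)) / dfAP
    n2 <- (sum(sq) - sum(np^2) / N) / dfAG
    n3 <- (N - sum(Ng^2) / N) / dfAG
    Vb <- (ssAP / dfAP - Vc) / n1
    Va <- (ssAG / dfAG - Vc - n2 * Vb) / n3
    tot <- Va + Vb + Vc
    list(ss = c(ssAG, ssAP, ssdWP), vc = c(Va, Vb, Vc),
         fct = Va / tot, fsc = Vb / (Vb + Vc), fst = (Va + Vb) / tot)
  }
}

# Tajima's D written out independently, coefficient by coefficient
tajimaOracle <- function(n, S, khat) {
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * n - 3)
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (khat - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

# raggedness written from the difference definition over classes 0..d
raggednessOracle <- function(freqs, classes) {
  d <- max(classes)
  F <- numeric(d + 2)           # classes 0..d plus empty class d+1
  F[classes + 1] <- freqs
  sum((F[2:(d + 2)] - F[1:(d + 1)])^2)
}

# random haplotype table for property tests
randomHapTable <- function(nPops = 4, nHaps = 5, lambda = 4,
                           maxDist = 6, withCoords = FALSE) {
  cnt <- matrix(rpois(nPops * nHaps, lambda) + 1L, nPops, nHaps,
                dimnames = list(paste0("p", seq_len(nPops)),
                                paste0("H", seq_len(nHaps))))
  d <- matrix(sample(0:maxDist, nHaps * nHaps, TRUE), nHaps, nHaps)
  d <- d + t(d); diag(d) <- 0
  dimnames(d) <- list(colnames(cnt), colnames(cnt))
  pd <- if (withCoords)
    data.frame(population = rownames(cnt),
               lat = runif(nPops, 25, 35),
               lon = runif(nPops, 85, 100), elevation = NA_real_)
  else NULL
  haplotypeTableFromCounts(cnt, d, L = 100, popData = pd)
}

# individual-level vectors from a count matrix (population-major order)
indVectorsFromCounts <- function(cnt) {
  hap <- integer(0); pop <- integer(0)
  for (p in seq_len(nrow(cnt))) for (h in seq_len(ncol(cnt))) {
    hap <- c(hap, rep(h, cnt[p, h]))
    pop <- c(pop, rep(p, cnt[p, h]))
  }
  list(hap = hap, pop = pop)
}
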