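#' Collapse aligned sequences into haplotypes
#'
#' Mirrors the classic DnaSP treatment: alignment columns containing a
#' gap, \code{N} or an IUPAC ambiguity code in any record are removed
#' (policy \code{"exclude_columns"}, the default), then two sequences
#' share a haplotype iff they are identical at every retained column.
#' Haplotypes are numbered in order of first appearance (H1, H2, ...).
#' Pairwise haplotype distances are substitution counts over the
#' retained columns; segregating sites are the retained polymorphic
#' columns.
#'
#' Under policy \code{"pairwise_complete"} all columns are retained for
#' haplotype definition (exact string identity) and each pairwise
#' distance counts only columns where both representatives carry an
#' unambiguous base; the distance is then not guaranteed to be a metric.
#'
#' @param aln a \code{DNAStringSet} of equal-length aligned sequences
#'   (see \code{\link{readAlignment}}).
#' @param gapPolicy \code{"exclude_columns"} or \code{"pairwise_complete"}.
#' @param hapPrefix label prefix, e.g. \code{"H"} for chlorotypes or
#'   \code{"R"} for ribotypes.
#' @return a list with elements \code{assignment} (named character,
#'   individual -> haplotype id), \code{hapSeq} (named character of
#'   representatives over retained columns), \code{distMat} (symmetric
#'   substitution-count matrix), \code{segSites} (original column
#'   indices of segregating sites) and \code{L} (alignment length).
#' @export
#' @examples
#' fx <- makePaperFixture("cpDNA")
#' ch <- collapseHaplotypes(fx$alignment)
#' length(ch$hapSeq)          # 6 haplotypes
#' length(ch$segSites)        # 7 segregating sites
collapseHaplotypes <- function(aln,
                               gapPolicy = c("exclude_columns",
                                             "pairwise_complete"),
                               hapPrefix = "H") {
  gapPolicy <- match.arg(gapPolicy)
  if (length(aln) < 1L) stop("empty alignment")
  mat <- .alnMatrix(aln)
  L <- ncol(mat)
  clean <- mat %in% c("A", "C", "G", "T")
  dim(clean) <- dim(mat)
  if (gapPolicy == "exclude_columns") {
    keep <- which(colSums(clean) == nrow(mat))
    if (length(keep) == 0L)
      stop("analysis error: no columns retained under gap policy")
    sub <- mat[, keep, drop = FALSE]
  } else {
    keep <- seq_len(L)
    sub <- mat
  }
  key <- apply(sub, 1L, paste, collapse = "")
  firsts <- !duplicated(key)
  reps <- key[firsts]
  hapIds <- paste0(hapPrefix, seq_along(reps))
  names(reps) <- hapIds
  assignment <- hapIds[match(key, reps)]
  names(assignment) <- rownames(mat)

  repMat <- sub[firsts, , drop = FALSE]
  k <- length(reps)
  d <- matrix(0, k, k, dimnames = list(hapIds, hapIds))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      a <- repMat[i, ]; b <- repMat[j, ]
      if (gapPolicy == "pairwise_complete") {
        ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
        d[i, j] <- d[j, i] <- sum(a[ok] != b[ok])
      } else {
        d[i, j] <- d[j, i] <- sum(a != b)
      }
    }
  }
  poly <- apply(repMat, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    length(unique(col)) > 1L
  })
  list(assignment = assignment, hapSeq = reps, distMat = d,
       segSites = as.integer(keep[poly]), L = as.integer(L))
}

.alnMatrix <- function(aln) {
  if (is.matrix(aln)) {
    mat <- toupper(aln)
  } else {
    ch <- toupper(as.character(aln))
    if (length(unique(nchar(ch))) != 1L)
      stop("alignment error: sequences have unequal lengths")
    mat <- do.call(rbind, strsplit(ch, ""))
    rownames(mat) <- if (is.null(names(aln)))
      paste0("seq", seq_along(ch)) else names(aln)
  }
  mat
}

#' Tabulate haplotypes by population
#'
#' Builds the population-by-haplotype count matrix (the machine form of
#' a classic haplotype-frequency table) from a haplotype assignment and
#' a population map. Populations appear in map order, haplotypes in
#' discovery order.
#'
#' @param collapsed the list returned by \code{\link{collapseHaplotypes}}.
#' @param popmap a \linkS4class{PopulationMap} covering every assigned
#'   individual.
#' @return a \linkS4class{HaplotypeTable}.
#' @export
tabulateByPopulation <- function(collapsed, popmap) {
  asn <- collapsed$assignment
  ind <- popmap@individuals
  missing <- setdiff(names(asn), ind$individual)
  if (length(missing))
    stop("individuals missing from population map: ",
         paste(utils::head(missing, 5), collapse = ", "))
  pops <- popmap@populations$population
  haps <- names(collapsed$hapSeq)
  cnt <- matrix(0L, nrow = length(pops), ncol = length(haps),
                dimnames = list(pops, haps))
  popOf <- ind$population[match(names(asn), ind$individual)]
  tab <- table(factor(popOf, levels = pops),
               factor(asn, levels = haps))
  cnt[] <- as.integer(tab)
  new("HaplotypeTable", counts = cnt, hapSeq = collapsed$hapSeq,
      distMat = collapsed$distMat, segSites = collapsed$segSites,
      L = collapsed$L, assignment = asn, popmap = popmap)
}

#' Build a HaplotypeTable directly from counts
#'
#' Convenience constructor for analyses that start from a published
#' haplotype-frequency table rather than raw sequences (e.g. when only
#' per-population counts and a distance matrix are available).
#'
#' @param counts population-by-haplotype count matrix with dimnames.
#' @param distMat optional symmetric haplotype distance matrix (defaults
#'   to all off-diagonal distances 1).
#' @param L alignment length in bp (default 1).
#' @param popData optional data.frame with columns population, lat, lon
#'   (decimal degrees or DMS strings), elevation.
#' @return a \linkS4class{HaplotypeTable}.
#' @export
haplotypeTableFromCounts <- function(counts, distMat = NULL, L = 1L,
                                     popData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("pop", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("H", seq_len(ncol(counts)))
  if (is.null(distMat)) {
    k <- ncol(counts)
    distMat <- matrix(1, k, k,
                      dimnames = list(colnames(counts), colnames(counts)))
    diag(distMat) <- 0
  }
  if (is.null(popData))
    popData <- data.frame(population = rownames(counts),
                          lat = NA_real_, lon = NA_real_,
                          elevation = NA_real_)
  if (is.character(popData$lat)) popData$lat <- parseDms(popData$lat)
  if (is.character(popData$lon)) popData$lon <- parseDms(popData$lon)
  if (is.null(popData$elevation)) popData$elevation <- NA_real_
  # synthesize one individual per sampled sequence so individual-level
  # procedures (AMOVA permutations, mismatch) work from counts alone
  asn <- character(0); indPop <- character(0)
  for (p in rownames(counts)) for (hp in colnames(counts)) {
    n <- counts[p, hp]
    if (n > 0) {
      ids <- paste0(p, "_", hp, "_", seq_len(n))
      asn[ids] <- hp
      indPop <- c(indPop, rep(p, n))
    }
  }
  pm <- new("PopulationMap",
            individuals = data.frame(individual = names(asn),
                                     population = indPop,
                                     stringsAsFactors = FALSE),
            populations = popData[, c("population", "lat", "lon",
                                      "elevation")])
  hapSeq <- stats::setNames(rep("", ncol(counts)), colnames(counts))
  new("HaplotypeTable", counts = counts, hapSeq = hapSeq,
      distMat = as.matrix(distMat), segSites = integer(0),
      L = as.integer(L), assignment = asn, popmap = pm)
}
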