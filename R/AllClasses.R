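#' @import methods
NULL

#' Population map: individuals, populations and coordinates
#'
#' Links every sequenced individual to a sampling population and carries
#' per-population metadata (decimal-degree latitude/longitude, elevation).
#' Coordinates may be missing for some populations, in which case spatial
#' analyses (SAMOVA, Mantel) are unavailable for them.
#'
#' @slot individuals data.frame with columns \code{individual},
#'   \code{population}; one row per sequenced individual.
#' @slot populations data.frame with columns \code{population},
#'   \code{lat}, \code{lon}, \code{elevation}; one row per population,
#'   in input order.
#' @exportClass PopulationMap
setClass("PopulationMap",
  representation(individuals = "data.frame", populations = "data.frame"),
  validity = function(object) {
    msg <- character()
    ind <- object@individuals
    pop <- object@populations
    if (!all(c("individual", "population") %in% names(ind)))
      msg <- c(msg, "individuals needs columns 'individual' and 'population'")
    if (!all(c("population", "lat", "lon") %in% names(pop)))
      msg <- c(msg, "populations needs columns 'population', 'lat', 'lon'")
    if (anyDuplicated(ind$individual))
      msg <- c(msg, "individuals mapped more than once")
    if (anyDuplicated(pop$population))
      msg <- c(msg, "duplicated population labels")
    if (!all(ind$population %in% pop$population))
      msg <- c(msg, "individuals assigned to unknown populations")
    ok <- stats::complete.cases(pop[, c("lat", "lon")])
    if (any(abs(pop$lat[ok]) > 90) || any(abs(pop$lon[ok]) > 180))
      msg <- c(msg, "coordinates outside [-90,90] x [-180,180]")
    if (length(msg)) msg else TRUE
  })

#' Haplotype-by-population count table
#'
#' The central container of the package: haplotypes discovered in an
#' alignment, their representative sequences over the retained columns,
#' the matrix of pairwise substitution distances between haplotypes, and
#' a population-by-haplotype count matrix.
#'
#' @slot counts integer matrix, populations (rows) by haplotypes
#'   (columns); row sums are per-population sample sizes.
#' @slot hapSeq named character vector of representative sequences over
#'   the retained alignment columns (one per haplotype, discovery order).
#' @slot distMat symmetric numeric matrix of substitution differences
#'   between haplotype representatives; zero diagonal.
#' @slot segSites integer vector of segregating-site column indices in
#'   the original alignment.
#' @slot L integer, alignment length in bp (columns before filtering).
#' @slot assignment named character vector individual -> haplotype id.
#' @slot popmap the \linkS4class{PopulationMap} used for tabulation.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable",
  representation(counts = "matrix", hapSeq = "character",
    distMat = "matrix", segSites = "integer", L = "integer",
    assignment = "character", popmap = "PopulationMap"),
  validity = function(object) {
    msg <- character()
    cn <- object@counts
    if (any(cn < 0)) msg <- c(msg, "negative haplotype counts")
    if (any(colSums(cn) < 1)) msg <- c(msg, "haplotype with zero total count")
    d <- object@distMat
    if (nrow(d) != ncol(cn)) msg <- c(msg, "distMat dimension != #haplotypes")
    if (nrow(d)) {
      if (any(abs(d - t(d)) > 1e-9)) msg <- c(msg, "distMat not symmetric")
      if (any(diag(d) != 0)) msg <- c(msg, "distMat diagonal not zero")
      if (any(d < 0)) msg <- c(msg, "negative distances")
    }
    if (length(object@assignment) &&
        sum(cn) != length(object@assignment))
      msg <- c(msg, "count total != number of assigned individuals")
    if (length(msg)) msg else TRUE
  })

#' Pons-Petit differentiation statistics
#'
#' Holds HS/HT/GST for unordered haplotypes and the distance-weighted
#' analogues vS/vT/NST, plus the permutation test of NST > GST.
#' HT (and vT) are reported both with the Nei-Chesser sample-size
#' correction and in the uncorrected form computed from unweighted mean
#' haplotype frequencies.
#'
#' @slot hs,ht,htUncorrected,gst numeric, unordered-allele statistics.
#' @slot vs,vt,vtUncorrected,nst numeric, ordered (distance-weighted).
#' @slot pValue numeric, one-sided permutation p for NST > GST (NA until
#'   \code{nstGstTest} is run).
#' @slot nPerm,seed integer, permutation settings.
#' @slot flags character vector of degeneracy notes.
#' @exportClass DifferentiationResult
setClass("DifferentiationResult",
  representation(hs = "numeric", ht = "numeric", htUncorrected = "numeric",
    gst = "numeric", vs = "numeric", vt = "numeric",
    vtUncorrected = "numeric", nst = "numeric", pValue = "numeric",
    nPerm = "integer", seed = "integer", flags = "character"))

#' AMOVA variance decomposition
#'
#' @slot table data.frame with one row per level: df, SS, variance
#'   component (VC) and percentage of variation (PV).
#' @slot phi named numeric vector of Phi-statistics (FST and, with
#'   groups, FSC and FCT).
#' @slot pValues named numeric vector of permutation p-values (NA when
#'   permutations were not run).
#' @slot groups named integer vector population -> group index (empty
#'   for the ungrouped two-level design).
#' @slot nPerm,seed integer permutation settings.
#' @slot flags character vector of degeneracy notes (zero variance etc.).
#' @exportClass AmovaResult
setClass("AmovaResult",
  representation(table = "data.frame", phi = "numeric",
    pValues = "numeric", groups = "integer", nPerm = "integer",
    seed = "integer", flags = "character"))

#' SAMOVA partition search result
#'
#' @slot k integer, number of groups searched.
#' @slot partition named integer vector population -> group in 1..k for
#'   the best partition found.
#' @slot fct numeric, FCT of the best partition.
#' @slot trajectory data.frame (columns K, fct) when a range of K was
#'   scanned, otherwise zero rows.
#' @slot nStarts,seed integer annealing settings.
#' @exportClass SamovaResult
setClass("SamovaResult",
  representation(k = "integer", partition = "integer", fct = "numeric",
    trajectory = "data.frame", nStarts = "integer", seed = "integer"))

#' Mantel isolation-by-distance test
#' @slot r numeric, Pearson correlation of off-diagonal distances.
#' @slot pValue numeric, one-sided permutation p for r > 0.
#' @slot nPerm,seed integer.
#' @slot method character, genetic-distance variant used.
#' @exportClass MantelResult
setClass("MantelResult",
  representation(r = "numeric", pValue = "numeric", nPerm = "integer",
    seed = "integer", method = "character"))

#' Mismatch-distribution analysis result
#'
#' @slot histogram named numeric vector of relative frequencies of
#'   pairwise differences (names are the classes 0..max).
#' @slot tau,theta0,theta1 numeric, fitted sudden-expansion parameters.
#' @slot ssd numeric, sum of squared deviations at the fit.
#' @slot pSsd,pRag numeric, parametric-bootstrap p-values (NA until
#'   \code{bootstrapGof} is run).
#' @slot raggedness numeric, Harpending's raggedness of the observed
#'   histogram.
#' @slot nBoot,seed integer bootstrap settings.
#' @slot flags character degeneracy notes.
#' @exportClass MismatchResult
setClass("MismatchResult",
  representation(histogram = "numeric", tau = "numeric",
    theta0 = "numeric", theta1 = "numeric", ssd = "numeric",
    pSsd = "numeric", raggedness = "numeric", pRag = "numeric",
    nBoot = "integer", seed = "integer", flags = "character"))

#' Neutrality-test result (Tajima's D, Fu's Fs)
#' @slot d,pD numeric, Tajima's D and its beta-approximation p (two-sided).
#' @slot fs,pFs numeric, Fu's Fs and its coalescent-simulation p
#'   (one-sided, small Fs = expansion-like; NA unless simulated).
#' @slot n,s integer, sample size and segregating sites.
#' @slot kHat numeric, mean pairwise differences.
#' @slot flags character degeneracy notes.
#' @exportClass NeutralityResult
setClass("NeutralityResult",
  representation(d = "numeric", pD = "numeric", fs = "numeric",
    pFs = "numeric", n = "integer", s = "integer", kHat = "numeric",
    flags = "character"))

#' Expansion-time estimate from tau
#'
#' Converts the mismatch expansion parameter tau into calendar time via
#' t = tau / (2u) with u = mu * k * g (per-generation locus-wide rate).
#'
#' @slot tau numeric, expansion age in mutational units.
#' @slot mu numeric, substitution rate in substitutions/site/year.
#' @slot k numeric, aligned length in bp.
#' @slot g numeric, generation time in years.
#' @slot u numeric, mu * k * g.
#' @slot tGenerations,tYears numeric, the estimate in generations and years.
#' @exportClass ExpansionEstimate
setClass("ExpansionEstimate",
  representation(tau = "numeric", mu = "numeric", k = "numeric",
    g = "numeric", u = "numeric", tGenerations = "numeric",
    tYears = "numeric"))

#' Minimum spanning haplotype network
#'
#' @slot nodes data.frame with haplotype id and total count.
#' @slot nodeComposition integer matrix, populations x haplotypes (the
#'   per-population composition used for pie-chart style annotation);
#'   zero rows when no population information was supplied.
#' @slot edges data.frame with columns from, to, weight, inMst.
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(nodes = "data.frame", nodeComposition = "matrix",
    edges = "data.frame"),
  validity = function(object) {
    e <- object@edges
    n <- nrow(object@nodes)
    if (n >= 2) {
      if (sum(e$inMst) != n - 1)
        return("MST edge count != #nodes - 1")
    }
    TRUE
  })
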