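#' Accessors for HaplotypeTable and friends
#'
#' \code{hapCounts} returns the population-by-haplotype count matrix;
#' \code{hapDist} the haplotype substitution-distance matrix;
#' \code{hapSeqs} the representative sequences; \code{segSites} the
#' segregating-site columns; \code{sampleSizes} the per-population N;
#' \code{popNames} the population labels in map order.
#'
#' @param x a \linkS4class{HaplotypeTable} (or
#'   \linkS4class{PopulationMap} for \code{popNames}).
#' @return matrix, vector or character as described above.
#' @name accessors
#' @examples
#' tbl <- makePaperFixture("cpDNA")$table
#' dim(hapCounts(tbl))
#' sampleSizes(tbl)
NULL

#' @rdname accessors
#' @export
setGeneric("hapCounts", function(x) standardGeneric("hapCounts"))
#' @rdname accessors
#' @export
setGeneric("hapDist", function(x) standardGeneric("hapDist"))
#' @rdname accessors
#' @export
setGeneric("hapSeqs", function(x) standardGeneric("hapSeqs"))
#' @rdname accessors
#' @export
setGeneric("segSites", function(x) standardGeneric("segSites"))
#' @rdname accessors
#' @export
setGeneric("sampleSizes", function(x) standardGeneric("sampleSizes"))
#' @rdname accessors
#' @export
setGeneric("popNames", function(x) standardGeneric("popNames"))

#' @rdname accessors
setMethod("hapCounts", "HaplotypeTable", function(x) x@counts)
#' @rdname accessors
setMethod("hapDist", "HaplotypeTable", function(x) x@distMat)
#' @rdname accessors
setMethod("hapSeqs", "HaplotypeTable", function(x) x@hapSeq)
#' @rdname accessors
setMethod("segSites", "HaplotypeTable", function(x) x@segSites)
#' @rdname accessors
setMethod("sampleSizes", "HaplotypeTable", function(x) rowSums(x@counts))
#' @rdname accessors
setMethod("popNames", "HaplotypeTable",
  function(x) rownames(x@counts))
#' @rdname accessors
setMethod("popNames", "PopulationMap",
  function(x) x@populations$population)

setMethod("show", "PopulationMap", function(object) {
  cat("PopulationMap:", nrow(object@individuals), "individuals in",
      nrow(object@populations), "populations\n")
  ok <- stats::complete.cases(object@populations[, c("lat", "lon")])
  if (!all(ok))
    cat("  populations without coordinates:",
        paste(object@populations$population[!ok], collapse = ", "), "\n")
})

setMethod("show", "HaplotypeTable", function(object) {
  cat("HaplotypeTable:", ncol(object@counts), "haplotypes,",
      nrow(object@counts), "populations, N =", sum(object@counts), "\n")
  cat("  segregating sites:", length(object@segSites),
      " alignment length:", object@L, "bp\n")
})

setMethod("show", "DifferentiationResult", function(object) {
  cat("Pons-Petit differentiation\n")
  cat(sprintf("  HS = %.4f  HT = %.4f (uncorrected %.4f)  GST = %.4f\n",
      object@hs, object@ht, object@htUncorrected, object@gst))
  cat(sprintf("  vS = %.4f  vT = %.4f  NST = %.4f\n",
      object@vs, object@vt, object@nst))
  if (!is.na(object@pValue))
    cat(sprintf("  P(NST > GST) = %.4g  (%d permutations)\n",
        object@pValue, object@nPerm))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "AmovaResult", function(object) {
  cat("AMOVA\n")
  print(object@table, digits = 5)
  phi <- object@phi
  for (nm in names(phi)) {
    p <- object@pValues[nm]
    cat(sprintf("  %s = %.5f%s\n", nm, phi[nm],
        if (!is.na(p)) sprintf("  (p = %.4g)", p) else ""))
  }
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "SamovaResult", function(object) {
  cat("SAMOVA: K =", object@k, " best FCT =",
      format(object@fct, digits = 5), "\n")
  sp <- split(names(object@partition), object@partition)
  for (g in seq_along(sp))
    cat("  group", g, ":", paste(sp[[g]], collapse = ", "), "\n")
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test (%s): r = %.4f, one-sided p = %.4g (%d perms)\n",
      object@method, object@r, object@pValue, object@nPerm))
})

setMethod("show", "MismatchResult", function(object) {
  cat("Mismatch distribution (sudden-expansion fit)\n")
  cat(sprintf("  tau = %.4f  theta0 = %.4f  theta1 = %.4f  SSD = %.6f\n",
      object@tau, object@theta0, object@theta1, object@ssd))
  cat(sprintf("  raggedness = %.5f\n", object@raggedness))
  if (!is.na(object@pSsd))
    cat(sprintf("  bootstrap p(SSD) = %.4g  p(raggedness) = %.4g  (B = %d)\n",
        object@pSsd, object@pRag, object@nBoot))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "NeutralityResult", function(object) {
  cat(sprintf("Neutrality tests (n = %d, S = %d, mean pairwise k = %.4f)\n",
      object@n, object@s, object@kHat))
  cat(sprintf("  Tajima's D = %.4f (p = %.4g)\n", object@d, object@pD))
  cat(sprintf("  Fu's Fs    = %.4f%s\n", object@fs,
      if (!is.na(object@pFs)) sprintf(" (p = %.4g)", object@pFs) else ""))
  if (length(object@flags)) cat("  flags:", object@flags, "\n")
})

setMethod("show", "ExpansionEstimate", function(object) {
  cat(sprintf(
    "Expansion time: tau = %.4f, u = %.4g /generation\n", object@tau,
    object@u))
  cat(sprintf("  t = %.4g generations = %.4g years (g = %g y)\n",
      object@tGenerations, object@tYears, object@g))
})

setMethod("show", "HaplotypeNetwork", function(object) {
  cat("Haplotype network:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges (", sum(object@edges$inMst),
      "in MST )\n")
})
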