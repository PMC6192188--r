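#' Convert the mismatch tau into an expansion time
#'
#' t = tau / (2u) in generations, with u = mu * k * g the locus-wide
#' per-generation substitution rate; the estimate is also converted to
#' years by the generation time. Reporting both units avoids the
#' ambiguity that arises when a generations-based formula is read as
#' years.
#'
#' @param tau expansion age in mutational units (>= 0).
#' @param mu substitution rate in substitutions/site/year (> 0).
#' @param k aligned sequence length in bp (> 0).
#' @param g generation time in years (> 0).
#' @return an \linkS4class{ExpansionEstimate}.
#' @export
#' @examples
#' expansionTime(tau = 1.488, mu = 2e-9, k = 1531, g = 10)
expansionTime <- function(tau, mu, k, g) {
  if (tau < 0) stop("tau must be non-negative")
  if (mu <= 0 || k <= 0 || g <= 0)
    stop("input error: mu, k and g must be positive")
  u <- mu * k * g
  tGen <- tau / (2 * u)
  new("ExpansionEstimate", tau = tau, mu = mu, k = k, g = g, u = u,
      tGenerations = tGen, tYears = tGen * g)
}

#' Strict-clock divergence time between two lineages
#'
#' Closed-form point estimate T = d_net / (2 mu), where the net
#' per-site distance corrects the mean between-lineage distance for
#' within-lineage polymorphism:
#' d_net = d_between - (d_within1 + d_within2) / 2. A negative net
#' distance is clamped to zero with a warning.
#'
#' @param netDistance net distance per site between the two lineages
#'   (or the raw between/within means via \code{dBetween},
#'   \code{dWithin1}, \code{dWithin2}).
#' @param mu substitution rate in substitutions/site/year (> 0).
#' @param dBetween,dWithin1,dWithin2 optional components used to form
#'   the net distance when \code{netDistance} is missing.
#' @return divergence time T in years.
#' @export
#' @examples
#' strictClockDivergence(0.004, mu = 2e-9)  # 1e6 years
strictClockDivergence <- function(netDistance = NULL, mu,
                                  dBetween = NULL, dWithin1 = 0,
                                  dWithin2 = 0) {
  if (mu <= 0) stop("mu must be positive")
  if (is.null(netDistance)) {
    if (is.null(dBetween)) stop("give netDistance or dBetween")
    netDistance <- dBetween - (dWithin1 + dWithin2) / 2
  }
  if (netDistance < 0) {
    warning("negative net distance clamped to 0")
    netDistance <- 0
  }
  netDistance / (2 * mu)
}
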