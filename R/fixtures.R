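# Fixture dataset shaped like the published survey: 16 populations,
# 253 individuals, a 1531-bp cpDNA-like locus with 7 substitutions
# defining 6 haplotypes, and a 606-column ITS-like locus with 4
# substitutions defining 6 ribotypes plus two indel columns (raw
# sequence lengths 604-606). The per-population haplotype counts and
# population coordinates are the published ones; the haplotype
# sequences themselves are unpublished, so the sequences and hence the
# inter-haplotype distance matrix are an explicit synthetic
# construction consistent with the reported substitution counts and
# clade statements (H3 and H6 are one substitution apart; R2 is the
# most divergent ribotype). Distance-dependent statistics computed on
# the fixture are therefore fixture-conditional.

.popTable <- function() {
  data.frame(
    population = c("DML", "DQ", "DD-1", "DD-2", "JCL", "ML", "SJL-1",
                   "SJL-2", "XL", "QE-1", "QE-2", "QE-3", "XC",
                   "HS-1", "HS-2", "HS-3"),
    lat = c("29°18′36″", "31°41′34″",
            "29°42′46″", "29°42′46″",
            "28°57′28″", "29°50′02″",
            "29°33′62″", "29°33′62″",
            "31°22′58″", "31°56′05″",
            "31°56′02″", "31°48′79″",
            "29°08′23″", "28°07′43″",
            "28°07′08″", "28°07′08″"),
    lon = c("97°00′59″", "94°55′31″",
            "97°57′43″", "97°57′43″",
            "87°23′37″", "92°20′02″",
            "94°34′58″", "94°34′42″",
            "93°46′32″", "98°55′43″",
            "98°56′02″", "98°34′78″",
            "100°03′24″", "99°53′51″",
            "99°54′02″", "99°54′02″"),
    elevation = c(4900, 4959, 5080, 5080, 5505.5, 5225, 4728, 4728,
                  5068, 4845, 4700, 4823, 4780, 4365, 4342, 4342),
    stringsAsFactors = FALSE)
}

.fixtureCounts <- function(kind) {
  pops <- .popTable()$population
  if (kind == "cpDNA") {
    haps <- paste0("H", 1:6)
    cnt <- matrix(0L, 16, 6, dimnames = list(pops, haps))
    cnt["DML", "H2"] <- 20L;  cnt["DQ", "H2"] <- 20L
    cnt["DD-1", c("H1", "H2")] <- c(18L, 1L)
    cnt["DD-2", "H1"] <- 14L; cnt["JCL", "H3"] <- 16L
    cnt["ML", c("H5", "H4", "H2")] <- c(3L, 16L, 1L)
    cnt["SJL-1", "H3"] <- 12L; cnt["SJL-2", "H3"] <- 10L
    cnt["XL", "H2"] <- 19L;   cnt["QE-1", "H2"] <- 17L
    cnt["QE-2", "H2"] <- 10L
    cnt["QE-3", c("H6", "H2")] <- c(3L, 13L)
    cnt["XC", "H2"] <- 18L;   cnt["HS-1", "H2"] <- 20L
    cnt["HS-2", "H2"] <- 12L; cnt["HS-3", "H2"] <- 10L
  } else {
    haps <- paste0("R", 1:6)
    cnt <- matrix(0L, 16, 6, dimnames = list(pops, haps))
    cnt["DML", "R1"] <- 20L;  cnt["DQ", "R1"] <- 20L
    cnt["DD-1", "R1"] <- 19L; cnt["DD-2", "R1"] <- 14L
    cnt["JCL", "R3"] <- 16L
    cnt["ML", c("R1", "R3", "R4")] <- c(7L, 2L, 11L)
    cnt["SJL-1", "R1"] <- 12L; cnt["SJL-2", "R1"] <- 10L
    cnt["XL", c("R1", "R6")] <- c(9L, 10L)
    cnt["QE-1", c("R1", "R5")] <- c(11L, 6L)
    cnt["QE-2", "R1"] <- 10L; cnt["QE-3", "R1"] <- 16L
    cnt["XC", c("R1", "R2")] <- c(6L, 12L)
    cnt["HS-1", c("R1", "R2")] <- c(18L, 2L)
    cnt["HS-2", "R1"] <- 12L; cnt["HS-3", "R1"] <- 10L
  }
  cnt
}

# derived-state patterns over the substitution columns (the synthetic
# haplotype construction)
.fixturePatterns <- function(kind) {
  if (kind == "cpDNA")
    list(H1 = 1L, H2 = integer(0), H3 = c(2L, 3L), H4 = 5L,
         H5 = c(5L, 6L, 7L), H6 = c(2L, 3L, 4L))
  else
    list(R1 = integer(0), R2 = c(1L, 2L), R3 = 3L, R4 = 4L,
         R5 = c(3L, 4L), R6 = c(2L, 4L))
}

#' Deterministic fixture dataset shaped like the published survey
#'
#' Builds an aligned FASTA and population map reproducing the published
#' per-population haplotype counts exactly: 16 populations, 253
#' individuals; the cpDNA-like locus is 1531 bp with 6 haplotypes on 7
#' segregating sites, the ITS-like locus 606 columns with 6 ribotypes
#' on 4 substitution sites plus two indel columns (raw lengths
#' 604-606). Haplotype sequences are a synthetic construction (the real
#' ones are unpublished) consistent with the reported substitution
#' counts and clade statements. Two invocations produce byte-identical
#' files.
#'
#' @param kind \code{"cpDNA"} or \code{"ITS"}.
#' @param dir directory for the FASTA/TSV files (default
#'   \code{tempdir()}).
#' @return list with \code{alignment} (\code{DNAStringSet}),
#'   \code{popmap} (\linkS4class{PopulationMap}), \code{table} (a
#'   \linkS4class{HaplotypeTable} carrying the published labels),
#'   \code{alignmentFile} and \code{popmapFile}.
#' @export
#' @examples
#' fx <- makePaperFixture("cpDNA")
#' sum(hapCounts(fx$table))  # 253
makePaperFixture <- function(kind = c("cpDNA", "ITS"),
                             dir = tempdir()) {
  kind <- match.arg(kind)
  oldSeed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(20181016L)

  L <- if (kind == "cpDNA") 1531L else 606L
  sites <- if (kind == "cpDNA")
    c(150L, 400L, 520L, 700L, 880L, 1100L, 1300L)
  else c(100L, 220L, 340L, 460L)
  pat <- .fixturePatterns(kind)
  cnt <- .fixtureCounts(kind)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  derived <- vapply(anc[sites], function(b)
    c(A = "G", G = "A", C = "T", T = "C")[[b]], character(1))

  hapStrings <- vapply(names(pat), function(h) {
    s <- anc
    s[sites[pat[[h]]]] <- derived[pat[[h]]]
    if (kind == "ITS") {
      # indel columns 600-601: R3/R5 miss both (604 bp), R6 one (605)
      if (h %in% c("R3", "R5")) s[600:601] <- "-"
      if (h == "R6") s[600] <- "-"
    }
    paste(s, collapse = "")
  }, character(1))

  ids <- character(0); popOf <- character(0); hapOf <- character(0)
  for (p in rownames(cnt)) {
    row <- cnt[p, ]
    haps <- rep(names(row), row)
    ids <- c(ids, sprintf("%s_%02d", gsub("-", "", p),
                          seq_along(haps)))
    popOf <- c(popOf, rep(p, length(haps)))
    hapOf <- c(hapOf, haps)
  }
  seqs <- Biostrings::DNAStringSet(hapStrings[hapOf])
  names(seqs) <- ids

  pt <- .popTable()
  popmap <- new("PopulationMap",
    individuals = data.frame(individual = ids, population = popOf,
                             stringsAsFactors = FALSE),
    populations = data.frame(population = pt$population,
      lat = suppressWarnings(parseDms(pt$lat)),
      lon = suppressWarnings(parseDms(pt$lon)),
      elevation = pt$elevation, stringsAsFactors = FALSE))

  prefix <- file.path(dir, paste0("fixture_", kind))
  alignmentFile <- paste0(prefix, "_alignment.fasta")
  popmapFile <- paste0(prefix, "_popmap.tsv")
  Biostrings::writeXStringSet(seqs, alignmentFile)
  mapRow <- match(popOf, pt$population)
  utils::write.table(
    data.frame(individual = ids, population = popOf,
               lat = pt$lat[mapRow], lon = pt$lon[mapRow],
               elevation = pt$elevation[mapRow]),
    popmapFile, sep = "\t", quote = FALSE, row.names = FALSE)

  # collapse, then relabel discovery-ordered haplotypes back to the
  # published labels by matching representatives over retained columns
  disc <- collapseHaplotypes(seqs,
    hapPrefix = if (kind == "cpDNA") "H" else "R")
  refMat <- do.call(rbind, strsplit(hapStrings, ""))
  keep <- apply(refMat, 2, function(col) all(col %in% bases))
  refOnKept <- apply(refMat[, keep, drop = FALSE], 1, paste,
                     collapse = "")
  lab <- names(hapStrings)[match(disc$hapSeq, refOnKept)]
  newSeq <- stats::setNames(disc$hapSeq, lab)[names(pat)]
  d <- disc$distMat
  dimnames(d) <- list(lab, lab)
  d <- d[names(pat), names(pat)]
  asn <- stats::setNames(lab[match(disc$assignment,
                                   names(disc$hapSeq))],
                         names(disc$assignment))
  collapsed <- list(assignment = asn, hapSeq = newSeq, distMat = d,
                    segSites = disc$segSites, L = disc$L)
  tbl <- tabulateByPopulation(collapsed, popmap)
  list(alignment = seqs, popmap = popmap, table = tbl,
       alignmentFile = alignmentFile, popmapFile = popmapFile)
}
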