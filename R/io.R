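#' Read an aligned FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format (one locus per
#' run; concatenated regions are treated as a single sequence). Bases
#' are uppercased; record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return a \code{\link[Biostrings]{DNAStringSet}} whose members all
#'   have the same length.
#' @export
#' @examples
#' fx <- makePaperFixture("cpDNA")
#' aln <- readAlignment(fx$alignmentFile)
#' length(aln)
readAlignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aln <- Biostrings::readDNAStringSet(path)
  if (length(aln) == 0L) stop("empty FASTA file: ", path)
  # keep only the record id (up to first whitespace)
  names(aln) <- sub("\\s.*$", "", names(aln))
  if (anyDuplicated(names(aln)))
    stop("duplicate record ids in alignment")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(w)), collapse = ", "), ")")
  if (w[1] == 0L) stop("alignment error: zero-length sequences")
  Biostrings::DNAStringSet(toupper(as.character(aln)))
}

#' Parse a degrees-minutes-seconds coordinate string
#'
#' Accepts decimal degrees (\code{"29.31"}) or DMS strings in the form
#' \code{"29°18′36″N"} with any of the common prime/quote characters.
#' A trailing hemisphere letter (N/S/E/W) sets the sign. Seconds (or
#' minutes) of 60 or more are accepted arithmetically with a warning,
#' since field tables occasionally print them that way.
#'
#' @param x character vector of coordinate strings.
#' @return numeric vector of decimal degrees.
#' @export
#' @examples
#' parseDms("29°18′36″N")  # 29.31
parseDms <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_real_)
    s <- trimws(s)
    # plain decimal degrees pass through
    if (grepl("^[-+]?[0-9]*\\.?[0-9]+$", s)) return(as.numeric(s))
    sign <- 1
    hem <- regmatches(s, regexpr("[NSEWnsew]\\s*$", s))
    if (length(hem) && nzchar(hem)) {
      if (toupper(trimws(hem)) %in% c("S", "W")) sign <- -1
      s <- sub("[NSEWnsew]\\s*$", "", s)
    }
    if (grepl("^-", s)) { sign <- -sign; s <- sub("^-", "", s) }
    parts <- regmatches(s, gregexpr("[0-9]+(\\.[0-9]+)?", s))[[1]]
    if (length(parts) < 1L || length(parts) > 3L)
      stop("cannot parse coordinate: ", s)
    v <- as.numeric(parts)
    v <- c(v, rep(0, 3 - length(v)))
    if (v[2] >= 60 || v[3] >= 60)
      warning("minutes/seconds >= 60 in coordinate '", s,
              "'; converting arithmetically")
    sign * (v[1] + v[2] / 60 + v[3] / 3600)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a population map
#'
#' Reads a TSV with one row per individual and columns
#' \code{individual}, \code{population}, \code{lat}, \code{lon} and
#' optionally \code{elevation}. Coordinates may be decimal degrees or
#' DMS strings (see \code{\link{parseDms}}); they are taken to be
#' constant within a population. Populations whose coordinates are
#' missing are retained but flagged: spatial analyses skip them.
#'
#' @param path path to the TSV file.
#' @param alignment optional \code{DNAStringSet}; individuals present
#'   in the map but absent from the alignment are reported by warning.
#' @return a \linkS4class{PopulationMap}.
#' @export
readPopulationMap <- function(path, alignment = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, strip.white = TRUE)
  need <- c("individual", "population", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("population map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$individual))
    stop("individual mapped twice: ",
         paste(unique(df$individual[duplicated(df$individual)]),
               collapse = ", "))
  ind <- data.frame(individual = df$individual,
                    population = df$population,
                    stringsAsFactors = FALSE)
  firsts <- !duplicated(df$population)
  pops <- data.frame(
    population = df$population[firsts],
    lat = parseDms(df$lat[firsts]),
    lon = parseDms(df$lon[firsts]),
    elevation = if ("elevation" %in% names(df))
      suppressWarnings(as.numeric(df$elevation[firsts])) else NA_real_,
    stringsAsFactors = FALSE)
  if (!is.null(alignment)) {
    missing <- setdiff(ind$individual, names(alignment))
    if (length(missing))
      warning("individuals absent from alignment: ",
              paste(missing, collapse = ", "))
  }
  new("PopulationMap", individuals = ind, populations = pops)
}

#' Write a haplotype table, distances and representatives to disk
#'
#' \code{writeHaplotypeTable} writes the population-by-haplotype counts
#' with a sample-size column as TSV; \code{writeDistMatrix} the pairwise
#' substitution-distance matrix; \code{writeHapFasta} the representative
#' sequence of each haplotype (over retained columns) as FASTA.
#'
#' @param tbl a \linkS4class{HaplotypeTable}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHaplotypeTable <- function(tbl, path) {
  out <- data.frame(population = rownames(tbl@counts),
                    N = rowSums(tbl@counts),
                    tbl@counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeHaplotypeTable
#' @export
writeDistMatrix <- function(tbl, path) {
  utils::write.table(
    data.frame(haplotype = rownames(tbl@distMat), tbl@distMat,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeHaplotypeTable
#' @export
writeHapFasta <- function(tbl, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(tbl@hapSeq), path)
  invisible(path)
}
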