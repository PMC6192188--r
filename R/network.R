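#' Minimum spanning haplotype network
#'
#' Kruskal minimum spanning tree over the haplotype distance matrix
#' with deterministic tie-breaking (edges of equal weight are taken in
#' lexicographic haplotype-id order), augmented with every non-tree
#' edge whose weight equals the maximum edge weight on the tree path
#' between its endpoints (epsilon = 0 co-minimality). The result is the
#' classic minimum spanning network used to display shallow haplotype
#' divergences.
#'
#' @param tbl a \linkS4class{HaplotypeTable} (or a bare symmetric
#'   distance matrix with dimnames).
#' @return a \linkS4class{HaplotypeNetwork}.
#' @export
#' @examples
#' net <- buildMsn(makePaperFixture("cpDNA")$table)
#' net@edges
buildMsn <- function(tbl) {
  if (is(tbl, "HaplotypeTable")) {
    d <- hapDist(tbl)
    counts <- colSums(hapCounts(tbl))
    comp <- hapCounts(tbl)
  } else {
    d <- as.matrix(tbl)
    counts <- stats::setNames(rep(NA_integer_, nrow(d)), rownames(d))
    comp <- matrix(integer(0), 0, nrow(d),
                   dimnames = list(NULL, rownames(d)))
  }
  ids <- rownames(d)
  k <- length(ids)
  nodes <- data.frame(haplotype = ids, count = as.integer(counts),
                      stringsAsFactors = FALSE)
  if (k < 2) {
    return(new("HaplotypeNetwork", nodes = nodes,
               nodeComposition = comp,
               edges = data.frame(from = character(0),
                                  to = character(0),
                                  weight = numeric(0),
                                  inMst = logical(0))))
  }
  # candidate edges sorted by (weight, from, to): deterministic Kruskal
  idx <- which(upper.tri(d), arr.ind = TRUE)
  cand <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                     weight = d[idx], stringsAsFactors = FALSE)
  cand <- cand[order(cand$weight, cand$from, cand$to), ]
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  inMst <- logical(nrow(cand))
  for (e in seq_len(nrow(cand))) {
    a <- find(match(cand$from[e], ids))
    b <- find(match(cand$to[e], ids))
    if (a != b) { parent[a] <- b; inMst[e] <- TRUE }
  }
  mst <- cand[inMst, ]
  # max edge weight on the MST path between every node pair
  adj <- lapply(seq_len(k), function(i) integer(0))
  wadj <- lapply(seq_len(k), function(i) numeric(0))
  for (e in seq_len(nrow(mst))) {
    a <- match(mst$from[e], ids); b <- match(mst$to[e], ids)
    adj[[a]] <- c(adj[[a]], b); wadj[[a]] <- c(wadj[[a]], mst$weight[e])
    adj[[b]] <- c(adj[[b]], a); wadj[[b]] <- c(wadj[[b]], mst$weight[e])
  }
  pathMax <- matrix(0, k, k)
  for (s in seq_len(k)) {  # DFS from each node
    seen <- rep(FALSE, k); seen[s] <- TRUE
    stack <- s; mx <- numeric(k)
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (j in seq_along(adj[[v]])) {
        u <- adj[[v]][j]
        if (!seen[u]) {
          seen[u] <- TRUE
          mx[u] <- max(mx[v], wadj[[v]][j])
          stack <- c(stack, u)
        }
      }
    }
    pathMax[s, ] <- mx
  }
  keepExtra <- !inMst & vapply(seq_len(nrow(cand)), function(e) {
    a <- match(cand$from[e], ids); b <- match(cand$to[e], ids)
    cand$weight[e] <= pathMax[a, b]
  }, logical(1))
  edges <- cand[inMst | keepExtra, ]
  edges$inMst <- inMst[inMst | keepExtra]
  rownames(edges) <- NULL
  new("HaplotypeNetwork", nodes = nodes, nodeComposition = comp,
      edges = edges)
}

#' Export / import a haplotype network
#'
#' \code{exportNetwork} writes an edge list TSV (with per-population
#' node composition columns appended as node annotation rows in a
#' companion \code{*.nodes.tsv}) or a GML file via igraph;
#' \code{readNetworkEdges} reads the edge-list TSV back.
#'
#' @param net a \linkS4class{HaplotypeNetwork}.
#' @param path output path.
#' @param format \code{"edgelist"} or \code{"gml"}.
#' @return the path, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("edgelist", "gml")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("input error: unknown format"))
  if (format == "edgelist") {
    utils::write.table(net@edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nodeOut <- net@nodes
    if (nrow(net@nodeComposition)) {
      compT <- t(net@nodeComposition)
      nodeOut <- cbind(nodeOut, as.data.frame(compT))
    }
    utils::write.table(nodeOut, paste0(path, ".nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- .asIgraph(net)
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

.asIgraph <- function(net) {
  e <- net@edges
  e$inMst <- as.integer(e$inMst)  # GML has no boolean type
  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = net@nodes)
  igraph::E(g)$weight <- net@edges$weight
  g
}

#' @rdname exportNetwork
#' @export
readNetworkEdges <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
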