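#' Confidence-weighted undirected protein interaction graph
#'
#' @param edges data frame with columns `a`, `b`, `confidence` in [0, 1];
#'   undirected, deduplicated, no self-loops.
#' @param nodes optional character vector of node names (defaults to the
#'   union of edge endpoints).
#' @return an object of class `weighted_graph` with `nodes` and `edges`
#'   (edge tiers `medium`/`high`/`highest`/`low` derived from confidence).
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("a", "b", "confidence") %in% names(edges)))
  if (any(edges$a == edges$b)) stop("self-loops are not allowed")
  if (any(edges$confidence < 0 | edges$confidence > 1))
    stop("confidences must lie in [0, 1]")
  if (is.null(nodes)) nodes <- sort(unique(c(edges$a, edges$b)))
  edges$tier <- edge_tier(edges$confidence)
  structure(list(nodes = nodes,
                 edges = edges[, c("a", "b", "confidence", "tier")]),
            class = "weighted_graph")
}

edge_tier <- function(conf) {
  ifelse(conf >= 0.9, "highest",
         ifelse(conf >= 0.7, "high",
                ifelse(conf >= 0.4, "medium", "low")))
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("weighted_graph: %d nodes, %d edges (tiers: %s)\n",
              length(x$nodes), nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$tier)),
                            table(x$edges$tier)), collapse = ", ")))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' TSV with columns nodeA, nodeB, score (header optional). Scores either
#' already in [0, 1] or on STRING's 0-1000 integer scale — if any score
#' exceeds 1 the whole file is taken as 0-1000 and divided by 1000.
#' Self-loop rows are dropped with a warning; duplicate undirected edges
#' keep the maximum confidence.
#'
#' @param path file path.
#' @return a `weighted_graph`.
#' @export
read_edges <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.delim(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  names(df)[1:3] <- c("a", "b", "score")
  if (any(is.na(df$score))) stop("non-numeric interaction score")
  if (any(df$score < 0 | df$score > 1000))
    stop("score outside both the [0,1] and the 0-1000 scale")
  conf <- if (any(df$score > 1)) df$score / 1000 else df$score
  df$confidence <- conf
  loops <- df$a == df$b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) dropped")
    df <- df[!loops, ]
  }
  key <- ifelse(df$a < df$b, paste(df$a, df$b, sep = "\r"),
                paste(df$b, df$a, sep = "\r"))
  best <- tapply(df$confidence, key, max)
  ab <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  weighted_graph(data.frame(a = ab[, 1], b = ab[, 2],
                            confidence = as.numeric(best),
                            stringsAsFactors = FALSE))
}

#' Confidence filter with removal of disconnected proteins
#'
#' Keeps edges whose confidence is strictly above `min_confidence` (the
#' "medium confidence > 0.4" convention), then removes nodes left without
#' any edge.
#'
#' @param g a `weighted_graph`.
#' @param min_confidence confidence threshold.
#' @return a filtered `weighted_graph`.
#' @export
filter_graph <- function(g, min_confidence = 0.4) {
  stopifnot(inherits(g, "weighted_graph"))
  e <- g$edges[g$edges$confidence > min_confidence, , drop = FALSE]
  keep <- sort(unique(c(e$a, e$b)))
  weighted_graph(e, nodes = keep)
}

#' Restrict a graph to a node set
#'
#' @param g a `weighted_graph`.
#' @param nodes character vector of node names to keep.
#' @return the induced subgraph (isolated nodes retained until
#'   [filter_graph()] removes them).
#' @export
subgraph_nodes <- function(g, nodes) {
  e <- g$edges[g$edges$a %in% nodes & g$edges$b %in% nodes, , drop = FALSE]
  weighted_graph(e, nodes = intersect(g$nodes, nodes))
}

#' Markov Cluster Algorithm on a confidence-weighted graph
#'
#' From-scratch MCL: build the column-stochastic transition matrix from the
#' edge confidences with a self-loop per node (weight = the node's maximum
#' incident confidence, the usual regularization), then alternate expansion
#' (matrix squaring) and inflation (elementwise power `inflation`, column
#' renormalization) with pruning of entries below `prune`, until the matrix
#' changes by less than 1e-8 or `max_iter` is reached (then a warning, and
#' clusters are read from the current state). Clusters are extracted from
#' attractors (nodes with positive diagonal mass in the limit): attractors
#' connected through nonzero limit entries form cluster seeds, and every
#' node joins the seed holding the largest share of its column mass, ties
#' going to the cluster with the lexicographically smallest seed node.
#'
#' @param g a `weighted_graph` (filtered, loop-free).
#' @param inflation inflation exponent, > 1; default 2.
#' @param max_iter iteration cap.
#' @param prune entries below this are zeroed each iteration.
#' @return list with `graph` (the input graph with `cluster` labels on
#'   nodes and an `intra` flag on edges), `membership` (named integer),
#'   and `iterations`.
#' @export
mcl_cluster <- function(g, inflation = 2, max_iter = 100L, prune = 1e-5) {
  stopifnot(inherits(g, "weighted_graph"), inflation > 1)
  n <- length(g$nodes)
  if (n == 0L) stop("empty graph")
  A <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  ia <- match(g$edges$a, g$nodes); ib <- match(g$edges$b, g$nodes)
  for (k in seq_along(ia)) {
    A[ia[k], ib[k]] <- g$edges$confidence[k]
    A[ib[k], ia[k]] <- g$edges$confidence[k]
  }
  self <- apply(A, 1L, max)
  self[self == 0] <- 1  # isolated node: inert self-walk
  diag(A) <- self
  M <- sweep(A, 2L, colSums(A), "/")
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M            # expansion
    M2 <- M2^inflation       # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2L, cs, "/")
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering current state")
  eps <- 1e-6
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)
  # attractor systems: attractors linked by nonzero limit flow share a seed
  sub <- (M[attractors, attractors, drop = FALSE] > eps) |
    t(M[attractors, attractors, drop = FALSE] > eps)
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    sub, mode = "undirected", diag = FALSE))$membership
  seed_names <- tapply(g$nodes[attractors], comp, function(v) min(v))
  membership <- integer(n)
  mass <- rowsum(M[attractors, , drop = FALSE], comp)  # cluster x node
  ord <- order(seed_names)                             # lexicographic ties
  mass <- mass[ord, , drop = FALSE]
  seed_names <- seed_names[ord]
  for (j in seq_len(n)) {
    col <- mass[, j]
    membership[j] <- if (max(col) <= 0) NA_integer_ else which.max(col)
  }
  # nodes with no attractor mass become singletons
  extra <- which(is.na(membership))
  for (idx in seq_along(extra))
    membership[extra[idx]] <- length(seed_names) + idx
  names(membership) <- g$nodes
  g$cluster <- membership
  g$edges$intra <- membership[g$edges$a] == membership[g$edges$b]
  list(graph = g, membership = membership, iterations = it)
}

#' Cluster assignment and edge table of an MCL result
#'
#' @param mcl result of [mcl_cluster()].
#' @return list of data frames: `nodes` (node, cluster) and `edges`
#'   (a, b, confidence, tier, intra).
#' @export
mcl_tables <- function(mcl) {
  list(nodes = data.frame(node = names(mcl$membership),
                          cluster = as.integer(mcl$membership),
                          stringsAsFactors = FALSE),
       edges = mcl$graph$edges)
}
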