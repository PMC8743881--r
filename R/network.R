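#' Build the directed dominance network
#'
#' One directed edge per strictly positive cell of the win/loss matrix,
#' weighted by the win count; antiparallel edges coexist when both members
#' of a dyad have won against each other. Individuals with no interactions
#' remain in the network as isolates.
#'
#' @param m a \code{\link{winLossMatrix}}.
#' @return an object of class \code{dominanceNetwork}: a list with
#'   \code{ids}, the count matrix \code{counts}, and an igraph \code{graph}.
#' @export
buildNetwork <- function(m) {
  counts <- unclass(m)
  ids <- rownames(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  edges <- rbind(ids[idx[, 1]], ids[idx[, 2]])
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[1, ], to = edges[2, ],
               weight = counts[idx], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  structure(list(ids = ids, counts = counts, graph = g),
            class = "dominanceNetwork")
}

#' @export
print.dominanceNetwork <- function(x, ...) {
  cat(sprintf("dominanceNetwork: %d individuals, %d directed edges\n",
              length(x$ids), igraph::ecount(x$graph)))
  invisible(x)
}

#' Census of decided dominance triangles
#'
#' Each dyad is first binarized to a single dominance direction by majority
#' win count (ties, including never-interacting dyads, are undecided). The
#' census then counts node triples whose three dyads are all decided: a
#' triple is transitive when one member dominates both others and one is
#' dominated by both, and intransitive (cyclic) otherwise.
#'
#' Counts are obtained from trace identities on the binarized dominance
#' matrix A: cyclic triples are trace(A^3)/3, and the total of fully
#' decided triples is the triangle count of the symmetrized decided-dyad
#' graph.
#'
#' @param net a \code{\link{buildNetwork}} result.
#' @return an object of class \code{triangleCensus}: list with counts
#'   \code{transitive} and \code{intransitive}.
#' @export
triadCensus <- function(net) {
  C <- net$counts
  A <- (C > t(C)) * 1.0            # majority dominance direction
  M <- A + t(A)                    # 1 iff dyad decided
  cyclic <- as.integer(round(sum(diag(A %*% A %*% A)) / 3))
  total <- as.integer(round(sum(diag(M %*% M %*% M)) / 6))
  structure(list(transitive = total - cyclic, intransitive = cyclic),
            class = "triangleCensus")
}

#' @export
print.triangleCensus <- function(x, ...) {
  cat(sprintf("triangleCensus: %d transitive, %d intransitive decided triples\n",
              x$transitive, x$intransitive))
  invisible(x)
}

#' Network-wide directed transitivity
#'
#' The proportion of fully decided triangles whose dominance directions form
#' a transitive (non-cyclic) pattern. When no triple is fully decided the
#' index is undefined and \code{default} is returned: the default of 1
#' treats the absence of any closed triangle as the absence of observed
#' intransitivity, so sparse chain-like networks retain their indirect
#' dominance information rather than having it discounted to nothing.
#'
#' @param census a \code{\link{triadCensus}} result.
#' @param default value in [0, 1] returned when no triple is decided.
#' @return transitivity index in [0, 1].
#' @export
transitivityIndex <- function(census, default = 1) {
  tot <- census$transitive + census$intransitive
  if (tot == 0) {
    return(default)
  }
  census$transitive / tot
}

#' Enumerate indirect dominance pathways between two individuals
#'
#' All simple directed paths (no repeated individuals, every step following
#' an observed winner-to-loser edge) of length 2 up to \code{L} from
#' \code{source} to \code{target}. Length-1 paths are the direct encounters
#' already present in the win/loss matrix and are excluded.
#'
#' @param net a \code{\link{buildNetwork}} result.
#' @param source,target distinct individual ids.
#' @param L maximum path length (edges), at least 2. Enumeration is
#'   exhaustive; cost grows combinatorially with \code{L} in dense networks.
#' @return object of class \code{pathSet}: list with \code{source},
#'   \code{target}, \code{L}, and \code{paths}, a list of id vectors.
#' @export
enumeratePaths <- function(net, source, target, L = 2) {
  if (!all(c(source, target) %in% net$ids)) {
    stopDominet("dominet_id_error", "unknown individual id")
  }
  if (source == target) {
    stopDominet("dominet_id_error", "source and target must differ")
  }
  if (L < 2) {
    stopDominet("dominet_parameter_error", "L must be at least 2")
  }
  ap <- igraph::all_simple_paths(net$graph, from = source, to = target,
                                 mode = "out", cutoff = L)
  paths <- lapply(ap, function(p) igraph::as_ids(p))
  paths <- paths[lengths(paths) >= 3]   # >= 2 edges
  structure(list(source = source, target = target, L = L, paths = paths),
            class = "pathSet")
}

#' @export
print.pathSet <- function(x, ...) {
  cat(sprintf("pathSet %s -> %s (L = %d): %d simple path(s)\n",
              x$source, x$target, x$L, length(x$paths)))
  invisible(x)
}

# Count simple directed paths of length 2..L between every ordered pair.
# Returns an n x n integer matrix; used by the certainty diagnostics.
countIndirectPaths <- function(net, L) {
  ids <- net$ids
  n <- length(ids)
  pc <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    ap <- igraph::all_simple_paths(net$graph, from = ids[i], mode = "out",
                                   cutoff = L)
    for (p in ap) {
      len <- length(p) - 1L
      if (len >= 2L) {
        tgt <- igraph::as_ids(p)[len + 1L]
        pc[i, tgt] <- pc[i, tgt] + 1L
      }
    }
  }
  pc
}
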