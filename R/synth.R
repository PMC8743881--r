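withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

synthIDs <- function(n) sprintf("m%02d", seq_len(n))

#' Simulate a group with a latent linear dominance hierarchy
#'
#' Generates agonistic interaction data from a known ground truth so every
#' inference stage can be validated. Each individual holds a latent rank
#' (1 = top, assigned at random to the ids). Each unordered dyad is a
#' structural zero (never interacts) with probability \code{z}; otherwise
#' it draws a Poisson(\code{lambda}) number of encounters, each won by the
#' higher-ranked member with probability \code{1 / (1 + exp(-a * d))} where
#' \code{d} is the absolute rank difference. \code{a = 0} makes every
#' encounter a fair coin; large \code{a} makes the hierarchy despotic, with
#' the higher-ranked member winning essentially always.
#'
#' @param n group size, at least 3.
#' @param a hierarchy steepness, >= 0 (logistic slope per unit rank
#'   difference).
#' @param lambda mean number of encounters per interacting dyad, > 0.
#' @param z structural-zero fraction in [0, 1): probability a dyad never
#'   interacts regardless of sampling.
#' @param seed integer RNG seed; the same seed reproduces the group
#'   bit-for-bit (the caller's RNG state is left untouched).
#' @return a \code{simulatedGroup}: list with \code{matrix} (a
#'   \code{\link{winLossMatrix}}), \code{latent_ranks} (named vector,
#'   1 = top), and \code{params}.
#' @export
simulateGroup <- function(n, a = 1, lambda = 5, z = 0, seed = NULL) {
  if (n < 3) stopDominet("dominet_parameter_error", "n must be at least 3")
  if (a < 0) stopDominet("dominet_parameter_error", "steepness a must be >= 0")
  if (lambda <= 0) stopDominet("dominet_parameter_error", "lambda must be > 0")
  if (z < 0 || z >= 1) stopDominet("dominet_parameter_error", "z must lie in [0, 1)")
  withSeed(seed, {
    ids <- synthIDs(n)
    latent <- sample.int(n)            # latent_ranks[i] = rank of ids[i]
    names(latent) <- ids
    counts <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (stats::runif(1) < z) next
        k <- stats::rpois(1, lambda)
        if (k == 0) next
        hi <- if (latent[i] < latent[j]) i else j   # smaller rank = higher
        lo <- if (hi == i) j else i
        p <- stats::plogis(a * abs(latent[i] - latent[j]))
        w <- stats::rbinom(1, k, p)
        counts[hi, lo] <- counts[hi, lo] + w
        counts[lo, hi] <- counts[lo, hi] + (k - w)
      }
    }
    structure(list(matrix = winLossMatrix(counts, ids),
                   latent_ranks = latent,
                   params = list(n = n, a = a, lambda = lambda, z = z,
                                 seed = seed)),
              class = "simulatedGroup")
  })
}

#' @export
print.simulatedGroup <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "simulatedGroup: n = %d, steepness a = %g, lambda = %g, z = %g, seed = %s\n",
    p$n, p$a, p$lambda, p$z, if (is.null(p$seed)) "NULL" else p$seed))
  invisible(x)
}

#' Linear dominance chain
#'
#' The canonical sparse-but-orderable input: individual i beats individual
#' i+1 exactly \code{m} times and no other dyad interacts. Only indirect
#' pathways order non-adjacent pairs.
#'
#' @param n number of individuals (>= 2).
#' @param m wins per chain edge.
#' @return a \code{\link{winLossMatrix}}.
#' @export
linearChain <- function(n, m = 1) {
  if (n < 2) stopDominet("dominet_parameter_error", "n must be at least 2")
  ids <- if (n <= 26) LETTERS[seq_len(n)] else synthIDs(n)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) counts[i, i + 1] <- m
  winLossMatrix(counts, ids)
}

#' Cyclic dominance network
#'
#' Individual i beats its successor around a ring: the archetype of a
#' network with circular pathways and no transitive structure.
#'
#' @param n ring size (>= 3).
#' @param m wins per edge.
#' @return a \code{\link{winLossMatrix}}.
#' @export
cycleNetwork <- function(n, m = 1) {
  if (n < 3) stopDominet("dominet_parameter_error", "n must be at least 3")
  ids <- if (n <= 26) LETTERS[seq_len(n)] else synthIDs(n)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) counts[i, i %% n + 1] <- m
  winLossMatrix(counts, ids)
}

#' Toy network of consistent and contradictory indirect pathways
#'
#' A small fixed fixture combining two classic inference motifs in one
#' matrix (all counts 1):
#' \itemize{
#'   \item A consistent motif: A beats E and E beats D, and a second
#'     parallel pathway A beats B and B beats D, while A and D never
#'     interact directly. Both pathways flow the same way, so A is inferred
#'     to outrank D with relatively high certainty.
#'   \item A contradictory motif: I beats J and J beats F (the short
#'     pathway says I outranks F) but F beats G, G beats H and H beats I (a
#'     longer pathway flowing the opposite way). F and I never interact
#'     directly, and once paths of length 3 or more are imputed the
#'     conflicting flows leave their relationship ambiguous.
#' }
#' The choice of two parallel consistent pathways (via E and via B) is a
#' fixture decision; any number of same-direction pathways gives the same
#' qualitative contrast.
#'
#' @return a \code{\link{winLossMatrix}} over ids A, B, D, E, F, G, H, I, J.
#' @export
indirectPathwaysFixture <- function() {
  edges <- rbind(
    c("A", "E"), c("E", "D"),          # consistent pathway 1
    c("A", "B"), c("B", "D"),          # consistent pathway 2
    c("I", "J"), c("J", "F"),          # short pathway: I over F
    c("F", "G"), c("G", "H"), c("H", "I"))  # contradictory long pathway
  ids <- c("A", "B", "D", "E", "F", "G", "H", "I", "J")
  counts <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(edges))) counts[edges[k, 1], edges[k, 2]] <- 1
  winLossMatrix(counts, ids)
}
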