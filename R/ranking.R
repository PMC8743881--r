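#' Upper-triangle score of a rank order
#'
#' The objective maximized by rank inference: the sum of dominance
#' probabilities dp(i, j) over all pairs in which i is placed above j.
#' Because dp(i, j) + dp(j, i) = 1, any order and its reverse score to
#' n(n-1)/2 in total.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @param ord a permutation of the ids (character) or of seq_len(n)
#'   (integer), position 1 = top rank.
#' @return the score (numeric scalar).
#' @export
orderScore <- function(dp, ord) {
  ord <- resolveOrder(dp, ord)
  P <- unclass(dp)[ord, ord]
  sum(P[upper.tri(P)])
}

resolveOrder <- function(dp, ord) {
  n <- nrow(dp)
  if (is.character(ord)) {
    ord <- match(ord, rownames(dp))
  }
  if (length(ord) != n || anyNA(ord) || !setequal(ord, seq_len(n))) {
    stopDominet("dominet_permutation_error",
                "ord must be a permutation of the matrix ids")
  }
  as.integer(ord)
}

rankOrderObj <- function(dp, ordIdx, score = NULL) {
  if (is.null(score)) score <- orderScore(dp, ordIdx)
  structure(list(order = rownames(dp)[ordIdx], score = score),
            class = "rankOrder")
}

#' @export
print.rankOrder <- function(x, ...) {
  cat(sprintf("rankOrder (score %.4f): %s\n", x$score,
              paste(x$order, collapse = " > ")))
  invisible(x)
}

# all permutations of 1..n in lexicographic order, as an n! x n matrix
permutationsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Exact optimal rank order by exhaustive permutation search
#'
#' Scans all n! orderings and returns the global maximizer of
#' \code{\link{orderScore}}. Among tied maxima the lexicographically
#' smallest id sequence is returned, making the result deterministic.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @param maxN guard against factorial blow-up; an error is raised when the
#'   group exceeds it.
#' @return a \code{rankOrder}: list with \code{order} (ids, top first) and
#'   \code{score}.
#' @export
bestOrderExact <- function(dp, maxN = 8) {
  n <- nrow(dp)
  if (n > maxN) {
    stopDominet("dominet_size_error", sprintf(
      "exact search limited to n <= %d (got n = %d); use bestOrderAnnealed",
      maxN, n))
  }
  idSorted <- order(rownames(dp))       # lexicographic base order
  P <- unclass(dp)[idSorted, idSorted]
  diag(P) <- 0
  ut <- upper.tri(P)
  perms <- permutationsOf(n)
  bestScore <- -Inf
  bestIdx <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    s <- sum(P[p, p][ut])
    if (s > bestScore + 1e-12) {        # first (lexicographic) max kept
      bestScore <- s
      bestIdx <- idSorted[p]
    }
  }
  rankOrderObj(dp, bestIdx, bestScore)
}

# deterministic starting order: descending row sums of dp, ties by id
startOrderIdx <- function(P, ids) {
  rs <- rowSums(P)
  order(-rs, ids)
}

# TRUE if id sequence a is lexicographically smaller than b
lexSmaller <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Stochastic rank-order search by simulated annealing
#'
#' The first restart begins at the descending row-sum order of the dp
#' matrix; subsequent restarts begin at random permutations so independent
#' basins of attraction are explored. Each restart proposes adjacent
#' transpositions (mostly) and random pair swaps, accepted
#' by the Metropolis rule under a geometric cooling schedule whose initial
#' temperature is the standard deviation of sampled single-move score
#' deltas. Every restart ends with deterministic hill-climbing passes
#' (adjacent transpositions and pairwise swaps to convergence), and the
#' best order ever visited is kept. The ensemble of per-restart optima is
#' returned; identical seeds reproduce identical ensembles.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @param restarts number of independent annealing runs.
#' @param seed integer RNG seed; \code{NULL} uses the current RNG state.
#' @param coolingFactor geometric cooling factor per temperature step.
#' @param tempSteps number of temperature steps per restart; each step
#'   proposes n moves.
#' @return a \code{rankOrderEnsemble}: list with \code{orders} (per-restart
#'   \code{rankOrder}s), \code{best} (ties broken by lexicographically
#'   smallest id sequence), \code{method}, \code{seed}, \code{restarts}.
#' @export
bestOrderAnnealed <- function(dp, restarts = 50, seed = NULL,
                              coolingFactor = 0.97, tempSteps = 150) {
  if (restarts < 1) {
    stopDominet("dominet_parameter_error", "restarts must be >= 1")
  }
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  ids <- rownames(dp)
  n <- nrow(dp)
  P <- unclass(dp)
  diag(P) <- 0
  ut <- upper.tri(P)
  ord0 <- startOrderIdx(P, ids)
  score0 <- sum(P[ord0, ord0][ut])
  orders <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    if (r == 1L) {
      cur0 <- ord0
      s0 <- score0
    } else {
      # later restarts begin at random permutations: a single fixed start
      # can leave every restart in the same local basin
      cur0 <- sample.int(n)
      s0 <- sum(P[cur0, cur0][ut])
    }
    res <- annealOnce(P, cur0, s0, n, coolingFactor, tempSteps)
    orders[[r]] <- rankOrderObj(dp, res$ord, res$score)
  }
  best <- orders[[1]]
  for (r in seq_along(orders)[-1]) {
    cand <- orders[[r]]
    if (cand$score > best$score + 1e-9 ||
        (abs(cand$score - best$score) <= 1e-9 &&
         lexSmaller(cand$order, best$order))) {
      best <- cand
    }
  }
  structure(list(orders = orders, best = best, method = "annealed",
                 seed = seed, restarts = restarts),
            class = "rankOrderEnsemble")
}

#' @export
print.rankOrderEnsemble <- function(x, ...) {
  cat(sprintf("rankOrderEnsemble: %d restart(s), method %s, best score %.4f\n",
              x$restarts, x$method, x$best$score))
  print(x$best)
  invisible(x)
}

annealOnce <- function(P, ord0, score0, n, coolingFactor, tempSteps) {
  cur <- ord0
  curScore <- score0
  bestOrd <- cur
  bestScore <- curScore
  # initial temperature: sd of adjacent-transposition deltas at the start
  a <- sample.int(n - 1L, 100L, replace = TRUE)
  deltas <- P[cbind(cur[a + 1L], cur[a])] - P[cbind(cur[a], cur[a + 1L])]
  T0 <- stats::sd(deltas)
  if (!is.finite(T0) || T0 < 1e-3) T0 <- 1e-3
  nMoves <- tempSteps * n
  # pre-drawn randomness: move type, positions, acceptance uniforms
  adjMove <- stats::runif(nMoves) < 0.75 | n == 2
  posAdj <- sample.int(n - 1L, nMoves, replace = TRUE)
  posA <- sample.int(n, nMoves, replace = TRUE)
  posB <- sample.int(n - 1L, nMoves, replace = TRUE)
  accU <- stats::runif(nMoves)
  temp <- rep(T0 * coolingFactor^(seq_len(tempSteps) - 1L), each = n)
  for (mv in seq_len(nMoves)) {
    if (adjMove[mv]) {
      a <- posAdj[mv]
      i <- cur[a]; j <- cur[a + 1L]
      delta <- P[j, i] - P[i, j]
      if (delta > 0 || accU[mv] < exp(delta / temp[mv])) {
        cur[a] <- j; cur[a + 1L] <- i
        curScore <- curScore + delta
        if (curScore > bestScore) { bestScore <- curScore; bestOrd <- cur }
      }
    } else {
      a <- posA[mv]
      b <- posB[mv]
      if (b >= a) b <- b + 1L                 # uniform pair a != b
      if (a > b) { tmp <- a; a <- b; b <- tmp }
      i <- cur[a]; j <- cur[b]
      mid <- if (b - a > 1L) cur[(a + 1L):(b - 1L)] else integer(0)
      delta <- P[j, i] - P[i, j] +
        sum(P[j, mid]) - sum(P[i, mid]) +
        sum(P[mid, i]) - sum(P[mid, j])
      if (delta > 0 || accU[mv] < exp(delta / temp[mv])) {
        cur[a] <- j; cur[b] <- i
        curScore <- curScore + delta
        if (curScore > bestScore) { bestScore <- curScore; bestOrd <- cur }
      }
    }
  }
  polishOrder(P, bestOrd, bestScore, n)
}

# deterministic local search: adjacent transpositions, pairwise swaps and
# single-element reinsertions, repeated until no pass improves
polishOrder <- function(P, ord, score, n) {
  repeat {
    improved <- FALSE
    for (a in seq_len(n - 1L)) {
      i <- ord[a]; j <- ord[a + 1L]
      delta <- P[j, i] - P[i, j]
      if (delta > 1e-12) {
        ord[a] <- j; ord[a + 1L] <- i
        score <- score + delta
        improved <- TRUE
      }
    }
    for (a in seq_len(n - 1L)) {
      for (b in seq((a + 1L), n)) {
        i <- ord[a]; j <- ord[b]
        mid <- if (b - a > 1L) ord[(a + 1L):(b - 1L)] else integer(0)
        delta <- P[j, i] - P[i, j] +
          sum(P[j, mid]) - sum(P[i, mid]) +
          sum(P[mid, i]) - sum(P[mid, j])
        if (delta > 1e-12) {
          ord[a] <- j; ord[b] <- i
          score <- score + delta
          improved <- TRUE
        }
      }
    }
    # reinsertion: move one element to its best position elsewhere
    for (a in seq_len(n)) {
      i <- ord[a]
      bestDelta <- 0
      bestPos <- a
      delta <- 0
      if (a < n) {                     # shift i downward past successors
        for (b in seq(a + 1L, n)) {
          j <- ord[b]
          delta <- delta + P[j, i] - P[i, j]
          if (delta > bestDelta + 1e-12) { bestDelta <- delta; bestPos <- b }
        }
      }
      delta <- 0
      if (a > 1L) {                    # shift i upward past predecessors
        for (b in seq(a - 1L, 1L)) {
          j <- ord[b]
          delta <- delta + P[i, j] - P[j, i]
          if (delta > bestDelta + 1e-12) { bestDelta <- delta; bestPos <- b }
        }
      }
      if (bestPos != a) {
        ord <- append(ord[-a], i, after = bestPos - 1L)
        score <- score + bestDelta
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  list(ord = ord, score = score)
}

#' Rank distance between two individuals
#'
#' Distance \code{|2 dp(i, j) - 1|}: 0 when the relationship is fully
#' ambiguous (dp = 0.5) and 1 when fully decided, so individuals that merge
#' low in the rank tree have the most ambiguous relationships. Symmetric in
#' i and j.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @param i,j distinct ids.
#' @return distance in [0, 1].
#' @export
rankDistance <- function(dp, i, j) {
  if (identical(i, j)) {
    stopDominet("dominet_id_error", "i and j must differ")
  }
  abs(2 * unclass(dp)[i, j] - 1)
}

rankDistanceMatrix <- function(dp) {
  d <- abs(2 * unclass(dp) - 1)
  diag(d) <- 0
  d
}

#' Hierarchical tree of rank distances
#'
#' Average-linkage agglomerative clustering of the pairwise rank distances
#' (\code{\link{rankDistance}}). Cutting the tree at a height h groups
#' individuals whose mutual dominance probabilities are closer to 0.5 than
#' the cut allows, a visual complement to \code{\link{rankTiers}}.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @return an \code{\link[stats]{hclust}} object.
#' @export
buildRankTree <- function(dp) {
  stats::hclust(stats::as.dist(rankDistanceMatrix(dp)), method = "average")
}

#' Assign nonlinear rank tiers along the ordered hierarchy
#'
#' Scans the best rank order from the top: when the dominance probability of
#' an individual over its immediate successor falls below \code{threshold}
#' the two are placed in the same tier, so tiers are contiguous runs of
#' mutually ambiguous neighbours along the diagonal of the reordered dp
#' matrix.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @param best a \code{rankOrder} (from \code{\link{bestOrderExact}} or the
#'   \code{best} element of \code{\link{bestOrderAnnealed}}).
#' @param threshold ambiguity cutoff in (0.5, 1]; adjacent dp below it
#'   merges ranks. Default 0.70.
#' @return a \code{tierAssignment}: list with \code{assignment}, a data
#'   frame (id, rank_position, tier), and \code{threshold}.
#' @export
rankTiers <- function(dp, best, threshold = 0.70) {
  if (threshold <= 0.5 || threshold > 1) {
    stopDominet("dominet_parameter_error", "threshold must lie in (0.5, 1]")
  }
  ord <- best$order
  n <- length(ord)
  tier <- integer(n)
  tier[1] <- 1L
  P <- unclass(dp)
  if (n > 1) {
    for (a in 2:n) {
      adj <- P[ord[a - 1], ord[a]]
      tier[a] <- tier[a - 1] + as.integer(adj >= threshold)
    }
  }
  structure(list(assignment = data.frame(id = ord, rank_position = seq_len(n),
                                         tier = tier,
                                         stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "tierAssignment")
}

#' @export
print.tierAssignment <- function(x, ...) {
  nt <- max(x$assignment$tier)
  cat(sprintf("tierAssignment: %d individual(s) in %d tier(s) (threshold %.2f)\n",
              nrow(x$assignment), nt, x$threshold))
  print(x$assignment, row.names = FALSE)
  invisible(x)
}
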