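# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (igraph enumeration, trace-identity census,
# annealing) so tests compare two independent routes.

randomWinLoss <- function(n, rate = 1.2, ids = NULL) {
  C <- matrix(stats::rpois(n * n, rate), n, n)
  diag(C) <- 0
  if (is.null(ids)) ids <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("x%03d", seq_len(n))
  winLossMatrix(C, ids)
}

randomDP <- function(n, ids = LETTERS[seq_len(n)]) {
  u <- matrix(stats::runif(n * n), n, n)
  dp <- u / (u + t(u))
  diag(dp) <- NA
  dimnames(dp) <- list(ids, ids)
  structure(dp, prior = 0.5, class = c("dpMatrix", "matrix"))
}

# brute-force enumeration of simple directed paths of length 2..L by
# recursive depth-first search over the positive cells of the count matrix
dfsPathsOracle <- function(counts, src, tgt, L) {
  ids <- rownames(counts)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) - 1 > L) return()
    if (last == tgt && length(path) >= 3) {
      out[[length(out) + 1]] <<- path
      return()   # simple paths cannot revisit tgt
    }
    if (length(path) - 1 == L) return()
    for (nxt in ids[counts[last, ] > 0]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(src)
  out
}

# brute-force triangle census: loop over all node triples, binarize each
# dyad by majority count, classify fully decided triples
bruteTriadOracle <- function(counts) {
  n <- nrow(counts)
  trans <- 0L
  intrans <- 0L
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 1, n - 1)) {
      for (k in seq(j + 1, n)) {
        trio <- c(i, j, k)
        wins <- outer(trio, trio, function(a, b) counts[cbind(a, b)])
        dom <- wins > t(wins)
        if (sum(dom) != 3) next          # some dyad undecided
        outdeg <- rowSums(dom)
        if (any(outdeg == 2)) trans <- trans + 1L else intrans <- intrans + 1L
      }
    }
  }
  list(transitive = trans, intransitive = intrans)
}

# exhaustive best order by scanning every permutation (own generator)
bruteBestOrder <- function(dp) {
  n <- nrow(dp)
  P <- unclass(dp)
  diag(P) <- 0
  best <- -Inf
  gen <- function(prefix, rest) {
    if (!length(rest)) {
      s <- sum(P[prefix, prefix][upper.tri(P)])
      if (s > best) best <<- s
      return()
    }
    for (r in rest) gen(c(prefix, r), setdiff(rest, r))
  }
  gen(integer(0), seq_len(n))
  best
}

# two-block dp matrix: fully ambiguous within blocks, decided between
blockDP <- function(sizes = c(3, 3), between = 0.95) {
  n <- sum(sizes)
  ids <- LETTERS[seq_len(n)]
  block <- rep(seq_along(sizes), sizes)
  dp <- matrix(0.5, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (block[i] < block[j]) dp[i, j] <- between
      if (block[i] > block[j]) dp[i, j] <- 1 - between
    }
  }
  diag(dp) <- NA
  structure(dp, prior = 0.5, class = c("dpMatrix", "matrix"))
}
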