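#' Transitivity-based weight of an indirect dominance pathway
#'
#' Indirect paths carry dominance information only insofar as the network's
#' higher-order structure is transitive. The weight is geometric in path
#' length, \code{beta^(l - 1)} with \code{beta = max(0, 2 t - 1)}: at
#' \code{t = 1} every path counts fully; at \code{t = 0.5} (triangle
#' directions at chance) indirect paths carry no information and the weight
#' is zero; longer paths are discounted more. Monotone nondecreasing in
#' \code{t} and nonincreasing in \code{l}.
#'
#' @param t transitivity index in [0, 1] (see \code{\link{transitivityIndex}}).
#' @param l path length in edges, at least 2. Vectorized over both arguments.
#' @return weight in [0, 1].
#' @export
pathWeight <- function(t, l) {
  if (any(l < 2)) {
    stopDominet("dominet_parameter_error", "path length l must be at least 2")
  }
  beta <- pmax(0, 2 * t - 1)
  beta^(l - 1)
}

#' Impute indirect dominance evidence from network pathways
#'
#' Builds the evidence matrix used to compute dominance probabilities: cell
#' (i, j) holds the direct wins c(i, j) plus, for every simple directed path
#' i -> ... -> j of length 2..L, an imputed fractional win equal to
#' \code{pathWeight(t, l)} times the product over traversed edges of the
#' edge's directional consistency f(e) = c(e) / (c(e) + c(reverse e)).
#' Each path therefore contributes at most one fractional win, so a long
#' noisy chain can never outweigh a direct observation. Paths in the two
#' directions of a dyad are imputed independently.
#'
#' With \code{L = 1} (or when \code{t <= 0.5}, giving weight zero) the
#' evidence equals the raw win counts exactly.
#'
#' @param net a \code{\link{buildNetwork}} result.
#' @param L maximum path length in edges (1 = direct observations only).
#' @param t transitivity index; normally the \code{\link{transitivityIndex}}
#'   of the same network, but may be overridden.
#' @return an \code{evidenceMatrix}: numeric matrix with ids as dimnames and
#'   attributes \code{L} and \code{transitivity}.
#' @export
imputeEvidence <- function(net, L = 2, t) {
  if (L < 1) {
    stopDominet("dominet_parameter_error", "L must be at least 1")
  }
  if (t < 0 || t > 1) {
    stopDominet("dominet_parameter_error", "transitivity t must lie in [0, 1]")
  }
  C <- net$counts
  n <- nrow(C)
  E <- C * 1.0
  beta <- max(0, 2 * t - 1)
  if (L >= 2 && beta > 0) {
    tot <- C + base::t(C)   # `t` here is the transitivity argument
    Fm <- matrix(0, n, n)
    pos <- C > 0
    Fm[pos] <- C[pos] / tot[pos]   # directional consistency per edge
    ids <- net$ids
    for (i in seq_len(n)) {
      ap <- igraph::all_simple_paths(net$graph, from = ids[i], mode = "out",
                                     cutoff = L)
      for (p in ap) {
        len <- length(p) - 1L
        if (len >= 2L) {
          v <- match(igraph::as_ids(p), ids)
          contrib <- beta^(len - 1) *
            prod(Fm[cbind(v[-length(v)], v[-1])])
          E[i, v[len + 1L]] <- E[i, v[len + 1L]] + contrib
        }
      }
    }
  }
  structure(E, L = L, transitivity = t, class = c("evidenceMatrix", "matrix"))
}

#' Dominance probability matrix
#'
#' Converts evidence (direct plus imputed wins) for each dyad into the
#' probability that i outranks j, with a symmetric smoothing prior of
#' \code{s} pseudo-wins per direction:
#' dp(i, j) = (e(i, j) + s) / (e(i, j) + e(j, i) + 2 s).
#' Rows and columns always satisfy dp(i, j) + dp(j, i) = 1; dyads with no
#' evidence in either direction sit exactly at 0.5 (full ambiguity). The
#' diagonal is masked as NA.
#'
#' @param e an \code{\link{imputeEvidence}} matrix (or any nonnegative
#'   square matrix with id dimnames).
#' @param s smoothing prior, pseudo-wins per direction; must be positive.
#'   The default 0.5 is a Jeffreys-style half win.
#' @return a \code{dpMatrix}: numeric matrix in [0, 1] with NA diagonal and
#'   attribute \code{prior}.
#' @export
dominanceProbability <- function(e, s = 0.5) {
  if (s <= 0) {
    stopDominet("dominet_parameter_error", "prior s must be positive")
  }
  E <- unclass(e)
  attr(E, "L") <- NULL
  attr(E, "transitivity") <- NULL
  dp <- (E + s) / (E + t(E) + 2 * s)
  diag(dp) <- NA_real_
  structure(dp, prior = s, class = c("dpMatrix", "matrix"))
}

#' @export
print.dpMatrix <- function(x, digits = 3, ...) {
  cat(sprintf("dpMatrix: %d individuals (prior %.3g per direction)\n",
              nrow(x), attr(x, "prior")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}
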