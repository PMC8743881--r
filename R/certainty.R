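#' Dyadic dominance certainty
#'
#' Certainty is the degree to which a relationship is decided:
#' DC(i, j) = max(dp(i, j), dp(j, i)), a symmetric matrix in [0.5, 1] where
#' 0.5 is complete ambiguity (no information, or perfectly contradictory
#' information) and 1 a fully decided relationship.
#'
#' @param dp a \code{\link{dominanceProbability}} matrix.
#' @return symmetric numeric matrix with NA diagonal.
#' @export
dyadicCertainty <- function(dp) {
  P <- unclass(dp)
  attr(P, "prior") <- NULL
  dc <- pmax(P, t(P))
  diag(dc) <- NA_real_
  dc
}

#' Individual dominance certainty
#'
#' An individual's certainty is the average certainty across all of its
#' pairwise relationships, including never-interacting dyads (whose
#' certainty comes from indirect pathways, or sits at 0.5 when no pathway
#' exists).
#'
#' @param dc a \code{\link{dyadicCertainty}} matrix.
#' @return named numeric vector, one value per individual, in [0.5, 1].
#' @export
individualCertainty <- function(dc) {
  if (nrow(dc) < 2) {
    stopDominet("dominet_small_n_error", "at least 2 individuals are required")
  }
  rowMeans(dc, na.rm = TRUE)
}

#' Group-level dominance certainty
#'
#' The average of individual certainties; because each dyad enters two
#' individual means symmetrically, this equals the mean over unordered
#' dyads of the dyadic certainties.
#'
#' @param ind an \code{\link{individualCertainty}} vector.
#' @return scalar in [0.5, 1].
#' @export
groupCertainty <- function(ind) {
  if (!length(ind)) {
    stopDominet("dominet_small_n_error", "no individuals")
  }
  mean(ind)
}

#' Diagnose inferential versus biological uncertainty
#'
#' Low certainty can mean two different things: not enough information
#' (inferential uncertainty) or genuinely unsettled relationships
#' (biological uncertainty). The diagnostic classifies every unordered dyad
#' as interacting or non-interacting and summarizes the number of indirect
#' pathways (both directions, lengths 2..L) available to each class. When
#' network transitivity is high and non-interacting dyads still have
#' abundant pathways, their ambiguity is informative and flagged as likely
#' biological; when transitivity is low or pathways are scarce, ambiguity
#' more plausibly reflects missing information and is flagged as likely
#' inferential.
#'
#' The flag is descriptive, not a hypothesis test, and its cutoffs are
#' reported alongside the summaries.
#'
#' @param net a \code{\link{buildNetwork}} result.
#' @param L maximum indirect path length, at least 2.
#' @param defaultTransitivity value used when no triple is decided.
#' @param highTransitivity cutoff above which transitivity counts as high.
#' @param minMedianPaths minimum median pathway count for non-interacting
#'   dyads to count as abundant.
#' @return a \code{certaintyDiagnostics} object: per-class path-count
#'   summaries, transitivity, and \code{flag}, one of
#'   \code{"likely biological"}, \code{"likely inferential"},
#'   \code{"no non-interacting dyads"}.
#' @export
certaintyDiagnostics <- function(net, L = 2, defaultTransitivity = 1,
                                 highTransitivity = 0.9, minMedianPaths = 1) {
  if (L < 2) {
    stopDominet("dominet_parameter_error", "L must be at least 2")
  }
  C <- net$counts
  n <- nrow(C)
  trans <- transitivityIndex(triadCensus(net), default = defaultTransitivity)
  pc <- countIndirectPaths(net, L)
  ut <- upper.tri(C)
  interacting <- (C + t(C))[ut] > 0
  dyadPaths <- (pc + t(pc))[ut]      # both directions per unordered dyad
  summarize <- function(x) {
    if (!length(x)) {
      return(c(n = 0, min = NA, q1 = NA, median = NA, mean = NA, q3 = NA,
               max = NA))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(x), min = min(x), q1 = q[1], median = q[2], mean = mean(x),
      q3 = q[3], max = max(x))
  }
  interSum <- summarize(dyadPaths[interacting])
  nonSum <- summarize(dyadPaths[!interacting])
  flag <- if (nonSum[["n"]] == 0) {
    "no non-interacting dyads"
  } else if (trans >= highTransitivity && nonSum[["median"]] >= minMedianPaths) {
    "likely biological"
  } else {
    "likely inferential"
  }
  structure(list(transitivity = trans, L = L,
                 interacting = interSum, non_interacting = nonSum,
                 cutoffs = c(high_transitivity = highTransitivity,
                             min_median_paths = minMedianPaths),
                 flag = flag),
            class = "certaintyDiagnostics")
}

#' @export
print.certaintyDiagnostics <- function(x, ...) {
  cat(sprintf("certaintyDiagnostics (L = %d): transitivity %.3f\n",
              x$L, x$transitivity))
  cat(sprintf("  interacting dyads:     n = %d, median paths = %s\n",
              x$interacting[["n"]],
              format(x$interacting[["median"]])))
  cat(sprintf("  non-interacting dyads: n = %d, median paths = %s\n",
              x$non_interacting[["n"]],
              format(x$non_interacting[["median"]])))
  cat(sprintf("  low certainty among non-interacting dyads: %s\n", x$flag))
  invisible(x)
}

# Assemble the full certainty report used by writeReport()/summary.json.
certaintyReport <- function(dp, net, L = 2, defaultTransitivity = 1) {
  dc <- dyadicCertainty(dp)
  ind <- individualCertainty(dc)
  structure(list(dyadic_dc = dc,
                 individual_dc = ind,
                 group_dc = groupCertainty(ind),
                 transitivity = transitivityIndex(triadCensus(net),
                                                  default = defaultTransitivity),
                 diagnostics = certaintyDiagnostics(
                   net, L = max(2, L),
                   defaultTransitivity = defaultTransitivity)),
            class = "certaintyReport")
}

#' @export
print.certaintyReport <- function(x, ...) {
  cat(sprintf("certaintyReport: group DC %.3f, transitivity %.3f\n",
              x$group_dc, x$transitivity))
  invisible(x)
}
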