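# Condition helper: every validation failure carries a distinct class under
# the common "dominet_error" umbrella so callers (and the CLI) can name the
# violated invariant.
stopDominet <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "dominet_error")))
}

#' Construct a win/loss matrix of agonistic outcomes
#'
#' A win/loss matrix records decided agonistic encounters in a group: cell
#' (i, j) is the number of encounters that individual i won against
#' individual j. It is the raw input to all dominance inference in this
#' package.
#'
#' @param counts square numeric matrix of nonnegative integer counts,
#'   winner in rows, loser in columns; the diagonal must be zero.
#' @param ids character vector of unique individual identifiers; defaults to
#'   the row names of \code{counts}.
#' @return an object of class \code{winLossMatrix}: the validated count
#'   matrix with \code{ids} as dimnames.
#' @examples
#' m <- winLossMatrix(matrix(c(0, 1, 3, 0), 2, 2), ids = c("A", "B"))
#' m["A", "B"]  # 3 wins of A over B
#' @export
winLossMatrix <- function(counts, ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(ids)) {
    stopDominet("dominet_id_error", "individual ids are required (no row names found)")
  }
  ids <- as.character(ids)
  if (nrow(counts) != ncol(counts)) {
    stopDominet("dominet_nonsquare_error", sprintf(
      "win/loss matrix must be square, got %d x %d", nrow(counts), ncol(counts)))
  }
  if (length(ids) != nrow(counts)) {
    stopDominet("dominet_id_error", "length of ids does not match matrix dimension")
  }
  if (anyDuplicated(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stopDominet("dominet_id_error", "ids must be unique, nonempty and non-missing")
  }
  if (length(ids) < 2) {
    stopDominet("dominet_small_n_error", "at least 2 individuals are required")
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    stopDominet("dominet_noninteger_error", "counts must be numeric and non-missing")
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0)) {
    stopDominet("dominet_negative_count_error", "counts must be nonnegative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stopDominet("dominet_noninteger_error", "counts must be whole numbers")
  }
  counts <- round(counts)
  if (any(diag(counts) != 0)) {
    stopDominet("dominet_nonzero_diagonal_error",
                "diagonal must be zero (no self-interactions)")
  }
  dimnames(counts) <- list(ids, ids)
  class(counts) <- c("winLossMatrix", class(counts))
  counts
}

#' Individual identifiers of a dominance object
#'
#' @param x a \code{winLossMatrix}, \code{dominanceNetwork}, or any object
#'   carrying ids as dimnames.
#' @return character vector of ids.
#' @export
individualIDs <- function(x) {
  if (is.list(x) && !is.null(x$ids)) return(x$ids)
  rownames(x)
}

#' @export
print.winLossMatrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("winLossMatrix: %d individuals, %d encounters, %d of %d dyads interacting\n",
              n, sum(x), sum((x + t(unclass(x)))[upper.tri(x)] > 0), n * (n - 1) / 2))
  print(unclass(x), ...)
  invisible(x)
}

#' Read a square win/loss CSV file
#'
#' The expected layout is a header row of ids, a first column of ids, and a
#' numeric body of win counts (row individual beat column individual). Row
#' and column ids must agree in content and order.
#'
#' @param path path to a CSV file.
#' @return a validated \code{\link{winLossMatrix}}.
#' @export
readWinLoss <- function(path) {
  if (!file.exists(path)) {
    stopDominet("dominet_io_error", sprintf("file not found: %s", path))
  }
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3) {
    stopDominet("dominet_nonsquare_error", "win/loss CSV needs an id column plus >= 2 count columns")
  }
  rowIDs <- as.character(raw[[1]])
  body <- raw[, -1, drop = FALSE]
  colIDs <- colnames(body)
  if (nrow(body) != ncol(body)) {
    stopDominet("dominet_nonsquare_error", sprintf(
      "win/loss CSV body must be square, got %d rows x %d columns",
      nrow(body), ncol(body)))
  }
  if (!identical(rowIDs, colIDs)) {
    stopDominet("dominet_id_mismatch_error",
                "row ids and column ids must match in content and order")
  }
  bad <- !vapply(body, is.numeric, logical(1))
  if (any(bad)) {
    stopDominet("dominet_noninteger_error", sprintf(
      "non-numeric count column(s): %s", paste(colIDs[bad], collapse = ", ")))
  }
  winLossMatrix(as.matrix(body), ids = rowIDs)
}

#' Write a win/loss matrix to CSV
#'
#' Inverse of \code{\link{readWinLoss}}: the written file round-trips to an
#' identical matrix (ids, counts, and order).
#'
#' @param m a \code{winLossMatrix}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeWinLoss <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a long-form edge list of agonistic interactions
#'
#' Expects a header with columns \code{winner} and \code{loser} and an
#' optional \code{count} column (default 1 per row). Duplicate
#' (winner, loser) rows are aggregated by summation. Individuals are indexed
#' in order of first appearance (winner before loser within a row).
#'
#' @param path path to a CSV file.
#' @return a validated \code{\link{winLossMatrix}}.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) {
    stopDominet("dominet_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("winner", "loser")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stopDominet("dominet_missing_column_error", sprintf(
      "edge list is missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  winner <- as.character(df$winner)
  loser <- as.character(df$loser)
  cnt <- if ("count" %in% colnames(df)) df$count else rep(1, nrow(df))
  if (!is.numeric(cnt) || anyNA(cnt) || any(cnt < 0)) {
    stopDominet("dominet_negative_count_error",
                "edge-list counts must be nonnegative numbers")
  }
  if (any(winner == loser)) {
    stopDominet("dominet_self_interaction_error", sprintf(
      "self-interaction (winner == loser) on row(s): %s",
      paste(which(winner == loser), collapse = ", ")))
  }
  # first-appearance id order: winner then loser within each row
  ids <- unique(as.vector(rbind(winner, loser)))
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_along(winner)) {
    counts[winner[k], loser[k]] <- counts[winner[k], loser[k]] + cnt[k]
  }
  winLossMatrix(counts, ids = ids)
}
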