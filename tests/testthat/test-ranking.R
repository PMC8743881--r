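test_that("order score sums the upper triangle under the permutation", {
  ids <- c("A", "B")
  dp <- matrix(c(NA, 0.3, 0.7, NA), 2, 2, dimnames = list(ids, ids))
  class(dp) <- c("dpMatrix", "matrix")
  expect_equal(orderScore(dp, c("A", "B")), 0.7)
  expect_equal(orderScore(dp, c("B", "A")), 0.3)
  expect_error(orderScore(dp, c("A", "A")), class = "dominet_permutation_error")
  expect_error(orderScore(dp, "A"), class = "dominet_permutation_error")

  # matches a hand-summed upper triangle on a random 5x5 matrix
  set.seed(41)
  dp5 <- randomDP(5)
  ord <- sample(rownames(dp5))
  manual <- 0
  for (a in 1:4) for (b in (a + 1):5) manual <- manual + dp5[ord[a], ord[b]]
  expect_equal(orderScore(dp5, ord), manual)

  # complement identity: score(order) + score(reverse) = n(n-1)/2
  expect_equal(orderScore(dp5, ord) + orderScore(dp5, rev(ord)), 10)
})

test_that("exact search maximizes the upper triangle with deterministic ties", {
  # consistent matrix: identity order wins
  n <- 5
  ids <- LETTERS[1:n]
  dp <- matrix(0.1, n, n, dimnames = list(ids, ids))
  dp[upper.tri(dp)] <- 0.9
  diag(dp) <- NA
  class(dp) <- c("dpMatrix", "matrix")
  expect_identical(bestOrderExact(dp)$order, ids)

  # all ties: lexicographically smallest id sequence
  flat <- matrix(0.5, 4, 4, dimnames = list(c("D", "B", "A", "C"),
                                            c("D", "B", "A", "C")))
  diag(flat) <- NA
  class(flat) <- c("dpMatrix", "matrix")
  expect_identical(bestOrderExact(flat)$order, c("A", "B", "C", "D"))

  expect_error(bestOrderExact(randomDP(9)), class = "dominet_size_error")

  # equals an exhaustive scan on random 6x6 matrices
  set.seed(42)
  for (k in 1:5) {
    dp6 <- randomDP(6)
    expect_equal(bestOrderExact(dp6)$score, bruteBestOrder(dp6))
  }
})

test_that("annealed search is seeded, reproducible, and reaches the optimum", {
  set.seed(43)
  dp <- randomDP(7)
  e1 <- bestOrderAnnealed(dp, restarts = 10, seed = 7)
  e2 <- bestOrderAnnealed(dp, restarts = 10, seed = 7)
  expect_identical(e1, e2)
  expect_equal(e1$restarts, 10)
  expect_true(all(e1$best$score + 1e-12 >=
                    vapply(e1$orders, function(o) o$score, 0)))

  # never below the row-sum starting order
  P <- unclass(dp); diag(P) <- 0
  startOrd <- rownames(dp)[order(-rowSums(P), rownames(dp))]
  expect_gte(e1$best$score, orderScore(dp, startOrd))

  # matches exact search here and beats 1000 random permutations
  expect_equal(e1$best$score, bestOrderExact(dp)$score, tolerance = 1e-9)
  for (k in 1:1000) {
    expect_gte(e1$best$score + 1e-12, orderScore(dp, sample(rownames(dp))))
  }
})

test_that("rank distance maps ambiguity to closeness", {
  ids <- c("A", "B")
  mk <- function(p) {
    dp <- matrix(c(NA, 1 - p, p, NA), 2, 2, dimnames = list(ids, ids))
    class(dp) <- c("dpMatrix", "matrix")
    dp
  }
  expect_equal(rankDistance(mk(0.5), "A", "B"), 0)
  expect_equal(rankDistance(mk(1), "A", "B"), 1)
  expect_equal(rankDistance(mk(0.70), "A", "B"), 0.4)
  expect_error(rankDistance(mk(0.7), "A", "A"), class = "dominet_id_error")
})

test_that("the rank tree merges ambiguous pairs low and decided pairs high", {
  ids <- c("A", "B")
  dp <- matrix(c(NA, 0.5, 0.5, NA), 2, 2, dimnames = list(ids, ids))
  class(dp) <- c("dpMatrix", "matrix")
  h <- buildRankTree(dp)
  expect_equal(h$height, 0)

  # block structure: cutting at 0.4 recovers the blocks
  dpb <- blockDP(c(3, 3), between = 0.95)
  cl <- stats::cutree(buildRankTree(dpb), h = 0.4)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[1:3])), 1)
  expect_equal(length(unique(cl[4:6])), 1)

  # fully decided relationships never merge below height 1
  dpd <- blockDP(c(1, 1, 1), between = 1)
  hd <- buildRankTree(dpd)
  expect_true(all(hd$height >= 1 - 1e-12))
})

test_that("tiers are contiguous runs of ambiguous neighbours", {
  # strongly decided adjacent relationships: all singleton tiers
  n <- 5
  ids <- LETTERS[1:n]
  dp <- matrix(0.01, n, n, dimnames = list(ids, ids))
  dp[upper.tri(dp)] <- 0.99
  diag(dp) <- NA
  class(dp) <- c("dpMatrix", "matrix")
  best <- bestOrderExact(dp)
  tiers <- rankTiers(dp, best, threshold = 0.70)
  expect_equal(tiers$assignment$tier, 1:5)

  # fully ambiguous: a single tier
  flat <- blockDP(c(4), between = 0.5)
  bflat <- bestOrderExact(flat)
  expect_equal(unique(rankTiers(flat, bflat, 0.70)$assignment$tier), 1L)

  # two-block matrix: exactly the two blocks at the default threshold
  dpb <- blockDP(c(3, 3), between = 0.95)
  bb <- bestOrderExact(dpb)
  tb <- rankTiers(dpb, bb, threshold = 0.70)
  expect_equal(max(tb$assignment$tier), 2)
  expect_equal(tb$assignment$tier, rep(1:2, each = 3))

  # threshold near 0.5 gives singletons when all dyads are decided;
  # threshold 1 pools everyone unless some dp = 1
  tlo <- rankTiers(dp, best, threshold = 0.5001)
  expect_equal(tlo$assignment$tier, 1:5)
  thi <- rankTiers(dp, best, threshold = 1)
  expect_equal(unique(thi$assignment$tier), 1L)
  expect_error(rankTiers(dp, best, threshold = 0.5),
               class = "dominet_parameter_error")
})
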