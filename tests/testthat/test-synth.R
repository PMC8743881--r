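test_that("simulation is seeded, valid, and parameter-checked", {
  g1 <- simulateGroup(10, a = 1.5, lambda = 4, z = 0.2, seed = 99)
  g2 <- simulateGroup(10, a = 1.5, lambda = 4, z = 0.2, seed = 99)
  expect_identical(g1, g2)
  expect_s3_class(g1$matrix, "winLossMatrix")
  expect_setequal(g1$latent_ranks, 1:10)
  g3 <- simulateGroup(10, a = 1.5, lambda = 4, z = 0.2, seed = 100)
  expect_false(identical(g1$matrix, g3$matrix))

  expect_error(simulateGroup(2, 1, 1, 0), class = "dominet_parameter_error")
  expect_error(simulateGroup(5, -1, 1, 0), class = "dominet_parameter_error")
  expect_error(simulateGroup(5, 1, 0, 0), class = "dominet_parameter_error")
  expect_error(simulateGroup(5, 1, 1, 1), class = "dominet_parameter_error")

  # simulateGroup leaves the caller's RNG stream untouched
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(simulateGroup(6, 1, 2, 0, seed = 3)); b <- runif(1)
  expect_identical(a, b)
})

test_that("steepness limits behave as the win-probability model predicts", {
  # despotic limit: the higher-ranked member wins every encounter and the
  # triangle census is fully transitive
  g <- simulateGroup(10, a = 50, lambda = 6, z = 0, seed = 1)
  C <- unclass(g$matrix)
  r <- g$latent_ranks
  for (i in 1:9) for (j in (i + 1):10) {
    lower <- if (r[i] < r[j]) j else i    # larger latent rank = subordinate
    higher <- if (lower == i) j else i
    expect_equal(C[lower, higher], 0)
  }
  cen <- triadCensus(buildNetwork(g$matrix))
  expect_gt(cen$transitive, 0)
  expect_equal(cen$intransitive, 0)

  # flat limit: wins split like a fair coin; pooled win fraction of the
  # nominally higher-ranked member approaches 1/2
  wins <- hi <- 0
  for (s in 1:5) {
    gf <- simulateGroup(12, a = 0, lambda = 20, z = 0, seed = s)
    Cf <- unclass(gf$matrix)
    rf <- gf$latent_ranks
    hiMat <- outer(rf, rf, "<")
    wins <- wins + sum(Cf[hiMat])
    hi <- hi + sum(Cf)
  }
  expect_lt(abs(wins / hi - 0.5), 0.03)
})

test_that("encounter volume matches the thinned-Poisson expectation", {
  n <- 15; lambda <- 10; z <- 0.3
  nd <- n * (n - 1) / 2
  totals <- vapply(1:20, function(s) {
    sum(simulateGroup(n, a = 2, lambda = lambda, z = z, seed = s)$matrix)
  }, 0)
  expected <- (1 - z) * lambda * nd
  # per-dyad variance of a Bernoulli(1-z)-thinned Poisson(lambda)
  vDyad <- (1 - z) * (lambda + lambda^2) - ((1 - z) * lambda)^2
  se <- sqrt(nd * vDyad / 20)
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("chains and cycles have their canonical structure", {
  ch <- linearChain(3, 1)
  expect_equal(sum(ch), 2)
  expect_equal(unclass(ch)["A", "B"], 1)
  expect_equal(unclass(ch)["B", "C"], 1)
  expect_equal(sum(linearChain(2, 4)), 4)

  cy <- cycleNetwork(3, 1)
  cen <- triadCensus(buildNetwork(cy))
  expect_equal(cen$transitive, 0)
  expect_equal(cen$intransitive, 1)
  expect_equal(transitivityIndex(cen), 0)

  # a 6-cycle has no decided triangle at all: the default applies
  cen6 <- triadCensus(buildNetwork(cycleNetwork(6, 2)))
  expect_equal(cen6$transitive + cen6$intransitive, 0)
  expect_equal(transitivityIndex(cen6, default = 1), 1)

  # with transitivity forced to 0, non-adjacent ring dyads stay neutral
  net6 <- buildNetwork(cycleNetwork(6, 2))
  dp6 <- dominanceProbability(imputeEvidence(net6, L = 3, t = 0))
  expect_equal(unclass(dp6)["A", "D"], 0.5)
  expect_equal(unclass(dp6)["B", "E"], 0.5)

  # chain order is recovered through indirect pathways alone
  res <- dominanceAnalysis(linearChain(6, 2), maxPathLength = 3, seed = 1)
  expect_identical(res$best$order, LETTERS[1:6])
})

test_that("steeper hierarchies are easier to recover and more certain", {
  rec <- function(a) {
    vapply(1:10, function(s) {
      g <- simulateGroup(10, a = a, lambda = 6, z = 0.2, seed = s)
      res <- dominanceAnalysis(g$matrix, seed = s)
      pos <- match(rownames(g$matrix), res$best$order)
      cor(pos, g$latent_ranks, method = "spearman")
    }, 0)
  }
  gdc <- function(a) {
    vapply(1:10, function(s) {
      g <- simulateGroup(10, a = a, lambda = 6, z = 0.2, seed = s)
      dominanceAnalysis(g$matrix, seed = s)$report$group_dc
    }, 0)
  }
  expect_gte(mean(rec(3)), mean(rec(0.5)))
  expect_gte(mean(gdc(3)), mean(gdc(0.5)))
})

test_that("the pathway fixture encodes the two inference motifs", {
  m <- indirectPathwaysFixture()
  C <- unclass(m)
  expect_equal(sum(C), 9)                      # nine single-count edges
  expect_equal(C["A", "D"] + C["D", "A"], 0)   # A and D never interact
  expect_equal(C["F", "I"] + C["I", "F"], 0)   # F and I never interact

  res <- dominanceAnalysis(m, maxPathLength = 4, seed = 1)
  dp <- unclass(res$dp)
  dc <- res$report$dyadic_dc
  expect_gt(dp["A", "D"], 0.5)                 # inferred without interaction
  expect_gt(dc["A", "D"], dc["F", "I"])        # contradiction lowers certainty

  # deleting the contradictory chain strictly raises DC(F, I)
  C2 <- C
  C2["F", "G"] <- C2["G", "H"] <- C2["H", "I"] <- 0
  res2 <- dominanceAnalysis(winLossMatrix(C2), maxPathLength = 4, seed = 1)
  expect_gt(res2$report$dyadic_dc["F", "I"], dc["F", "I"])
})
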