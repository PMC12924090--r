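# random symmetric Fisher-z matrix from independent Gaussian series
randomZMatrix <- function(K, Tn = 60) {
  fisherZMatrix(matrix(rnorm(K * Tn), K, Tn,
                       dimnames = list(sprintf("R%d", 1:K), NULL)))
}

test_that("Spearman upper-triangle similarity behaves like rank-then-Pearson", {
  set.seed(21)
  A <- randomZMatrix(4)
  expect_equal(spearmanUppertri(A, A), 1)

  # rank-reversing transform of A
  B <- ConnectivityMatrix(-zValues(A), roiLabels(A))
  expect_equal(spearmanUppertri(A, B), -1)

  # hand-built pair against an independent rank-then-Pearson oracle
  B2 <- randomZMatrix(4)
  va <- zValues(A)[upper.tri(zValues(A))]
  vb <- zValues(B2)[upper.tri(zValues(B2))]
  expect_equal(spearmanUppertri(A, B2), cor(rank(va), rank(vb)))
  expect_equal(spearmanUppertri(A, B2), cor(va, vb, method = "spearman"))

  mism <- ConnectivityMatrix(zValues(B2), c("x", "y", "z", "w"))
  expect_error(spearmanUppertri(A, mism), "labels")
})

test_that("rho is invariant under a common ROI relabeling", {
  set.seed(22)
  A <- randomZMatrix(6); B <- randomZMatrix(6)
  p <- sample(6)
  Ap <- ConnectivityMatrix(zValues(A)[p, p], roiLabels(A)[p])
  Bp <- ConnectivityMatrix(zValues(B)[p, p], roiLabels(B)[p])
  expect_equal(spearmanUppertri(Ap, Bp), spearmanUppertri(A, B),
               tolerance = 1e-12)
})

test_that("permutation similarity flags identity as extreme and is seed-stable", {
  set.seed(23)
  A <- randomZMatrix(8)
  r1 <- permutationSimilarity(A, A, nIter = 999, seed = 7)
  expect_equal(r1@rho, 1)
  expect_lte(r1@p, 0.01)
  expect_equal(r1@method, "permutation")

  r2 <- permutationSimilarity(A, A, nIter = 999, seed = 7)
  expect_identical(r1@p, r2@p)
  r3 <- permutationSimilarity(A, A, nIter = 999, seed = 8)
  expect_equal(r3@rho, r1@rho)                   # rho does not depend on the seed

  expect_error(permutationSimilarity(A, A, nIter = 0, seed = 1), "nIter")
})

test_that("the exact Mantel test enumerates all joint label permutations", {
  set.seed(24)
  A <- randomZMatrix(3)
  res <- mantelExact(A, A)
  expect_equal(res@nIter, 6L)                    # 3! permutations
  expect_equal(res@rho, 1)
  expect_equal(res@method, "mantel_exact")

  # p equals the brute-force enumeration count / 6 (identity included)
  B <- randomZMatrix(3)
  obs <- spearmanUppertri(A, B)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  rhos <- vapply(perms, function(p) {
    Bp <- ConnectivityMatrix(zValues(B)[p, p], roiLabels(B))
    spearmanUppertri(A, Bp)
  }, numeric(1))
  kGe <- sum(rhos >= obs - 1e-12)
  got <- mantelExact(A, B)
  expect_equal(got@p, kGe / 6)
  expect_gte(got@p, 1 / 6)
  expect_equal(got@p * 6, round(got@p * 6))      # granularity 1/6

  expect_error(mantelExact(randomZMatrix(8), randomZMatrix(8)), "sampled")
})

test_that("exact and sampled Mantel agree within Monte Carlo error at K = 5", {
  set.seed(25)
  A <- randomZMatrix(5); B <- randomZMatrix(5)
  pe <- mantelExact(A, B)@p
  ps <- permutationSimilarity(A, B, nIter = 10000, seed = 3)@p
  se <- sqrt(pe * (1 - pe) / 10000)
  expect_lt(abs(ps - pe), 3 * se + 2 / 10000)
})

test_that("the Mantel statistic matches the field-standard implementation", {
  skip_if_not_installed("vegan")
  set.seed(26)
  A <- randomZMatrix(6); B <- randomZMatrix(6)
  vg <- vegan::mantel(as.dist(zValues(A)), as.dist(zValues(B)),
                      method = "spearman", permutations = 0)
  expect_equal(spearmanUppertri(A, B), unname(vg$statistic), tolerance = 1e-12)
})

test_that("Steiger's dependent-correlation test has the documented behaviour", {
  expect_equal(as.numeric(compareDependentCorrelations(0.5, 0.5, 0.3, 100)), 1)
  # symmetry in the two correlations
  p1 <- compareDependentCorrelations(0.60, 0.47, 0.51, 200)
  p2 <- compareDependentCorrelations(0.47, 0.60, 0.51, 200)
  expect_equal(as.numeric(p1), as.numeric(p2))
  expect_equal(attr(p1, "z"), -attr(p2, "z"))

  # worked example against an independently coded oracle of the same formulas
  steigerOracle <- function(r13, r23, r12, n) {
    z13 <- 0.5 * log((1 + r13) / (1 - r13))
    z23 <- 0.5 * log((1 + r23) / (1 - r23))
    rb <- (r13 + r23) / 2
    cov <- (r12 * (1 - 2 * rb^2) - 0.5 * rb^2 * (1 - 2 * rb^2 - r12^2)) /
      (1 - rb^2)^2
    zstat <- (z13 - z23) * sqrt((n - 3) / (2 - 2 * cov))
    2 * (1 - pnorm(abs(zstat)))
  }
  got <- compareDependentCorrelations(0.6, 0.47, 0.51, 150)
  expect_equal(as.numeric(got), steigerOracle(0.6, 0.47, 0.51, 150),
               tolerance = 1e-12)
  # a larger sample makes the same difference more significant
  expect_lt(as.numeric(compareDependentCorrelations(0.6, 0.47, 0.51, 2000)),
            as.numeric(got))

  expect_error(compareDependentCorrelations(1, 0.5, 0.3, 100), "strictly")
  expect_error(compareDependentCorrelations(0.5, 0.4, 0.3, 3), "nEff")
})
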