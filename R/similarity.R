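# Between-method similarity of connectivity matrices: Spearman rho over the
# upper triangles, with Mantel-style permutation nulls that permute ROI labels
# jointly on rows and columns (cells of a symmetric matrix are not
# exchangeable; label permutation is).

upperTriValues <- function(cm) {
  m <- if (is(cm, "ConnectivityMatrix")) cm@values else as.matrix(cm)
  m[upper.tri(m)]
}

checkSameRois <- function(A, B) {
  la <- if (is(A, "ConnectivityMatrix")) A@roiLabels else rownames(A)
  lb <- if (is(B, "ConnectivityMatrix")) B@roiLabels else rownames(B)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("the two matrices have different ROI labels or ordering")
  invisible(TRUE)
}

# centred-rank Pearson with average-rank ties
spearmanVec <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ra <- ra - mean(ra); rb <- rb - mean(rb)
  sum(ra * rb) / sqrt(sum(ra^2) * sum(rb^2))
}

#' Spearman similarity of two connectivity matrices
#'
#' Spearman rank correlation of the K(K-1)/2 upper-triangle entries, with
#' average-rank tie handling. Both matrices must carry the same ROI labels in
#' the same order.
#'
#' @param A,B \linkS4class{ConnectivityMatrix} objects (or symmetric matrices)
#'   over the same ROIs, K >= 3.
#' @return Spearman rho.
#' @export
spearmanUppertri <- function(A, B) {
  checkSameRois(A, B)
  va <- upperTriValues(A); vb <- upperTriValues(B)
  if (length(va) < 3L) stop("need at least 3 ROIs")
  spearmanVec(va, vb)
}

#' Monte Carlo permutation test of matrix similarity
#'
#' Builds the null by jointly permuting the row and column labels of B
#' (symmetry-preserving, Mantel-style) \code{nIter} times and computing the
#' Spearman upper-triangle correlation each time. The one-sided p-value is
#' \code{(1 + #\{rho_perm >= rho_obs\}) / (1 + nIter)}; the +1 keeps p > 0.
#'
#' @param A,B matrices as in \code{\link{spearmanUppertri}}.
#' @param nIter permutation count (default 5000).
#' @param seed integer RNG seed.
#' @param alternative "greater" (default; the similarity hypothesis) or
#'   "two.sided".
#' @return A \linkS4class{SimilarityResult} with method "permutation".
#' @export
permutationSimilarity <- function(A, B, nIter = 5000, seed,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nIter <- as.integer(nIter)
  if (nIter < 1L) stop("nIter must be >= 1")
  checkSameRois(A, B)
  mb <- if (is(B, "ConnectivityMatrix")) B@values else as.matrix(B)
  K <- nrow(mb)
  va <- upperTriValues(A)
  if (length(va) < 3L) stop("need at least 3 ROIs")
  ra <- rank(va); ra <- ra - mean(ra); da <- sqrt(sum(ra^2))
  rhoOf <- function(m) {
    vb <- m[upper.tri(m)]
    rb <- rank(vb); rb <- rb - mean(rb)
    sum(ra * rb) / (da * sqrt(sum(rb^2)))
  }
  obs <- rhoOf(mb)
  set.seed(as.integer(seed))
  perm <- numeric(nIter)
  for (i in seq_len(nIter)) {
    p <- sample.int(K)
    perm[i] <- rhoOf(mb[p, p])
  }
  exceed <- if (alternative == "greater") sum(perm >= obs)
            else sum(abs(perm) >= abs(obs))
  p <- (1 + exceed) / (1 + nIter)
  new("SimilarityResult", rho = obs, p = p, nIter = nIter,
      seed = as.integer(seed), method = "permutation")
}

# all permutations of 1..n (n small)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Exact Mantel test for small matrices
#'
#' Enumerates all K! joint row/column label permutations of B and reports
#' \code{p = #\{rho_perm >= rho_obs\} / K!}. The identity permutation is part
#' of the enumeration, so p >= 1/K! and p has granularity 1/K!.
#'
#' @param A,B matrices as in \code{\link{spearmanUppertri}}, K <= 7.
#' @return A \linkS4class{SimilarityResult} with method "mantel_exact" and
#'   \code{nIter = K!}.
#' @export
mantelExact <- function(A, B) {
  checkSameRois(A, B)
  mb <- if (is(B, "ConnectivityMatrix")) B@values else as.matrix(B)
  K <- nrow(mb)
  if (K > 7L)
    stop("K > 7: exact enumeration infeasible, use permutationSimilarity ",
         "(sampled Mantel) instead")
  va <- upperTriValues(A)
  if (length(va) < 3L) stop("need at least 3 ROIs")
  perms <- allPermutations(K)
  obs <- spearmanVec(va, mb[upper.tri(mb)])
  rhos <- apply(perms, 1, function(p) {
    m <- mb[p, p]
    spearmanVec(va, m[upper.tri(m)])
  })
  p <- sum(rhos >= obs - 1e-12) / nrow(perms)
  new("SimilarityResult", rho = obs, p = p, nIter = as.integer(nrow(perms)),
      seed = NA_integer_, method = "mantel_exact")
}

#' Steiger's test for two dependent correlations sharing one variable
#'
#' Tests whether two correlations with a common variable (here: each method's
#' network map correlated with the same template) differ, using Steiger's
#' modification of Dunn and Clark's z with the mean correlation plugged into
#' the covariance term; two-sided normal-approximation p-value.
#'
#' Spatial autocorrelation makes the voxel count an overestimate of the
#' effective sample size; \code{nEff} must be supplied by the caller.
#'
#' @param rA,rB the two dependent correlations (each in (-1, 1)).
#' @param rAB correlation between the two maps (in (-1, 1)).
#' @param nEff effective sample size (>= 4).
#' @return Two-sided p-value, with attributes \code{"z"} (the test statistic).
#' @export
compareDependentCorrelations <- function(rA, rB, rAB, nEff) {
  vals <- c(rA = rA, rB = rB, rAB = rAB)
  if (any(abs(vals) >= 1)) stop("correlations must lie strictly in (-1, 1)")
  if (nEff < 4) stop("nEff must be >= 4")
  z1 <- atanh(rA); z2 <- atanh(rB)
  rbar <- (rA + rB) / 2
  s <- (rAB * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - rAB^2)) /
    (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((nEff - 3) / (2 * (1 - s)))
  p <- 2 * stats::pnorm(-abs(z))
  attr(p, "z") <- z
  p
}
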