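#' Genomic relationship matrices
#'
#' `grm_additive()` builds the VanRaden additive relationship matrix
#' \deqn{A = W W' / (2 \sum_k p_k (1 - p_k)),}
#' where `W = M - 2P` centers the dosage matrix by twice the allele frequency
#' of each marker. `grm_dominance()` builds the Vitezica dominance matrix
#' \deqn{D = H H' / \sum_k (2 p_k q_k)^2,}
#' with the dominance covariate per marker equal to `-2q^2`, `2pq`, `-2p^2`
#' for dosages 2, 1, 0 (`q = 1 - p`). Allele frequencies are estimated from
#' the supplied matrix itself (the hybrids whose relationships are described),
#' which makes every row of `A` sum to zero exactly.
#'
#' Both matrices are symmetric positive semidefinite by construction (they are
#' Gram matrices). Monomorphic markers contribute nothing; if the whole panel
#' is monomorphic the normalizing constant is zero and an error is raised.
#'
#' @param hybrids A [geno_matrix()] with no missing dosages.
#' @return A symmetric matrix with entity dimnames and attributes `kind`
#'   ("additive" or "dominance") and `freq` (allele frequencies used).
#' @examples
#' m <- geno_matrix(matrix(c(0, 2), 2, 1, dimnames = list(c("h1", "h2"), "M1")),
#'                  kind = "hybrid")
#' grm_additive(m)  # [[2, -2], [-2, 2]]
#' @export
grm_additive <- function(hybrids) {
  parts <- additive_design(hybrids)
  A <- tcrossprod(parts$W) / parts$c
  dimnames(A) <- list(rownames(hybrids), rownames(hybrids))
  structure(A, kind = "additive", freq = parts$p)
}

#' @rdname grm_additive
#' @export
grm_dominance <- function(hybrids) {
  parts <- dominance_design(hybrids)
  D <- tcrossprod(parts$H) / parts$c
  dimnames(D) <- list(rownames(hybrids), rownames(hybrids))
  structure(D, kind = "dominance", freq = parts$p)
}

# centered additive design W = M - 2p and its normalizer c = 2*sum(p*q);
# shared between the kernels and the generative model so that simulated
# genetic values have covariance sigma2 * A exactly.
additive_design <- function(geno) {
  m <- unclass(geno)
  if (anyNA(m)) abort("dosage matrix contains missing values; impute first")
  p <- colMeans(m) / 2
  c_a <- 2 * sum(p * (1 - p))
  if (c_a <= 0) abort("all markers monomorphic: additive normalizer is zero")
  list(W = sweep(m, 2, 2 * p), p = p, c = c_a)
}

dominance_design <- function(geno) {
  m <- unclass(geno)
  if (anyNA(m)) abort("dosage matrix contains missing values; impute first")
  p <- colMeans(m) / 2
  q <- 1 - p
  c_d <- sum((2 * p * q)^2)
  if (c_d <= 0) abort("all markers monomorphic: dominance normalizer is zero")
  H <- matrix(rep(-2 * p^2, each = nrow(m)), nrow(m), ncol(m))
  H[m == 1] <- matrix(rep(2 * p * q, each = nrow(m)), nrow(m), ncol(m))[m == 1]
  H[m == 2] <- matrix(rep(-2 * q^2, each = nrow(m)), nrow(m), ncol(m))[m == 2]
  dimnames(H) <- dimnames(m)
  list(H = H, p = p, c = c_d)
}
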