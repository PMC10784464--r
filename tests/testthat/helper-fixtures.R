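# Small in-code fixtures shared across the suite.

small_config <- function(seed = 1L, ...) {
  sim_config(
    n_lines_per_group = c(dent = 15, flint = 15, C = 6),
    n_hybrids = 45, n_snps = 200, n_chromosomes = 4,
    seed = seed, ...
  )
}

small_sim <- function(seed = 1L, ...) {
  simulate_met(small_config(seed = seed, ...))
}

# dosage matrix built column-by-column from a list of marker vectors
toy_geno <- function(..., kind = "hybrid") {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("M%d", seq_along(cols))
  rownames(m) <- sprintf("h%d", seq_len(nrow(m)))
  geno_matrix(m, kind = kind)
}

# brute-force VanRaden / Vitezica kernels by explicit double loops
oracle_additive <- function(m) {
  p <- colMeans(m) / 2
  W <- sweep(m, 2, 2 * p)
  n <- nrow(m)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      A[i, j] <- sum(W[i, ] * W[j, ])
    }
  }
  A / (2 * sum(p * (1 - p)))
}

oracle_dominance <- function(m) {
  p <- colMeans(m) / 2
  q <- 1 - p
  n <- nrow(m)
  H <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    for (k in seq_len(ncol(m))) {
      H[i, k] <- switch(as.character(m[i, k]),
                        "0" = -2 * p[k]^2,
                        "1" = 2 * p[k] * q[k],
                        "2" = -2 * q[k]^2)
    }
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      D[i, j] <- sum(H[i, ] * H[j, ])
    }
  }
  D / sum((2 * p * q)^2)
}

# random PSD kernel with unit mean diagonal
random_kernel <- function(n, seed, ids = sprintf("h%d", seq_len(n))) {
  withr::with_seed(seed, {
    L <- matrix(rnorm(n * n), n, n)
    K <- crossprod(L) / n
  })
  K <- K / mean(diag(K))
  dimnames(K) <- list(ids, ids)
  K
}

# SNP + environment-factor feature fixture for the tree-ensemble tests
feature_fixture <- function(seed = 1, p_hyb = 40, n_snps = 30, noise = 0.3) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:2, p_hyb * n_snps, replace = TRUE), p_hyb, n_snps)
    dimnames(m) <- list(sprintf("h%d", 1:p_hyb), sprintf("M%d", 1:n_snps))
    g <- geno_matrix(m, kind = "hybrid")
    env_info <- tibble::tibble(environment = c("J10", "T10", "J11", "T11"),
                               location = c("J", "T", "J", "T"),
                               year = c(2010L, 2010L, 2011L, 2011L))
    cells <- tidyr::expand_grid(environment = env_info$environment,
                                hybrid = rownames(m))
    beta <- rnorm(n_snps, 0, 0.2)
    env_eff <- c(J10 = 0, T10 = 1, J11 = -0.5, T11 = 0.5)
    cells$eblue <- drop(m[cells$hybrid, ] %*% beta) +
      env_eff[cells$environment] + rnorm(nrow(cells), 0, noise)
  })
  list(geno = g, env_info = env_info, cells = tibble::as_tibble(cells))
}
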