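#' Likelihood ratio test for a variance component
#'
#' `LRT = 2 (logL_complete - logL_reduced)`, referred to a chi-square
#' distribution with one degree of freedom at the 5% level. The plain
#' one-df reference is used even though the tested parameter sits on the
#' boundary of its space under the null (where a 50:50 chi-square mixture
#' would be less conservative); this matches long-standing practice in
#' variance-component testing and is applied here deliberately.
#'
#' @param full,reduced `gblup_fit` objects (or bare log-likelihood numbers);
#'   `reduced` must be nested in `full`.
#' @param tol Tolerance for a slightly negative statistic caused by
#'   convergence noise; beyond it an error is raised.
#' @return Tibble with `statistic`, `df`, `p_value`, `significant`
#'   (strict `p < 0.05`).
#' @examples
#' lrt(-100, -102)  # statistic 4, p ~ 0.0455
#' @export
lrt <- function(full, reduced, tol = 1e-6) {
  lf <- if (inherits(full, "gblup_fit")) full$logL else full
  lr <- if (inherits(reduced, "gblup_fit")) reduced$logL else reduced
  stat <- 2 * (lf - lr)
  if (stat < -tol) {
    abort(sprintf(
      "negative LRT statistic (%.6f): models not nested or the full fit did not converge",
      stat))
  }
  stat <- max(stat, 0)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  tibble(statistic = stat, df = 1L, p_value = p, significant = p < 0.05)
}

#' Genetic parameters from variance components
#'
#' Narrow-sense heritability, dominance proportion and broad-sense
#' heritability as variance ratios:
#' \deqn{h^2 = \sigma^2_{u_a} / (\sigma^2_{u_a} + \sigma^2_{u_d} + \sigma^2_e),
#'   \quad d^2 = \sigma^2_{u_d} / (\cdot), \quad H^2 = h^2 + d^2.}
#'
#' @param x Additive variance, or a `gblup_fit`.
#' @param ... Passed between methods.
#' @return Tibble with columns `h2`, `d2`, `H2`.
#' @examples
#' genetic_params(0.60, 0.30, 0.81)  # h2 = 0.35, H2 = 0.53 (2 dp)
#' @export
genetic_params <- function(x, ...) UseMethod("genetic_params")

#' @rdname genetic_params
#' @param sigma2_d Dominance variance (0 for an additive-only fit).
#' @param sigma2_e Residual variance.
#' @export
genetic_params.default <- function(x, sigma2_d = 0, sigma2_e, ...) {
  sigma2_a <- x
  if (any(c(sigma2_a, sigma2_d, sigma2_e) < 0)) abort("variances must be nonnegative")
  tot <- sigma2_a + sigma2_d + sigma2_e
  if (length(tot) == 1 && tot == 0) {
    abort("all variance components are zero: heritability undefined")
  }
  tibble(h2 = sigma2_a / tot, d2 = sigma2_d / tot,
         H2 = (sigma2_a + sigma2_d) / tot)
}

#' @rdname genetic_params
#' @export
genetic_params.gblup_fit <- function(x, ...) {
  genetic_params(x$vc$sigma2_a, x$vc$sigma2_d %||% 0, x$vc$sigma2_e)
}

#' Predict hybrid-by-environment cells from a fitted GBLUP model
#'
#' Computes, for each requested cell, the fixed environment mean by
#' generalized least squares plus the BLUP of the genetic value:
#' \deqn{\hat y_{ij} = \hat b_j + Cov(u_{ij}, y_{obs}) V_{obs}^{-1}
#'   (y_{obs} - X \hat b),}
#' with the covariance assembled from the compound-symmetry-by-kernel blocks
#' of the joint model. Target hybrids may be unphenotyped (CV1) or observed in
#' other environments (CV2); hybrids absent from the kernels are an error.
#'
#' @param object A `gblup_fit`.
#' @param targets Tibble with columns `hybrid`, `environment`.
#' @param A,D Optional kernels superseding the ones stored in the fit (must
#'   contain all target and observed hybrids; used when the fit was made on a
#'   training subset).
#' @param ... Unused.
#' @return Tibble `hybrid`, `environment`, `method`, `pred`.
#' @export
predict_cells <- function(object, targets, A = NULL, D = NULL, ...) {
  stopifnot(inherits(object, "gblup_fit"))
  # kernels stored in the fit already carry the ridge; user-supplied ones get it here
  if (is.null(A)) {
    A <- object$A
  } else {
    A <- A + object$jitter * diag(nrow(A))
  }
  if (object$model == "AD") {
    if (is.null(D)) {
      D <- object$D
    } else {
      D <- D + object$jitter * diag(nrow(D))
    }
  } else {
    D <- NULL
  }
  hyb_all <- rownames(A)
  missing_h <- setdiff(targets$hybrid, hyb_all)
  if (length(missing_h)) {
    abort(paste("target hybrids absent from the kernels:",
                paste(utils::head(missing_h, 5), collapse = ", ")))
  }
  env_levels <- object$env_levels
  if (!all(targets$environment %in% env_levels)) {
    abort("target environment not part of the fitted model")
  }
  q <- object$q
  p <- length(hyb_all)
  obs <- object$eblues
  oi <- (match(obs$environment, env_levels) - 1L) * p + match(obs$hybrid, hyb_all)
  ti <- (match(targets$environment, env_levels) - 1L) * p +
    match(targets$hybrid, hyb_all)

  vc <- object$vc
  G <- kronecker(cs_matrix(q, vc$sigma2_a, vc$rho_a %||% 0), A)
  if (!is.null(D)) {
    G <- G + kronecker(cs_matrix(q, vc$sigma2_d %||% 0, vc$rho_d %||% 0), D)
  }
  Voo <- G[oi, oi, drop = FALSE]
  diag(Voo) <- diag(Voo) + vc$sigma2_e
  ch <- chol(Voo)
  X <- matrix(0, length(oi), q)
  X[cbind(seq_along(oi), match(obs$environment, env_levels))] <- 1
  ViX <- chol2inv(ch) %*% X
  beta <- solve(crossprod(X, ViX), crossprod(ViX, obs$value))
  resid <- obs$value - X %*% beta
  alpha <- backsolve(ch, backsolve(ch, resid, transpose = TRUE))
  pred <- beta[match(targets$environment, env_levels)] +
    G[ti, oi, drop = FALSE] %*% alpha
  tibble(hybrid = targets$hybrid, environment = targets$environment,
         method = paste0("gblup_", tolower(object$model)),
         pred = as.numeric(pred))
}

#' @export
#' @rdname reml_fit
#' @param x A `gblup_fit` (for the broom methods).
tidy.gblup_fit <- function(x, ...) {
  tibble(term = names(unlist(x$vc)), estimate = as.numeric(unlist(x$vc)))
}

#' @export
#' @rdname reml_fit
glance.gblup_fit <- function(x, ...) {
  tibble(logLik = x$logL, model = paste0("GBLUP-", x$model), q = x$q,
         n_obs = nrow(x$eblues), converged = x$converged,
         boundary = length(x$boundary) > 0)
}
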