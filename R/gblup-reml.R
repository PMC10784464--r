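#' Multi-environment GBLUP variance components by REML
#'
#' Fits the joint model \eqn{\bar y = Xb + u_a (+ u_d) + e} over
#' hybrid-by-environment adjusted means with
#' \eqn{u_a \sim N(0, CS(\sigma^2_{u_a}, \rho_a) \otimes A)},
#' \eqn{u_d \sim N(0, CS(\sigma^2_{u_d}, \rho_d) \otimes D)} and iid residuals,
#' environment means as fixed effects, by maximizing the restricted
#' log-likelihood
#' \deqn{\ell_R = -\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py +
#'   (n - q)\log 2\pi\right].}
#'
#' Optimization runs on transformed parameters (log variances; a scaled
#' logistic map of each correlation onto its open interval
#' \eqn{(-1/(q-1), 1)}) with analytic gradients, via bounded quasi-Newton
#' (`optim` L-BFGS-B). When the observed cells form a complete grid the
#' likelihood factorizes exactly into `q` blocks of size `p` through the
#' shared eigenbasis of the two compound-symmetry structures, which is used
#' automatically; incomplete grids (masked cells) use a dense representation
#' whose Kronecker pieces are precomputed once. Missing cells are handled by
#' row/column deletion of `V`; cells simply absent from `eblues` are treated
#' as missing.
#'
#' @param eblues Tibble with columns `hybrid`, `environment` and the response
#'   (`eblue` or `value`); one trait at a time.
#' @param A Additive kernel (dimnames = hybrid ids); may contain hybrids
#'   without phenotypes (used later for prediction).
#' @param D Dominance kernel, required for `model = "AD"`.
#' @param model `"AD"` (additive + dominance) or `"A"` (additive only).
#' @param env_levels Environment ordering; default sorted unique values.
#' @param start Optional named numeric vector of starting values on the
#'   natural scale (`sigma2_a`, `rho_a`, `sigma2_d`, `rho_d`, `sigma2_e`).
#'   The default splits the phenotypic variance equally over the included
#'   components and starts correlations at 0.3.
#' @param n_starts Additional jittered starts tried if the optimizer fails.
#' @param max_iter,tol Optimizer iteration cap and relative tolerance.
#' @param jitter Ridge added to the kernel diagonals before any factorization
#'   (realized kernels can be numerically singular).
#' @return Object of class `gblup_fit`: variance components (`vc`), restricted
#'   log-likelihood (`logL`), convergence diagnostics, and the data/kernels
#'   needed by [predict_cells()]. Parameters that reach the optimizer's box
#'   are flagged in `$boundary`, never silently clipped.
#' @seealso [fit_within_environment()], [predict_cells()], [lrt()],
#'   [genetic_params()]
#' @export
reml_fit <- function(eblues, A, D = NULL, model = c("AD", "A"),
                     env_levels = NULL, start = NULL, n_starts = 3,
                     max_iter = 200, tol = 1e-8, jitter = 1e-6) {
  model <- match.arg(model)
  if (model == "AD" && is.null(D)) abort("model 'AD' requires a dominance kernel D")
  if (model == "A") D <- NULL
  prob <- reml_setup(eblues, A, D, env_levels, jitter)
  q <- prob$q

  nm <- reml_par_names(model, q)
  theta0 <- reml_start(start, prob, model, q)

  fngr <- reml_make_fngr(prob, model)
  attempts <- list(theta0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      attempts[[k + 1]] <- theta0 + withr::with_seed(1000L + k, rnorm(length(theta0), 0, 0.5))
    }
  }
  best <- NULL
  trace <- character(0)
  for (th in attempts) {
    opt <- tryCatch(
      optim(th, fn = function(x) fngr(x)$value, gr = function(x) fngr(x)$grad,
            method = "L-BFGS-B", lower = -30, upper = 30,
            control = list(maxit = max_iter,
                           factr = max(tol / .Machine$double.eps, 10))),
      error = function(e) e
    )
    if (inherits(opt, "error")) {
      trace <- c(trace, conditionMessage(opt))
      next
    }
    trace <- c(trace, sprintf("value %.6f convergence %d", opt$value, opt$convergence))
    if (opt$convergence == 0 && (is.null(best) || opt$value < best$value)) best <- opt
    if (is.null(best) && opt$convergence == 1) best <- opt  # iteration cap: keep, flag
  }
  if (is.null(best)) {
    abort(c("REML did not converge from any start", trace))
  }
  theta <- setNames(best$par, nm)
  vc <- reml_untransform(theta, model, q)
  structure(list(
    vc = vc, logL = -best$value, model = model, q = q,
    converged = best$convergence == 0,
    boundary = nm[abs(best$par) > 29],
    counts = best$counts, trace = trace,
    env_levels = prob$env_levels, hybrids = prob$hybrids,
    eblues = prob$obs_tbl, A = prob$A_full, D = prob$D_full,
    jitter = jitter, theta = theta
  ), class = "gblup_fit")
}

#' Single-environment GBLUP fit
#'
#' Restricts the adjusted means to one environment and fits the `q = 1` model
#' (no across-environment correlations), as used to estimate genetic
#' parameters within each environment separately.
#'
#' @inheritParams reml_fit
#' @param environment Environment id to keep.
#' @export
fit_within_environment <- function(eblues, A, D = NULL, environment,
                                   model = c("AD", "A"), ...) {
  sub <- eblues[eblues$environment == environment, , drop = FALSE]
  if (nrow(sub) == 0) abort(sprintf("environment %s not present", environment))
  reml_fit(sub, A, D, model = match.arg(model), env_levels = environment, ...)
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> GBLUP-%s, %d environment(s), %d hybrids, logL = %.3f%s\n",
              x$model, x$q, length(x$hybrids), x$logL,
              if (x$converged) "" else " (NOT converged)"))
  est <- unlist(x$vc)
  cat(paste(sprintf("  %-9s %.4f", names(est), est), collapse = "\n"), "\n")
  if (length(x$boundary)) cat("  at boundary:", paste(x$boundary, collapse = ", "), "\n")
  invisible(x)
}

# ---- internals ---------------------------------------------------------------

reml_par_names <- function(model, q) {
  nm <- "lsa"
  if (q > 1) nm <- c(nm, "ta")
  if (model == "AD") {
    nm <- c(nm, "lsd")
    if (q > 1) nm <- c(nm, "td")
  }
  c(nm, "lse")
}

rho_from_t <- function(t, q) {
  lo <- -1 / (q - 1)
  lo + (1 - lo) * plogis(t)
}

t_from_rho <- function(rho, q) {
  lo <- -1 / (q - 1)
  x <- (rho - lo) / (1 - lo)
  qlogis(pmin(pmax(x, 1e-8), 1 - 1e-8))
}

reml_untransform <- function(theta, model, q) {
  vc <- list(sigma2_a = exp(theta[["lsa"]]))
  if (q > 1) vc$rho_a <- rho_from_t(theta[["ta"]], q)
  if (model == "AD") {
    vc$sigma2_d <- exp(theta[["lsd"]])
    if (q > 1) vc$rho_d <- rho_from_t(theta[["td"]], q)
  }
  vc$sigma2_e <- exp(theta[["lse"]])
  vc
}

reml_start <- function(start, prob, model, q) {
  nm <- reml_par_names(model, q)
  n_var <- if (model == "AD") 3 else 2
  v0 <- max(var(prob$y_all), 1e-4) / n_var
  defaults <- c(lsa = log(v0), ta = t_from_rho(0.3, max(q, 2)),
                lsd = log(v0), td = t_from_rho(0.3, max(q, 2)), lse = log(v0))
  th <- defaults[nm]
  if (!is.null(start)) {
    if (!is.null(start$sigma2_a)) th["lsa"] <- log(max(start$sigma2_a, 1e-8))
    if (!is.null(start$sigma2_d) && "lsd" %in% nm) th["lsd"] <- log(max(start$sigma2_d, 1e-8))
    if (!is.null(start$sigma2_e)) th["lse"] <- log(max(start$sigma2_e, 1e-8))
    if (!is.null(start$rho_a) && "ta" %in% nm) th["ta"] <- t_from_rho(start$rho_a, q)
    if (!is.null(start$rho_d) && "td" %in% nm) th["td"] <- t_from_rho(start$rho_d, q)
  }
  setNames(as.numeric(th), nm)
}

# Shared data layout for the two likelihood paths. Cells are indexed
# environment-major, hybrid-minor over the observed hybrids.
reml_setup <- function(eblues, A, D, env_levels, jitter) {
  val_col <- intersect(c("eblue", "value"), names(eblues))[1]
  if (is.na(val_col)) abort("eblues needs an 'eblue' (or 'value') column")
  if ("trait" %in% names(eblues) && length(unique(eblues$trait)) > 1) {
    abort("eblues contains several traits; filter to one before fitting")
  }
  tbl <- as_tibble(eblues)[, c("hybrid", "environment", val_col)]
  names(tbl)[3] <- "value"
  tbl <- filter(tbl, !is.na(.data$value))
  if (anyDuplicated(tbl[c("hybrid", "environment")])) {
    abort("duplicate hybrid-by-environment cells in eblues")
  }
  env_levels <- env_levels %||% sort(unique(tbl$environment))
  if (!all(tbl$environment %in% env_levels)) abort("environment outside env_levels")
  unknown <- setdiff(tbl$hybrid, rownames(A))
  if (length(unknown)) {
    abort(paste("hybrids absent from the kernel:",
                paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (!is.null(D) && !identical(rownames(A), rownames(D))) {
    abort("A and D must be indexed identically")
  }
  A_full <- A + jitter * diag(nrow(A))
  D_full <- if (!is.null(D)) D + jitter * diag(nrow(D)) else NULL
  dimnames(A_full) <- dimnames(A)
  if (!is.null(D_full)) dimnames(D_full) <- dimnames(D)

  hy <- intersect(rownames(A), unique(tbl$hybrid))  # kernel order
  p <- length(hy)
  q <- length(env_levels)
  ei <- match(tbl$environment, env_levels)
  hi <- match(tbl$hybrid, hy)
  cell <- (ei - 1L) * p + hi
  ord <- order(cell)
  tbl <- tbl[ord, ]
  cell <- cell[ord]

  full_grid <- length(cell) == p * q
  Asub <- A_full[hy, hy, drop = FALSE]
  Dsub <- if (!is.null(D_full)) D_full[hy, hy, drop = FALSE] else NULL

  prob <- list(q = q, p = p, env_levels = env_levels, hybrids = hy,
               y_all = tbl$value, obs_tbl = tbl, cell = cell,
               A_full = A_full, D_full = D_full,
               Asub = Asub, Dsub = Dsub, full_grid = full_grid)
  if (full_grid) {
    prob$Y <- matrix(tbl$value, p, q)  # column j = environment j
    prob$U <- cs_eigenbasis(q)
  } else {
    Iq <- diag(q); Jq <- matrix(1, q, q)
    prob$Mad <- kronecker(Iq, Asub)[cell, cell, drop = FALSE]
    prob$Mao <- kronecker(Jq - Iq, Asub)[cell, cell, drop = FALSE]
    if (!is.null(Dsub)) {
      prob$Mdd <- kronecker(Iq, Dsub)[cell, cell, drop = FALSE]
      prob$Mdo <- kronecker(Jq - Iq, Dsub)[cell, cell, drop = FALSE]
    }
    X <- matrix(0, length(cell), q)
    X[cbind(seq_along(cell), (cell - 1L) %/% p + 1L)] <- 1
    prob$X <- X
  }
  prob
}

# orthonormal basis whose first vector is constant: shared eigenvectors of
# every q x q compound-symmetry matrix
cs_eigenbasis <- function(q) {
  if (q == 1) return(matrix(1, 1, 1))
  M <- cbind(rep(1, q), diag(q)[, seq_len(q - 1)])
  Q <- qr.Q(qr(M))
  if (Q[1, 1] < 0) Q <- -Q
  Q
}

cs_eigvals <- function(sigma2, rho, q) {
  if (q == 1) return(sigma2)
  c(sigma2 * (1 + (q - 1) * rho), rep(sigma2 * (1 - rho), q - 1))
}

# closure returning value and analytic gradient of -logL_R at theta,
# caching the most recent evaluation (optim calls fn and gr separately)
reml_make_fngr <- function(prob, model) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  function(theta) {
    if (!is.null(cache$theta) && identical(theta, cache$theta)) return(cache$res)
    res <- if (prob$full_grid) {
      reml_eval_blocks(theta, prob, model)
    } else {
      reml_eval_dense(theta, prob, model)
    }
    cache$theta <- theta
    cache$res <- res
    res
  }
}

# fast exact path for complete grids: rotate environments into the CS
# eigenbasis; V splits into q independent p x p blocks
reml_eval_blocks <- function(theta, prob, model) {
  q <- prob$q; p <- prob$p
  nm <- reml_par_names(model, q)
  th <- setNames(theta, nm)
  sa <- exp(th[["lsa"]]); se <- exp(th[["lse"]])
  ra <- if (q > 1) rho_from_t(th[["ta"]], q) else 0
  has_d <- model == "AD"
  if (has_d) {
    sd_ <- exp(th[["lsd"]])
    rd <- if (q > 1) rho_from_t(th[["td"]], q) else 0
  }
  la <- cs_eigvals(sa, ra, q)
  ld <- if (has_d) cs_eigvals(sd_, rd, q) else rep(0, q)
  U <- prob$U
  Yt <- prob$Y %*% U
  A <- prob$Asub; D <- prob$Dsub

  # eigenvalue derivatives wrt each transformed parameter
  dla <- list(lsa = la)
  if (q > 1) {
    dr <- (1 + 1 / (q - 1)) * plogis(th[["ta"]]) * (1 - plogis(th[["ta"]]))
    dla$ta <- c(sa * (q - 1), rep(-sa, q - 1)) * dr
  }
  dld <- list()
  if (has_d) {
    dld$lsd <- ld
    if (q > 1) {
      drd <- (1 + 1 / (q - 1)) * plogis(th[["td"]]) * (1 - plogis(th[["td"]]))
      dld$td <- c(sd_ * (q - 1), rep(-sd_, q - 1)) * drd
    }
  }

  logdetV <- 0
  S <- matrix(0, q, q)
  c1 <- numeric(q)
  yVy <- 0
  blocks <- vector("list", q)
  for (m in seq_len(q)) {
    Vm <- la[m] * A + se * diag(p)
    if (has_d) Vm <- Vm + ld[m] * D
    ch <- tryCatch(chol(Vm), error = function(e) NULL)
    if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
    logdetV <- logdetV + 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    y <- Yt[, m]
    Viy <- Vi %*% y
    w <- rowSums(Vi)             # Vi %*% 1
    u <- U[, m]                  # fixed-effect block: X_m = 1_p %*% t(u)
    S <- S + sum(w) * tcrossprod(u)
    c1 <- c1 + u * sum(Viy)
    yVy <- yVy + sum(y * Viy)
    blocks[[m]] <- list(Vi = Vi, Viy = Viy, w = w, u = u, y = y)
  }
  chS <- chol(S)
  logdetS <- 2 * sum(log(diag(chS)))
  Sinv <- chol2inv(chS)
  beta <- Sinv %*% c1
  yPy <- yVy - sum(c1 * beta)
  n <- p * q
  value <- 0.5 * (logdetV + logdetS + yPy + (n - q) * log(2 * pi))

  grad <- setNames(numeric(length(nm)), nm)
  for (m in seq_len(q)) {
    b <- blocks[[m]]
    rm_ <- b$Viy - b$w * sum(b$u * beta)   # (Py) restricted to block m
    uSu <- drop(crossprod(b$u, Sinv %*% b$u))
    # per-structure scalars for this block
    trViA <- sum(b$Vi * A)
    wAw <- drop(crossprod(b$w, A %*% b$w))
    rAr <- drop(crossprod(rm_, A %*% rm_))
    for (k in names(dla)) {
      d <- dla[[k]][m]
      grad[k] <- grad[k] + 0.5 * d * ((trViA - uSu * wAw) - rAr)
    }
    if (has_d) {
      trViD <- sum(b$Vi * D)
      wDw <- drop(crossprod(b$w, D %*% b$w))
      rDr <- drop(crossprod(rm_, D %*% rm_))
      for (k in names(dld)) {
        d <- dld[[k]][m]
        grad[k] <- grad[k] + 0.5 * d * ((trViD - uSu * wDw) - rDr)
      }
    }
    trVi <- sum(diag(b$Vi))
    ww <- sum(b$w^2)
    rr <- sum(rm_^2)
    grad["lse"] <- grad["lse"] + 0.5 * se * ((trVi - uSu * ww) - rr)
  }
  list(value = as.numeric(value), grad = as.numeric(grad))
}

# dense path for incomplete grids; the Kronecker pieces are precomputed in
# reml_setup so each evaluation is scalar combinations plus one Cholesky
reml_eval_dense <- function(theta, prob, model) {
  q <- prob$q
  nm <- reml_par_names(model, q)
  th <- setNames(theta, nm)
  sa <- exp(th[["lsa"]]); se <- exp(th[["lse"]])
  ra <- if (q > 1) rho_from_t(th[["ta"]], q) else 0
  has_d <- model == "AD"
  n <- length(prob$y_all)
  V <- sa * prob$Mad
  if (q > 1) V <- V + (sa * ra) * prob$Mao
  if (has_d) {
    sd_ <- exp(th[["lsd"]])
    rd <- if (q > 1) rho_from_t(th[["td"]], q) else 0
    V <- V + sd_ * prob$Mdd
    if (q > 1) V <- V + (sd_ * rd) * prob$Mdo
  }
  diag(V) <- diag(V) + se
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  X <- prob$X
  y <- prob$y_all
  ViX <- Vi %*% X
  S <- crossprod(X, ViX)
  chS <- chol(S)
  Sinv <- chol2inv(chS)
  Viy <- Vi %*% y
  c1 <- crossprod(X, Viy)
  beta <- Sinv %*% c1
  yPy <- sum(y * Viy) - sum(c1 * beta)
  value <- 0.5 * (logdetV + 2 * sum(log(diag(chS))) + yPy +
                    (n - ncol(X)) * log(2 * pi))

  P <- Vi - ViX %*% tcrossprod(Sinv, ViX)
  r <- Viy - ViX %*% beta                 # P y
  grad <- setNames(numeric(length(nm)), nm)
  dmats <- list(lsa = if (q > 1) sa * (prob$Mad + ra * prob$Mao) else sa * prob$Mad)
  if (q > 1) {
    dr <- (1 + 1 / (q - 1)) * plogis(th[["ta"]]) * (1 - plogis(th[["ta"]]))
    dmats$ta <- (sa * dr) * prob$Mao
  }
  if (has_d) {
    dmats$lsd <- if (q > 1) sd_ * (prob$Mdd + rd * prob$Mdo) else sd_ * prob$Mdd
    if (q > 1) {
      drd <- (1 + 1 / (q - 1)) * plogis(th[["td"]]) * (1 - plogis(th[["td"]]))
      dmats$td <- (sd_ * drd) * prob$Mdo
    }
  }
  for (k in names(dmats)) {
    dV <- dmats[[k]]
    grad[k] <- 0.5 * (sum(P * dV) - drop(crossprod(r, dV %*% r)))
  }
  grad["lse"] <- 0.5 * se * (sum(diag(P)) - sum(r^2))
  list(value = as.numeric(value), grad = as.numeric(grad))
}
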