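#' Simulate environment-correlated genetic effects
#'
#' For each marker, the vector of additive effects across the `q` environments
#' is drawn from a multivariate normal with compound-symmetric correlation
#' `rho_a`; dominance effects are drawn analogously with `rho_d`. Effects are
#' scaled so that the per-environment genetic values `u_a = W alpha` and
#' `u_d = H delta` (with `W`, `H` the centered additive and dominance designs
#' used by [grm_additive()] and [grm_dominance()]) have covariance exactly
#' `sigma2_a * CS(rho_a) %x% A` and `sigma2_d * CS(rho_d) %x% D` over hybrids
#' and environments. The fitted GBLUP model is therefore the exact generative
#' model, which is what parameter-recovery checks require.
#'
#' @param config A [sim_config()].
#' @param hybrids Hybrid [geno_matrix()] from [infer_hybrid_genotypes()].
#' @return Object of class `true_effects`: list with per-environment marker
#'   effects `alpha`, `delta` (markers x environments), genetic values `u_a`,
#'   `u_d` (hybrids x environments), and `env_intercepts`.
#' @export
simulate_effects <- function(config, hybrids) {
  stopifnot(inherits(config, "sim_config"))
  q <- config$q_env
  lo <- if (q > 1) -1 / (q - 1) else -1
  for (r in c("rho_a", "rho_d")) {
    if (config[[r]] <= lo || config[[r]] > 1) {
      abort(sprintf("%s outside (%.4f, 1]: CS matrix not positive definite", r, lo))
    }
  }
  ad <- additive_design(hybrids)
  dd <- dominance_design(hybrids)
  n_mark <- ncol(hybrids)

  withr::with_seed(config$seed + 23L, {
    alpha <- draw_cs_effects(n_mark, q, config$sigma2_a / ad$c, config$rho_a)
    delta <- draw_cs_effects(n_mark, q, config$sigma2_d / dd$c, config$rho_d)
  })
  u_a <- ad$W %*% alpha
  u_d <- dd$H %*% delta
  env_names <- config$env$environment
  colnames(alpha) <- colnames(delta) <- colnames(u_a) <- colnames(u_d) <- env_names
  structure(list(alpha = alpha, delta = delta, u_a = u_a, u_d = u_d,
                 env_intercepts = config$env_means, env = config$env,
                 config = config),
            class = "true_effects")
}

# draw n iid rows from N(0, tau2 * CS(rho)) of dimension q; the symmetric
# square root via eigendecomposition tolerates the rho = 1 boundary.
draw_cs_effects <- function(n, q, tau2, rho) {
  if (tau2 <= 0) return(matrix(0, n, q))
  R <- (1 - rho) * diag(q) + rho * matrix(1, q, q)
  e <- eigen(R, symmetric = TRUE)
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  z <- matrix(rnorm(n * q), n, q)
  sqrt(tau2) * z %*% S
}

#' Simulate hybrid-by-environment adjusted means
#'
#' Generates one record per hybrid and environment on the scale of stage-1
#' adjusted means: environment intercept + additive value + dominance value +
#' independent noise with variance `sigma2_e`. This is the direct generative
#' counterpart of the joint GBLUP model and the natural input for
#' [reml_fit()] and [run_cv()].
#'
#' @param effects A `true_effects` object.
#' @param config The [sim_config()] used to create it (defaults to the one
#'   stored in `effects`).
#' @return Tibble with columns `hybrid`, `environment`, `location`, `year`,
#'   `regime`, `trait`, `eblue`.
#' @export
simulate_cells <- function(effects, config = effects$config) {
  stopifnot(inherits(effects, "true_effects"))
  q <- config$q_env
  hybrids <- rownames(effects$u_a)
  p <- length(hybrids)
  withr::with_seed(config$seed + 31L, {
    eps <- matrix(rnorm(p * q, 0, sqrt(config$sigma2_e)), p, q)
  })
  vals <- sweep(effects$u_a + effects$u_d + eps, 2, config$env_means, "+")
  expand_grid(environment = config$env$environment, hybrid = hybrids) |>
    left_join(config$env, by = "environment") |>
    mutate(regime = config$regime, trait = config$trait,
           eblue = as.vector(vals)) |>
    select("hybrid", "environment", "location", "year", "regime", "trait", "eblue")
}

#' Simulate plot-level trial records
#'
#' Builds a complete randomized-block trial series: every hybrid is allocated
#' once to a set (reused across trials), and each trial contributes
#' `n_reps` replicate plots per hybrid. A plot value is the environment
#' intercept plus replicate and set shifts (default 0), the hybrid's additive
#' and dominance values in that environment, and independent
#' `N(0, sigma2_e)` noise.
#'
#' @inheritParams simulate_cells
#' @return Tibble with columns `trial`, `location`, `year`, `regime`,
#'   `replicate`, `set`, `hybrid`, `trait`, `value` (one row per plot).
#' @export
simulate_plots <- function(effects, config = effects$config) {
  stopifnot(inherits(effects, "true_effects"))
  if (config$n_reps < 1) abort("invalid config: n_reps must be >= 1")
  hybrids <- rownames(effects$u_a)
  p <- length(hybrids)
  q <- config$q_env
  rep_eff <- rep_len(config$rep_effects %||% 0, config$n_reps)
  set_eff <- rep_len(config$set_effects %||% 0, config$n_sets)

  withr::with_seed(config$seed + 47L, {
    set_of <- setNames(sprintf("S%d", rep_len(seq_len(config$n_sets), p))[sample(p)],
                       hybrids)
    grid <- expand_grid(
      environment = config$env$environment,
      replicate = sprintf("R%d", seq_len(config$n_reps)),
      hybrid = hybrids
    )
    idx <- cbind(match(grid$hybrid, hybrids), match(grid$environment,
                                                    config$env$environment))
    gvals <- effects$u_a[idx] + effects$u_d[idx]
    grid$value <- config$env_means[grid$environment] +
      rep_eff[as.integer(sub("R", "", grid$replicate))] +
      set_eff[as.integer(sub("S", "", set_of[grid$hybrid]))] +
      gvals + rnorm(nrow(grid), 0, sqrt(config$sigma2_e))
  })
  grid |>
    left_join(config$env, by = "environment") |>
    mutate(trial = .data$environment, set = set_of[.data$hybrid],
           regime = config$regime, trait = config$trait) |>
    select("trial", "location", "year", "regime", "replicate", "set",
           "hybrid", "trait", "value")
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: parents, crossing design, inferred hybrid genotypes,
#' genetic effects, plot records and cell-level adjusted means in one call.
#'
#' @param config A [sim_config()].
#' @return List of class `met_sim` with elements `config`, `parents`,
#'   `crosses`, `hybrids`, `effects`, `plots`, `cells`.
#' @export
simulate_met <- function(config) {
  parents <- simulate_parents(config)
  crosses <- make_crosses(parents, config$n_hybrids, seed = config$seed)
  hybrids <- infer_hybrid_genotypes(parents, crosses)
  effects <- simulate_effects(config, hybrids)
  structure(list(
    config = config, parents = parents, crosses = crosses, hybrids = hybrids,
    effects = effects,
    plots = simulate_plots(effects, config),
    cells = simulate_cells(effects, config)
  ), class = "met_sim")
}

#' @export
print.met_sim <- function(x, ...) {
  cat(sprintf("<met_sim> %d hybrids x %d environments, %d markers, %d plot records\n",
              nrow(x$hybrids), x$config$q_env, ncol(x$hybrids), nrow(x$plots)))
  invisible(x)
}
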