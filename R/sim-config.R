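#' Configuration for the synthetic testcross-trial generator
#'
#' Collects every knob of the simulator in one validated object. The defaults
#' emulate a tropical maize testcross program under water stress: 188 inbred
#' lines in three heterotic groups (dent, flint, and a third unrelated group)
#' crossed to two testers giving 265 single-cross hybrids, evaluated in four
#' environments (two locations by two years) with compound-symmetric additive
#' and dominance genetic correlations across environments.
#'
#' Variance components are on the scale of the trait (t/ha for grain yield):
#' `sigma2_a` and `sigma2_d` are the per-environment additive and dominance
#' genetic variances, `sigma2_e` the residual variance of one observation
#' (a plot for [simulate_plots()], an adjusted mean for [simulate_cells()]).
#' `rho_a` and `rho_d` are the across-environment genetic correlations; for the
#' compound-symmetry structure to be positive definite they must lie in
#' `(-1/(q-1), 1]` where `q = q_env`.
#'
#' @param n_lines_per_group Named integer vector, inbred lines per heterotic
#'   group. Names become group labels.
#' @param n_testers Number of tester lines (crossed to many lines). Testers are
#'   assigned to groups by cycling over the first group labels.
#' @param n_hybrids Total number of line-by-tester hybrids to create. Must lie
#'   between the number of lines and `lines * testers`.
#' @param n_snps,n_chromosomes Marker panel size and chromosome count; markers
#'   are spread near-uniformly over chromosomes.
#' @param maf_range Interval in `(0, 0.5]` from which the base minor allele
#'   frequency of each marker is drawn.
#' @param group_divergence Nonnegative scale of the logit-normal perturbation
#'   applied to each group's allele frequencies around the shared base
#'   frequency; 0 makes all groups draw from identical frequencies.
#' @param q_env Number of environments (trials) in the regime group.
#' @param env_means Per-environment intercepts (trait units). Defaults to
#'   typical water-stress grain-yield trial means when `q_env = 4`.
#' @param sigma2_a,sigma2_d,sigma2_e Variance components (see Details).
#' @param rho_a,rho_d Across-environment genetic correlations.
#' @param n_reps Replicates per trial (2 or 3 in practice).
#' @param n_sets Number of sets hybrids are allocated to within each trial.
#' @param rep_effects,set_effects Optional fixed shifts per replicate / per set
#'   (recycled); default 0 so stage-1 adjustment can be exercised explicitly.
#'   The magnitude of such effects in real trials is rarely reported, so no
#'   nonzero default is assumed.
#' @param regime Label for the water regime of the simulated trial group.
#' @param trait Trait label attached to simulated records.
#' @param seed Integer seed; every generator derives its stream from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_parents()], [simulate_effects()], [simulate_plots()],
#'   [simulate_met()]
#' @examples
#' cfg <- sim_config(n_lines_per_group = c(dent = 10, flint = 10), n_hybrids = 30,
#'                   n_snps = 50, n_chromosomes = 5, seed = 42)
#' cfg$q_env
#' @export
sim_config <- function(n_lines_per_group = c(dent = 85, flint = 86, C = 17),
                       n_testers = 2,
                       n_hybrids = 265,
                       n_snps = 1000,
                       n_chromosomes = 10,
                       maf_range = c(0.1, 0.5),
                       group_divergence = 0.3,
                       q_env = 4,
                       env_means = NULL,
                       sigma2_a = 0.6,
                       sigma2_d = 0.3,
                       sigma2_e = 0.8,
                       rho_a = 0.35,
                       rho_d = 0.8,
                       n_reps = 3,
                       n_sets = 6,
                       rep_effects = NULL,
                       set_effects = NULL,
                       regime = "WS",
                       trait = "GY",
                       seed = 1L) {
  if (is.null(names(n_lines_per_group))) {
    names(n_lines_per_group) <- paste0("G", seq_along(n_lines_per_group))
  }
  env <- env_labels(q_env)
  if (is.null(env_means)) {
    env_means <- if (q_env == 4) c(3.49, 2.86, 3.34, 4.93) else
      seq(3, 5, length.out = q_env)
  }
  env_means <- rep_len(env_means, q_env)
  names(env_means) <- env$environment

  cfg <- structure(list(
    n_lines_per_group = n_lines_per_group,
    n_testers = as.integer(n_testers),
    n_hybrids = as.integer(n_hybrids),
    n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    maf_range = maf_range,
    group_divergence = group_divergence,
    q_env = as.integer(q_env),
    env = env,
    env_means = env_means,
    sigma2_a = sigma2_a, sigma2_d = sigma2_d, sigma2_e = sigma2_e,
    rho_a = rho_a, rho_d = rho_d,
    n_reps = as.integer(n_reps),
    n_sets = as.integer(n_sets),
    rep_effects = rep_effects,
    set_effects = set_effects,
    regime = regime,
    trait = trait,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  n_lines <- sum(cfg$n_lines_per_group)
  if (any(cfg$n_lines_per_group < 1)) abort("each heterotic group needs at least one line")
  if (cfg$n_testers < 1) abort("n_testers must be >= 1")
  if (cfg$n_snps < cfg$n_chromosomes) {
    abort("invalid config: n_snps must be at least n_chromosomes")
  }
  if (length(cfg$maf_range) != 2 || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || diff(cfg$maf_range) < 0) {
    abort("maf_range must be an increasing interval within (0, 0.5]")
  }
  if (cfg$group_divergence < 0) abort("group_divergence must be nonnegative")
  for (v in c("sigma2_a", "sigma2_d", "sigma2_e")) {
    if (cfg[[v]] < 0) abort(paste(v, "must be nonnegative"))
  }
  q <- cfg$q_env
  lo <- if (q > 1) -1 / (q - 1) else -1
  for (r in c("rho_a", "rho_d")) {
    if (cfg[[r]] <= lo || cfg[[r]] > 1) {
      abort(sprintf("%s must lie in (%.4f, 1] for a positive-definite CS structure",
                    r, lo))
    }
  }
  if (cfg$n_reps < 1) abort("invalid config: n_reps must be >= 1")
  if (cfg$n_sets < 1) abort("n_sets must be >= 1")
  if (cfg$n_hybrids < n_lines || cfg$n_hybrids > n_lines * cfg$n_testers) {
    abort(sprintf("n_hybrids must lie in [%d, %d] for %d lines and %d testers",
                  n_lines, n_lines * cfg$n_testers, n_lines, cfg$n_testers))
  }
  cfg
}

# Environment labels: two locations cycled over years, matching the
# location x year x regime layout of a typical trial series.
env_labels <- function(q) {
  locs <- rep_len(c("J", "T"), q)
  years <- 2010 + (seq_len(q) - 1) %/% 2
  tibble(
    environment = paste0(locs, substr(as.character(years), 3, 4)),
    location = locs,
    year = as.integer(years)
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  lines: %s (total %d), testers: %d, hybrids: %d\n",
              paste(sprintf("%s=%d", names(x$n_lines_per_group), x$n_lines_per_group),
                    collapse = ", "),
              sum(x$n_lines_per_group), x$n_testers, x$n_hybrids))
  cat(sprintf("  markers: %d on %d chromosomes, MAF in [%.2f, %.2f]\n",
              x$n_snps, x$n_chromosomes, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  environments: %s (%s)\n",
              paste(x$env$environment, collapse = ", "), x$regime))
  cat(sprintf("  variances (a/d/e): %.3g / %.3g / %.3g; rho_a = %.2f, rho_d = %.2f\n",
              x$sigma2_a, x$sigma2_d, x$sigma2_e, x$rho_a, x$rho_d))
  cat(sprintf("  reps: %d, sets: %d, seed: %d\n", x$n_reps, x$n_sets, x$seed))
  invisible(x)
}
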