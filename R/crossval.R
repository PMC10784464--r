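#' Stratified k-fold assignment of hybrids
#'
#' Shuffles hybrids within each stratum (cross group, e.g. dent x flint) under
#' the seed, then deals them round-robin into `k` folds from a random starting
#' fold, so per-stratum fold sizes never differ by more than one and every
#' fold contains all cross types proportionally.
#'
#' @param hybrids Character vector of hybrid ids.
#' @param strata Optional named vector (or tibble with columns `hybrid`,
#'   `cross_group`) of stratum labels; default one stratum.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Tibble with columns `hybrid`, `stratum`, `fold`.
#' @export
make_folds <- function(hybrids, strata = NULL, k = 5, seed = 1L) {
  if (k < 2) abort("k must be >= 2")
  if (k > length(hybrids)) abort("more folds than hybrids")
  if (is.data.frame(strata)) {
    strata <- setNames(strata$cross_group, strata$hybrid)[hybrids]
  }
  if (is.null(strata)) strata <- setNames(rep("all", length(hybrids)), hybrids)
  stopifnot(length(strata) == length(hybrids))
  withr::with_seed(seed + 101L, {
    out <- lapply(split(hybrids, strata[hybrids]), function(h) {
      h <- if (length(h) > 1) sample(h) else h
      offset <- sample.int(k, 1)
      tibble(hybrid = h,
             fold = ((seq_along(h) - 1L + offset) %% k) + 1L)
    })
  })
  list_rbind(out, names_to = "stratum") |>
    select("hybrid", "stratum", "fold") |>
    arrange(match(.data$hybrid, hybrids))
}

#' Build the held-out cell mask for a validation scenario
#'
#' For each fold in turn acting as the validation set:
#' * `CV1` masks every environment of each validation hybrid (no phenotypes
#'   anywhere);
#' * `CV2_50` masks a random half of the environments of each validation
#'   hybrid;
#' * `CV2_25` masks a random quarter (one of four in the canonical `q = 4`).
#'
#' The masked environments are drawn independently per hybrid, uniformly over
#' subsets of the required size: a random permutation of the environments is
#' drawn per hybrid under the seed and each scenario masks a prefix of it.
#' Calling `build_mask()` with the same seed for different scenarios therefore
#' yields nested masks (the CV2-25% masked cell of a hybrid is among its
#' CV2-50% masked cells), which pairs scenario comparisons without changing
#' any scenario's marginal masking law. Hybrids outside the fold are never
#' masked.
#'
#' @param folds Fold assignment from [make_folds()].
#' @param scenario `"CV1"`, `"CV2_50"` or `"CV2_25"`.
#' @param environments Character vector of environment ids (length `q`).
#' @param seed Integer seed.
#' @return Tibble with one row per hybrid-by-environment cell and columns
#'   `hybrid`, `fold`, `environment`, `masked` (`TRUE` when the cell is held
#'   out while that hybrid's fold is the validation fold).
#' @export
build_mask <- function(folds, scenario = c("CV1", "CV2_50", "CV2_25"),
                       environments, seed = 1L) {
  scenario <- match.arg(scenario)
  q <- length(environments)
  n_mask <- switch(scenario,
    CV1 = q,
    CV2_50 = {
      if (q %% 2 != 0) abort("CV2_50 needs q divisible by 2; give an explicit mask size")
      q %/% 2L
    },
    CV2_25 = {
      if (q %% 4 != 0) abort("CV2_25 needs q divisible by 4; give an explicit mask size")
      q %/% 4L
    }
  )
  withr::with_seed(seed + 211L, {
    masked_envs <- lapply(folds$hybrid, function(h) {
      sample(environments)[seq_len(n_mask)]
    })
  })
  grid <- expand_grid(folds, environment = environments)
  sel <- map2(masked_envs, seq_len(nrow(folds)),
              function(envs, i) tibble(hybrid = folds$hybrid[i], environment = envs))
  sel <- list_rbind(sel) |> mutate(masked = TRUE)
  grid |>
    left_join(sel, by = c("hybrid", "environment")) |>
    mutate(masked = !is.na(.data$masked)) |>
    select("hybrid", "fold", "environment", "masked")
}

#' Per-environment Pearson predictive ability
#'
#' Correlates adjusted means (eBLUEs) with predictions over the held-out cells
#' only, separately for each environment. Environments with fewer than three
#' scored cells, or zero variance in either vector, yield `NA` with a warning.
#'
#' @param eblues eBLUE tibble (`hybrid`, `environment`, `eblue`).
#' @param preds Prediction tibble (`hybrid`, `environment`, `pred`).
#' @param mask Tibble of held-out cells (`hybrid`, `environment`), e.g. the
#'   `masked` rows of [build_mask()] for the validation fold.
#' @return Tibble with columns `environment`, `n`, `r`.
#' @export
predictive_ability <- function(eblues, preds, mask) {
  val_col <- intersect(c("eblue", "value"), names(eblues))[1]
  scored <- mask |>
    select("hybrid", "environment") |>
    inner_join(eblues[, c("hybrid", "environment", val_col)],
               by = c("hybrid", "environment")) |>
    inner_join(preds[, c("hybrid", "environment", "pred")],
               by = c("hybrid", "environment"))
  scored |>
    summarise(n = dplyr::n(), r = {
      if (dplyr::n() < 3) {
        warn(sprintf("fewer than 3 held-out cells in environment %s",
                     .data$environment[1]))
        NA_real_
      } else if (sd(.data[[val_col]]) == 0 || sd(.data$pred) == 0) {
        warn(sprintf("zero variance in environment %s: ability undefined",
                     .data$environment[1]))
        NA_real_
      } else {
        cor(.data[[val_col]], .data$pred)
      }
    }, .by = "environment")
}

#' Run the full cross-validation factorial
#'
#' For every repeat, scenario and fold: build the mask, fit each method on the
#' unmasked cells, predict the masked cells, and score per-environment Pearson
#' predictive ability. Folds and masks are generated once per repeat and
#' shared across methods, so method comparisons are paired. GBLUP fits can be
#' warm-started from a fit to all cells of the repeat (starting values only).
#'
#' @param eblues eBLUE tibble for one trait (`hybrid`, `environment`,
#'   `eblue`).
#' @param A,D Kernels over all hybrids (D required by `gblup_ad`).
#' @param geno Hybrid [geno_matrix()] (required by the tree methods).
#' @param env_info Tibble `environment`, `location`, `year` (tree methods).
#' @param methods Subset of `"gblup_a"`, `"gblup_ad"`, `"bagging"`,
#'   `"random_forest"`, `"boosting"`.
#' @param scenarios Subset of `"CV1"`, `"CV2_50"`, `"CV2_25"`.
#' @param k,repeats Folds (default 5) and repeats (default 5).
#' @param strata Stratum labels for [make_folds()] (e.g. cross groups).
#' @param seed Integer seed; fold, mask and ensemble seeds derive from it.
#' @param reml_control List of arguments passed on to [reml_fit()]
#'   (`max_iter`, `tol`, `jitter`, `n_starts`).
#' @param ensemble_control List of arguments passed on to [fit_ensemble()].
#' @param warm_start Use full-data variance components as REML starting
#'   values within each repeat (numerical head start only; default `TRUE`).
#' @param score_by Scoring granularity. `"repeat"` (default) pools the masked
#'   cells of all folds within a repeat before correlating — every hybrid is
#'   held out exactly once per repeat, so this correlates the assembled
#'   cross-validated predictions with the observed means, per environment.
#'   `"fold"` scores each fold separately (fewer cells per correlation, so
#'   individual values are noisier and slightly biased toward zero).
#' @param se_denom Denominator convention for the standard error: the default
#'   `sqrt(repeats)` treats the ability values within a repeat as one
#'   replication set.
#' @return Tibble of class `cv_ability`: `environment`, `method`, `scenario`,
#'   `mean_r`, `se_r`, `n_vals`, with per-repeat (or per-fold) details in
#'   attribute `details` and one log row per fit-predict-score execution in
#'   attribute `log`.
#' @export
run_cv <- function(eblues, A = NULL, D = NULL, geno = NULL, env_info = NULL,
                   methods = c("gblup_ad"), scenarios = c("CV1", "CV2_50", "CV2_25"),
                   k = 5, repeats = 5, strata = NULL, seed = 1L,
                   reml_control = list(), ensemble_control = list(),
                   warm_start = TRUE, score_by = c("repeat", "fold"),
                   se_denom = NULL) {
  score_by <- match.arg(score_by)
  known <- c("gblup_a", "gblup_ad", "bagging", "random_forest", "boosting")
  bad <- setdiff(methods, known)
  if (length(bad)) abort(paste("unknown method:", paste(bad, collapse = ", ")))
  gblup_methods <- intersect(methods, c("gblup_a", "gblup_ad"))
  tree_methods <- setdiff(methods, gblup_methods)
  if (length(gblup_methods) && is.null(A)) abort("GBLUP methods need kernel A")
  if ("gblup_ad" %in% methods && is.null(D)) abort("gblup_ad needs kernel D")
  if (length(tree_methods) && (is.null(geno) || is.null(env_info))) {
    abort("tree methods need hybrid genotypes and env_info")
  }
  hybrids <- unique(eblues$hybrid)
  environments <- sort(unique(eblues$environment))
  details <- list()
  log <- list()

  for (rep_i in seq_len(repeats)) {
    rs <- (seed + 7919L * rep_i) %% .Machine$integer.max
    folds <- make_folds(hybrids, strata = strata, k = k, seed = rs)
    warm <- list()
    if (warm_start && length(gblup_methods)) {
      for (m in gblup_methods) {
        model <- if (m == "gblup_ad") "AD" else "A"
        f <- do.call(reml_fit, c(list(eblues = eblues, A = A,
                                      D = if (model == "AD") D else NULL,
                                      model = model, env_levels = environments),
                                 reml_control))
        warm[[m]] <- f$vc
      }
    }
    for (sc in scenarios) {
      # one seed per repeat for every scenario: masks nest across scenarios,
      # so scenario comparisons are paired (see build_mask)
      mask <- build_mask(folds, sc, environments, seed = rs)
      pooled <- list()
      for (fold_i in seq_len(k)) {
        held <- filter(mask, .data$fold == fold_i, .data$masked)
        train <- anti_join(eblues, held, by = c("hybrid", "environment"))
        targets <- semi_join(eblues, held, by = c("hybrid", "environment"))
        for (m in methods) {
          t0 <- proc.time()[3]
          preds <- cv_fit_predict(m, train, targets, A, D, geno, env_info,
                                  environments, warm[[m]], reml_control,
                                  ensemble_control,
                                  seed = rs + 13L * fold_i + match(m, known))
          if (score_by == "fold") {
            ab <- predictive_ability(eblues, preds, held)
            details[[length(details) + 1]] <- ab |>
              mutate(method = m, scenario = sc, repeat_i = rep_i, fold = fold_i)
          } else {
            pooled[[paste(m, fold_i)]] <- preds
          }
          log[[length(log) + 1]] <- tibble(
            repeat_i = rep_i, scenario = sc, fold = fold_i, method = m,
            n_train = nrow(train), n_test = nrow(targets),
            elapsed = proc.time()[3] - t0
          )
        }
      }
      if (score_by == "repeat") {
        for (m in methods) {
          preds <- list_rbind(pooled[paste(m, seq_len(k))])
          held_all <- filter(mask, .data$masked)
          ab <- predictive_ability(eblues, preds, held_all)
          details[[length(details) + 1]] <- ab |>
            mutate(method = m, scenario = sc, repeat_i = rep_i, fold = NA_integer_)
        }
      }
    }
  }
  details <- list_rbind(details)
  denom <- se_denom %||% sqrt(repeats)
  out <- details |>
    summarise(mean_r = mean(.data$r, na.rm = TRUE),
              se_r = sd(.data$r, na.rm = TRUE) / denom,
              n_vals = sum(!is.na(.data$r)),
              .by = c("environment", "method", "scenario"))
  attr(out, "details") <- details
  attr(out, "log") <- list_rbind(log)
  class(out) <- c("cv_ability", class(out))
  out
}

cv_fit_predict <- function(method, train, targets, A, D, geno, env_info,
                           environments, warm, reml_control, ensemble_control,
                           seed) {
  if (method %in% c("gblup_a", "gblup_ad")) {
    model <- if (method == "gblup_ad") "AD" else "A"
    fit <- do.call(reml_fit, c(list(eblues = train, A = A,
                                    D = if (model == "AD") D else NULL,
                                    model = model, env_levels = environments,
                                    start = warm),
                               reml_control))
    predict_cells(fit, targets)
  } else {
    ft <- encode_features(geno, train, env_info)
    fx <- encode_features(geno, targets[, c("hybrid", "environment")], env_info)
    ens <- do.call(fit_ensemble, c(list(train = ft, method = method, seed = seed),
                                   ensemble_control))
    predict(ens, fx)
  }
}

#' Phenotyping and genotyping budget for a hybrid trial program
#'
#' Simple cost arithmetic for the value-of-genomic-prediction argument:
#' phenotyping = hybrids x trials x replicates x cost per plot; genotyping =
#' parental lines x cost per line; savings = a stated fraction of the
#' phenotyping total (e.g. the share of plots genomic prediction can replace
#' in a sparse design).
#'
#' @param n_hybrids,n_trials,n_reps Trial dimensions.
#' @param cost_per_plot Cost of one field plot (currency units).
#' @param n_lines,cost_per_line Genotyping dimensions (default 0).
#' @param savings_fraction Fraction of the phenotyping budget saved.
#' @return Tibble with `phenotyping`, `genotyping`, `savings`.
#' @examples
#' budget_estimate(265, 8, 3, 17)  # phenotyping 108120
#' @export
budget_estimate <- function(n_hybrids, n_trials, n_reps, cost_per_plot,
                            n_lines = 0, cost_per_line = 0,
                            savings_fraction = 0) {
  args <- c(n_hybrids, n_trials, n_reps, cost_per_plot, n_lines, cost_per_line,
            savings_fraction)
  if (any(args < 0)) abort("budget inputs must be nonnegative")
  phen <- n_hybrids * n_trials * n_reps * cost_per_plot
  tibble(phenotyping = phen,
         genotyping = n_lines * cost_per_line,
         savings = savings_fraction * phen)
}
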