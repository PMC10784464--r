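#' Per-trial fixed-effects analysis (stage 1)
#'
#' Fits, by ordinary least squares, the stage-1 model
#' \deqn{y = 1\mu + X_1 r + X_2 s + X_3 h + e}
#' with fixed replicate (`r`), set (`s`) and hybrid (`h`) effects for one trial
#' and trait, and returns the adjusted hybrid mean (eBLUE) for every hybrid.
#' Sum-to-zero contrasts are used so that the eBLUE is the estimated marginal
#' mean of the hybrid: its fitted value at its own set, averaged over
#' replicates. In a balanced complete design this equals the raw hybrid mean,
#' and a constant shift applied to one replicate is fully absorbed by the
#' replicate effect. Because hybrids are nested in sets, set and hybrid effects
#' are partially aliased; the marginal mean is estimable regardless of which
#' aliased columns the fit drops.
#'
#' @param plots Plot-level tibble with columns `trial`, `replicate`, `set`,
#'   `hybrid`, `trait`, `value`.
#' @param trial,trait The trial (environment) and trait to analyse.
#' @return Tibble with columns `hybrid`, `eblue`, plus attributes `sigma2_e`
#'   (residual variance, RSS over residual df; `NA` for saturated fits) and
#'   `df_residual`.
#' @export
fit_trial_model <- function(plots, trial, trait) {
  df <- plots[plots$trial == trial & plots$trait == trait, , drop = FALSE]
  if (nrow(df) == 0) abort(sprintf("trial %s / trait %s not present", trial, trait))
  df <- as_tibble(df)
  df$replicate <- factor(df$replicate)
  df$set <- factor(df$set)
  df$hybrid <- factor(df$hybrid)

  terms <- c("replicate", "set", "hybrid")[
    c(nlevels(df$replicate) > 1, nlevels(df$set) > 1, nlevels(df$hybrid) > 1)]
  if (length(terms) == 0) terms <- "1"
  form <- stats::as.formula(paste("value ~", paste(terms, collapse = " + ")))
  ctr <- lapply(setNames(nm = setdiff(terms, "1")), function(.) "contr.sum")
  fit <- if (length(ctr)) lm(form, data = df, contrasts = ctr) else lm(form, data = df)

  # marginal mean: each hybrid at its own set, averaged over replicate levels
  key <- distinct(df, .data$hybrid, .data$set)
  new <- expand_grid(key, replicate = levels(df$replicate))
  pred <- suppressWarnings(predict(fit, newdata = new))
  if (anyNA(pred)) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("hybrid effects are not estimable in trial ", trial,
                 "; aliased terms: ", paste(aliased, collapse = ", ")))
  }
  out <- new |>
    mutate(.pred = pred) |>
    summarise(eblue = mean(.data$.pred), .by = "hybrid") |>
    mutate(hybrid = as.character(.data$hybrid)) |>
    arrange(.data$hybrid)
  dfres <- df.residual(fit)
  attr(out, "sigma2_e") <- if (dfres > 0) sum(residuals(fit)^2) / dfres else NA_real_
  attr(out, "df_residual") <- dfres
  out
}

#' Adjusted means for every trial and trait
#'
#' Applies [fit_trial_model()] to each trial-by-trait combination and stacks
#' the results into an eBLUE table, carrying location/year/regime labels when
#' present in the plot table. Checks (commercial cultivars) can be excluded
#' from the output since only hybrids enter genomic prediction.
#'
#' @param plots Plot-level tibble (see [fit_trial_model()]).
#' @param checks Optional character vector of entry ids to drop from the
#'   output after fitting (they still inform the trial model).
#' @return Tibble with columns `hybrid`, `environment`, `trait`, `eblue` (plus
#'   any of `location`, `year`, `regime` present in `plots`), with attribute
#'   `residual_var`: tibble of per trial-by-trait residual variances.
#' @export
compute_eblues <- function(plots, checks = NULL) {
  combos <- distinct(plots, .data$trial, .data$trait)
  extras <- intersect(c("location", "year", "regime"), names(plots))
  labels <- distinct(plots, .data$trial, pick(all_of(extras)))
  res <- vector("list", nrow(combos))
  rv <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fr <- fit_trial_model(plots, combos$trial[i], combos$trait[i])
    res[[i]] <- fr |>
      mutate(environment = combos$trial[i], trait = combos$trait[i])
    rv[[i]] <- tibble(environment = combos$trial[i], trait = combos$trait[i],
                      sigma2_e = attr(fr, "sigma2_e"),
                      df_residual = attr(fr, "df_residual"))
  }
  out <- list_rbind(res) |>
    left_join(labels, by = c(environment = "trial")) |>
    select("hybrid", "environment", all_of(extras), "trait", "eblue")
  if (!is.null(checks)) out <- filter(out, !.data$hybrid %in% checks)
  attr(out, "residual_var") <- list_rbind(rv)
  out
}

#' Interquartile-range outlier filter for adjusted means
#'
#' Drops, within each environment-by-trait group, values lying outside the
#' closed interval `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`. Quartiles use the
#' linear-interpolation convention (`stats::quantile()` type 7). The rule is
#' applied in a single pass: fences are computed once from the incoming values
#' and are not re-estimated from the filtered ones, which keeps the operation
#' deterministic.
#'
#' @param eblues eBLUE tibble with at least the grouping columns and `eblue`.
#' @param value_col Name of the value column (default `"eblue"`).
#' @param group_cols Columns defining the fence groups; defaults to whichever
#'   of `environment` and `trait` are present.
#' @return The filtered tibble, with attribute `removed` holding the dropped
#'   rows plus their fences.
#' @examples
#' tb <- tibble::tibble(environment = "E1", trait = "GY",
#'                      eblue = c(1:9, 100))
#' nrow(remove_outliers(tb))  # 9: only the value 100 is outside the fence
#' @export
remove_outliers <- function(eblues, value_col = "eblue",
                            group_cols = intersect(c("environment", "trait"),
                                                   names(eblues))) {
  fences <- eblues |>
    summarise(
      q1 = quantile(.data[[value_col]], 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile(.data[[value_col]], 0.75, na.rm = TRUE, names = FALSE),
      .by = all_of(group_cols)
    ) |>
    mutate(lower = .data$q1 - 1.5 * (.data$q3 - .data$q1),
           upper = .data$q3 + 1.5 * (.data$q3 - .data$q1))
  joined <- if (length(group_cols)) {
    left_join(eblues, fences, by = group_cols)
  } else {
    bind_cols(eblues, fences)
  }
  out_of <- !is.na(joined[[value_col]]) &
    (joined[[value_col]] < joined$lower | joined[[value_col]] > joined$upper)
  kept <- eblues[!out_of, , drop = FALSE]
  attr(kept, "removed") <- joined[out_of, , drop = FALSE]
  kept
}
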