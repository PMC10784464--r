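test_that("fold assignment balances within strata and is deterministic", {
  hy <- sprintf("h%03d", 1:265)
  f1 <- make_folds(hy, k = 5, seed = 3)
  expect_equal(unname(table(f1$fold)), rep(53L, 5), ignore_attr = TRUE)
  expect_identical(f1, make_folds(hy, k = 5, seed = 3))
  f2 <- make_folds(hy, k = 5, seed = 4)
  expect_false(identical(f1$fold, f2$fold))
  # stratified round-robin arithmetic on strata of sizes 10 and 7
  hy2 <- sprintf("x%02d", 1:17)
  strata <- setNames(rep(c("a", "b"), c(10, 7)), hy2)
  f3 <- make_folds(hy2, strata = strata, k = 5, seed = 1)
  sizes <- f3 |> dplyr::count(stratum, fold) |> dplyr::arrange(stratum, -n)
  expect_equal(sizes$n[sizes$stratum == "a"], rep(2L, 5))
  expect_equal(sort(sizes$n[sizes$stratum == "b"], decreasing = TRUE),
               c(2L, 2L, 1L, 1L, 1L))
  expect_error(make_folds(hy2[1:3], k = 5), "more folds")
})

test_that("mask cardinalities match each scenario exactly", {
  hy <- sprintf("h%03d", 1:265)
  folds <- make_folds(hy, k = 5, seed = 7)
  envs <- c("J10", "T10", "J11", "T11")
  for (sc in c("CV1", "CV2_50", "CV2_25")) {
    mask <- build_mask(folds, sc, envs, seed = 7)
    per_hybrid <- mask |>
      dplyr::summarise(n_masked = sum(masked), .by = hybrid)
    want <- switch(sc, CV1 = 4L, CV2_50 = 2L, CV2_25 = 1L)
    expect_true(all(per_hybrid$n_masked == want))
    # fold-level cardinality: 53 hybrids per fold
    fold1 <- mask |> dplyr::filter(fold == 1, masked)
    expect_equal(nrow(fold1), 53L * want)
  }
  expect_error(build_mask(folds, "CV2_25", envs[1:3]), "divisible")
})

test_that("a four-hybrid instance reproduces the canonical NA patterns", {
  folds <- tibble::tibble(hybrid = sprintf("H%d", 1:4), stratum = "all",
                          fold = c(1L, 1L, 2L, 2L))
  envs <- c("J10", "J11", "T10", "T11")
  na_counts <- function(sc) {
    build_mask(folds, sc, envs, seed = 2) |>
      dplyr::summarise(n = sum(masked), .by = hybrid)
  }
  expect_equal(na_counts("CV1")$n, rep(4L, 4))     # whole row of NAs
  expect_equal(na_counts("CV2_50")$n, rep(2L, 4))  # half the environments
  expect_equal(na_counts("CV2_25")$n, rep(1L, 4))  # one environment
})

test_that("Pearson ability scores held-out cells per environment", {
  eb <- tibble::tibble(hybrid = sprintf("h%d", 1:4), environment = "E1",
                       eblue = c(1, 2, 3, 4))
  mask <- eb[, c("hybrid", "environment")]
  pr <- dplyr::mutate(mask, pred = c(2, 1, 4, 3))
  r <- predictive_ability(eb, pr, mask)
  # hand computation on (1,2),(2,1),(3,4),(4,3): cross-products 3, sds sqrt(5)
  expect_equal(r$r, 0.6)
  expect_equal(r$n, 4L)
  # perfect and anti-perfect predictions
  expect_equal(predictive_ability(eb, dplyr::mutate(mask, pred = eb$eblue),
                                  mask)$r, 1)
  expect_equal(predictive_ability(eb, dplyr::mutate(mask, pred = -eb$eblue + 7),
                                  mask)$r, -1)
  # affine invariance with positive slope
  expect_equal(predictive_ability(eb, dplyr::mutate(pr, pred = 3 * pred + 2),
                                  mask)$r, 0.6)
  # zero variance is NA with a warning
  expect_warning(
    r0 <- predictive_ability(eb, dplyr::mutate(mask, pred = 1), mask),
    "zero variance")
  expect_true(is.na(r0$r))
  expect_warning(
    r1 <- predictive_ability(eb[1:2, ], pr[1:2, ], mask[1:2, ]),
    "fewer than 3")
})

test_that("run_cv pairs masks across methods and logs every execution", {
  sim <- small_sim(seed = 23)
  A <- grm_additive(sim$hybrids)
  D <- grm_dominance(sim$hybrids)
  env_info <- sim$config$env
  ab <- run_cv(sim$cells, A = A, D = D, geno = sim$hybrids, env_info = env_info,
               methods = c("gblup_a", "boosting"),
               scenarios = c("CV1", "CV2_50"), k = 3, repeats = 2, seed = 5,
               reml_control = list(max_iter = 40, tol = 1e-6, n_starts = 1),
               ensemble_control = list(n_trees = 10))
  log <- attr(ab, "log")
  expect_equal(nrow(log), 2 * 2 * 3 * 2)  # methods x scenarios x folds x repeats
  # identical masked sets across methods: n_train/n_test agree within a
  # repeat-scenario-fold triple
  chk <- log |>
    dplyr::summarise(same = dplyr::n_distinct(n_test) == 1,
                     .by = c(repeat_i, scenario, fold))
  expect_true(all(chk$same))
  expect_true(all(ab$mean_r >= -1 & ab$mean_r <= 1))
  expect_true(all(ab$se_r >= 0))
  # a masked hybrid cell never contributes to training
  expect_equal(max(log$n_train) + min(log$n_test),
               nrow(sim$cells))
  expect_error(run_cv(sim$cells, A = A, methods = "nope"), "unknown method")
})

test_that("run_cv is reproducible under a fixed seed", {
  sim <- small_sim(seed = 24)
  A <- grm_additive(sim$hybrids)
  args <- list(sim$cells, A = A, methods = "gblup_a", scenarios = "CV2_50",
               k = 3, repeats = 1, seed = 11,
               reml_control = list(max_iter = 40, n_starts = 1))
  ab1 <- do.call(run_cv, args)
  ab2 <- do.call(run_cv, args)
  expect_equal(ab1$mean_r, ab2$mean_r, tolerance = 1e-12)
})

test_that("held-out cells are disjoint from the training rows by construction", {
  hy <- sprintf("h%d", 1:20)
  folds <- make_folds(hy, k = 4, seed = 2)
  envs <- sprintf("E%d", 1:4)
  mask <- build_mask(folds, "CV2_50", envs, seed = 2)
  eb <- tidyr::expand_grid(environment = envs, hybrid = hy)
  eb$eblue <- seq_len(nrow(eb))
  for (f in 1:4) {
    held <- dplyr::filter(mask, fold == f, masked)
    train <- dplyr::anti_join(eb, held, by = c("hybrid", "environment"))
    expect_equal(nrow(dplyr::inner_join(train, held,
                                        by = c("hybrid", "environment"))), 0)
    # training hybrids outside the fold keep all their cells
    outside <- dplyr::filter(folds, fold != f)$hybrid
    expect_equal(sum(train$hybrid %in% outside), length(outside) * 4)
  }
})

test_that("budget arithmetic reproduces the worked trial-program example", {
  b <- budget_estimate(265, 8, 3, 17, n_lines = 190, cost_per_line = 25.38,
                       savings_fraction = 0.25)
  expect_equal(b$phenotyping, 108120)
  expect_equal(b$savings, 27030)
  expect_equal(b$genotyping, 190 * 25.38)
  expect_equal(budget_estimate(0, 8, 3, 17)$phenotyping, 0)
  expect_error(budget_estimate(-1, 8, 3, 17), "nonnegative")
})
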