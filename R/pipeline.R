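#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: simulate (or read) trial data, stage-1
#' adjusted means with outlier removal, genotype QC and kernels,
#' cross-validation, and a plain-text report. Every intermediate table is
#' written to `out_dir` and a manifest records the configuration, seeds, a
#' configuration hash and the package version, so a rerun with the same
#' configuration reproduces every output.
#'
#' The configuration is a nested list (or a YAML file path) with sections:
#' * `sim`: arguments for [sim_config()] (omit to supply `paths` instead);
#' * `paths`: `genotypes` (parent dosage TSV), `crosses` (CSV with `hybrid`,
#'   `line`, `tester`), `plots` (plot CSV) for real data;
#' * `qc`: `maf_min`, `max_missing`, `max_het`, `apply_to` ("parents");
#' * `cv`: `methods`, `scenarios`, `k`, `repeats`, plus optional
#'   `reml_control` / `ensemble_control`;
#' * `budget`: optional arguments for [budget_estimate()];
#' * `seed`, `out_dir`, `trait`.
#'
#' @param config Nested list or path to a YAML file.
#' @return Invisibly, a list of run artifacts (`config`, `eblues`, `kernels`,
#'   `ability`, `manifest`, `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # --- data: simulate or read -------------------------------------------------
  if (!is.null(config$sim)) {
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% seed
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_met(cfg)
    parents <- sim$parents
    crosses <- sim$crosses
    plots <- sim$plots
    write_dosage(parents, file.path(out_dir, "parents.tsv"))
    readr::write_csv(crosses, file.path(out_dir, "crosses.csv"))
  } else {
    parents <- read_dosage(config$paths$genotypes, kind = "inbred")
    crosses <- readr::read_csv(config$paths$crosses, show_col_types = FALSE)
    plots <- readr::read_csv(config$paths$plots, show_col_types = FALSE)
  }
  readr::write_csv(plots, file.path(out_dir, "plots.csv"))

  # --- stage 1 ----------------------------------------------------------------
  eblues <- compute_eblues(plots, checks = config$checks)
  eblues <- remove_outliers(eblues)
  removed <- attr(eblues, "removed")
  readr::write_csv(eblues, file.path(out_dir, "eblues.csv"))
  if (!is.null(removed) && nrow(removed)) {
    readr::write_csv(removed, file.path(out_dir, "outliers_removed.csv"))
  }

  # --- genotypes and kernels --------------------------------------------------
  qc <- config$qc
  parents_qc <- qc_filter(parents, qc$maf_min, qc$max_missing, qc$max_het)
  parents_imp <- force_homozygous(impute_genotypes(parents_qc))
  hybrids <- infer_hybrid_genotypes(parents_imp, crosses)
  A <- grm_additive(hybrids)
  Dk <- grm_dominance(hybrids)
  write_kernel(A, file.path(out_dir, "kernel_additive.csv"))
  write_kernel(Dk, file.path(out_dir, "kernel_dominance.csv"))

  # --- cross-validation -------------------------------------------------------
  trait <- config$trait %||% unique(eblues$trait)[1]
  eb <- eblues[eblues$trait == trait, , drop = FALSE]
  strata <- setNames(crosses$cross_group, crosses$hybrid)
  ability <- run_cv(
    eb, A = A, D = Dk, geno = hybrids,
    env_info = distinct(eb, .data$environment, .data$location, .data$year),
    methods = config$cv$methods, scenarios = config$cv$scenarios,
    k = config$cv$k, repeats = config$cv$repeats,
    strata = strata[unique(eb$hybrid)],
    seed = (seed + 389L) %% .Machine$integer.max,
    reml_control = config$cv$reml_control %||% list(),
    ensemble_control = config$cv$ensemble_control %||% list()
  )
  readr::write_csv(ability, file.path(out_dir, "ability.csv"))
  readr::write_csv(attr(ability, "log"), file.path(out_dir, "cv_log.csv"))

  manifest <- list(
    package = "metgp",
    version = as.character(utils::packageVersion("metgp")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = rlang::hash(config),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  artifacts <- list(config = config, eblues = eblues, kernels = list(A = A, D = Dk),
                    ability = ability, manifest = manifest, out_dir = out_dir)
  report_run(artifacts)
  invisible(artifacts)
}

validate_run_config <- function(config) {
  if (is.null(config$out_dir)) abort("config needs an out_dir")
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$sim) && is.null(config$paths)) {
    abort("config needs either a 'sim' section or a 'paths' section")
  }
  if (!is.null(config$paths)) {
    for (p in unlist(config$paths)) {
      if (!file.exists(p)) abort(paste("input path does not exist:", p))
    }
  }
  config$qc <- utils::modifyList(
    list(maf_min = 0.05, max_missing = 0.20, max_het = 0.05),
    config$qc %||% list())
  cv <- utils::modifyList(
    list(methods = c("gblup_a", "gblup_ad"),
         scenarios = c("CV1", "CV2_50", "CV2_25"), k = 5, repeats = 5),
    config$cv %||% list())
  known <- c("gblup_a", "gblup_ad", "bagging", "random_forest", "boosting")
  bad <- setdiff(cv$methods, known)
  if (length(bad)) abort(paste("unknown method in config:", paste(bad, collapse = ", ")))
  bad_sc <- setdiff(cv$scenarios, c("CV1", "CV2_50", "CV2_25"))
  if (length(bad_sc)) abort(paste("unknown scenario:", paste(bad_sc, collapse = ", ")))
  config$cv <- cv
  config
}

#' Render a plain-text run report
#'
#' Writes `report.txt` in the run directory: per-environment predictive
#' abilities by method and scenario, stage-1 summaries, and (when a `budget`
#' section is configured) the cost arithmetic.
#'
#' @param artifacts Artifact list from [run_pipeline()], or a run directory
#'   containing `ability.csv` / `eblues.csv` / `manifest.json`.
#' @return The report path, invisibly.
#' @export
report_run <- function(artifacts) {
  if (is.character(artifacts)) {
    out_dir <- artifacts
    need <- file.path(out_dir, c("ability.csv", "eblues.csv", "manifest.json"))
    absent <- need[!file.exists(need)]
    if (length(absent)) {
      abort(c("missing run artifacts:", absent))
    }
    artifacts <- list(
      ability = readr::read_csv(need[1], show_col_types = FALSE),
      eblues = readr::read_csv(need[2], show_col_types = FALSE),
      manifest = jsonlite::read_json(need[3]),
      config = jsonlite::read_json(need[3])$config,
      out_dir = out_dir
    )
  }
  out <- file.path(artifacts$out_dir, "report.txt")
  lines <- c(
    "Multi-environment genomic prediction run",
    paste("generated:", artifacts$manifest$created),
    paste("seed:", artifacts$manifest$seed),
    paste("config hash:", artifacts$manifest$config_hash),
    ""
  )
  ab <- artifacts$ability
  if (is.null(ab) || nrow(ab) == 0) {
    lines <- c(lines, "Predictive ability: no results")
  } else {
    lines <- c(lines, "Per-environment predictive ability (Pearson r, mean +- SE)")
    for (sc in unique(ab$scenario)) {
      for (m in unique(ab$method)) {
        block <- ab[ab$scenario == sc & ab$method == m, ]
        if (nrow(block) == 0) next
        lines <- c(lines, sprintf("  [%s / %s]", sc, m))
        lines <- c(lines, sprintf("    %-6s r = %6.3f +- %.3f (n = %d)",
                                  block$environment, block$mean_r, block$se_r,
                                  block$n_vals))
      }
    }
  }
  bud <- artifacts$config$budget
  if (!is.null(bud)) {
    b <- do.call(budget_estimate, bud)
    lines <- c(lines, "", "Budget",
               sprintf("  phenotyping: %.2f", b$phenotyping),
               sprintf("  genotyping:  %.2f", b$genotyping),
               sprintf("  savings:     %.2f", b$savings))
  }
  writeLines(lines, out)
  invisible(out)
}
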