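#' Simulate parental inbred genotypes
#'
#' Draws fully homozygous dosages (0 or 2) for the inbred lines and testers of
#' a testcross program. Each marker has a shared base allele frequency drawn
#' from `maf_range`; each heterotic group perturbs it on the logit scale with
#' standard deviation `group_divergence`, so groups diverge smoothly without
#' group-specific allele-substitution effects. Markers are assigned to
#' chromosomes near-uniformly. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A [geno_matrix()] of kind "inbred" holding all lines followed by the
#'   testers, with `group` and `role` attributes.
#' @examples
#' g <- simulate_parents(sim_config(n_lines_per_group = c(dent = 5, flint = 5),
#'                                  n_hybrids = 15, n_snps = 20,
#'                                  n_chromosomes = 2, seed = 7))
#' table(g)  # only 0 and 2: inbreds are homozygous
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 11L, {
    groups <- names(config$n_lines_per_group)
    n_snps <- config$n_snps

    base_p <- runif(n_snps, config$maf_range[1], config$maf_range[2])
    # each group's frequency wobbles around the shared base on the logit scale
    group_p <- vapply(groups, function(g) {
      plogis(qlogis(base_p) + rnorm(n_snps, 0, config$group_divergence))
    }, numeric(n_snps))

    line_ids <- character(0)
    line_groups <- character(0)
    rows <- list()
    for (g in groups) {
      n_g <- config$n_lines_per_group[[g]]
      ids <- sprintf("L_%s_%03d", g, seq_len(n_g))
      dos <- matrix(
        2 * rbinom(n_g * n_snps, 1, rep(group_p[, g], each = n_g)),
        nrow = n_g, ncol = n_snps
      )
      rows[[g]] <- dos
      line_ids <- c(line_ids, ids)
      line_groups <- c(line_groups, rep(g, n_g))
    }

    # testers come from the dent/flint pools when those exist (as in L3/L228-3)
    pool <- intersect(c("flint", "dent"), groups)
    if (length(pool) == 0) pool <- groups
    tester_groups <- rep_len(pool, config$n_testers)
    tester_ids <- sprintf("T%d", seq_len(config$n_testers))
    testers <- matrix(0, nrow = config$n_testers, ncol = n_snps)
    for (k in seq_len(config$n_testers)) {
      testers[k, ] <- 2 * rbinom(n_snps, 1, group_p[, tester_groups[k]])
    }

    m <- rbind(do.call(rbind, rows), testers)
    rownames(m) <- c(line_ids, tester_ids)
    colnames(m) <- sprintf("M%05d", seq_len(n_snps))

    map <- tibble(
      marker = colnames(m),
      chrom = sort(rep_len(seq_len(config$n_chromosomes), n_snps))
    )
    group <- setNames(c(line_groups, tester_groups), rownames(m))
    role <- setNames(c(rep("line", length(line_ids)),
                       rep("tester", length(tester_ids))), rownames(m))
    geno_matrix(m, kind = "inbred", map = map, group = group, role = role)
  })
}

#' Build a line-by-tester crossing design
#'
#' Assigns every line to at least one tester and crosses a random subset of
#' lines to additional testers until `n_hybrids` crosses exist, mirroring
#' partially overlapping testcross designs. The cross group (line group x
#' tester group) provides the strata used by [make_folds()].
#'
#' @param parents Inbred [geno_matrix()] from [simulate_parents()].
#' @param n_hybrids Number of crosses to generate.
#' @param seed Integer seed.
#' @return Tibble with columns `hybrid`, `line`, `tester`, `cross_group`.
#' @export
make_crosses <- function(parents, n_hybrids, seed = 1L) {
  role <- attr(parents, "role")
  group <- attr(parents, "group")
  lines <- names(role)[role == "line"]
  testers <- names(role)[role == "tester"]
  if (length(testers) == 0) abort("parents contain no testers")
  n_lines <- length(lines)
  if (n_hybrids < n_lines || n_hybrids > n_lines * length(testers)) {
    abort(sprintf("n_hybrids must lie in [%d, %d]", n_lines,
                  n_lines * length(testers)))
  }
  withr::with_seed(seed + 13L, {
    first <- sample(rep_len(testers, n_lines))
    pairs <- tibble(line = lines, tester = first)
    all_pairs <- expand_grid(line = lines, tester = testers)
    remaining <- anti_join(all_pairs, pairs, by = c("line", "tester"))
    n_extra <- n_hybrids - n_lines
    if (n_extra > 0) {
      extra <- remaining[sample(nrow(remaining), n_extra), ]
      pairs <- bind_rows(pairs, extra)
    }
  })
  pairs |>
    arrange(.data$line, .data$tester) |>
    mutate(
      hybrid = paste(.data$line, .data$tester, sep = "x"),
      cross_group = paste(group[.data$line], group[.data$tester], sep = "x")
    ) |>
    select("hybrid", "line", "tester", "cross_group")
}
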