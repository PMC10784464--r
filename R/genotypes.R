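#' SNP quality control
#'
#' Discards markers whose minor allele frequency (computed from non-missing
#' dosages) falls below `maf_min`, whose missing fraction exceeds
#' `max_missing`, or whose heterozygous fraction exceeds `max_het`. The default
#' thresholds (5% MAF, 20% missing, 5% heterozygous) are the usual panel for
#' inbred parents genotyped by sequencing. A per-rule discard count is attached
#' as attribute `qc_log`; a marker violating several rules is counted under
#' each.
#'
#' The filter is idempotent: marker statistics do not change when markers are
#' dropped, so applying it twice equals applying it once.
#'
#' @param geno A [geno_matrix()].
#' @param maf_min,max_missing,max_het Thresholds in `[0, 1]`.
#' @return The filtered [geno_matrix()], with attribute `qc_log` (tibble with
#'   columns `rule`, `n_discarded`) and `qc_kept` (markers retained).
#' @export
qc_filter <- function(geno, maf_min = 0.05, max_missing = 0.20, max_het = 0.05) {
  if (ncol(geno) == 0 || nrow(geno) == 0) abort("empty genotype matrix")
  for (th in c(maf_min, max_missing, max_het)) {
    if (th < 0 || th > 1) abort("QC thresholds must lie in [0, 1]")
  }
  st <- marker_stats(geno)
  fail_missing <- st$missing > max_missing
  # markers with no calls at all fail the missingness rule; their maf/het are NaN
  fail_maf <- !is.na(st$maf) & st$maf < maf_min
  fail_het <- !is.na(st$het) & st$het > max_het
  keep <- !(fail_missing | fail_maf | fail_het)
  if (!any(keep)) abort("empty panel: all markers discarded by QC")
  out <- geno[, keep, drop = FALSE]
  attr(out, "qc_log") <- tibble(
    rule = c("maf", "missing", "het"),
    threshold = c(maf_min, max_missing, max_het),
    n_discarded = c(sum(fail_maf, na.rm = TRUE), sum(fail_missing),
                    sum(fail_het, na.rm = TRUE))
  )
  attr(out, "qc_kept") <- colnames(out)
  out
}

#' Impute missing dosages by the per-marker mode
#'
#' Replaces every missing call with the most frequent non-missing dosage of the
#' marker, breaking ties toward the lower dosage. For inbred matrices only the
#' homozygous dosages (0, 2) are candidate values, so inbreds never receive an
#' imputed heterozygote. This deliberately simple rule stands in for
#' haplotype-based imputation; imputation accuracy is not part of any
#' inferential contract downstream.
#'
#' @param geno A [geno_matrix()] that already passed [qc_filter()].
#' @return The matrix with no missing values.
#' @export
impute_genotypes <- function(geno) {
  m <- unclass(geno)
  miss_cols <- which(colSums(is.na(m)) > 0)
  if (length(miss_cols) == 0) return(geno)
  inbred <- identical(attr(geno, "kind"), "inbred")
  candidates <- if (inbred) c(0, 2) else c(0, 1, 2)
  for (j in miss_cols) {
    x <- m[, j]
    counts <- vapply(candidates, function(v) sum(x == v, na.rm = TRUE), 0)
    if (sum(counts) == 0) {
      abort(sprintf("marker %s is entirely missing; it should have been removed by QC",
                    colnames(m)[j]))
    }
    m[is.na(x), j] <- candidates[which.max(counts)]
  }
  restore_geno(m, geno)
}

#' Force residual heterozygous calls in inbreds to the modal homozygote
#'
#' Inbred parents may retain a few heterozygous calls after QC (at most 5% per
#' marker). Before hybrid genotypes are inferred these are set to the marker's
#' most frequent homozygote (ties toward dosage 0) so that inference from
#' parental dosages is deterministic.
#'
#' @param geno An inbred [geno_matrix()] without missing values.
#' @return The matrix with all dosages in {0, 2}.
#' @export
force_homozygous <- function(geno) {
  m <- unclass(geno)
  het_cols <- which(colSums(m == 1, na.rm = TRUE) > 0)
  for (j in het_cols) {
    x <- m[, j]
    mode_h <- if (sum(x == 2) > sum(x == 0)) 2 else 0
    m[x == 1, j] <- mode_h
  }
  restore_geno(m, geno)
}

#' Infer hybrid genotypes from homozygous parents
#'
#' A single-cross hybrid inherits one allele from each homozygous parent, so
#' its dosage is the parental average: (0,0) -> 0, (0,2) -> 1, (2,2) -> 2.
#'
#' @param parents Imputed, fully homozygous inbred [geno_matrix()].
#' @param crosses Tibble mapping `hybrid` to `line` and `tester` (as produced
#'   by [make_crosses()]).
#' @return A [geno_matrix()] of kind "hybrid", one row per cross, carrying the
#'   crossing design as attribute `crosses`.
#' @export
infer_hybrid_genotypes <- function(parents, crosses) {
  m <- unclass(parents)
  need <- union(crosses$line, crosses$tester)
  missing_par <- setdiff(need, rownames(m))
  if (length(missing_par) > 0) {
    abort(paste("crosses reference unknown parents:",
                paste(utils::head(missing_par, 5), collapse = ", ")))
  }
  sub <- m[need, , drop = FALSE]
  if (anyNA(sub)) abort("parents contain missing dosages; impute first")
  if (any(sub == 1)) {
    abort("parents contain heterozygous dosages; run force_homozygous() first")
  }
  h <- (m[crosses$line, , drop = FALSE] + m[crosses$tester, , drop = FALSE]) / 2
  rownames(h) <- crosses$hybrid
  out <- geno_matrix(h, kind = "hybrid", map = attr(parents, "map"))
  attr(out, "crosses") <- crosses
  out
}
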