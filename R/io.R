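#' Read and write dosage matrices
#'
#' The dosage dialect is a tab-separated table: a header row of marker ids,
#' one row per entity with the entity id in the first column, missing values
#' as `NA`.
#'
#' @param geno A [geno_matrix()].
#' @param path File path.
#' @return `write_dosage()` returns `path` invisibly; `read_dosage()` returns
#'   a [geno_matrix()].
#' @export
write_dosage <- function(geno, path) {
  df <- as.data.frame(unclass(geno))
  df <- cbind(entity = rownames(geno), df)
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_dosage
#' @param kind Entity kind of the matrix being read.
#' @param map Optional marker map tibble (`marker`, `chrom`).
#' @export
read_dosage <- function(path, kind = c("inbred", "hybrid"), map = NULL) {
  kind <- match.arg(kind)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  geno_matrix(m, kind = kind, map = map)
}

#' Read and write kernel matrices
#'
#' Kernels are written as CSV with a header row and a leading column of
#' hybrid ids.
#'
#' @param K Symmetric kernel matrix with dimnames.
#' @param path File path.
#' @export
write_kernel <- function(K, path) {
  df <- as.data.frame(K)
  df <- cbind(hybrid = rownames(K), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Published variance components for a maize drought-tolerance trial series
#'
#' Variance-component and genetic-parameter estimates reported for a tropical
#' maize testcross program: 265 single-cross hybrids, grain yield (GY, t/ha)
#' and female flowering time (FFT, days), evaluated under well-watered (WW)
#' and water-stress (WS) regimes at two locations (J, T) over two years. Each
#' regime group was analysed jointly over its four environments (with
#' across-environment additive and dominance correlations) and within each
#' environment separately. The printed genetic parameters allow the
#' variance-ratio arithmetic of [genetic_params()] to be checked against an
#' independently published table.
#'
#' @return Tibble with columns `trait`, `regime`, `analysis`, `environment`,
#'   `sigma2_a`, `sigma2_d`, `sigma2_e`, `rho_a`, `rho_d`, and the printed
#'   ratios `h2`, `d2`, `H2`.
#' @export
met_reference_varcomp <- function() {
  path <- system.file("extdata", "maize_met_varcomp.csv", package = "metgp")
  readr::read_csv(path, show_col_types = FALSE)
}
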