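#' Dosage matrix helpers
#'
#' Genotypes are stored as plain numeric matrices of reference-allele dosages
#' (entities in rows, markers in columns) with three attributes: `kind`
#' ("inbred" or "hybrid"), `map` (a tibble with columns `marker` and `chrom`),
#' and, for parents, `group` (named character vector of heterotic groups) and
#' `role` ("line"/"tester"). Values are 0, 1, 2 or `NA`.
#'
#' @param x Numeric matrix with entity rownames and marker colnames.
#' @param kind "inbred" or "hybrid".
#' @param map Tibble with columns `marker`, `chrom` (one row per column of `x`).
#' @param group Optional named character vector of group labels per entity.
#' @param role Optional named character vector ("line"/"tester") per entity.
#' @return The matrix with class `geno_matrix` and the attributes attached.
#' @export
geno_matrix <- function(x, kind = c("inbred", "hybrid"), map = NULL,
                        group = NULL, role = NULL) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (is.null(rownames(x))) abort("dosage matrix needs entity rownames")
  if (is.null(colnames(x))) abort("dosage matrix needs marker colnames")
  bad <- !(x %in% c(0, 1, 2)) & !is.na(x)
  if (any(bad)) abort("dosages must be 0, 1, 2 or NA")
  if (is.null(map)) map <- tibble(marker = colnames(x), chrom = 1L)
  stopifnot(nrow(map) == ncol(x))
  structure(x, kind = kind, map = map, group = group, role = role,
            class = c("geno_matrix", class(matrix())))
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d %s entities x %d markers (%s missing)\n",
              nrow(x), attr(x, "kind"), ncol(x),
              sprintf("%.1f%%", 100 * mean(is.na(x)))))
  print(utils::head(unclass(x)[, seq_len(min(6, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
`[.geno_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (!is.matrix(out)) return(out)
  map <- attr(x, "map")
  if (!missing(j)) {
    idx <- seq_len(ncol(x))
    names(idx) <- colnames(x)
    map <- map[idx[colnames(out)], , drop = FALSE]
  }
  grp <- attr(x, "group")
  role <- attr(x, "role")
  geno_matrix(out, kind = attr(x, "kind"), map = map,
              group = if (!is.null(grp)) grp[rownames(out)] else NULL,
              role = if (!is.null(role)) role[rownames(out)] else NULL)
}

#' @rdname geno_matrix
#' @export
marker_map <- function(x) attr(x, "map")

# restore geno attributes after an operation that returns a bare matrix
restore_geno <- function(new, old, kind = attr(old, "kind")) {
  geno_matrix(new, kind = kind, map = attr(old, "map"),
              group = attr(old, "group"), role = attr(old, "role"))
}

# per-marker summaries used by QC and the kernels
marker_stats <- function(geno) {
  m <- unclass(geno)
  n_ok <- colSums(!is.na(m))
  p <- colMeans(m, na.rm = TRUE) / 2
  tibble(
    marker = colnames(m),
    p = p,
    maf = pmin(p, 1 - p),
    missing = 1 - n_ok / nrow(m),
    het = colMeans(m == 1, na.rm = TRUE)
  )
}
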