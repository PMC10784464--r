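#' Compound-symmetry covariance matrix
#'
#' `CS(q, sigma2, rho) = sigma2 * [(1 - rho) I_q + rho J_q]`: equal variance
#' and equal pairwise correlation across the `q` environments. Positive
#' definite exactly when `rho` lies in `(-1/(q-1), 1)`.
#'
#' @param q Dimension (number of environments).
#' @param sigma2 Common variance.
#' @param rho Common correlation (ignored when `q = 1`).
#' @return A `q x q` matrix.
#' @export
cs_matrix <- function(q, sigma2, rho = 0) {
  if (q == 1) return(matrix(sigma2, 1, 1))
  if (rho <= -1 / (q - 1) || rho > 1) {
    abort(sprintf("rho = %.4f outside (%.4f, 1]: CS matrix not positive definite",
                  rho, -1 / (q - 1)))
  }
  sigma2 * ((1 - rho) * diag(q) + rho * matrix(1, q, q))
}

#' Covariance of observed hybrid-by-environment cells
#'
#' Assembles the joint model covariance
#' \deqn{V = CS(\sigma^2_{u_a}, \rho_a) \otimes A +
#'           CS(\sigma^2_{u_d}, \rho_d) \otimes D + \sigma^2_e I}
#' over the full hybrid-by-environment grid (records ordered
#' environment-major, hybrid-minor: all hybrids of environment 1, then all of
#' environment 2, ...) and restricts it to the observed cells.
#'
#' @param params Named list with `sigma2_a`, `rho_a`, `sigma2_e` and, when a
#'   dominance kernel is supplied, `sigma2_d`, `rho_d`.
#' @param A Additive kernel over hybrids (rows/columns define hybrid order).
#' @param D Optional dominance kernel with identical dimnames.
#' @param q Number of environments.
#' @param obs Optional integer vector of observed cell indices into the
#'   environment-major grid (default: all `nrow(A) * q` cells).
#' @return The covariance matrix over the requested cells.
#' @export
build_covariance <- function(params, A, D = NULL, q, obs = NULL) {
  p <- nrow(A)
  Ka <- cs_matrix(q, params$sigma2_a, params$rho_a %||% 0)
  V <- kronecker(Ka, A)
  if (!is.null(D)) {
    stopifnot(identical(dimnames(A), dimnames(D)))
    Kd <- cs_matrix(q, params$sigma2_d, params$rho_d %||% 0)
    V <- V + kronecker(Kd, D)
  }
  diag(V) <- diag(V) + params$sigma2_e
  if (!is.null(obs)) V <- V[obs, obs, drop = FALSE]
  V
}
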