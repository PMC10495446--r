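# Spherical-spline scalp interpolation (order m = 4), used both for
# reconstructing removed channels and for the bad-channel predictability
# criterion.

legendre_table <- function(x, n_max) {
  # rows: n = 1..n_max, columns: x
  P <- matrix(0, n_max, length(x))
  P[1, ] <- x
  if (n_max >= 2) P[2, ] <- (3 * x^2 - 1) / 2
  if (n_max >= 3) for (n in 3:n_max)
    P[n, ] <- ((2 * n - 1) * x * P[n - 1, ] - (n - 1) * P[n - 2, ]) / n
  P
}

#' Spherical-spline kernel g(cos angle), order m, truncated series
#' @noRd
spline_g <- function(x, m = 4, n_terms = 15) {
  n <- seq_len(n_terms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_table(pmin(pmax(x, -1), 1), n_terms)
  as.vector(crossprod(coef, P)) / (4 * pi)
}

unit_rows <- function(pos) {
  r <- sqrt(rowSums(pos^2))
  if (any(r == 0)) stop("electrode position at the origin cannot be projected")
  pos / r
}

#' Linear operator mapping data at `from` electrodes to estimates at `to`
#'
#' Solves the spherical-spline system on the unit sphere and returns the
#' `n_to x n_from` matrix `T` such that `est = T %*% data_from`. A small
#' ridge on the Gram matrix stabilizes nearly coincident electrodes.
#'
#' @param from_pos n_from x 3 positions
#' @param to_pos n_to x 3 positions
#' @param m spline order
#' @param lambda ridge added to the Gram diagonal
#' @return interpolation matrix
#' @export
spline_interp_matrix <- function(from_pos, to_pos, m = 4, lambda = 1e-8) {
  from_u <- unit_rows(as.matrix(from_pos))
  to_u <- unit_rows(matrix(as.matrix(to_pos), ncol = 3))
  k <- nrow(from_u)
  G <- matrix(spline_g(tcrossprod(from_u), m = m), k, k) + lambda * diag(k)
  aug <- rbind(cbind(G, 1), c(rep(1, k), 0))
  Minv <- solve(aug)[, seq_len(k), drop = FALSE]      # (k+1) x k
  Gto <- matrix(spline_g(tcrossprod(to_u, from_u), m = m), nrow(to_u), k)
  cbind(Gto, 1) %*% Minv
}
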