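#' Second-order random-walk penalty matrix
#'
#' Builds the scaled precision matrix of the intrinsic second-order
#' random-walk (RW2) prior used for the nonlinear component of the time
#' trends. The matrix is the crossproduct of the second-difference operator,
#' `P = t(D2) %*% D2`, where `D2` is the `(T-2) x T` operator taking second
#' differences of a length-`T` vector. Its diagonal is
#' `(1, 5, 6, ..., 6, 5, 1)`, the first off-diagonal `(-2, -4, ..., -4, -2)`
#' and the second off-diagonal is constant 1. `P` is rank `T - 2`: its null
#' space is spanned by the constant and the linear ramp, so the prior is flat
#' on the mean and linear slope of the smooth, which are carried instead by
#' the hierarchical intercepts and slopes.
#'
#' @param T_len integer grid length (number of time points), at least 4.
#' @return An object of class `gmr_penalty`: a list with elements `T` (grid
#'   length) and `P` (the `T x T` symmetric penalty matrix).
#' @examples
#' pen <- build_penalty(5)
#' diag(pen$P)       # 1 5 6 5 1
#' range(pen$P %*% rep(1, 5))  # numerically zero: constant in null space
#' @export
build_penalty <- function(T_len) {
  T_len <- as.integer(T_len)
  if (length(T_len) != 1L || is.na(T_len) || T_len < 4L)
    stop("build_penalty() requires an integer grid length T >= 4")
  D2 <- second_difference_operator(T_len)
  P <- crossprod(D2)
  structure(list(T = T_len, P = P), class = "gmr_penalty")
}

# (T-2) x T second-difference operator: rows are (..., 1, -2, 1, ...)
second_difference_operator <- function(T_len) {
  D2 <- matrix(0, T_len - 2L, T_len)
  for (i in seq_len(T_len - 2L)) D2[i, i:(i + 2L)] <- c(1, -2, 1)
  D2
}

#' RW2 (intrinsic GMRF) log prior density
#'
#' Log density of the improper second-order random-walk prior, up to an
#' additive constant:
#' \deqn{\log p(u \mid \lambda) = \frac{T-2}{2}\log\lambda -
#'       \frac{\lambda}{2} u' P u + \mathrm{const},}
#' the exponent reflecting the rank `T - 2` of `P`. The density is evaluated
#' for vectors satisfying the zero-mean / zero-slope identifiability
#' constraints; it is well defined (but improper) for any `u`.
#'
#' @param u numeric vector of length `T`.
#' @param lambda positive precision multiplier.
#' @param penalty a `gmr_penalty` from [build_penalty()].
#' @return log density (scalar), up to an additive constant.
#' @export
rw2_log_density <- function(u, lambda, penalty) {
  stopifnot(inherits(penalty, "gmr_penalty"))
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a positive scalar")
  if (length(u) != penalty$T)
    stop("u must have length ", penalty$T)
  q <- drop(crossprod(u, penalty$P %*% u))
  (penalty$T - 2) / 2 * log(lambda) - lambda / 2 * q
}

# Eigen decomposition of P with its two-dimensional null space dropped.
# Returned once per fit and reused for constrained prior sampling.
penalty_eigen <- function(penalty) {
  e <- eigen(penalty$P, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  list(values = e$values[keep], vectors = e$vectors[, keep, drop = FALSE])
}

# Draw from the RW2 prior N(0, (lambda P)^+): sampling in the row space of P
# automatically enforces the zero-mean and zero-slope constraints because the
# null space of P is exactly span{constant, linear ramp}.
rw2_prior_draw <- function(pe, lambda) {
  z <- stats::rnorm(length(pe$values))
  drop(pe$vectors %*% (z / sqrt(lambda * pe$values)))
}
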