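#' Sex- and outcome-specific cubic spline age basis
#'
#' Truncated-power cubic basis for the age curve of mean height or BMI:
#' columns \eqn{\tilde z, \tilde z^2, \tilde z^3, (z-k_1)_+^3, \ldots} where
#' \eqn{\tilde z = z - 12} is age centred at 12 years. Height uses four knots
#' (girls at ages 8, 10, 12, 14; boys at 10, 12, 14, 16, reflecting the
#' roughly two-year-earlier growth spurt in girls); BMI uses two knots at
#' ages 10 and 15 for both sexes. There is no intercept column: the level of
#' the curve is carried by the hierarchical intercepts. For conditioning and
#' identifiability, columns are scaled to unit maximum absolute value on the
#' reference grid (ages 5-19) and then centred to zero mean over that grid:
#' without the centring the basis can approximate a constant almost exactly,
#' leaving the split of the overall level between intercepts and spline
#' coefficients on a near-flat ridge. Scale and centring are recorded in the
#' basis object so coefficients remain interpretable and evaluation on any
#' age grid is consistent.
#'
#' @param ages numeric vector of ages (years) in `[5, 19]` at which to
#'   evaluate the basis.
#' @param sex `"female"` or `"male"`.
#' @param outcome `"height"` or `"bmi"`.
#' @param z_center centring constant for age (years); default 12.
#' @return An object of class `gmr_basis`: list with `knots`, `z_center`,
#'   `scale` (per-column divisor), `ages`, and `B` (the design matrix, one
#'   row per age, `3 + length(knots)` columns).
#' @examples
#' b <- build_spline_basis(5:19, "female", "height")
#' ncol(b$B)  # 7 coefficients
#' @export
build_spline_basis <- function(ages, sex, outcome, z_center = 12) {
  sex <- match.arg(sex, c("female", "male"))
  outcome <- match.arg(outcome, c("height", "bmi"))
  if (any(ages < 5 - 1e-9) || any(ages > 19 + 1e-9))
    stop("ages must lie in [5, 19]")
  knots <- spline_knots(sex, outcome)
  ref <- raw_power_basis(5:19, knots, z_center)
  scl <- apply(abs(ref), 2, max)
  ctr <- colMeans(sweep(ref, 2, scl, "/"))
  B <- sweep(sweep(raw_power_basis(ages, knots, z_center), 2, scl, "/"),
             2, ctr, "-")
  structure(list(knots = knots, z_center = z_center, scale = scl,
                 center = ctr, ages = ages, B = B),
            class = "gmr_basis")
}

#' Spline knot ages by sex and outcome
#'
#' @inheritParams build_spline_basis
#' @return numeric vector of knot ages (years).
#' @export
spline_knots <- function(sex, outcome) {
  sex <- match.arg(sex, c("female", "male"))
  outcome <- match.arg(outcome, c("height", "bmi"))
  if (outcome == "bmi") return(c(10, 15))
  if (sex == "female") c(8, 10, 12, 14) else c(10, 12, 14, 16)
}

raw_power_basis <- function(ages, knots, z_center) {
  zc <- ages - z_center
  cols <- cbind(zc, zc^2, zc^3)
  for (k in knots) cols <- cbind(cols, pmax(ages - k, 0)^3)
  colnames(cols) <- c("z", "z2", "z3", paste0("k", seq_along(knots)))
  cols
}

#' Evaluate a spline basis at new ages
#'
#' Reuses the knots, centring and column scaling frozen in `basis`, so
#' coefficients estimated on one age grid apply on any other.
#'
#' @param basis a `gmr_basis` from [build_spline_basis()].
#' @param ages numeric vector of ages in `[5, 19]`.
#' @return design matrix with `length(ages)` rows.
#' @export
basis_matrix <- function(basis, ages) {
  stopifnot(inherits(basis, "gmr_basis"))
  if (any(ages < 5 - 1e-9) || any(ages > 19 + 1e-9))
    stop("ages must lie in [5, 19]")
  sweep(sweep(raw_power_basis(ages, basis$knots, basis$z_center), 2,
              basis$scale, "/"), 2, basis$center, "-")
}
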