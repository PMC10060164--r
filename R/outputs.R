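#' Posterior prediction grids
#'
#' Evaluates, for every retained draw, the country-level mean on a
#' country x year x age x stratum grid with all study-level terms (coverage
#' offsets, study random effects) set to zero:
#' `a_j + b_j*t~ + u_{j,t} + gamma_j(z) + I*(p_j + q_j*t~ + r_j*z~)` with
#' `I = +1` (urban) or `-1` (rural). For BMI the model time of cell
#' (year, age) is the year; for height it is the birth cohort
#' `year - age`, which must lie on the fitted cohort grid (cells outside it
#' are refused, not extrapolated). For height the grid is (by default)
#' monotonized over age within each draw x country x stratum x birth
#' cohort by weighted-least-squares isotonic regression ([apply_pava()]).
#'
#' @param object a `gmr_fit`.
#' @param years calendar years to predict (default: all years fully
#'   covered by the fitted time grid).
#' @param ages ages to predict (default: the fitted ages).
#' @param strata subset of `c("urban", "rural")`.
#' @param monotonize apply the within-cohort isotonic constraint (default:
#'   height only).
#' @param ... unused.
#' @return object of class `gmr_grid`: a 5-d array
#'   `[draw, country, year, age, stratum]` with dimnames, plus attributes
#'   `outcome`, `timescale`.
#' @export
predict.gmr_fit <- function(object, years = NULL, ages = NULL,
                            strata = c("urban", "rural"),
                            monotonize = NULL, ...) {
  spec <- object$spec
  dr <- object$draws
  strata <- match.arg(strata, several.ok = TRUE)
  if (is.null(ages)) ages <- spec$ages
  if (is.null(years)) {
    years <- if (spec$timescale == "observation") spec$years
             else (min(spec$years) + max(ages)):(max(spec$years) + min(ages))
  }
  if (is.null(monotonize)) monotonize <- spec$outcome == "height"
  tmod <- if (spec$timescale == "observation")
    outer(years, ages, function(y, z) y)
  else outer(years, ages, function(y, z) y - z)
  if (any(!(tmod %in% spec$years)))
    stop("some (year, age) cells need model time points outside the ",
         "fitted grid ", min(spec$years), "-", max(spec$years),
         "; refuse to extrapolate")
  nd <- dr$n_draws
  J <- ncol(dr$a)
  Bz <- basis_matrix(object$data$basis, ages)
  g <- array(NA_real_, c(nd, J, length(years), length(ages),
                         length(strata)),
             dimnames = list(NULL, dr$countries, years, ages, strata))
  gam <- matrix(dr$gamma, nd * J, dim(dr$gamma)[3])
  for (yi in seq_along(years)) for (zi in seq_along(ages)) {
    ti <- match(tmod[yi, zi], spec$years)
    tc <- tmod[yi, zi] - spec$t_center
    zc <- ages[zi] - spec$z_center
    base <- dr$a + dr$b * tc + dr$u[, , ti] +
      matrix(gam %*% Bz[zi, ], nd, J)
    off <- dr$p + dr$q * tc + dr$r * zc
    for (si in seq_along(strata)) {
      I <- if (strata[si] == "urban") 1 else -1
      g[, , yi, zi, si] <- base + I * off
    }
  }
  g <- structure(g, class = "gmr_grid", outcome = spec$outcome,
                 timescale = spec$timescale)
  if (monotonize) g <- monotonize_grid(g)
  g
}

#' Weighted pool-adjacent-violators algorithm
#'
#' Weighted least-squares isotonic (nondecreasing) regression: returns the
#' nondecreasing sequence minimizing `sum(w * (fit - x)^2)`. Adjacent
#' violating blocks are pooled to their weighted mean until the fit is
#' monotone; the weighted mean of the input is preserved.
#'
#' @param values numeric sequence.
#' @param weights positive weights, recycled to `length(values)`.
#' @return the isotonic fit, same length as `values`.
#' @examples
#' apply_pava(c(3, 1, 2))  # 2 2 2
#' @export
apply_pava <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n == 0L) return(values)
  weights <- rep_len(weights, n)
  if (any(weights <= 0)) stop("weights must be positive")
  mean_b <- numeric(n)   # block means
  w_b <- numeric(n)      # block weights
  len_b <- integer(n)    # block lengths
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    mean_b[nb] <- values[i]
    w_b[nb] <- weights[i]
    len_b[nb] <- 1L
    while (nb > 1L && mean_b[nb - 1L] > mean_b[nb]) {
      wsum <- w_b[nb - 1L] + w_b[nb]
      mean_b[nb - 1L] <- (w_b[nb - 1L] * mean_b[nb - 1L] +
                            w_b[nb] * mean_b[nb]) / wsum
      w_b[nb - 1L] <- wsum
      len_b[nb - 1L] <- len_b[nb - 1L] + len_b[nb]
      nb <- nb - 1L
    }
  }
  rep(mean_b[seq_len(nb)], len_b[seq_len(nb)])
}

# Apply the isotonic constraint along birth-cohort trajectories of a
# height grid: for each draw, country, stratum and cohort c, the cells
# (year = c + z, age = z) must be nondecreasing in z.
monotonize_grid <- function(grid, weights = NULL) {
  stopifnot(inherits(grid, "gmr_grid"))
  dn <- dimnames(grid)
  years <- as.integer(dn[[3]])
  ages <- as.integer(dn[[4]])
  nd <- dim(grid)[1]
  J <- dim(grid)[2]
  ns <- dim(grid)[5]
  for (coh in (min(years) - max(ages)):(max(years) - min(ages))) {
    zs <- ages[(coh + ages) %in% years]
    if (length(zs) < 2L) next
    yi <- match(coh + zs, years)
    zi <- match(zs, ages)
    w <- if (is.null(weights)) rep(1, length(zs))
         else rep_len(weights, length(zs))
    idx <- cbind(rep(yi, each = 1), zi)
    for (si in seq_len(ns)) for (jj in seq_len(J)) for (di in seq_len(nd)) {
      v <- grid[cbind(di, jj, yi, zi, si)]
      if (is.unsorted(v)) grid[cbind(di, jj, yi, zi, si)] <- apply_pava(v, w)
    }
  }
  grid
}

#' Standard-population age weights
#'
#' Weights over single-year ages used to age-standardize age-specific
#' estimates. Defaults to uniform weights; standard-population weights
#' (for example the WHO standard) are supplied as values and validated to
#' be nonnegative and to sum to one.
#'
#' @param ages integer ages.
#' @param values optional weights (recycled not allowed; one per age). If
#'   omitted, uniform.
#' @return named numeric vector summing to 1.
#' @export
standard_weights <- function(ages, values = NULL) {
  if (is.null(values)) values <- rep(1 / length(ages), length(ages))
  if (length(values) != length(ages))
    stop("need exactly one weight per age")
  if (any(values < 0)) stop("weights must be nonnegative")
  if (abs(sum(values) - 1) > 1e-12)
    stop("weights must sum to 1 (within 1e-12)")
  stats::setNames(values, ages)
}

#' Read or write age weights as YAML
#' @param weights named weight vector from [standard_weights()].
#' @param path file path.
#' @export
write_weights <- function(weights, path) {
  yaml::write_yaml(list(age = as.integer(names(weights)),
                        weight = as.numeric(weights)), path,
                   precision = 15)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  y <- yaml::read_yaml(path)
  standard_weights(unlist(y$age), unlist(y$weight))
}

#' Age-standardize age-specific values
#'
#' Weighted mean of age-specific values using standard-population weights.
#' For a prediction grid, collapses the age dimension; every age carried by
#' the weights must be present.
#'
#' @param x numeric vector of age-specific values (named by age, or in the
#'   order of `weights`), or a `gmr_grid`.
#' @param weights weights from [standard_weights()].
#' @return scalar for a vector input; for a grid, an array
#'   `[draw, country, year, stratum]`.
#' @export
age_standardize <- function(x, weights) {
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  if (inherits(x, "gmr_grid")) {
    ages <- dimnames(x)[[4]]
    if (!setequal(names(weights), ages) ||
        length(weights) != length(ages))
      stop("grid ages and weight ages must match exactly")
    w <- weights[ages]
    d <- dim(x)
    out <- array(0, d[-4], dimnames = dimnames(x)[-4])
    for (zi in seq_along(ages))
      out <- out + w[zi] * array(x[, , , zi, , drop = FALSE], d[-4])
    return(out)
  }
  x <- as.numeric(if (!is.null(names(x)) && !is.null(names(weights)))
    x[names(weights)] else x)
  if (length(x) != length(weights) || anyNA(x))
    stop("need a value for every age in the weights")
  sum(weights * x)
}

#' Summarize posterior draws
#'
#' Posterior mean, SD and equal-tailed 95% credible interval (2.5th and
#' 97.5th percentiles, linear interpolation of order statistics).
#'
#' @param x numeric vector of draws, or a matrix/array whose first
#'   dimension indexes draws.
#' @return data frame with columns `mean`, `sd`, `lower`, `upper` (one row
#'   per non-draw cell, in column-major order with dimnames preserved
#'   where available).
#' @export
summarize_draws <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  m <- matrix(x, nrow = dim(x)[1])
  if (nrow(m) < 2) stop("need at least 2 draws")
  qs <- apply(m, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  data.frame(mean = colMeans(m), sd = apply(m, 2, stats::sd),
             lower = qs[1, ], upper = qs[2, ])
}

#' Change between two time points and its posterior probability
#'
#' Per-draw change `value2 - value1` summarized with the posterior
#' probability that the change is a true increase (the fraction of draws
#' above zero). The probability of a decrease is one minus that of an
#' increase; a change statistically indistinguishable from zero has both
#' near 0.5.
#'
#' @param draws1,draws2 paired per-draw values (same length, same draws).
#' @return list with `summary` (from [summarize_draws()]), `pp_increase`,
#'   `pp_decrease`.
#' @export
change_and_pp <- function(draws1, draws2) {
  if (length(draws1) != length(draws2))
    stop("draw sets must be paired (equal length)")
  ch <- draws2 - draws1
  pp <- mean(ch > 0)
  list(summary = summarize_draws(ch), pp_increase = pp,
       pp_decrease = 1 - pp)
}

#' Urban-rural difference grid
#'
#' Per-draw urban minus rural difference: positive values mean the urban
#' mean is higher. Countries listed in `not_estimated` (for example
#' territories that are entirely urban or entirely rural, where the
#' contrast is not defined) are returned as `NA`, never as 0.
#'
#' @param grid a `gmr_grid` containing both strata.
#' @param not_estimated character vector of country names to mark as not
#'   estimated.
#' @return array `[draw, country, year, age]`.
#' @export
urban_rural_difference <- function(grid, not_estimated = NULL) {
  stopifnot(inherits(grid, "gmr_grid"))
  strata <- dimnames(grid)[[5]]
  if (!all(c("urban", "rural") %in% strata))
    stop("grid must contain both urban and rural strata")
  ui <- match("urban", strata)
  ri <- match("rural", strata)
  d <- array(grid[, , , , ui, drop = FALSE] -
               grid[, , , , ri, drop = FALSE],
             dim(grid)[1:4], dimnames = dimnames(grid)[1:4])
  if (!is.null(not_estimated)) {
    jj <- match(not_estimated, dimnames(grid)[[2]])
    if (anyNA(jj)) stop("unknown country in not_estimated")
    d[, jj, , ] <- NA_real_
  }
  d
}

#' Tidy summary table of a prediction grid
#'
#' One row per country x year x quantity (urban, rural, difference) x age
#' group (each reporting age plus the age-standardized value), with
#' posterior mean, 95% CrI and posterior SD. Difference rows for countries
#' whose contrast is not estimated carry NA values and `estimated = FALSE`.
#'
#' @param grid a `gmr_grid` with both strata.
#' @param weights age-standardization weights (default uniform over the
#'   grid ages).
#' @param report_ages ages to report individually (subset of grid ages).
#' @param not_estimated countries whose urban-rural difference is not
#'   estimated.
#' @return data frame with columns `country, year, quantity, age, mean,
#'   lower, upper, sd, estimated`.
#' @export
build_summary_table <- function(grid, weights = NULL,
                                report_ages = c(5, 10, 15, 19),
                                not_estimated = NULL) {
  stopifnot(inherits(grid, "gmr_grid"))
  dn <- dimnames(grid)
  ages <- as.integer(dn[[4]])
  report_ages <- intersect(report_ages, ages)
  if (is.null(weights)) weights <- standard_weights(ages)
  std <- age_standardize(grid, weights)       # [draw, country, year, stratum]
  diffg <- urban_rural_difference(grid, not_estimated)
  ui <- match("urban", dimnames(std)[[4]])
  ri <- match("rural", dimnames(std)[[4]])
  std_diff <- array(std[, , , ui, drop = FALSE] -
                      std[, , , ri, drop = FALSE], dim(std)[1:3])
  if (!is.null(not_estimated))
    std_diff[, match(not_estimated, dn[[2]]), ] <- NA_real_
  rows <- list()
  emit <- function(draw_mat, country, year, quantity, age) {
    ok <- !anyNA(draw_mat)
    s <- if (ok) summarize_draws(draw_mat)
         else data.frame(mean = NA_real_, sd = NA_real_,
                         lower = NA_real_, upper = NA_real_)
    data.frame(country = country, year = year, quantity = quantity,
               age = age, mean = s$mean, lower = s$lower, upper = s$upper,
               sd = s$sd, estimated = ok)
  }
  for (jj in seq_along(dn[[2]])) for (yy in seq_along(dn[[3]])) {
    cn <- dn[[2]][jj]; yr <- as.integer(dn[[3]][yy])
    rows[[length(rows) + 1]] <-
      emit(std[, jj, yy, "urban"], cn, yr, "urban", "std")
    rows[[length(rows) + 1]] <-
      emit(std[, jj, yy, "rural"], cn, yr, "rural", "std")
    rows[[length(rows) + 1]] <-
      emit(std_diff[, jj, yy], cn, yr, "difference", "std")
    for (za in report_ages) {
      zi <- match(za, ages)
      rows[[length(rows) + 1]] <-
        emit(grid[, jj, yy, zi, "urban"], cn, yr, "urban", as.character(za))
      rows[[length(rows) + 1]] <-
        emit(grid[, jj, yy, zi, "rural"], cn, yr, "rural", as.character(za))
      rows[[length(rows) + 1]] <-
        emit(diffg[, jj, yy, zi], cn, yr, "difference", as.character(za))
    }
  }
  do.call(rbind, rows)
}

#' Change-over-time table with posterior probabilities
#'
#' Per country x quantity, the age-standardized change between two years
#' with its 95% CrI and the posterior probabilities of a true increase and
#' decrease.
#'
#' @inheritParams build_summary_table
#' @param year1,year2 the two calendar years compared (both on the grid).
#' @return data frame with columns `country, quantity, year1, year2,
#'   change, lower, upper, sd, pp_increase, pp_decrease`.
#' @export
build_change_table <- function(grid, year1, year2, weights = NULL,
                               not_estimated = NULL) {
  dn <- dimnames(grid)
  ages <- as.integer(dn[[4]])
  if (is.null(weights)) weights <- standard_weights(ages)
  std <- age_standardize(grid, weights)
  y1 <- match(as.character(year1), dn[[3]])
  y2 <- match(as.character(year2), dn[[3]])
  if (is.na(y1) || is.na(y2)) stop("both years must be on the grid")
  rows <- list()
  for (jj in seq_along(dn[[2]])) {
    for (qt in c("urban", "rural", "difference")) {
      v1 <- if (qt == "difference")
        std[, jj, y1, "urban"] - std[, jj, y1, "rural"]
      else std[, jj, y1, qt]
      v2 <- if (qt == "difference")
        std[, jj, y2, "urban"] - std[, jj, y2, "rural"]
      else std[, jj, y2, qt]
      ne <- !is.null(not_estimated) && dn[[2]][jj] %in% not_estimated &&
        qt == "difference"
      if (ne) {
        rows[[length(rows) + 1]] <- data.frame(
          country = dn[[2]][jj], quantity = qt, year1 = year1,
          year2 = year2, change = NA_real_, lower = NA_real_,
          upper = NA_real_, sd = NA_real_, pp_increase = NA_real_,
          pp_decrease = NA_real_, estimated = FALSE)
      } else {
        cp <- change_and_pp(v1, v2)
        rows[[length(rows) + 1]] <- data.frame(
          country = dn[[2]][jj], quantity = qt, year1 = year1,
          year2 = year2, change = cp$summary$mean,
          lower = cp$summary$lower, upper = cp$summary$upper,
          sd = cp$summary$sd, pp_increase = cp$pp_increase,
          pp_decrease = cp$pp_decrease, estimated = TRUE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Write report tables and run metadata
#'
#' Writes each table as a tidy CSV plus a JSON metadata file (seed, spec
#' summary, draw counts). Tables round-trip through `read.csv`.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param meta named list of metadata to record.
#' @return named character vector of written file paths.
#' @export
write_reports <- function(tables, dir, meta = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE, na = "NE")
    paths[nm] <- p
  }
  mp <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  paths["metadata"] <- mp
  paths
}

#' @rdname write_reports
#' @param path a CSV written by `write_reports()`.
#' @export
read_report <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NE",
                  colClasses = NA)
}
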