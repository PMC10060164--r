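#' Centred urbanicity indicator
#'
#' Maps a stratum label and urban fraction to the centred covariate
#' `I = -1 + 2 * X_urb`, where `X_urb` is 1 for urban-only observations, 0
#' for rural-only ones, and the country-year urban population share for
#' mixed (unstratified) observations. The indicator multiplies the
#' urban-rural offset `p + q*t + r*z + d`, so a mixed observation is modelled
#' as the known-fraction weighted sum of the urban and rural stratum means.
#'
#' @param stratum `"urban"`, `"rural"` or `"mixed"` (vectorized).
#' @param urban_fraction urban population share in `[0, 1]`; required for
#'   `"mixed"`, must equal 1 for `"urban"` and 0 for `"rural"` if supplied.
#' @return numeric in `[-1, 1]`.
#' @examples
#' urbanicity_indicator("mixed", 0.75)  # 0.5
#' @export
urbanicity_indicator <- function(stratum, urban_fraction = NULL) {
  stratum <- match_stratum(stratum)
  n <- length(stratum)
  if (is.null(urban_fraction)) urban_fraction <- rep(NA_real_, n)
  urban_fraction <- rep_len(as.numeric(urban_fraction), n)
  f <- ifelse(stratum == "urban", 1,
       ifelse(stratum == "rural", 0, urban_fraction))
  if (anyNA(f[stratum == "mixed"]))
    stop("mixed observations require an urban_fraction")
  if (any(!is.na(urban_fraction) & stratum == "urban" & urban_fraction != 1) ||
      any(!is.na(urban_fraction) & stratum == "rural" & urban_fraction != 0))
    stop("urban_fraction inconsistent with stratum (urban => 1, rural => 0)")
  if (any(f < 0 | f > 1)) stop("urban_fraction must lie in [0, 1]")
  -1 + 2 * f
}

match_stratum <- function(stratum) {
  ok <- c("urban", "rural", "mixed")
  stratum <- as.character(stratum)
  if (!all(stratum %in% ok))
    stop("stratum must be one of ", paste(ok, collapse = ", "))
  stratum
}

#' Coverage design row
#'
#' The four-column fixed-effect design multiplying `beta1..beta4`:
#' indicators for subnational and community coverage and their interactions
#' with centred time. National studies are the reference level (all zeros).
#'
#' @param coverage `"national"`, `"subnational"` or `"community"`
#'   (vectorized).
#' @param t centred time (years from the grid midpoint), recycled.
#' @return numeric matrix with columns
#'   `(subnational, subnational_t, community, community_t)`; a vector input
#'   of length 1 yields a 1-row matrix.
#' @export
coverage_design <- function(coverage, t) {
  ok <- c("national", "subnational", "community")
  coverage <- as.character(coverage)
  if (!all(coverage %in% ok))
    stop("coverage must be one of ", paste(ok, collapse = ", "))
  n <- max(length(coverage), length(t))
  coverage <- rep_len(coverage, n)
  t <- rep_len(as.numeric(t), n)
  sub <- as.numeric(coverage == "subnational")
  com <- as.numeric(coverage == "community")
  cbind(subnational = sub, subnational_t = sub * t,
        community = com, community_t = com * t)
}

#' Model specification
#'
#' Frozen configuration shared by the synthetic-data generator, the fitting
#' function and prediction: outcome and sex (which fix the spline knots and
#' the timescale), the model time grid, the age grid, centring constants and
#' the truncation bound on the log RW2 precisions. For BMI the timescale is
#' the observation year; for height it is the birth cohort, so the time grid
#' is a grid of birth years.
#'
#' @param outcome `"height"` or `"bmi"`.
#' @param sex `"female"` or `"male"`.
#' @param years integer vector of consecutive model time points (observation
#'   years for BMI, birth cohorts for height); length at least 4.
#' @param ages integer ages modelled, a subset of 5:19.
#' @param z_center age centring constant (years).
#' @param loglambda_max truncation bound for each log RW2 precision.
#' @return object of class `gmr_spec`.
#' @export
gmr_spec <- function(outcome = c("height", "bmi"),
                     sex = c("female", "male"),
                     years = 1990:2020, ages = 5:19,
                     z_center = 12, loglambda_max = 20) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  years <- as.integer(years)
  ages <- as.integer(ages)
  if (length(years) < 4L || any(diff(years) != 1L))
    stop("years must be >= 4 consecutive integers")
  if (!all(ages %in% 5:19)) stop("ages must be a subset of 5:19")
  structure(list(
    outcome = outcome, sex = sex,
    years = years, ages = ages,
    timescale = if (outcome == "bmi") "observation" else "cohort",
    t_center = mean(years), z_center = z_center,
    knots = spline_knots(sex, outcome),
    loglambda_max = loglambda_max
  ), class = "gmr_spec")
}

#' @export
print.gmr_spec <- function(x, ...) {
  cat("Model specification (gmr_spec)\n")
  cat("  outcome:  ", x$outcome, " (", x$sex, "), timescale: ", x$timescale,
      "\n", sep = "")
  cat("  time grid:", min(x$years), "-", max(x$years),
      " (T =", length(x$years), ", centred at", x$t_center, ")\n")
  cat("  ages:     ", min(x$ages), "-", max(x$ages),
      " (centred at", x$z_center, ")\n")
  cat("  knots:    ", paste(x$knots, collapse = ", "), "\n")
  cat("  log-lambda bound:", x$loglambda_max, "\n")
  invisible(x)
}

#' Read or write a model specification as YAML
#'
#' @param spec a `gmr_spec`.
#' @param path file path.
#' @return `read_spec()` returns a `gmr_spec`; `write_spec()` returns `path`
#'   invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "gmr_spec"))
  yaml::write_yaml(list(outcome = spec$outcome, sex = spec$sex,
                        years = as.integer(range(spec$years)),
                        ages = as.integer(spec$ages),
                        z_center = spec$z_center,
                        loglambda_max = spec$loglambda_max), path)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  y <- yaml::read_yaml(path)
  gmr_spec(outcome = y$outcome, sex = y$sex,
           years = y$years[1]:y$years[2], ages = y$ages,
           z_center = y$z_center, loglambda_max = y$loglambda_max)
}

#' Geographic hierarchy
#'
#' Indexes countries into regions and regions into super-regions; every
#' hierarchical prior in the model shares this structure. The fitting
#' function requires at least two children at every level so that the flat
#' priors on the hierarchical standard deviations yield proper posteriors.
#'
#' @param table data frame with character columns `country`, `region`,
#'   `super_region`, one row per country; each region must belong to exactly
#'   one super-region.
#' @return object of class `gmr_hierarchy`: the table plus integer index
#'   maps `j2k` (country to region) and `k2l` (region to super-region) and
#'   counts `J`, `K`, `L`.
#' @export
gmr_hierarchy <- function(table) {
  need <- c("country", "region", "super_region")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("hierarchy table needs columns country, region, super_region")
  if (anyDuplicated(table$country)) stop("duplicate countries in hierarchy")
  countries <- as.character(table$country)
  regions <- unique(as.character(table$region))
  sregs <- unique(as.character(table$super_region))
  j2k <- match(table$region, regions)
  reg_sreg <- tapply(as.character(table$super_region), table$region,
                     function(s) unique(s))
  if (any(lengths(reg_sreg) != 1L))
    stop("each region must belong to exactly one super-region")
  k2l <- match(unlist(reg_sreg)[regions], sregs)
  structure(list(table = table, countries = countries, regions = regions,
                 super_regions = sregs, j2k = j2k, k2l = k2l,
                 J = length(countries), K = length(regions),
                 L = length(sregs)),
            class = "gmr_hierarchy")
}

#' @export
print.gmr_hierarchy <- function(x, ...) {
  cat("Geographic hierarchy:", x$J, "countries /", x$K, "regions /",
      x$L, "super-regions\n")
  invisible(x)
}
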