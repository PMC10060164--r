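#' Assemble model-ready observations from study records
#'
#' Flattens a list of study records into the observation table the sampler
#' consumes: one row per study x age x stratum summary, carrying the model
#' time index (observation year for BMI, birth cohort for height; assigned
#' via [assign_time_index()] if not already present), centred time and age
#' covariates, the centred urbanicity indicator, the spline and coverage
#' design matrices, and the sampling variance `se^2` that enters the
#' likelihood as `SD^2/n`.
#'
#' @param records list of [gmr_study()] records (one sex).
#' @param hierarchy a [gmr_hierarchy()] covering every study's country.
#' @param spec a [gmr_spec()].
#' @return object of class `gmr_data`: list with `obs` (data frame), `B`
#'   (spline design), `Xcov` (coverage design), `studies` (study-level
#'   table), `basis`, `hierarchy`, `spec`.
#' @export
gmr_data <- function(records, hierarchy, spec) {
  stopifnot(inherits(hierarchy, "gmr_hierarchy"), inherits(spec, "gmr_spec"))
  if (length(records) == 0L) stop("no study records supplied")
  rows <- vector("list", length(records))
  stud <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    stopifnot(inherits(r, "gmr_study"))
    if (r$sex != spec$sex)
      stop("study ", r$study_id, " has sex ", r$sex, ", spec is ", spec$sex)
    if (is.null(r$summaries$time_index) || anyNA(r$summaries$time_index))
      r <- assign_time_index(r, spec$outcome)
    j <- match(r$country, hierarchy$countries)
    if (is.na(j)) stop("country ", r$country, " not in hierarchy")
    s <- r$summaries
    ti <- match(s$time_index, spec$years)
    if (anyNA(ti))
      stop("study ", r$study_id, ": time index outside the model grid (",
           min(spec$years), "-", max(spec$years), ")")
    I <- urbanicity_indicator(r$stratum, r$urban_fraction)
    rows[[i]] <- data.frame(
      study = i, j = j, k = hierarchy$j2k[j],
      l = hierarchy$k2l[hierarchy$j2k[j]],
      t = ti, tc = s$time_index - spec$t_center,
      z = s$age, zc = s$age - spec$z_center,
      I = I, y = s$mean, var0 = s$se^2)
    stud[[i]] <- data.frame(study = i, study_id = r$study_id, j = j,
                            coverage = r$coverage, I = I)
  }
  obs <- do.call(rbind, rows)
  studies <- do.call(rbind, stud)
  basis <- build_spline_basis(spec$ages, spec$sex, spec$outcome,
                              spec$z_center)
  B <- basis_matrix(basis, obs$z)
  Xcov <- coverage_design(studies$coverage[obs$study], obs$tc)
  structure(list(obs = obs, B = B, Xcov = Xcov, studies = studies,
                 basis = basis, hierarchy = hierarchy, spec = spec),
            class = "gmr_data")
}

#' @export
print.gmr_data <- function(x, ...) {
  cat("Model data:", nrow(x$obs), "observations from",
      nrow(x$studies), "studies in",
      length(unique(x$obs$j)), "of", x$hierarchy$J, "countries\n")
  tb <- table(x$studies$coverage)
  cat("  coverage:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  tb2 <- table(ifelse(x$studies$I == 1, "urban",
                      ifelse(x$studies$I == -1, "rural", "mixed")))
  cat("  strata:  ", paste(names(tb2), tb2, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Observation log likelihood
#'
#' Sum over observations of the normal log density with the supplied fitted
#' means and variance `se^2 + tau^2` (the sampling variance `SD^2/n` plus
#' the residual age-by-study component).
#'
#' @param data a `gmr_data`.
#' @param mu fitted mean per observation.
#' @param tau residual age-by-study SD (nonnegative).
#' @return scalar log likelihood.
#' @export
gmr_loglik <- function(data, mu, tau) {
  stopifnot(inherits(data, "gmr_data"), length(mu) == nrow(data$obs))
  v <- data$obs$var0 + tau^2
  if (anyNA(v) || any(v <= 0))
    stop("non-positive observation variance")
  sum(stats::dnorm(data$obs$y, mu, sqrt(v), log = TRUE))
}
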