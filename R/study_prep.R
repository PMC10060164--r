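#' Apply participant-level exclusion rules
#'
#' Removes implausible and ineligible participant rows before
#' summarization, using fixed age-banded plausibility windows:
#' height below 60 or above 180 cm for ages under 10, below 80 or above
#' 200 cm for ages 10-14, below 100 or above 250 cm for ages 15 and over;
#' weight outside 5-90, 8-150 and 12-300 kg for the same bands; BMI outside
#' 6-40, 8-60 and 10-80 kg/m^2. Rows whose reported age is below 18 years
#' but not a whole year are removed (growth is strongly nonlinear at these
#' ages, so fractional-age grouping is unreliable), and for the BMI outcome
#' females pregnant at measurement are removed (height is retained for
#' them). Each removed row is attributed to the first rule it violates, in
#' the order age-format, pregnancy, height, weight, BMI, so the report
#' counts reconcile exactly with the input.
#'
#' @param rows data frame of participant rows with (some of) the columns
#'   `age`, `sex`, `height`, `weight`, `bmi`, `pregnant`.
#' @param outcome `"height"` or `"bmi"`.
#' @return list with `rows` (retained data frame) and `report` (class
#'   `gmr_filter_report`: per-rule removal counts plus `retained` and
#'   `input`).
#' @export
filter_participants <- function(rows, outcome = c("height", "bmi")) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(rows))
  n <- nrow(rows)
  counts <- c(age_format = 0L, pregnancy = 0L, height = 0L,
              weight = 0L, bmi = 0L)
  if (n == 0L) {
    rep <- structure(as.list(c(counts, retained = 0L, input = 0L)),
                     class = "gmr_filter_report")
    return(list(rows = rows, report = rep))
  }
  age <- rows$age
  removed <- rep(NA_character_, n)

  bad_age <- !is.na(age) & age < 18 & (age %% 1 != 0)
  removed[is.na(removed) & bad_age] <- "age_format"

  if (outcome == "bmi" && !is.null(rows$pregnant)) {
    preg <- !is.na(rows$pregnant) & rows$pregnant
    if (!is.null(rows$sex)) preg <- preg & rows$sex == "female"
    removed[is.na(removed) & preg] <- "pregnancy"
  }

  band <- findInterval(age, c(-Inf, 10, 15))  # 1: <10, 2: 10-14, 3: >=15
  out_of <- function(x, lo, hi) {
    !is.na(x) & (x < lo[band] | x > hi[band])
  }
  if (!is.null(rows$height)) {
    bad <- out_of(rows$height, c(60, 80, 100), c(180, 200, 250))
    removed[is.na(removed) & bad] <- "height"
  }
  if (!is.null(rows$weight)) {
    bad <- out_of(rows$weight, c(5, 8, 12), c(90, 150, 300))
    removed[is.na(removed) & bad] <- "weight"
  }
  if (!is.null(rows$bmi)) {
    bad <- out_of(rows$bmi, c(6, 8, 10), c(40, 60, 80))
    removed[is.na(removed) & bad] <- "bmi"
  }

  tab <- table(factor(removed, levels = names(counts)))
  counts[names(tab)] <- as.integer(tab)
  keep <- is.na(removed)
  rep <- structure(as.list(c(counts, retained = sum(keep), input = n)),
                   class = "gmr_filter_report")
  list(rows = rows[keep, , drop = FALSE], report = rep)
}

#' @export
print.gmr_filter_report <- function(x, ...) {
  cat("Participant filter report:", x$input, "rows in,", x$retained,
      "retained\n")
  for (r in c("age_format", "pregnancy", "height", "weight", "bmi"))
    if (x[[r]] > 0) cat("  removed (", r, "): ", x[[r]], "\n", sep = "")
  invisible(x)
}

#' Write a filter report as JSON
#' @param report a `gmr_filter_report`.
#' @param path output file.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "gmr_filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Survey-design-aware age-group summaries
#'
#' Computes, per single year of age, the weighted mean and its standard
#' error. Under simple random sampling the SE is `sd/sqrt(n)`. Under a
#' stratified cluster design the SE is the Taylor-series linearization of
#' the ratio (Hajek) mean: with per-row weights \eqn{w_i}, weighted mean
#' \eqn{\bar y}, and cluster totals
#' \eqn{z_{hc} = \sum_{i \in hc} w_i (y_i - \bar y)}, the variance is
#' \eqn{\sum_h \frac{n_h}{n_h - 1} \sum_c (z_{hc} - \bar z_h)^2 / W^2}
#' where \eqn{n_h} is the number of clusters in stratum \eqn{h} and
#' \eqn{W = \sum_i w_i}. With one stratum, singleton clusters and equal
#' weights this reduces exactly to `sd/sqrt(n)`. Ages whose design leaves a
#' stratum with a single cluster have no defined SE and are dropped with a
#' warning.
#'
#' @param rows data frame with `age`, the measurement column, and for
#'   `design = "stratified_cluster"` also `sample_weight`, `stratum_id`,
#'   `cluster_id`.
#' @param variable `"height"` or `"bmi"`.
#' @param design `"srs"` or `"stratified_cluster"`.
#' @return data frame with one row per age: `age`, `mean`, `sd`, `n`, `se`.
#' @export
survey_weighted_summary <- function(rows, variable = c("height", "bmi"),
                                    design = c("srs", "stratified_cluster")) {
  variable <- match.arg(variable)
  design <- match.arg(design)
  stopifnot(is.data.frame(rows), variable %in% names(rows))
  y_all <- rows[[variable]]
  keep <- !is.na(y_all) & !is.na(rows$age)
  rows <- rows[keep, , drop = FALSE]
  ages <- floor(rows$age)
  out <- lapply(sort(unique(ages)), function(a) {
    sub <- rows[ages == a, , drop = FALSE]
    y <- sub[[variable]]
    n <- length(y)
    if (design == "srs") {
      m <- mean(y)
      s <- stats::sd(y)
      if (n == 1L) s <- 0
      return(data.frame(age = a, mean = m, sd = s, n = n,
                        se = if (n > 1) s / sqrt(n) else NA_real_))
    }
    w <- sub$sample_weight
    if (is.null(w) || is.null(sub$stratum_id) || is.null(sub$cluster_id))
      stop("stratified_cluster design needs sample_weight, stratum_id, cluster_id")
    if (any(w < 0)) stop("sample weights must be nonnegative")
    W <- sum(w)
    m <- sum(w * y) / W
    # design-weighted sd with the srs-consistent n/(n-1) correction
    s <- if (n > 1) sqrt(sum(w * (y - m)^2) / W * n / (n - 1)) else 0
    strata <- split(seq_len(n), sub$stratum_id)
    v <- 0
    for (idx in strata) {
      cl <- split(idx, sub$cluster_id[idx])
      nh <- length(cl)
      if (nh < 2L) return(NULL)  # singleton cluster: SE undefined
      z <- vapply(cl, function(ii) sum(w[ii] * (y[ii] - m)), numeric(1))
      v <- v + nh / (nh - 1) * sum((z - mean(z))^2)
    }
    data.frame(age = a, mean = m, sd = s, n = n, se = sqrt(v) / W)
  })
  dropped <- vapply(out, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " age group(s) dropped: a stratum had a single ",
            "cluster, so the linearized SE is undefined")
  do.call(rbind, out[!dropped])
}

#' Assign model time indices (observation year or birth cohort)
#'
#' BMI observations are indexed by the year of measurement. Height
#' observations are indexed by birth cohort (measurement year minus age),
#' so that trends track successive cohorts; participants aged 20-30 years
#' contribute at age 19 of their own birth cohort, since attained adult
#' height at those ages is at least the height at age 19. Height rows above
#' age 30 are rejected (shrinkage with age would bias the cohort's attained
#' height).
#'
#' @param record a `gmr_study` (see [gmr_study()]).
#' @param outcome `"height"` or `"bmi"`.
#' @return the record with a `time_index` column added to its `summaries`
#'   (and ages 20-30 recoded to 19 for height).
#' @export
assign_time_index <- function(record, outcome = c("height", "bmi")) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(record, "gmr_study"))
  s <- record$summaries
  yr <- record$measurement_year
  if (outcome == "bmi") {
    if (any(s$age > 19)) stop("BMI summaries must be for ages 5-19")
    s$time_index <- rep(as.integer(yr), nrow(s))
    record$time_index <- as.integer(yr)
  } else {
    if (any(s$age > 30)) stop("height rows with age > 30 are not usable")
    s$time_index <- as.integer(yr - s$age)
    s$age[s$age >= 20] <- 19
    if (anyDuplicated(paste(s$age, s$time_index)))
      stop("duplicate (age, cohort) rows after cohort assignment")
    record$time_index <- NA_integer_
  }
  record$summaries <- s
  record
}

#' Convert BMI category prevalences to mean BMI
#'
#' Applies a user-supplied linear conversion
#' `mean = alpha + sum_m beta_m * g_m(prev_m)` with declared transforms, for
#' study rows that report prevalence of BMI categories (for example
#' BMI >= 30) instead of the mean. No default coefficient set ships with the
#' package: the validated regression coefficients are external inputs and
#' must be provided explicitly.
#'
#' @param prevalences named numeric vector of prevalence metrics (proportions).
#' @param coefficients list with `alpha` (scalar), `terms` (list of
#'   `list(name=, beta=, transform=)`, `transform` a function or the name of
#'   one, defaulting to identity), and optionally `resid_var` (residual
#'   variance of the conversion regression) — see Details.
#' @param prev_se optional named numeric vector of standard errors of the
#'   prevalences, combined with `resid_var` by the delta method.
#' @return list with `mean` and `se` (NA if no variance information given).
#' @export
convert_prevalence_to_mean <- function(prevalences, coefficients,
                                       prev_se = NULL) {
  if (missing(coefficients) || is.null(coefficients))
    stop("no conversion coefficients supplied; provide the externally ",
         "estimated regression coefficients (alpha, terms, resid_var) — ",
         "there is no default")
  stopifnot(is.list(coefficients), !is.null(coefficients$terms))
  if (length(prevalences) == 0L) stop("at least one prevalence metric needed")
  est <- coefficients$alpha %||% 0
  var <- coefficients$resid_var %||% 0
  for (tm in coefficients$terms) {
    if (!tm$name %in% names(prevalences))
      stop("prevalence metric '", tm$name, "' required by the coefficient ",
           "set is missing")
    g <- tm$transform %||% identity
    if (is.character(g)) g <- match.fun(g)
    p <- prevalences[[tm$name]]
    est <- est + tm$beta * g(p)
    if (!is.null(prev_se) && tm$name %in% names(prev_se)) {
      h <- 1e-6 * max(1, abs(p))
      grad <- (g(p + h) - g(p - h)) / (2 * h)
      var <- var + (tm$beta * grad * prev_se[[tm$name]])^2
    }
  }
  has_var <- !is.null(coefficients$resid_var) || !is.null(prev_se)
  list(mean = est, se = if (has_var) sqrt(var) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study eligibility by sampling frame
#'
#' School-based studies are kept only where school enrolment for the
#' age-sex group is at least 70%; insurance-frame studies only where at
#' least 80% of the population is insured. Probability samples of the
#' general population need no frame metadata. Missing required metadata
#' drops the record with a logged reason.
#'
#' @param frame sampling frame: `"household"`, `"school"`, `"insurance"`,
#'   or `"primary_care"`.
#' @param enrolment school enrolment share in `[0,1]` (school frames).
#' @param insured_share insured population share in `[0,1]` (insurance
#'   frames).
#' @return list with `keep` (logical) and `reason` (character).
#' @export
eligibility_flags <- function(frame, enrolment = NA_real_,
                              insured_share = NA_real_) {
  frame <- match.arg(frame, c("household", "school", "insurance",
                              "primary_care"))
  if (frame == "school") {
    if (is.na(enrolment))
      return(list(keep = FALSE, reason = "school frame without enrolment metadata"))
    if (enrolment >= 0.70) return(list(keep = TRUE, reason = "enrolment >= 70%"))
    return(list(keep = FALSE, reason = "school enrolment below 70%"))
  }
  if (frame == "insurance") {
    if (is.na(insured_share))
      return(list(keep = FALSE, reason = "insurance frame without coverage metadata"))
    if (insured_share >= 0.80)
      return(list(keep = TRUE, reason = "insured share >= 80%"))
    return(list(keep = FALSE, reason = "insured share below 80%"))
  }
  list(keep = TRUE, reason = "population-based frame")
}

#' Construct a study record
#'
#' One study's stratified summary statistics: metadata plus one row per
#' single year of age with mean, sample SD, n and SE. If `se` is missing it
#' is computed as `sd/sqrt(n)`; if only `se` is given, `sd = se * sqrt(n)`
#' is back-filled (the likelihood uses the sampling variance `se^2` only).
#'
#' @param study_id character identifier.
#' @param country country name (must appear in the hierarchy at fit time).
#' @param sex `"female"` or `"male"`.
#' @param measurement_year calendar year of data collection.
#' @param coverage `"national"`, `"subnational"` or `"community"`.
#' @param stratum `"urban"`, `"rural"` or `"mixed"`.
#' @param urban_fraction urban population share (required for mixed;
#'   forced to 1/0 for urban/rural).
#' @param summaries data frame with columns `age`, `mean`, and `sd` + `n`
#'   and/or `se` (plus optionally `time_index`).
#' @return object of class `gmr_study`.
#' @export
gmr_study <- function(study_id, country, sex, measurement_year, coverage,
                      stratum, urban_fraction = NA_real_, summaries) {
  stratum <- match_stratum(stratum)
  if (stratum == "urban") urban_fraction <- 1
  if (stratum == "rural") urban_fraction <- 0
  if (stratum == "mixed" &&
      (is.na(urban_fraction) || urban_fraction < 0 || urban_fraction > 1))
    stop("mixed studies need urban_fraction in [0, 1]")
  stopifnot(is.data.frame(summaries),
            all(c("age", "mean") %in% names(summaries)))
  if (anyDuplicated(summaries$age))
    stop("ages within one study record must be distinct")
  if (is.null(summaries$n)) summaries$n <- NA_integer_
  if (is.null(summaries$sd)) summaries$sd <- NA_real_
  if (is.null(summaries$se)) summaries$se <- NA_real_
  miss_se <- is.na(summaries$se)
  summaries$se[miss_se] <- summaries$sd[miss_se] / sqrt(summaries$n[miss_se])
  miss_sd <- is.na(summaries$sd)
  summaries$sd[miss_sd] <- summaries$se[miss_sd] * sqrt(summaries$n[miss_sd])
  if (anyNA(summaries$se))
    stop("each summary row needs se, or sd and n")
  if (any(summaries$n < 1, na.rm = TRUE) || any(summaries$sd < 0, na.rm = TRUE))
    stop("n must be >= 1 and sd >= 0")
  structure(list(study_id = as.character(study_id), country = country,
                 sex = sex, measurement_year = as.integer(measurement_year),
                 time_index = NA_integer_,
                 coverage = match.arg(coverage,
                                      c("national", "subnational", "community")),
                 stratum = stratum,
                 urban_fraction = as.numeric(urban_fraction),
                 summaries = summaries),
            class = "gmr_study")
}

#' Read and write study summary records as tidy CSV
#'
#' One row per study x age: columns `study_id, country, sex,
#' measurement_year, coverage, stratum, urban_fraction, age, mean, sd, n,
#' se` (plus `time_index` when assigned). Round-trippable.
#'
#' @param records list of `gmr_study` objects.
#' @param path CSV file path.
#' @return `read_studies()` returns a list of `gmr_study`; `write_studies()`
#'   returns `path` invisibly.
#' @export
write_studies <- function(records, path) {
  rows <- lapply(records, function(r) {
    s <- r$summaries
    data.frame(study_id = r$study_id, country = r$country, sex = r$sex,
               measurement_year = r$measurement_year, coverage = r$coverage,
               stratum = r$stratum, urban_fraction = r$urban_fraction,
               age = s$age, mean = s$mean, sd = s$sd, n = s$n, se = s$se,
               time_index = if (!is.null(s$time_index)) s$time_index
                            else NA_integer_)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_studies
#' @export
read_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$study_id), function(d) {
    sm <- d[, c("age", "mean", "sd", "n", "se")]
    if (!all(is.na(d$time_index))) sm$time_index <- d$time_index
    gmr_study(d$study_id[1], d$country[1], d$sex[1], d$measurement_year[1],
              d$coverage[1], d$stratum[1], d$urban_fraction[1], sm)
  })
  unname(out[unique(df$study_id)])
}

#' Flag potential duplicate studies
#'
#' Potential duplicates share (country, measurement year, coverage, total
#' n). They are reported with a warning, never deleted automatically:
#' resolving true duplicates needs source-level knowledge.
#'
#' @param records list of `gmr_study`.
#' @return character vector of study_ids flagged (possibly empty).
#' @export
flag_duplicates <- function(records) {
  key <- vapply(records, function(r)
    paste(r$country, r$measurement_year, r$coverage,
          sum(r$summaries$n), sep = "|"), character(1))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  ids <- vapply(records[dup], `[[`, character(1), "study_id")
  if (length(ids))
    warning("possible duplicate studies (same country/year/coverage/n): ",
            paste(ids, collapse = ", "))
  ids
}
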