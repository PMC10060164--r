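# Deterministic child seeds so regenerating one layer (world, studies,
# sampler chains) never perturbs another. Exact in double precision and
# always below 2^31.
child_seed <- function(seed, purpose) {
  offset <- switch(purpose, world = 1, studies = 2, sampler = 3,
                   stop("unknown seed purpose"))
  (as.numeric(seed) * 1000003 + offset * 97003) %% 2147483647
}

#' Specification of a synthetic ground-truth world
#'
#' Defines the scale and every variance component of a synthetic study
#' database with exactly the statistical structure the model assumes:
#' nested country/region/super-region effects, linear plus RW2-smooth
#' nonlinear time trends, spline-shaped age curves with a sex-specific
#' growth spurt, urban-rural offsets varying by country, time and age,
#' coverage-dependent study offsets and random effects, and residual
#' age-by-study variability. The default scale (3 super-regions x 2
#' regions x 3 countries = 18 countries, 31 years, ages 5-19) is the
#' smallest at which every hierarchy level has several children, as the
#' flat-on-SD hierarchical priors require for proper posteriors.
#'
#' @param n_super super-regions; `n_region` regions per super-region;
#'   `n_country` countries per region.
#' @param n_region,n_country see `n_super`.
#' @param outcome,sex,years,ages as in [gmr_spec()].
#' @param sd_a,sd_b SDs of country/region/super-region intercept and slope
#'   deviations (length 3, order c, r, s); units cm (or kg/m^2) and
#'   cm/year.
#' @param lambda RW2 precisions per level, named c, r, s, g; must be
#'   increasing (countries wiggle more than the globe).
#' @param spline_sd SDs of country/region/super-region spline-coefficient
#'   deviations (on the unit-scaled basis; length 3).
#' @param beta coverage fixed effects (subnational, subnational x t,
#'   community, community x t).
#' @param v_sd study random-effect SDs by coverage (national < subnational
#'   < community).
#' @param d_sd SD of study-level urban-offset effects.
#' @param tau residual age-by-study SD.
#' @param p_g,q_g,r_g global urban-rural offset intercept, time slope and
#'   age slope (half the urban-minus-rural gap at the centring point).
#' @param sd_p,sd_q,sd_r hierarchical SDs of the urban-offset components
#'   (length 3, order c, r, s).
#' @param global_slope global linear time trend (units per year).
#' @return object of class `gmr_world_spec`.
#' @export
gmr_world_spec <- function(n_super = 3, n_region = 2, n_country = 3,
                           outcome = "height", sex = "female",
                           years = 1990:2020, ages = 5:19,
                           sd_a = c(2, 1.5, 1), sd_b = c(0.05, 0.03, 0.02),
                           lambda = c(c = 10, r = 30, s = 100, g = 300),
                           spline_sd = c(0.8, 0.5, 0.3),
                           beta = c(-0.5, 0.01, -1.0, 0.02),
                           v_sd = c(national = 0.2, subnational = 0.5,
                                    community = 1.0),
                           d_sd = 0.2, tau = 0.3,
                           p_g = 1, q_g = 0.01, r_g = 0.05,
                           sd_p = c(0.6, 0.4, 0.25),
                           sd_q = c(0.015, 0.01, 0.006),
                           sd_r = c(0.03, 0.02, 0.012),
                           global_slope = if (outcome == "height") 0.05
                                          else 0.03) {
  stopifnot(n_super >= 1, n_region >= 1, n_country >= 1)
  if (!(v_sd[1] < v_sd[2] && v_sd[2] < v_sd[3]))
    stop("study-effect SDs must satisfy national < subnational < community")
  if (!all(diff(unname(lambda[c("c", "r", "s", "g")])) > 0))
    stop("RW2 precisions must satisfy lambda_c < lambda_r < lambda_s < lambda_g")
  sds <- c(sd_a, sd_b, spline_sd, v_sd, d_sd, tau, sd_p, sd_q, sd_r)
  if (any(sds < 0)) stop("all SDs must be nonnegative")
  structure(list(n_super = n_super, n_region = n_region,
                 n_country = n_country,
                 outcome = outcome, sex = sex, years = as.integer(years),
                 ages = as.integer(ages),
                 sd_a = sd_a, sd_b = sd_b, lambda = lambda,
                 spline_sd = spline_sd, beta = beta, v_sd = v_sd,
                 d_sd = d_sd, tau = tau,
                 p_g = p_g, q_g = q_g, r_g = r_g,
                 sd_p = sd_p, sd_q = sd_q, sd_r = sd_r,
                 global_slope = global_slope),
            class = "gmr_world_spec")
}

#' Read or write a world specification as YAML
#' @param wspec a `gmr_world_spec`; `path` a file path.
#' @param path file path.
#' @export
write_world_spec <- function(wspec, path) {
  stopifnot(inherits(wspec, "gmr_world_spec"))
  # named vectors become YAML maps so names survive the round trip
  out <- lapply(unclass(wspec), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_world_spec
#' @export
read_world_spec <- function(path) {
  y <- yaml::read_yaml(path)
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  y$years <- as.integer(y$years)
  y$ages <- as.integer(y$ages)
  do.call(gmr_world_spec, y)
}

# Stylized mean age curve used for the default global spline coefficients:
# steady childhood growth that tails off after a pubertal spurt whose peak
# comes about two years earlier in girls than boys. Heights in cm, BMI in
# kg/m^2.
default_age_curve <- function(outcome, sex) {
  if (outcome == "bmi")
    return(function(z) 15.3 + 0.32 * (z - 5) + 0.012 * (z - 5)^2)
  spurt <- if (sex == "female") 11.5 else 13.5
  h5 <- if (sex == "female") 110 else 111
  function(z) {
    vel <- function(a) 5.2 / (1 + exp((a - (spurt + 1.5)) / 0.9)) +
      3.3 * exp(-(a - spurt)^2 / 2)
    vapply(z, function(zz)
      h5 + stats::integrate(vel, 5, zz)$value, numeric(1))
  }
}

#' Generate a ground-truth world
#'
#' Draws every hierarchical component of the model from its prior at the
#' SDs/precisions fixed in the world specification: country, region,
#' super-region and global intercepts, slopes and urban-offset terms from
#' normals; each nonlinear time component from the RW2 prior at its level's
#' precision (sampled in the row space of the penalty, which enforces the
#' zero-mean/zero-slope constraints exactly); spline coefficients around a
#' stylized growth curve. Also lays down per-country urban population
#' fraction trajectories used for mixed-stratum studies.
#'
#' @param wspec a [gmr_world_spec()].
#' @param seed integer seed; the world stream is independent of the study
#'   and sampler streams derived from the same root seed.
#' @return object of class `gmr_world`: the hierarchy, model spec, all
#'   level components, per-country totals, the spline basis and truth
#'   oracle inputs.
#' @export
generate_world <- function(wspec, seed = 1) {
  stopifnot(inherits(wspec, "gmr_world_spec"))
  J <- wspec$n_super * wspec$n_region * wspec$n_country
  if (J < 1) stop("degenerate world: no countries")
  set.seed(child_seed(seed, "world"))

  K <- wspec$n_super * wspec$n_region
  L <- wspec$n_super
  tab <- data.frame(
    country = sprintf("C%02d", seq_len(J)),
    region = rep(sprintf("R%02d", seq_len(K)), each = wspec$n_country),
    super_region = rep(sprintf("S%d", seq_len(L)),
                       each = wspec$n_region * wspec$n_country))
  hier <- gmr_hierarchy(tab)
  spec <- gmr_spec(wspec$outcome, wspec$sex, wspec$years, wspec$ages)
  T_len <- length(spec$years)
  pen <- build_penalty(T_len)
  pe <- penalty_eigen(pen)
  basis <- build_spline_basis(spec$ages, spec$sex, spec$outcome,
                              spec$z_center)
  Kc <- ncol(basis$B)

  # global age curve: least squares of the stylized curve on the basis;
  # the fitted intercept becomes the global level a^g
  curve <- default_age_curve(wspec$outcome, wspec$sex)
  zs <- seq(5, 19, by = 0.5)
  fit <- stats::lm.fit(cbind(1, basis_matrix(basis, zs)), curve(zs))
  a_g <- unname(fit$coefficients[1])
  psi <- unname(fit$coefficients[-1])

  lev3 <- function(sds, p = 1) list(
    c = matrix(stats::rnorm(J * p, 0, sds[1]), J, p),
    r = matrix(stats::rnorm(K * p, 0, sds[2]), K, p),
    s = matrix(stats::rnorm(L * p, 0, sds[3]), L, p))
  a <- lev3(wspec$sd_a); b <- lev3(wspec$sd_b)
  p <- lev3(wspec$sd_p); q <- lev3(wspec$sd_q); r <- lev3(wspec$sd_r)
  spl <- list(c = matrix(0, J, Kc), r = matrix(0, K, Kc),
              s = matrix(0, L, Kc))
  for (kk in seq_len(Kc)) {
    spl$c[, kk] <- stats::rnorm(J, 0, wspec$spline_sd[1])
    spl$r[, kk] <- stats::rnorm(K, 0, wspec$spline_sd[2])
    spl$s[, kk] <- stats::rnorm(L, 0, wspec$spline_sd[3])
  }
  draw_u <- function(n, lam) {
    m <- matrix(0, n, T_len)
    for (i in seq_len(n)) m[i, ] <- rw2_prior_draw(pe, lam)
    m
  }
  u <- list(c = draw_u(J, wspec$lambda[["c"]]),
            r = draw_u(K, wspec$lambda[["r"]]),
            s = draw_u(L, wspec$lambda[["s"]]),
            g = drop(draw_u(1, wspec$lambda[["g"]])))

  j2k <- hier$j2k; k2l <- hier$k2l
  tot <- function(x, g) drop(x$c) + drop(x$r)[j2k] + drop(x$s)[k2l[j2k]] + g
  a_j <- tot(a, a_g)
  b_j <- tot(b, wspec$global_slope)
  p_j <- tot(p, wspec$p_g); q_j <- tot(q, wspec$q_g); r_j <- tot(r, wspec$r_g)
  gamma <- sweep(spl$c + spl$r[j2k, , drop = FALSE] +
                   spl$s[k2l[j2k], , drop = FALSE], 2, psi, "+")
  u_tot <- u$c + u$r[j2k, , drop = FALSE] + u$s[k2l[j2k], , drop = FALSE] +
    matrix(u$g, J, T_len, byrow = TRUE)

  # per-country urban population share: rising linear trajectories
  f0 <- stats::runif(J, 0.2, 0.55)
  f1 <- pmin(f0 + stats::runif(J, 0.1, 0.3), 0.9)
  urb <- t(vapply(seq_len(J), function(j)
    seq(f0[j], f1[j], length.out = T_len), numeric(T_len)))

  structure(list(
    wspec = wspec, spec = spec, hierarchy = hier, basis = basis,
    penalty = pen,
    levels = list(a = a, b = b, p = p, q = q, r = r, spline = spl, u = u,
                  a_g = a_g, b_g = wspec$global_slope, psi = psi,
                  p_g = wspec$p_g, q_g = wspec$q_g, r_g = wspec$r_g),
    a_j = a_j, b_j = b_j, p_j = p_j, q_j = q_j, r_j = r_j,
    gamma = gamma, u_tot = u_tot, urban_fraction = urb,
    beta = wspec$beta, v_sd = wspec$v_sd, d_sd = wspec$d_sd,
    tau = wspec$tau, seed = seed), class = "gmr_world")
}

#' @export
print.gmr_world <- function(x, ...) {
  h <- x$hierarchy
  cat("Synthetic ground-truth world:", h$J, "countries,", h$K, "regions,",
      h$L, "super-regions;", x$spec$outcome, "(", x$spec$sex, "),",
      length(x$spec$years), "time points, ages",
      paste(range(x$spec$ages), collapse = "-"), "\n")
  invisible(x)
}

#' Noise-free stratum mean from a world's truth oracle
#'
#' Evaluates the model's linear predictor at the true parameter values,
#' with all study-level terms (coverage offsets, study random effects) at
#' zero:
#' `a_j + b_j*t~ + u_{j,t} + gamma_j(z) + I * (p_j + q_j*t~ + r_j*z~)`,
#' where `I` is the centred urbanicity indicator (+1 urban, -1 rural,
#' `-1 + 2f` mixed). Arguments are recycled to a common length.
#'
#' @param world a `gmr_world`.
#' @param country country name or index.
#' @param t model time point (calendar year of the world grid).
#' @param age age in years.
#' @param stratum `"urban"`, `"rural"` or `"mixed"`.
#' @param f urban fraction for mixed (defaults to the world's country-year
#'   share).
#' @return numeric vector of true stratum means.
#' @export
truth_mean <- function(world, country, t, age, stratum = "mixed", f = NULL) {
  stopifnot(inherits(world, "gmr_world"))
  spec <- world$spec
  n <- max(length(country), length(t), length(age), length(stratum),
           if (is.null(f)) 0 else length(f))
  j <- if (is.numeric(country)) rep_len(as.integer(country), n)
       else match(rep_len(country, n), world$hierarchy$countries)
  if (anyNA(j)) stop("unknown country")
  t <- rep_len(t, n); age <- rep_len(age, n)
  stratum <- match_stratum(rep_len(stratum, n))
  ti <- match(t, spec$years)
  if (anyNA(ti)) stop("time point outside the world grid")
  zi <- match(age, spec$ages)
  if (anyNA(zi)) stop("age outside the world grid")
  if (is.null(f)) f <- world$urban_fraction[cbind(j, ti)]
  else f <- rep_len(f, n)
  I <- urbanicity_indicator(stratum, ifelse(stratum == "urban", 1,
                             ifelse(stratum == "rural", 0, f)))
  tc <- t - spec$t_center
  zc <- age - spec$z_center
  Bz <- basis_matrix(world$basis, age)
  base <- world$a_j[j] + world$b_j[j] * tc + world$u_tot[cbind(j, ti)] +
    rowSums(Bz * world$gamma[j, , drop = FALSE])
  base + I * (world$p_j[j] + world$q_j[j] * tc + world$r_j[j] * zc)
}

#' Generate a synthetic study database from a world
#'
#' Simulates study records with the model's full error structure: each
#' study draws a country, a time point, a coverage level and a stratum
#' (mixed studies use the country-year urban fraction); a study random
#' effect with coverage-dependent SD; a study-level urban-offset effect;
#' coverage fixed offsets for subnational/community studies; and per-age
#' observation noise with variance `sd^2/n + tau^2`. Studies are generated
#' directly on the model timescale (their `time_index` is the world time
#' point).
#'
#' @param world a `gmr_world`.
#' @param n_studies number of studies.
#' @param coverage_probs,stratum_probs named sampling probabilities for
#'   coverage levels and strata.
#' @param ages ages measured per study (default: all world ages).
#' @param n_per_age sample size per age group.
#' @param sd_scale typical within-age sample SD (defaults: 6.5 cm height,
#'   3 kg/m^2 BMI).
#' @param years candidate time points (default: all world years; must lie
#'   on the world grid).
#' @param seed integer seed (study stream).
#' @return list of [gmr_study()] records.
#' @export
generate_studies <- function(world, n_studies,
                             coverage_probs = c(national = 0.6,
                                                subnational = 0.25,
                                                community = 0.15),
                             stratum_probs = c(urban = 0.395,
                                               rural = 0.395,
                                               mixed = 0.21),
                             ages = NULL, n_per_age = 300,
                             sd_scale = NULL, years = NULL, seed = 1) {
  stopifnot(inherits(world, "gmr_world"))
  spec <- world$spec
  if (is.null(ages)) ages <- spec$ages
  if (is.null(years)) years <- spec$years
  if (!all(years %in% spec$years))
    stop("requested years outside the world time grid")
  if (!all(ages %in% spec$ages)) stop("requested ages outside the world grid")
  if (is.null(sd_scale)) sd_scale <- if (spec$outcome == "height") 6.5 else 3
  set.seed(child_seed(seed, "studies"))
  cov_lv <- c("national", "subnational", "community")
  str_lv <- c("urban", "rural", "mixed")
  records <- vector("list", n_studies)
  for (i in seq_len(n_studies)) {
    j <- sample.int(world$hierarchy$J, 1)
    yr <- if (length(years) == 1L) years else sample(years, 1)
    ti <- match(yr, spec$years)
    coverage <- sample(cov_lv, 1, prob = coverage_probs[cov_lv])
    stratum <- sample(str_lv, 1, prob = stratum_probs[str_lv])
    f <- switch(stratum, urban = 1, rural = 0,
                mixed = world$urban_fraction[j, ti])
    I <- urbanicity_indicator(stratum, f)
    e_i <- stats::rnorm(1, 0, world$v_sd[[coverage]])
    d_i <- stats::rnorm(1, 0, world$d_sd)
    tc <- yr - spec$t_center
    off <- drop(coverage_design(coverage, tc) %*% world$beta)
    mu <- truth_mean(world, j, rep(yr, length(ages)), ages, stratum, f)
    sds <- sd_scale * stats::runif(length(ages), 0.9, 1.1)
    nn <- rep(n_per_age, length(ages))
    y <- mu + off + e_i + I * d_i +
      stats::rnorm(length(ages), 0, sqrt(sds^2 / nn + world$tau^2))
    sm <- data.frame(age = ages, mean = y, sd = sds, n = nn,
                     se = sds / sqrt(nn), time_index = yr)
    records[[i]] <- gmr_study(sprintf("SYN%04d", i),
                              world$hierarchy$countries[j], spec$sex, yr,
                              coverage, stratum, f, sm)
  }
  records
}
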