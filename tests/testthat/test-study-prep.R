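test_that("plausibility filters apply the age-banded windows", {
  # a 9-year-old at 59 cm is below the under-10 height window
  r <- data.frame(age = 9, sex = "female", height = 59, weight = 25,
                  pregnant = FALSE)
  out <- filter_participants(r, "height")
  expect_equal(out$report$height, 1)
  expect_equal(out$report$retained, 0)

  # boundary values are retained (windows are exclusive of the bounds)
  r2 <- data.frame(age = c(9, 12, 16), height = c(60, 200, 250),
                   weight = c(20, 40, 60))
  expect_equal(filter_participants(r2, "height")$report$retained, 3)
})

test_that("empty input yields empty output with zero counts", {
  out <- filter_participants(data.frame(age = numeric(0)), "bmi")
  expect_equal(nrow(out$rows), 0)
  expect_equal(out$report$retained, 0)
  expect_equal(out$report$input, 0)
})

test_that("toy roster with three planted violations retains nine rows", {
  out <- filter_participants(toy_roster(), "height")
  expect_equal(out$report$retained, 9)
  expect_equal(out$report$height, 2)  # one under-10, one 15-plus
  expect_equal(out$report$weight, 1)  # one in the 10-14 band
  expect_equal(out$report$input, 12)
  expect_equal(out$report$retained + out$report$height +
                 out$report$weight + out$report$age_format +
                 out$report$pregnancy + out$report$bmi, 12)
})

test_that("filtering is idempotent", {
  once <- filter_participants(toy_roster(), "height")$rows
  twice <- filter_participants(once, "height")
  expect_equal(twice$rows, once)
  expect_equal(twice$report$retained, nrow(once))
})

test_that("age-format and pregnancy rules apply as specified", {
  r <- data.frame(age = c(9.5, 9, 18.5, 16),
                  sex = c("female", "female", "female", "female"),
                  bmi = c(18, 18, 22, 22),
                  height = c(130, 130, 165, 160),
                  pregnant = c(FALSE, FALSE, FALSE, TRUE))
  out <- filter_participants(r, "bmi")
  expect_equal(out$report$age_format, 1)   # 9.5: fractional age under 18
  expect_equal(out$report$pregnancy, 1)    # pregnant, BMI outcome
  expect_equal(out$report$retained, 2)     # 18.5 allowed; 9 allowed
  # pregnancy does not remove rows for the height outcome
  out_h <- filter_participants(r, "height")
  expect_equal(out_h$report$pregnancy, 0)
  expect_equal(out_h$report$retained, 3)
})

test_that("SRS summaries give mean, sd and se = sd/sqrt(n)", {
  set.seed(7)
  r <- data.frame(age = rep(c(10, 11), each = 20),
                  height = rnorm(40, 140, 6))
  s <- survey_weighted_summary(r, "height", "srs")
  for (i in 1:2) {
    sub <- r$height[r$age == sort(unique(r$age))[i]]
    expect_equal(s$mean[i], mean(sub))
    expect_equal(s$se[i], sd(sub) / sqrt(20), tolerance = 1e-12)
  }
  # all rows identical: zero variance
  r0 <- data.frame(age = rep(10, 5), height = rep(140, 5))
  expect_equal(survey_weighted_summary(r0, "height", "srs")$se, 0)
})

test_that("Taylor linearization reduces to the SRS closed form", {
  set.seed(8)
  n <- 30
  r <- data.frame(age = rep(12, n), height = rnorm(n, 150, 7),
                  sample_weight = rep(2.5, n), stratum_id = 1,
                  cluster_id = seq_len(n))
  s <- survey_weighted_summary(r, "height", "stratified_cluster")
  expect_equal(s$mean, mean(r$height), tolerance = 1e-12)
  expect_equal(s$se, sd(r$height) / sqrt(n), tolerance = 1e-9)
  # weighted mean invariant to rescaling all weights
  r2 <- r
  r2$sample_weight <- r$sample_weight * 17
  s2 <- survey_weighted_summary(r2, "height", "stratified_cluster")
  expect_equal(s2$mean, s$mean, tolerance = 1e-12)
  expect_equal(s2$se, s$se, tolerance = 1e-12)
})

test_that("Taylor SE agrees with a cluster-bootstrap oracle", {
  set.seed(9)
  df <- expand.grid(stratum_id = 1:2, cluster_id = 1:3, rep = 1:10)
  cl_eff <- rnorm(6, 0, 3)
  df$height <- 150 + cl_eff[(df$stratum_id - 1) * 3 + df$cluster_id] +
    rnorm(nrow(df), 0, 4)
  df$cluster_id <- paste(df$stratum_id, df$cluster_id)  # unique labels
  df$sample_weight <- runif(nrow(df), 0.5, 2)
  df$age <- 14
  s <- survey_weighted_summary(df, "height", "stratified_cluster")
  se_boot <- bootstrap_se(df, "height", reps = 10000)
  expect_lt(abs(s$se - se_boot) / se_boot, 0.15)
})

test_that("a stratum with a single cluster is excluded with a warning", {
  df <- data.frame(age = rep(10, 8), height = rnorm(8, 140, 5),
                   sample_weight = 1,
                   stratum_id = rep(1:2, each = 4),
                   cluster_id = c(1, 1, 2, 2, 3, 3, 3, 3))
  expect_warning(out <- survey_weighted_summary(df, "height",
                                                "stratified_cluster"),
                 "single")
  expect_null(out)
})

test_that("time indexing uses observation year for BMI, cohort for height", {
  sm <- data.frame(age = c(5, 10, 15), mean = c(15.5, 17, 20),
                   sd = c(2, 2.5, 3), n = c(100, 100, 100))
  st <- gmr_study("S1", "A", "female", 2005, "national", "mixed", 0.5, sm)
  bmi <- assign_time_index(st, "bmi")
  expect_equal(bmi$summaries$time_index, rep(2005, 3))

  smh <- data.frame(age = c(10, 19, 25), mean = c(138, 162, 163),
                    sd = 6, n = 200)
  sth <- gmr_study("S2", "A", "female", 2010, "national", "urban", 1, smh)
  ht <- assign_time_index(sth, "height")
  expect_equal(ht$summaries$time_index, c(2000, 1991, 1985))
  expect_equal(ht$summaries$age, c(10, 19, 19))  # 25 contributes at age 19

  smh2 <- data.frame(age = c(10, 31), mean = c(138, 160), sd = 6, n = 50)
  sth2 <- gmr_study("S3", "A", "female", 2000, "national", "rural", 0, smh2)
  expect_error(assign_time_index(sth2, "height"), "30")
})

test_that("cohort assignment is a bijection on (year, age) for ages 5-19", {
  grid <- expand.grid(year = 1990:2020, age = 5:19)
  cohort <- grid$year - grid$age
  expect_equal(cohort + grid$age, grid$year)
  expect_equal(anyDuplicated(paste(cohort, grid$age)), 0)
})

test_that("prevalence conversion applies the supplied linear form", {
  ident <- list(alpha = 0, terms = list(list(name = "mean_proxy",
                                             beta = 1)))
  expect_equal(convert_prevalence_to_mean(c(mean_proxy = 21.5),
                                          ident)$mean, 21.5)
  cf <- list(alpha = 15, terms = list(list(name = "obese", beta = 10)))
  expect_equal(convert_prevalence_to_mean(c(obese = 0.2), cf)$mean, 17)
  expect_error(convert_prevalence_to_mean(c(obese = 0.2), NULL),
               "no conversion coefficients")
  expect_error(convert_prevalence_to_mean(c(other = 0.2), cf), "missing")
})

test_that("round-trip: refit conversion coefficients predict held-out means", {
  set.seed(10)
  n <- 200
  mu <- runif(n, 20, 30)
  # exact relation: prevalence of BMI >= 30 in a N(mu, 4) population
  prev <- pnorm((mu - 30) / 4)
  noise_sd <- 0.3
  obs <- mu + rnorm(n, 0, noise_sd)
  train <- seq_len(n / 2)
  fit <- lm(obs[train] ~ qnorm(prev[train]))
  cf <- list(alpha = unname(coef(fit)[1]),
             terms = list(list(name = "obese", beta = unname(coef(fit)[2]),
                               transform = qnorm)),
             resid_var = summary(fit)$sigma^2)
  pred <- vapply(prev[-train], function(p)
    convert_prevalence_to_mean(c(obese = p), cf)$mean, numeric(1))
  rmse <- sqrt(mean((pred - mu[-train])^2))
  expect_lt(rmse, noise_sd)
  expect_true(all(vapply(prev[-train][1:5], function(p)
    convert_prevalence_to_mean(c(obese = p), cf)$se, numeric(1)) > 0))
})

test_that("eligibility thresholds are inclusive as published", {
  expect_false(eligibility_flags("school", enrolment = 0.69)$keep)
  expect_true(eligibility_flags("school", enrolment = 0.70)$keep)
  expect_true(eligibility_flags("household")$keep)
  expect_false(eligibility_flags("school")$keep)  # missing metadata
  expect_false(eligibility_flags("insurance", insured_share = 0.79)$keep)
  expect_true(eligibility_flags("insurance", insured_share = 0.80)$keep)
})

test_that("study records back-fill se/sd and round-trip through CSV", {
  sm <- data.frame(age = 5:7, mean = c(110, 116, 121), sd = c(5, 5.5, 6),
                   n = c(120, 130, 110))
  st <- gmr_study("X1", "A", "female", 2001, "subnational", "mixed", 0.4, sm)
  expect_equal(st$summaries$se, st$summaries$sd / sqrt(st$summaries$n))
  sm2 <- data.frame(age = 5:6, mean = c(110, 116), se = c(0.5, 0.6),
                    n = c(100, 100))
  st2 <- gmr_study("X2", "B", "female", 2002, "national", "urban", 1, sm2)
  expect_equal(st2$summaries$sd, c(0.5, 0.6) * 10)
  expect_error(gmr_study("X3", "A", "female", 2001, "national", "rural", 0,
                         data.frame(age = c(5, 5), mean = c(1, 2),
                                    sd = 1, n = 10)), "distinct")

  tmp <- tempfile(fileext = ".csv")
  write_studies(list(st, st2), tmp)
  back <- read_studies(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$summaries$mean, sm$mean)
  expect_equal(back[[1]]$urban_fraction, 0.4)
  expect_equal(back[[2]]$coverage, "national")
})

test_that("potential duplicates are flagged, not deleted", {
  sm <- data.frame(age = 5, mean = 110, sd = 5, n = 100)
  a <- gmr_study("D1", "A", "female", 2001, "national", "urban", 1, sm)
  b <- gmr_study("D2", "A", "female", 2001, "national", "urban", 1, sm)
  expect_warning(ids <- flag_duplicates(list(a, b)), "duplicate")
  expect_setequal(ids, c("D1", "D2"))
})
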