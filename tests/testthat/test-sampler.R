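test_that("initial state: pooled least squares and valid invariants", {
  ws <- tiny_world_spec()
  w <- generate_world(ws, seed = 1)
  recs <- generate_studies(w, 15, seed = 1)
  # constant data: intercept at the constant, zero slope
  recs_c <- lapply(recs, function(r) {
    r$summaries$mean <- rep(17, nrow(r$summaries))
    r
  })
  d <- gmr_data(recs_c, w$hierarchy, w$spec)
  st <- growthmeta:::init_state(growthmeta:::precompute(d), seed = 1)
  expect_equal(unname(st$a_g), 17, tolerance = 1e-6)
  expect_equal(unname(st$b_g), 0, tolerance = 1e-6)
  expect_lt(max(abs(st$psi)), 1e-6)

  # invariants hold and hyperparameter starts are overdispersed/distinct
  d2 <- gmr_data(recs, w$hierarchy, w$spec)
  pre <- growthmeta:::precompute(d2)
  s1 <- growthmeta:::init_state(pre, seed = 1)
  s2 <- growthmeta:::init_state(pre, seed = 2)
  for (s in list(s1, s2)) {
    expect_true(all(diff(s$lambda) > 0))
    expect_true(all(diff(s$v_sd) > 0))
    expect_true(all(log(s$lambda) <= 20))
  }
  expect_false(isTRUE(all.equal(s1$sd_a, s2$sd_a)))
  expect_false(isTRUE(all.equal(s1$tau, s2$tau)))
})

test_that("Gaussian block draw: prior-sampling limit with no data", {
  set.seed(20)
  s <- 2.3
  draws <- replicate(2000, growthmeta:::draw_gauss_block(
    matrix(numeric(0), 0, 1), numeric(0), numeric(0),
    matrix(1 / s^2), "test"))
  # variance test against the prior
  stat <- sum((draws / s)^2)
  expect_gt(stat, qchisq(0.001, 2000))
  expect_lt(stat, qchisq(0.999, 2000))
  expect_lt(abs(mean(draws)), 4 * s / sqrt(2000))
})

test_that("Gaussian block conditional mean matches the WLS oracle", {
  set.seed(21)
  n <- 40
  X <- cbind(1, runif(n, -5, 5))
  w <- runif(n, 0.5, 3)
  r <- drop(X %*% c(2, -0.4)) + rnorm(n)
  # extract the conditional mean by linearity: with the same RNG stream,
  # draw(r) = m(r) + noise and draw(2r) = 2 m(r) + noise
  flat <- diag(1e-12, 2)
  set.seed(99); th1 <- growthmeta:::draw_gauss_block(X, w, r, flat)
  set.seed(99); th2 <- growthmeta:::draw_gauss_block(X, w, 2 * r, flat)
  m <- th2 - th1
  wls <- stats::lm.wfit(X, r, w)$coefficients
  expect_equal(unname(m), unname(wls), tolerance = 1e-6)
})

test_that("scalar study-effect conditional matches the normal-normal form", {
  set.seed(22)
  n <- 12
  w <- runif(n, 1, 4)
  r <- rnorm(n, 1.2, 0.5)
  v <- 0.7  # prior sd
  prec <- 1 / v^2 + sum(w)
  m_exp <- sum(w * r) / prec
  set.seed(55); z <- rnorm(1)
  set.seed(55)
  th <- growthmeta:::draw_gauss_block(matrix(1, n, 1), w, r,
                                      matrix(1 / v^2), "e")
  expect_equal(drop(th), m_exp + z / sqrt(prec), tolerance = 1e-9)
})

test_that("singular unidentified blocks are rejected with a diagnostic", {
  X <- cbind(1, 1)  # perfectly collinear columns
  expect_error(growthmeta:::draw_gauss_block(
    matrix(rep(1, 8), 4, 2), rep(1, 4), rnorm(4), diag(0, 2), "dup"),
    "dup")
})

test_that("constrained RW2 draw: constraints, prior limit, dense oracle", {
  set.seed(23)
  T_len <- 12
  pen <- build_penalty(T_len)
  pe <- growthmeta:::penalty_eigen(pen)
  tcg <- seq_len(T_len) - mean(seq_len(T_len))
  A <- rbind(rep(1, T_len), tcg)

  check_constraints <- function(u) {
    expect_lt(abs(mean(u)), 1e-8)
    expect_lt(abs(sum(u * tcg)) / sum(tcg^2), 1e-8)
  }
  # data-rich, single-time-point and no-data regimes
  wt_rich <- runif(T_len, 0.5, 4)
  rhs_rich <- rnorm(T_len) * wt_rich
  wt_one <- numeric(T_len); wt_one[5] <- 3; rhs_one <- numeric(T_len)
  rhs_one[5] <- 2.4
  for (cfg in list(list(wt_rich, rhs_rich), list(wt_one, rhs_one),
                   list(numeric(T_len), numeric(T_len)))) {
    u <- growthmeta:::draw_u_unit(pen$P, pe, 3, cfg[[1]], cfg[[2]], A)
    check_constraints(u)
  }
  # no data at the truncation bound: the smooth vanishes
  u0 <- growthmeta:::draw_u_unit(pen$P, pe, exp(20), numeric(T_len),
                                 numeric(T_len), A)
  expect_lt(max(abs(u0)), 1e-3)

  # dense noiseless-quadratic oracle: posterior mean from a standalone
  # dense computation with the kriging correction
  lam <- 5
  yq <- 0.02 * (tcg^2 - mean(tcg^2))
  wt <- rep(50, T_len)
  rhs <- wt * yq
  Q <- lam * pen$P + diag(wt)
  m_dense <- solve(Q, rhs)
  V <- solve(Q, t(A))
  m_constr <- drop(m_dense - V %*% solve(A %*% V, A %*% m_dense))
  set.seed(77); u1 <- growthmeta:::draw_u_unit(pen$P, pe, lam, wt, rhs, A)
  set.seed(77); u2 <- growthmeta:::draw_u_unit(pen$P, pe, lam, wt, 2 * rhs, A)
  expect_equal(u2 - u1, m_constr, tolerance = 1e-6)
})

test_that("flat-on-SD Metropolis matches a numerical quadrature posterior", {
  set.seed(24)
  vals <- rnorm(20, 0, 1.5)
  S <- sum(vals^2)
  m <- length(vals)
  # exact posterior on the sd scale by quadrature
  grid <- seq(1e-3, 12, length.out = 1e6)
  dens <- grid^(-m) * exp(-S / (2 * grid^2))
  cdf <- cumsum(dens) / sum(dens)
  # Metropolis chain using the package update
  s_cur <- 1
  out <- numeric(120000)
  for (i in seq_along(out)) {
    s_cur <- growthmeta:::mh_sd_flat(s_cur, vals)$sd
    out[i] <- s_cur
  }
  out <- out[seq(20001, length(out), by = 10)]
  ks <- max(abs(ecdf(out)(grid[seq(1, 1e6, by = 1000)]) -
                  cdf[seq(1, 1e6, by = 1000)]))
  expect_lt(ks, 0.02)
})

test_that("impropriety guards fire for unidentified SDs", {
  expect_error(growthmeta:::mh_sd_flat(1, numeric(0)), "improper")
  expect_error(growthmeta:::mh_sd_flat(1, 3.2), "improper")
})

test_that("lambda updates respect ordering and the log-lambda bound", {
  set.seed(25)
  lam <- c(c = 1, r = 2, s = 4, g = 8)
  for (i in 1:2000) {
    lv <- sample(c("c", "r", "s", "g"), 1)
    lam <- growthmeta:::mh_lambda(lam, lv, quad = 0.01, n_units = 3,
                                  T_len = 10)$lambda
    stopifnot(all(diff(lam) > 0))
  }
  expect_true(all(diff(lam) > 0))
  expect_true(all(log(lam) <= 20))
})

test_that("log likelihood: reordered-sum oracle and translation identity", {
  w <- generate_world(tiny_world_spec(), seed = 2)
  recs <- generate_studies(w, 10, seed = 2)
  d <- gmr_data(recs, w$hierarchy, w$spec)
  set.seed(26)
  mu <- d$obs$y + rnorm(nrow(d$obs), 0, 0.3)
  tau <- 0.4
  got <- gmr_loglik(d, mu, tau)
  # independently coded per-observation normal log pdf, summed in
  # reverse order
  v <- d$obs$var0 + tau^2
  ll <- 0
  for (i in rev(seq_len(nrow(d$obs))))
    ll <- ll - 0.5 * (log(2 * pi * v[i]) + (d$obs$y[i] - mu[i])^2 / v[i])
  expect_equal(got, ll, tolerance = 1e-9)
  # translating data and predictions together changes nothing
  d2 <- d
  d2$obs$y <- d$obs$y + 5
  expect_equal(gmr_loglik(d2, mu + 5, tau), got, tolerance = 1e-9)
  expect_error(gmr_loglik(d, mu, tau = NaN), "variance")
})

test_that("fits are reproducible and bookkeeping is exact", {
  w <- generate_world(tiny_world_spec(), seed = 3)
  recs <- generate_studies(w, 20, seed = 3,
                           coverage_probs = c(national = 1,
                                              subnational = 0,
                                              community = 0))
  d <- gmr_data(recs, w$hierarchy, w$spec)
  fit_q <- function(...) suppressWarnings(gmr_fit(...))
  f1 <- fit_q(d, chains = 2, iters = 60, burnin = 20, thin = 4, seed = 11)
  f2 <- fit_q(d, chains = 2, iters = 60, burnin = 20, thin = 4, seed = 11)
  expect_identical(f1$draws$a, f2$draws$a)
  expect_identical(f1$draws$hyper, f2$draws$hyper)
  expect_identical(f1$draws$ll_trace, f2$draws$ll_trace)
  expect_equal(f1$draws$n_draws, 2 * floor((60 - 20) / 4))
  expect_equal(unname(table(f1$draws$chain)), rep(10L, 2),
               ignore_attr = TRUE)
  # a different seed moves the draws
  f3 <- fit_q(d, chains = 1, iters = 60, burnin = 20, thin = 4, seed = 12)
  expect_false(identical(f1$draws$a[1:10, ], f3$draws$a))
  # shuffled scan runs and remains reproducible
  f4 <- fit_q(d, chains = 1, iters = 30, burnin = 10, thin = 2, seed = 1,
              scan = "shuffled")
  f5 <- fit_q(d, chains = 1, iters = 30, burnin = 10, thin = 2, seed = 1,
              scan = "shuffled")
  expect_identical(f4$draws$a, f5$draws$a)
})

test_that("every retained draw satisfies the ordering and constraint rules", {
  w <- generate_world(tiny_world_spec(), seed = 4)
  recs <- generate_studies(w, 25, seed = 4)
  d <- gmr_data(recs, w$hierarchy, w$spec)
  f <- gmr_fit(d, chains = 2, iters = 200, burnin = 100, thin = 2, seed = 2)
  hy <- f$draws$hyper
  lam <- hy[, c("lambda_c", "lambda_r", "lambda_s", "lambda_g")]
  expect_true(all(lam[, 1] < lam[, 2] & lam[, 2] < lam[, 3] &
                    lam[, 3] < lam[, 4]))
  expect_true(all(log(lam) <= 20))
  expect_true(all(hy[, "v_n"] < hy[, "v_s"] & hy[, "v_s"] < hy[, "v_c"]))
  expect_lt(max(f$draws$u_constraint_max), 1e-8)
})

test_that("hierarchies too small for the flat-SD priors are refused", {
  tab <- data.frame(country = c("A", "B"), region = c("R1", "R1"),
                    super_region = c("S1", "S1"))
  h <- gmr_hierarchy(tab)
  spec <- gmr_spec("bmi", "female", 2000:2005, c(8, 10, 12))
  sm <- data.frame(age = c(8, 10, 12), mean = c(16, 17, 18), sd = 2, n = 50)
  recs <- list(gmr_study("s1", "A", "female", 2002, "national", "mixed",
                         0.5, sm),
               gmr_study("s2", "B", "female", 2003, "national", "urban",
                         1, sm))
  expect_error(gmr_fit(recs, h, spec, chains = 1, iters = 10),
               "at least 2 units")
})

test_that("posterior matches the exact dense Gaussian posterior (fixed hypers)", {
  ws <- tiny_world_spec()
  w <- generate_world(ws, seed = 3)
  recs <- generate_studies(w, 30, n_per_age = 200, seed = 3)
  d <- gmr_data(recs, w$hierarchy, w$spec)
  pre <- growthmeta:::precompute(d)
  fx <- list(sd_a = ws$sd_a, sd_b = ws$sd_b, spline_sd = ws$spline_sd,
             sd_p = ws$sd_p, sd_q = ws$sd_q, sd_r = ws$sd_r,
             lambda = ws$lambda, v_sd = ws$v_sd, d_sd = ws$d_sd,
             tau = ws$tau)
  J <- pre$J; Kc <- pre$Kc; n <- pre$n
  nlev <- c(pre$J, pre$K, pre$L)
  lvidx <- list(pre$j, pre$k, pre$l)
  blocks <- list(); prior <- c()
  addb <- function(X, pv) {
    blocks[[length(blocks) + 1]] <<- X
    prior <<- c(prior, rep(pv, ncol(X)))
  }
  ind <- function(idx, m) {
    M <- matrix(0, n, m); M[cbind(seq_len(n), idx)] <- 1; M
  }
  addb(pre$Xbig, 1e8)
  for (li in 1:3) {
    Ij <- ind(lvidx[[li]], nlev[li])
    addb(Ij, fx$sd_a[li]^2)
    addb(Ij * pre$tc, fx$sd_b[li]^2)
    addb(Ij * pre$I, fx$sd_p[li]^2)
    addb(Ij * pre$Xloc[, 4], fx$sd_q[li]^2)
    addb(Ij * pre$Xloc[, 5], fx$sd_r[li]^2)
    for (kk in seq_len(Kc)) addb(Ij * pre$B[, kk], fx$spline_sd[li]^2)
  }
  uts <- pre$pe$vectors
  for (li in 1:3) for (uu in seq_len(nlev[li])) {
    sel <- as.numeric(lvidx[[li]] == uu)
    blocks[[length(blocks) + 1]] <- sel * uts[pre$t, , drop = FALSE]
    prior <- c(prior,
               1 / (fx$lambda[[c("c", "r", "s")[li]]] * pre$pe$values))
  }
  blocks[[length(blocks) + 1]] <- uts[pre$t, , drop = FALSE]
  prior <- c(prior, 1 / (fx$lambda[["g"]] * pre$pe$values))
  addb(pre$Xcov, 1e8)
  covf <- match(pre$stud_cov, c("national", "subnational", "community"))
  Is <- ind(pre$study, pre$S)
  addb(Is, 1)
  prior[(length(prior) - pre$S + 1):length(prior)] <- fx$v_sd[covf]^2
  addb(Is * pre$I, fx$d_sd^2)
  X <- do.call(cbind, blocks)
  wobs <- 1 / (pre$var0 + fx$tau^2)
  Sig <- solve(diag(1 / prior) + crossprod(X, X * wobs))
  mpost <- drop(Sig %*% crossprod(X, wobs * pre$y))
  off <- 5 + Kc
  pick <- function(fam_i, li) {
    base <- off
    for (l2 in seq_len(li - 1)) base <- base + nlev[l2] * (5 + Kc)
    base + (fam_i - 1) * nlev[li] + seq_len(nlev[li])
  }
  tot <- function(fam_i, gcol)
    mpost[pick(fam_i, 1)] + mpost[pick(fam_i, 2)][pre$j2k] +
      mpost[pick(fam_i, 3)][pre$k2l[pre$j2k]] + mpost[gcol]
  sd_tot <- function(fam_i, gcol) {
    vapply(seq_len(J), function(j) {
      ii <- c(pick(fam_i, 1)[j], pick(fam_i, 2)[pre$j2k[j]],
              pick(fam_i, 3)[pre$k2l[pre$j2k[j]]], gcol)
      sqrt(sum(Sig[ii, ii]))
    }, numeric(1))
  }
  f <- gmr_fit(d, chains = 2, iters = 2500, burnin = 500, thin = 2,
               seed = 9, fix_hyper = fx)
  dr <- f$draws
  expect_lt(max(abs(colMeans(dr$a) - tot(1, 1))), 0.2)
  expect_lt(max(abs(colMeans(dr$p) - tot(3, 3))), 0.2)
  expect_lt(max(abs(apply(dr$a, 2, sd) / sd_tot(1, 1) - 1)), 0.25)
  expect_lt(max(abs(apply(dr$p, 2, sd) / sd_tot(3, 3) - 1)), 0.25)
})

test_that("mostly-mixed data still recover the urban-offset sign where
           stratified data exist", {
  ws <- gmr_world_spec(p_g = 1.5, sd_p = c(0.4, 0.25, 0.15))
  w <- generate_world(ws, seed = 14)
  recs <- generate_studies(w, 100, n_per_age = 400, seed = 14,
                           stratum_probs = c(urban = 0.1, rural = 0.1,
                                             mixed = 0.8))
  d <- gmr_data(recs, w$hierarchy, w$spec)
  f <- gmr_fit(d, chains = 1, iters = 1500, burnin = 700, thin = 5, seed = 6)
  est <- colMeans(f$draws$p)
  strat <- vapply(seq_len(18), function(j)
    sum(d$studies$j == j & abs(d$studies$I) == 1), numeric(1))
  sel <- strat >= 2 & abs(w$p_j) > 0.4
  expect_gt(sum(sel), 4)
  expect_gt(mean(sign(est[sel]) == sign(w$p_j[sel])), 0.85)
})
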