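# Internal sampler machinery: exact Gaussian block draws from sparse full
# conditionals, constrained RW2 (GMRF) draws, and random-walk Metropolis on
# log-SD for the flat-on-SD variance hyperparameters.

# Draw a Gaussian block from its full conditional.
#   X: n x p design, w: n observation precisions, r: partial residual
#   (data minus all other terms), prior_prec: p x p prior precision
#   (0 for flat priors). Returns the sampled coefficient vector.
# Columns with no support in the data and no prior mass are held at zero;
# a genuinely singular conditional is an identification failure and errors.
draw_gauss_block <- function(X, w, r, prior_prec, block = "block") {
  X <- as.matrix(X)
  p <- ncol(X)
  Q <- prior_prec + crossprod(X, X * w)
  active <- diag(Q) > 0
  theta <- numeric(p)
  if (!any(active)) return(theta)
  Qa <- Q[active, active, drop = FALSE]
  ba <- crossprod(X[, active, drop = FALSE], w * r)
  U <- tryCatch(chol(Qa), error = function(e)
    stop("full conditional for block '", block,
         "' is singular: the block is not identified by data or prior"))
  m <- backsolve(U, backsolve(U, ba, transpose = TRUE))
  theta[active] <- m + backsolve(U, stats::rnorm(sum(active)))
  theta
}

# Pseudo-inverse of a small symmetric matrix (constraint correction).
ginv_small <- function(M, tol = 1e-9) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) *
                                   t(s$u[, keep, drop = FALSE]))
}

# Draw one RW2 smooth u (length T) from its Gaussian full conditional with
# precision lambda*P + diag(wt) and then impose the zero-mean / zero-slope
# identifiability constraints exactly by conditioning by kriging
# (Rue-Held). Three data regimes:
#   >= 2 observed time points: full-rank conditional, Cholesky path;
#   1 observed time point: rank T-1; generalized inverse zeroes the
#     non-identified slope direction, then the one-dimensional kriging
#     correction restores the mean constraint;
#   no data: the Moore-Penrose pseudoinverse of lambda*P; sampling in the
#     row space of P already satisfies both constraints.
#   wt, rhs: per-time-point likelihood precision and precision-weighted
#   partial residual sums; A: 2 x T constraint matrix (ones; centred ramp).
draw_u_unit <- function(P, pe, lambda, wt, rhs, A) {
  T_len <- nrow(P)
  n_t <- sum(wt > 0)
  if (n_t == 0L) return(rw2_prior_draw(pe, lambda))
  Q <- lambda * P
  diag(Q) <- diag(Q) + wt
  if (n_t >= 2L) {
    U <- chol(Q)
    m <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
    x <- m + backsolve(U, stats::rnorm(T_len))
    V <- backsolve(U, backsolve(U, t(A), transpose = TRUE))
  } else {
    e <- eigen(Q, symmetric = TRUE)
    keep <- e$values > 1e-9 * max(e$values)
    Vp <- e$vectors[, keep, drop = FALSE]
    vals <- e$values[keep]
    m <- Vp %*% (crossprod(Vp, rhs) / vals)
    x <- m + Vp %*% (stats::rnorm(length(vals)) / sqrt(vals))
    V <- Vp %*% (crossprod(Vp, t(A)) / vals)
  }
  Bc <- A %*% V
  x <- x - V %*% (ginv_small(Bc) %*% (A %*% x))
  drop(x)
}

# Exact recentring ("sweep") Gibbs moves along the translation-redundant
# directions of an additive hierarchy x_j = x^c_j + x^r_k + x^s_l + x^g:
# a constant shifted between a parent and all its children leaves every
# total (and hence the likelihood) unchanged, so its full conditional
# involves only the level priors and is a cheap univariate Gaussian.
# Without these moves the redundant split wanders slowly under the
# one-level-at-a-time scan and retards mixing of unit totals in data-poor
# units. Returns the recentred component lists.
sweep_family <- function(xc, xr, xs, xg, sdc, sdr, sds_, j2k, k2l) {
  for (k in seq_along(xr)) {
    jj <- which(j2k == k)
    m <- length(jj)
    prec <- 1 / sdr^2 + m / sdc^2
    mu <- (sum(xc[jj]) / sdc^2 - xr[k] / sdr^2) / prec
    delta <- stats::rnorm(1, mu, 1 / sqrt(prec))
    xr[k] <- xr[k] + delta
    xc[jj] <- xc[jj] - delta
  }
  for (l in seq_along(xs)) {
    kk <- which(k2l == l)
    m <- length(kk)
    prec <- 1 / sds_^2 + m / sdr^2
    mu <- (sum(xr[kk]) / sdr^2 - xs[l] / sds_^2) / prec
    delta <- stats::rnorm(1, mu, 1 / sqrt(prec))
    xs[l] <- xs[l] + delta
    xr[kk] <- xr[kk] - delta
  }
  L <- length(xs)
  delta <- stats::rnorm(1, mean(xs), sds_ / sqrt(L))
  xg <- xg + delta
  xs <- xs - delta
  list(c = xc, r = xr, s = xs, g = xg)
}

# Same recentring between a global location with flat prior and a set of
# zero-mean random effects (e.g. the overall level vs the study effects):
# shift delta into the global term and out of every effect.
sweep_effects <- function(xg, eff, prec_eff) {
  prec <- sum(prec_eff)
  delta <- stats::rnorm(1, sum(prec_eff * eff) / prec, 1 / sqrt(prec))
  list(g = xg + delta, eff = eff - delta)
}

# Random-walk Metropolis on theta = log(sd) for a flat prior on the sd
# scale, given centred Gaussian values with that sd. Posterior density
# pi(sd) ~ sd^(-m) exp(-S/(2 sd^2)); on the log scale the Jacobian adds one
# power of sd. Requires m >= 2: with fewer values the flat prior gives an
# improper (divergent) posterior and the update refuses to run.
mh_sd_flat <- function(sd_cur, values, prop_sd = 0.35) {
  m <- length(values)
  if (m < 2L)
    stop("flat-on-SD prior with fewer than two values: the posterior for ",
         "this standard deviation is improper; refusing to update")
  S <- sum(values^2)
  lt <- function(th) (1 - m) * th - S * exp(-2 * th) / 2
  th <- log(sd_cur)
  th_new <- th + stats::rnorm(1, 0, prop_sd)
  if (th_new > 46)  # e^46 dwarfs any data scale: impropriety guard
    stop("SD hyperparameter diverging; posterior appears improper")
  acc <- log(stats::runif(1)) < lt(th_new) - lt(th)
  list(sd = if (acc) exp(th_new) else sd_cur, accepted = acc)
}

# Metropolis update for one RW2 precision lambda on the log scale.
# Flat prior on the sd scale 1/sqrt(lambda) => p(lambda) ~ lambda^(-3/2);
# with the log-scale Jacobian the target exponent is
# (n_units (T-2)/2 - 1/2). Proposals violating the a-priori ordering
# lambda_c < lambda_r < lambda_s < lambda_g or the truncation
# log(lambda) <= bound are rejected outright.
mh_lambda <- function(lambda, which, quad, n_units, T_len, bound = 20,
                      prop_sd = 0.5) {
  th <- log(lambda[which])
  th_new <- th + stats::rnorm(1, 0, prop_sd)
  cand <- lambda
  cand[which] <- exp(th_new)
  ordered <- all(diff(cand) > 0)
  if (!ordered || th_new > bound)
    return(list(lambda = lambda, accepted = FALSE))
  lt <- function(t) (n_units * (T_len - 2) / 2 - 0.5) * t -
    exp(t) * quad / 2
  acc <- log(stats::runif(1)) < lt(th_new) - lt(th)
  if (acc) lambda[which] <- exp(th_new)
  list(lambda = lambda, accepted = acc)
}

# Collapsed Metropolis update for a random-effect SD: the effects are
# integrated out analytically, so the target uses the per-study summary
# statistics m_i ~ N(0, sd^2 + Winv_i) (posterior-mean contrasts with
# their conditional variances). Avoids the funnel between the SD and its
# effects; the effects are redrawn from their full conditionals right
# after (a valid blocked update of the pair). Optional (lower, upper)
# bounds on the SD enforce ordering constraints by rejection.
mh_sd_marginal <- function(sd_cur, m, Winv, prop_sd = 0.35,
                           lower = 0, upper = Inf) {
  if (length(m) < 2L) return(list(sd = sd_cur, accepted = NA))
  lt <- function(s) sum(stats::dnorm(m, 0, sqrt(s^2 + Winv), log = TRUE)) +
    log(s)  # flat prior on the sd scale + log-scale Jacobian
  th_new <- log(sd_cur) + stats::rnorm(1, 0, prop_sd)
  s_new <- exp(th_new)
  if (s_new <= lower || s_new >= upper)
    return(list(sd = sd_cur, accepted = FALSE))
  acc <- log(stats::runif(1)) < lt(s_new) - lt(sd_cur)
  list(sd = if (acc) s_new else sd_cur, accepted = acc)
}

# Ancillarity-sufficiency interweaving (ASIS) rescaling move for one
# hierarchical SD: with the standardized effects z = x/sd held fixed
# (non-centred parameterization), a proposal sd' rescales every effect by
# rho = sd'/sd and is accepted by the likelihood ratio (flat-on-SD prior,
# log-scale Jacobian). Interweaving the centred and non-centred updates
# breaks the funnel between an SD and its effects.
#   contrib: the current contribution of this block to the fitted values.
asis_scale <- function(sd_cur, contrib, resid, w, prop_sd = 0.3) {
  th_new <- log(sd_cur) + stats::rnorm(1, 0, prop_sd)
  rho <- exp(th_new) / sd_cur
  rnew <- resid - (rho - 1) * contrib
  dll <- -0.5 * sum(w * (rnew^2 - resid^2)) + (th_new - log(sd_cur))
  if (log(stats::runif(1)) < dll)
    list(sd = exp(th_new), rho = rho, resid = rnew, accepted = TRUE)
  else list(sd = sd_cur, rho = 1, resid = resid, accepted = FALSE)
}

# Metropolis update for one study-effect SD with the ordering constraint
# v_national < v_subnational < v_community enforced by rejection.
mh_v <- function(v_sd, which, values, prop_sd = 0.35) {
  m <- length(values)
  if (m < 2L) return(list(v_sd = v_sd, accepted = NA))
  th <- log(v_sd[which])
  th_new <- th + stats::rnorm(1, 0, prop_sd)
  cand <- v_sd
  cand[which] <- exp(th_new)
  if (!all(diff(cand) > 0)) return(list(v_sd = v_sd, accepted = FALSE))
  S <- sum(values^2)
  lt <- function(t) (1 - m) * t - S * exp(-2 * t) / 2
  acc <- log(stats::runif(1)) < lt(th_new) - lt(th)
  if (acc) v_sd[which] <- exp(th_new)
  list(v_sd = v_sd, accepted = acc)
}

# Metropolis update for the residual age-by-study SD tau, which enters
# every observation variance var0 + tau^2. Flat prior on tau.
mh_tau <- function(tau, resid, var0, prop_sd = 0.2) {
  lt <- function(th) {
    v <- var0 + exp(2 * th)
    sum(-0.5 * log(v) - resid^2 / (2 * v)) + th
  }
  th <- log(tau)
  th_new <- th + stats::rnorm(1, 0, prop_sd)
  acc <- log(stats::runif(1)) < lt(th_new) - lt(th)
  list(tau = if (acc) exp(th_new) else tau, accepted = acc)
}
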