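#' Fit the hierarchical meta-regression by MCMC
#'
#' Metropolis-within-Gibbs sampler for the full model: mean
#' \eqn{a_j + b_j \tilde t + u_{j,t} + \gamma_j(z) + X\beta + e_i +
#' I_{s,i}[p_j + q_j \tilde t + r_j \tilde z + d_i]} with observation
#' variance \eqn{SD^2/n + \tau^2}. All Gaussian location blocks (the
#' hierarchical intercepts and slopes, spline coefficients, coverage fixed
#' effects, study effects, urban-rural offset terms and the RW2 smooths)
#' are drawn from their exact multivariate-normal full conditionals; every
#' variance hyperparameter uses random-walk Metropolis on the log-SD scale
#' with the flat-on-SD prior, the a-priori orderings
#' \eqn{\lambda_c < \lambda_r < \lambda_s < \lambda_g} and
#' \eqn{v_n < v_s < v_c} and the truncation \eqn{\log\lambda \le 20}
#' enforced by proposal rejection. RW2 smooths are constrained to zero mean
#' and zero slope by exact conditioning by kriging, with generalized-inverse
#' handling for units observed at one or zero time points. The scan order
#' is fixed (hierarchy top-down, then smooths, then study terms, then
#' variances); a shuffled-scan mode exists for sensitivity checks. Chains
#' start from deterministic pooled least-squares locations with
#' overdispersed random hyperparameter values. The first `burnin`
#' iterations are discarded and the remainder thinned.
#'
#' @param data a [gmr_data()] object, or a list of [gmr_study()] records
#'   (then `hierarchy` and `spec` are required).
#' @param hierarchy,spec used only when `data` is a record list.
#' @param chains number of chains.
#' @param iters iterations per chain.
#' @param burnin iterations discarded per chain (default: half).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed root seed; per-chain streams are derived from it.
#' @param scan `"fixed"` or `"shuffled"` update order.
#' @param fix_hyper optional named list of hyperparameters to hold fixed
#'   (any of `sd_a`, `sd_b`, `spline_sd`, `sd_p`, `sd_q`, `sd_r` (length-3
#'   vectors), `lambda` (length 4), `v_sd` (length 3), `d_sd`, `tau`);
#'   their Metropolis updates are skipped. Used for calibration studies.
#' @param verbose print per-chain progress.
#' @return object of class `gmr_fit` with elements `draws` (class
#'   `gmr_draws`), `data`, `spec`, `hierarchy`.
#' @export
gmr_fit <- function(data, hierarchy = NULL, spec = NULL, chains = 3,
                    iters = 2000, burnin = floor(iters / 2), thin = 10,
                    seed = 1, scan = c("fixed", "shuffled"),
                    fix_hyper = NULL, verbose = FALSE) {
  scan <- match.arg(scan)
  if (!inherits(data, "gmr_data")) {
    if (is.null(hierarchy) || is.null(spec))
      stop("supply a gmr_data object, or records plus hierarchy and spec")
    data <- gmr_data(data, hierarchy, spec)
  }
  stopifnot(chains >= 1, iters >= 2, burnin >= 0, burnin < iters, thin >= 1)
  pre <- precompute(data)
  if (pre$J < 2 || pre$K < 2 || pre$L < 2)
    stop("each hierarchy level needs at least 2 units for the flat-on-SD ",
         "priors to give a proper posterior (got J=", pre$J, ", K=", pre$K,
         ", L=", pre$L, ")")
  low <- names(which(table(factor(pre$stud_cov,
                                  c("national", "subnational",
                                    "community"))) < 2))
  if (length(low))
    warning("coverage class(es) with <2 studies: ",
            paste(low, collapse = ", "),
            "; their study-effect SD is held at its initial value")
  res <- lapply(seq_len(chains), function(ch) {
    if (verbose) message("chain ", ch, "/", chains)
    run_one_chain(pre, chain_seed = child_seed(seed, "sampler") + ch,
                  iters = iters, burnin = burnin, thin = thin,
                  scan = scan, fix_hyper = fix_hyper, chain_id = ch)
  })
  draws <- combine_chains(res, pre, chains, iters, burnin, thin, seed)
  structure(list(draws = draws, data = data, spec = data$spec,
                 hierarchy = data$hierarchy, call = match.call()),
            class = "gmr_fit")
}

# Flatten a gmr_data into plain vectors/matrices and index lists.
precompute <- function(data) {
  obs <- data$obs
  spec <- data$spec
  h <- data$hierarchy
  T_len <- length(spec$years)
  pen <- build_penalty(T_len)
  n <- nrow(obs)
  list(
    n = n, J = h$J, K = h$K, L = h$L, S = nrow(data$studies),
    T = T_len, Kc = ncol(data$B),
    y = obs$y, var0 = obs$var0, t = obs$t, tc = obs$tc, zc = obs$zc,
    I = obs$I, j = obs$j, k = obs$k, l = obs$l, study = obs$study,
    B = data$B, Xcov = data$Xcov,
    # joint design for (a, b, p, q, r): intercept, centred time, and the
    # urbanicity-indicator interactions; one block per hierarchy unit so
    # the a-p ridge induced by mixed-stratum data is sampled jointly
    Xloc = cbind(1, obs$tc, obs$I, obs$I * obs$tc, obs$I * obs$zc),
    Xbig = cbind(1, obs$tc, obs$I, obs$I * obs$tc, obs$I * obs$zc,
                 data$B),
    idx_j = split(seq_len(n), factor(obs$j, seq_len(h$J))),
    idx_k = split(seq_len(n), factor(obs$k, seq_len(h$K))),
    idx_l = split(seq_len(n), factor(obs$l, seq_len(h$L))),
    f_study = factor(obs$study, seq_len(nrow(data$studies))),
    stud_cov = data$studies$coverage,
    stud_I = data$studies$I,
    j2k = h$j2k, k2l = h$k2l,
    P = pen$P, pe = penalty_eigen(pen),
    A = rbind(rep(1, T_len), spec$years - spec$t_center),
    spec = spec, hierarchy = h)
}

# Deterministic pooled least-squares locations; overdispersed random
# hyperparameter starting values (distinct across seeds/chains).
init_state <- function(pre, seed) {
  set.seed(seed)
  w0 <- 1 / pre$var0
  fit <- stats::lm.wfit(pre$Xloc[, 1:2, drop = FALSE], pre$y, w0)
  cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  r1 <- pre$y - pre$Xloc[, 1:2, drop = FALSE] %*% cf
  fit2 <- stats::lm.wfit(pre$B, drop(r1), w0)
  psi <- ifelse(is.na(fit2$coefficients), 0, fit2$coefficients)
  s0 <- max(stats::sd(fit2$residuals), 0.1)
  od <- function(k = 1) exp(stats::runif(k, -1, 1))
  st <- list(
    a_g = cf[1], b_g = cf[2],
    a_c = numeric(pre$J), a_r = numeric(pre$K), a_s = numeric(pre$L),
    b_c = numeric(pre$J), b_r = numeric(pre$K), b_s = numeric(pre$L),
    psi = drop(psi),
    spl_c = matrix(0, pre$J, pre$Kc), spl_r = matrix(0, pre$K, pre$Kc),
    spl_s = matrix(0, pre$L, pre$Kc),
    u_c = matrix(0, pre$J, pre$T), u_r = matrix(0, pre$K, pre$T),
    u_s = matrix(0, pre$L, pre$T), u_g = numeric(pre$T),
    beta = numeric(4),
    e = numeric(pre$S), d = numeric(pre$S),
    p_g = 0, q_g = 0, r_g = 0,
    p_c = numeric(pre$J), p_r = numeric(pre$K), p_s = numeric(pre$L),
    q_c = numeric(pre$J), q_r = numeric(pre$K), q_s = numeric(pre$L),
    r_c = numeric(pre$J), r_r = numeric(pre$K), r_s = numeric(pre$L),
    sd_a = s0 * c(1, 0.7, 0.5) * od(3),
    sd_b = 0.05 * s0 * c(1, 0.7, 0.5) * od(3),
    spline_sd = 0.3 * s0 * c(1, 0.7, 0.5) * od(3),
    sd_p = 0.5 * s0 * c(1, 0.7, 0.5) * od(3),
    sd_q = 0.02 * s0 * c(1, 0.7, 0.5) * od(3),
    sd_r = 0.05 * s0 * c(1, 0.7, 0.5) * od(3),
    lambda = sort(exp(stats::runif(4, 0, 5))),
    v_sd = sort(s0 * c(0.2, 0.5, 1) * od(3)),
    d_sd = 0.3 * s0 * od(1),
    tau = 0.5 * s0 * od(1))
  names(st$lambda) <- c("c", "r", "s", "g")
  names(st$v_sd) <- c("national", "subnational", "community")
  st
}

run_one_chain <- function(pre, chain_seed, iters, burnin, thin, scan,
                          fix_hyper, chain_id) {
  set.seed(chain_seed %% 2147483647)
  st <- init_state(pre, chain_seed %% 2147483647)
  for (nm in names(fix_hyper)) st[[nm]] <- fix_hyper[[nm]]
  fixed <- names(fix_hyper)
  n <- pre$n
  w <- 1 / (pre$var0 + st$tau^2)

  # initial fitted values and residual
  mu <- drop(pre$Xloc[, 1:2, drop = FALSE] %*% c(st$a_g, st$b_g)) + drop(pre$B %*% st$psi)
  resid <- pre$y - mu

  n_keep <- floor((iters - burnin) / thin)
  keep <- list(
    a = matrix(0, n_keep, pre$J), b = matrix(0, n_keep, pre$J),
    p = matrix(0, n_keep, pre$J), q = matrix(0, n_keep, pre$J),
    r = matrix(0, n_keep, pre$J),
    u = array(0, c(n_keep, pre$J, pre$T)),
    gamma = array(0, c(n_keep, pre$J, pre$Kc)),
    beta = matrix(0, n_keep, 4),
    hyper = matrix(0, n_keep, 27),
    ll = numeric(n_keep), iter = integer(n_keep),
    u_constraint_max = numeric(n_keep))
  colnames(keep$hyper) <- c(
    paste0("sd_a_", c("c", "r", "s")), paste0("sd_b_", c("c", "r", "s")),
    paste0("spline_sd_", c("c", "r", "s")),
    paste0("sd_p_", c("c", "r", "s")), paste0("sd_q_", c("c", "r", "s")),
    paste0("sd_r_", c("c", "r", "s")),
    paste0("lambda_", c("c", "r", "s", "g")),
    "v_n", "v_s", "v_c", "d_sd", "tau")
  ll_trace <- numeric(iters)
  acc <- c(lambda = 0, sd = 0, v = 0, tau = 0, asis = 0)
  try_n <- c(lambda = 0, sd = 0, v = 0, tau = 0, asis = 0)

  # --- grouped Gaussian block update over one hierarchy level ----------
  upd_grouped <- function(X, idx_list, coefs, prior_sds, name) {
    pp <- diag(1 / prior_sds^2, length(prior_sds))
    for (uu in seq_along(idx_list)) {
      ii <- idx_list[[uu]]
      Xi <- X[ii, , drop = FALSE]
      old <- coefs[uu, ]
      rp <- resid[ii] + drop(Xi %*% old)
      th <- draw_gauss_block(Xi, w[ii], rp, pp, name)
      resid[ii] <<- rp - drop(Xi %*% th)
      coefs[uu, ] <- th
    }
    coefs
  }
  upd_global <- function(X, old, name) {
    rp <- resid + drop(X %*% old)
    th <- draw_gauss_block(X, w, rp, matrix(0, ncol(X), ncol(X)), name)
    resid <<- rp - drop(X %*% th)
    th
  }
  upd_u_level <- function(Umat, idx_list, lam, name) {
    for (uu in seq_len(nrow(Umat))) {
      ii <- idx_list[[uu]]
      uvec <- Umat[uu, ]
      wt <- numeric(pre$T)
      rhs <- numeric(pre$T)
      if (length(ii)) {
        rp <- resid[ii] + uvec[pre$t[ii]]
        tmp <- rowsum(cbind(w[ii], w[ii] * rp), pre$t[ii])
        tix <- as.integer(rownames(tmp))
        wt[tix] <- tmp[, 1]
        rhs[tix] <- tmp[, 2]
      }
      unew <- draw_u_unit(pre$P, pre$pe, lam, wt, rhs, pre$A)
      if (length(ii)) resid[ii] <<- rp - unew[pre$t[ii]]
      Umat[uu, ] <- unew
    }
    Umat
  }
  upd_study_scalar <- function(vals, design, prior_prec_vec, name) {
    # vectorized scalar conjugate update, one value per study
    rp <- resid + vals[pre$study] * design
    sw <- rowsum(cbind(w * design^2, w * design * rp), pre$f_study)
    prec <- prior_prec_vec + sw[, 1]
    m <- sw[, 2] / prec
    new <- m + stats::rnorm(pre$S) / sqrt(prec)
    resid <<- rp - new[pre$study] * design
    new
  }
  mh_try <- function(kind, res_ok) {
    try_n[kind] <<- try_n[kind] + 1
    if (isTRUE(res_ok)) acc[kind] <<- acc[kind] + 1
  }

  stages <- c("loc", "u", "beta", "e", "d", "sweep", "asis", "var")
  for (it in seq_len(iters)) {
    order_now <- if (scan == "fixed") stages else sample(stages)
    for (stage in order_now) {
      switch(stage,
        loc = {
          # joint (a, b, p, q, r, spline) block per hierarchy unit: units
          # observed on partial age or stratum ranges induce strong
          # posterior correlation between their intercept, urban offset
          # and spline deviations, so these are sampled together
          th <- upd_global(pre$Xbig,
                           c(st$a_g, st$b_g, st$p_g, st$q_g, st$r_g,
                             st$psi), "a/b/p/q/r/spline global")
          st$a_g <- th[1]; st$b_g <- th[2]
          st$p_g <- th[3]; st$q_g <- th[4]; st$r_g <- th[5]
          st$psi <- th[-(1:5)]
          lv_sds <- function(li) c(st$sd_a[li], st$sd_b[li], st$sd_p[li],
                                   st$sd_q[li], st$sd_r[li],
                                   rep(st$spline_sd[li], pre$Kc))
          m <- upd_grouped(pre$Xbig, pre$idx_l,
                           cbind(st$a_s, st$b_s, st$p_s, st$q_s, st$r_s,
                                 st$spl_s), lv_sds(3),
                           "a/b/p/q/r/spline super-region")
          st$a_s <- m[, 1]; st$b_s <- m[, 2]
          st$p_s <- m[, 3]; st$q_s <- m[, 4]; st$r_s <- m[, 5]
          st$spl_s <- m[, -(1:5), drop = FALSE]
          m <- upd_grouped(pre$Xbig, pre$idx_k,
                           cbind(st$a_r, st$b_r, st$p_r, st$q_r, st$r_r,
                                 st$spl_r), lv_sds(2),
                           "a/b/p/q/r/spline region")
          st$a_r <- m[, 1]; st$b_r <- m[, 2]
          st$p_r <- m[, 3]; st$q_r <- m[, 4]; st$r_r <- m[, 5]
          st$spl_r <- m[, -(1:5), drop = FALSE]
          m <- upd_grouped(pre$Xbig, pre$idx_j,
                           cbind(st$a_c, st$b_c, st$p_c, st$q_c, st$r_c,
                                 st$spl_c), lv_sds(1),
                           "a/b/p/q/r/spline country")
          st$a_c <- m[, 1]; st$b_c <- m[, 2]
          st$p_c <- m[, 3]; st$q_c <- m[, 4]; st$r_c <- m[, 5]
          st$spl_c <- m[, -(1:5), drop = FALSE]
        },
        u = {
          st$u_g <- drop(upd_u_level(matrix(st$u_g, 1), list(seq_len(n)),
                                     st$lambda[["g"]], "u global"))
          st$u_s <- upd_u_level(st$u_s, pre$idx_l, st$lambda[["s"]],
                                "u super-region")
          st$u_r <- upd_u_level(st$u_r, pre$idx_k, st$lambda[["r"]],
                                "u region")
          st$u_c <- upd_u_level(st$u_c, pre$idx_j, st$lambda[["c"]],
                                "u country")
        },
        beta = {
          st$beta <- upd_global(pre$Xcov, st$beta, "beta coverage")
        },
        e = {
          st$e <- upd_study_scalar(st$e, rep(1, n),
                                   1 / st$v_sd[match(pre$stud_cov,
                                     c("national", "subnational",
                                       "community"))]^2, "e study")
        },
        d = {
          st$d <- upd_study_scalar(st$d, pre$I,
                                   rep(1 / st$d_sd^2, pre$S), "d study")
        },
        sweep = {
          # recentre the redundant additive splits; totals (and the
          # residual) are invariant under these moves
          fams <- list(
            list(c = "a_c", r = "a_r", s = "a_s", g = "a_g", sd = st$sd_a),
            list(c = "b_c", r = "b_r", s = "b_s", g = "b_g", sd = st$sd_b),
            list(c = "p_c", r = "p_r", s = "p_s", g = "p_g", sd = st$sd_p),
            list(c = "q_c", r = "q_r", s = "q_s", g = "q_g", sd = st$sd_q),
            list(c = "r_c", r = "r_r", s = "r_s", g = "r_g", sd = st$sd_r))
          for (fm in fams) {
            sw <- sweep_family(st[[fm$c]], st[[fm$r]], st[[fm$s]],
                               st[[fm$g]], fm$sd[1], fm$sd[2], fm$sd[3],
                               pre$j2k, pre$k2l)
            st[[fm$c]] <- sw$c; st[[fm$r]] <- sw$r
            st[[fm$s]] <- sw$s; st[[fm$g]] <- sw$g
          }
          for (kk in seq_len(pre$Kc)) {
            sw <- sweep_family(st$spl_c[, kk], st$spl_r[, kk],
                               st$spl_s[, kk], st$psi[kk],
                               st$spline_sd[1], st$spline_sd[2],
                               st$spline_sd[3], pre$j2k, pre$k2l)
            st$spl_c[, kk] <- sw$c; st$spl_r[, kk] <- sw$r
            st$spl_s[, kk] <- sw$s; st$psi[kk] <- sw$g
          }
          covf <- match(pre$stud_cov,
                        c("national", "subnational", "community"))
          sw <- sweep_effects(st$a_g, st$e, 1 / st$v_sd[covf]^2)
          st$a_g <- sw$g; st$e <- sw$eff
          sw <- sweep_effects(st$p_g, st$d, rep(1 / st$d_sd^2, pre$S))
          st$p_g <- sw$g; st$d <- sw$eff
        },
        asis = {
          # interweaved non-centred rescaling of the hierarchical SDs:
          # with standardized effects held fixed, each SD proposal rescales
          # its whole block and is accepted by the likelihood ratio
          covjkl <- list(pre$j, pre$k, pre$l)
          fams <- list(
            list(sd = "sd_a", comp = c("a_c", "a_r", "a_s"),
                 x = rep(1, n)),
            list(sd = "sd_b", comp = c("b_c", "b_r", "b_s"), x = pre$tc),
            list(sd = "sd_p", comp = c("p_c", "p_r", "p_s"), x = pre$I),
            list(sd = "sd_q", comp = c("q_c", "q_r", "q_s"),
                 x = pre$Xloc[, 4]),
            list(sd = "sd_r", comp = c("r_c", "r_r", "r_s"),
                 x = pre$Xloc[, 5]))
          for (fm in fams) {
            if (fm$sd %in% fixed) next
            for (li in 1:3) {
              comp <- st[[fm$comp[li]]]
              contrib <- comp[covjkl[[li]]] * fm$x
              r <- asis_scale(st[[fm$sd]][li], contrib, resid, w)
              mh_try("asis", r$accepted)
              resid <- r$resid
              if (r$rho != 1) st[[fm$comp[li]]] <- comp * r$rho
              st[[fm$sd]][li] <- r$sd
            }
          }
          if (!"spline_sd" %in% fixed) {
            mats <- c("spl_c", "spl_r", "spl_s")
            for (li in 1:3) {
              comp <- st[[mats[li]]]
              contrib <- rowSums(pre$B * comp[covjkl[[li]], , drop = FALSE])
              r <- asis_scale(st$spline_sd[li], contrib, resid, w)
              mh_try("asis", r$accepted)
              resid <- r$resid
              if (r$rho != 1) st[[mats[li]]] <- comp * r$rho
              st$spline_sd[li] <- r$sd
            }
          }
        },
        var = {
          sd_one <- function(cur, vals) {
            r <- mh_sd_flat(cur, vals)
            mh_try("sd", r$accepted)
            r$sd
          }
          if (!"sd_a" %in% fixed)
            st$sd_a <- c(sd_one(st$sd_a[1], st$a_c),
                         sd_one(st$sd_a[2], st$a_r),
                         sd_one(st$sd_a[3], st$a_s))
          if (!"sd_b" %in% fixed)
            st$sd_b <- c(sd_one(st$sd_b[1], st$b_c),
                         sd_one(st$sd_b[2], st$b_r),
                         sd_one(st$sd_b[3], st$b_s))
          if (!"spline_sd" %in% fixed)
            st$spline_sd <- c(sd_one(st$spline_sd[1], c(st$spl_c)),
                              sd_one(st$spline_sd[2], c(st$spl_r)),
                              sd_one(st$spline_sd[3], c(st$spl_s)))
          if (!"sd_p" %in% fixed)
            st$sd_p <- c(sd_one(st$sd_p[1], st$p_c),
                         sd_one(st$sd_p[2], st$p_r),
                         sd_one(st$sd_p[3], st$p_s))
          if (!"sd_q" %in% fixed)
            st$sd_q <- c(sd_one(st$sd_q[1], st$q_c),
                         sd_one(st$sd_q[2], st$q_r),
                         sd_one(st$sd_q[3], st$q_s))
          if (!"sd_r" %in% fixed)
            st$sd_r <- c(sd_one(st$sd_r[1], st$r_c),
                         sd_one(st$sd_r[2], st$r_r),
                         sd_one(st$sd_r[3], st$r_s))
          if (!"lambda" %in% fixed) {
            quads <- c(
              c = sum(rowSums((st$u_c %*% pre$P) * st$u_c)),
              r = sum(rowSums((st$u_r %*% pre$P) * st$u_r)),
              s = sum(rowSums((st$u_s %*% pre$P) * st$u_s)),
              g = drop(crossprod(st$u_g, pre$P %*% st$u_g)))
            nu <- c(c = pre$J, r = pre$K, s = pre$L, g = 1)
            for (lv in c("c", "r", "s", "g")) {
              r <- mh_lambda(st$lambda, lv, quads[[lv]], nu[[lv]], pre$T,
                             bound = pre$spec$loglambda_max)
              mh_try("lambda", r$accepted)
              st$lambda <- r$lambda
            }
          }
          if (!"v_sd" %in% fixed) {
            # collapsed update: study effects integrated out, then redrawn
            covf <- match(pre$stud_cov,
                          c("national", "subnational", "community"))
            rp <- resid + st$e[pre$study]
            Wi <- rowsum(w, pre$f_study)[, 1]
            mi <- rowsum(w * rp, pre$f_study)[, 1] / Wi
            for (ci in 1:3) {
              sel <- covf == ci
              r <- mh_sd_marginal(st$v_sd[ci], mi[sel], 1 / Wi[sel],
                                  lower = if (ci > 1) st$v_sd[ci - 1] else 0,
                                  upper = if (ci < 3) st$v_sd[ci + 1] else Inf)
              if (!is.na(r$accepted)) mh_try("v", r$accepted)
              st$v_sd[ci] <- r$sd
            }
            st$e <- upd_study_scalar(st$e, rep(1, n),
                                     1 / st$v_sd[covf]^2, "e study")
          }
          if (!"d_sd" %in% fixed) {
            rp <- resid + st$d[pre$study] * pre$I
            Wd <- rowsum(w * pre$I^2, pre$f_study)[, 1]
            info <- Wd > 1e-12
            md <- rowsum(w * pre$I * rp, pre$f_study)[, 1] / pmax(Wd, 1e-12)
            r <- mh_sd_marginal(st$d_sd, md[info], 1 / Wd[info])
            if (!is.na(r$accepted)) mh_try("sd", r$accepted)
            st$d_sd <- r$sd
            st$d <- upd_study_scalar(st$d, pre$I,
                                     rep(1 / st$d_sd^2, pre$S), "d study")
          }
          if (!"tau" %in% fixed) {
            r <- mh_tau(st$tau, resid, pre$var0)
            mh_try("tau", r$accepted)
            if (r$tau != st$tau) {
              st$tau <- r$tau
              w <- 1 / (pre$var0 + st$tau^2)
            }
          }
        })
      if (!all(is.finite(resid)))
        stop("non-finite values after update stage '", stage,
             "' at iteration ", it)
    }
    vv <- pre$var0 + st$tau^2
    ll_trace[it] <- -0.5 * sum(log(2 * pi * vv) + resid^2 / vv)

    if (it > burnin && (it - burnin) %% thin == 0) {
      kk <- (it - burnin) %/% thin
      a_j <- st$a_c + st$a_r[pre$j2k] + st$a_s[pre$k2l[pre$j2k]] + st$a_g
      b_j <- st$b_c + st$b_r[pre$j2k] + st$b_s[pre$k2l[pre$j2k]] + st$b_g
      p_j <- st$p_c + st$p_r[pre$j2k] + st$p_s[pre$k2l[pre$j2k]] + st$p_g
      q_j <- st$q_c + st$q_r[pre$j2k] + st$q_s[pre$k2l[pre$j2k]] + st$q_g
      r_j <- st$r_c + st$r_r[pre$j2k] + st$r_s[pre$k2l[pre$j2k]] + st$r_g
      keep$a[kk, ] <- a_j; keep$b[kk, ] <- b_j
      keep$p[kk, ] <- p_j; keep$q[kk, ] <- q_j; keep$r[kk, ] <- r_j
      keep$u[kk, , ] <- st$u_c + st$u_r[pre$j2k, , drop = FALSE] +
        st$u_s[pre$k2l[pre$j2k], , drop = FALSE] +
        matrix(st$u_g, pre$J, pre$T, byrow = TRUE)
      keep$gamma[kk, , ] <- sweep(st$spl_c +
          st$spl_r[pre$j2k, , drop = FALSE] +
          st$spl_s[pre$k2l[pre$j2k], , drop = FALSE], 2, st$psi, "+")
      keep$beta[kk, ] <- st$beta
      keep$hyper[kk, ] <- c(st$sd_a, st$sd_b, st$spline_sd, st$sd_p,
                            st$sd_q, st$sd_r, st$lambda, st$v_sd,
                            st$d_sd, st$tau)
      keep$ll[kk] <- ll_trace[it]
      keep$iter[kk] <- it
      allu <- rbind(st$u_c, st$u_r, st$u_s, st$u_g)
      tcg <- pre$A[2, ]
      keep$u_constraint_max[kk] <- max(abs(rowMeans(allu)),
        abs(allu %*% tcg) / sum(tcg^2))
    }
  }
  keep$ll_trace <- ll_trace
  keep$acc <- ifelse(try_n > 0, acc / try_n, NA)
  keep
}

combine_chains <- function(res, pre, chains, iters, burnin, thin, seed) {
  n_keep <- floor((iters - burnin) / thin)
  bindmat <- function(nm) do.call(rbind, lapply(res, `[[`, nm))
  bindarr <- function(nm) {
    out <- array(0, c(chains * n_keep, dim(res[[1]][[nm]])[-1]))
    for (ch in seq_len(chains))
      out[(ch - 1) * n_keep + seq_len(n_keep), , ] <- res[[ch]][[nm]]
    out
  }
  structure(list(
    a = bindmat("a"), b = bindmat("b"), p = bindmat("p"),
    q = bindmat("q"), r = bindmat("r"),
    u = bindarr("u"), gamma = bindarr("gamma"), beta = bindmat("beta"),
    hyper = bindmat("hyper"),
    ll = unlist(lapply(res, `[[`, "ll")),
    iter = unlist(lapply(res, `[[`, "iter")),
    chain = rep(seq_len(chains), each = n_keep),
    u_constraint_max = unlist(lapply(res, `[[`, "u_constraint_max")),
    ll_trace = vapply(res, `[[`, numeric(iters), "ll_trace"),
    acc = do.call(rbind, lapply(res, `[[`, "acc")),
    chains = chains, iters = iters, burnin = burnin, thin = thin,
    n_draws = chains * n_keep, seed = seed,
    countries = pre$hierarchy$countries),
    class = "gmr_draws")
}

#' @export
print.gmr_draws <- function(x, ...) {
  cat("Posterior draws:", x$n_draws, "retained (", x$chains, "chains x",
      x$iters, "iters, burn-in", x$burnin, ", thin", x$thin, ")\n")
  invisible(x)
}
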