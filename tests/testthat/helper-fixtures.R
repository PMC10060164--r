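# Shared fixtures, built in code.

# Tiny BMI world: 8 countries, 8 years, 8 ages. Cheap to generate and fit.
tiny_world_spec <- function(...) {
  gmr_world_spec(n_super = 2, n_region = 2, n_country = 2,
                 outcome = "bmi", years = 2000:2007,
                 ages = seq(5, 19, 2), ...)
}

# Lazily cached small fitted model shared by output-method tests.
.fit_cache <- new.env(parent = emptyenv())
cached_tiny_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    w <- generate_world(tiny_world_spec(), seed = 8)
    recs <- generate_studies(w, 40, n_per_age = 300, seed = 8)
    d <- gmr_data(recs, w$hierarchy, w$spec)
    .fit_cache$world <- w
    .fit_cache$fit <- suppressWarnings(
      gmr_fit(d, chains = 2, iters = 400, burnin = 200, thin = 5, seed = 3))
  }
  list(world = .fit_cache$world, fit = .fit_cache$fit)
}

# A 12-row participant roster with 3 planted plausibility violations
# (one per age band), used by the filter tests; the expected outcome was
# worked out row by row against the banded thresholds.
toy_roster <- function() {
  data.frame(
    age = c(6, 7, 9, 9, 11, 12, 14, 15, 16, 17, 18, 19),
    sex = rep(c("female", "male"), 6),
    height = c(115, 120, 59,  135, 140, 150, 199, 165, 170, 172, 251, 174),
    #                    ^ <60 under 10          (199 ok 10-14)   ^ >250 15+
    weight = c(20, 22, 28, 30, 35, 151, 50, 55, 60, 64, 68, 70),
    #                              ^ >150 in 10-14 band
    pregnant = FALSE)
}

# Weighted isotonic fit by brute force: enumerate every partition of the
# sequence into contiguous blocks, fit each block at its weighted mean,
# keep the feasible (nondecreasing) fits, return the one with least
# weighted squared error. Independent of the pool-adjacent-violators path.
brute_isotonic <- function(x, w = rep(1, length(x))) {
  n <- length(x)
  if (n == 0) return(x)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      ii <- (bounds[b] + 1):bounds[b + 1]
      fit[ii] <- sum(w[ii] * x[ii]) / sum(w[ii])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (fit - x)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Stratified cluster-bootstrap SE oracle (Rao-Wu): resample n_h - 1
# clusters per stratum with replacement, rescaling weights by
# n_h / (n_h - 1).
bootstrap_se <- function(df, variable, reps = 2000) {
  strat <- split(seq_len(nrow(df)), df$stratum_id)
  means <- replicate(reps, {
    idx <- c(); mult <- c()
    for (ii in strat) {
      cl <- split(ii, df$cluster_id[ii])
      nh <- length(cl)
      pick <- sample(nh, nh - 1, replace = TRUE)
      for (ci in pick) {
        idx <- c(idx, cl[[ci]])
        mult <- c(mult, rep(nh / (nh - 1), length(cl[[ci]])))
      }
    }
    wgt <- df$sample_weight[idx] * mult
    sum(wgt * df[[variable]][idx]) / sum(wgt)
  })
  stats::sd(means)
}
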