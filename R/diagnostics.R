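#' Split R-hat convergence diagnostic
#'
#' Gelman-Rubin potential scale reduction computed on split half-chains:
#' each chain is cut in half, and with `m` half-chains of length `n`,
#' within-chain variance `W` (mean of the half-chain variances) and
#' between-chain variance `B` (n times the variance of half-chain means),
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n \, W + B/n}{W}}.}
#' Values near 1 indicate the chains agree; splitting also catches a single
#' drifting chain. All-constant traces have `W = 0` and an undefined ratio;
#' they are flagged as `Inf` with a warning rather than silently reported
#' as 1.
#'
#' @param traces a list of numeric vectors (one per chain), or a matrix
#'   with one column per chain. Chains of odd length drop their last
#'   element before splitting.
#' @return scalar R-hat (possibly `Inf` for degenerate traces).
#' @export
split_rhat <- function(traces) {
  if (is.matrix(traces)) traces <- lapply(seq_len(ncol(traces)),
                                          function(i) traces[, i])
  stopifnot(is.list(traces), length(traces) >= 1)
  halves <- list()
  for (tr in traces) {
    if (length(tr) < 4) stop("each chain needs length >= 4")
    n2 <- (length(tr) %/% 2) * 2
    tr <- tr[seq_len(n2)]
    halves <- c(halves, list(tr[seq_len(n2 / 2)]),
                list(tr[n2 / 2 + seq_len(n2 / 2)]))
  }
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0 || !is.finite(W)) {
    if (B > 0) {
      warning("within-chain variance is zero with nonzero between-chain ",
              "variance; R-hat undefined, reported as Inf")
      return(Inf)
    }
    warning("all-constant traces: R-hat undefined, reported as Inf")
    return(Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Automated burn-in screen: select chains with stationary log likelihood
#'
#' Keeps chains whose log-likelihood trace, after the burn-in window, looks
#' stationary: the difference between the means of its first and second
#' halves must be below `tol` times the post-window standard deviation.
#' This is the automated stand-in for visually inspecting trace plots to
#' drop chains that have not completed burn-in within the window.
#'
#' @param traces list of per-chain numeric log-likelihood traces, or a
#'   matrix with one column per chain (full traces, including burn-in).
#' @param window number of initial iterations regarded as the burn-in
#'   allowance.
#' @param tol stationarity tolerance (default 0.2).
#' @return object of class `gmr_chain_report`: list with `kept` (integer
#'   chain ids), `dropped`, `reason` (per chain), `failed` (TRUE if no
#'   chain passed).
#' @export
select_chains <- function(traces, window, tol = 0.2) {
  if (is.matrix(traces)) traces <- lapply(seq_len(ncol(traces)),
                                          function(i) traces[, i])
  stopifnot(length(traces) >= 2)
  verdict <- vapply(seq_along(traces), function(ci) {
    tr <- traces[[ci]]
    if (window >= length(tr) - 3) return("window leaves too few iterations")
    post <- tr[(window + 1):length(tr)]
    h <- length(post) %/% 2
    d <- abs(mean(post[seq_len(h)]) - mean(post[(h + 1):(2 * h)]))
    s <- stats::sd(post)
    if (s == 0 || d <= tol * s) "stationary" else "drift after window"
  }, character(1))
  kept <- which(verdict == "stationary")
  rep <- structure(list(kept = kept,
                        dropped = setdiff(seq_along(traces), kept),
                        reason = verdict,
                        failed = length(kept) == 0),
                   class = "gmr_chain_report")
  if (rep$failed) warning("no chain passed the stationarity screen")
  rep
}

#' @export
print.gmr_chain_report <- function(x, ...) {
  cat("Chain selection:", length(x$kept), "kept,", length(x$dropped),
      "dropped\n")
  for (i in seq_along(x$reason))
    cat("  chain ", i, ": ", x$reason[i], "\n", sep = "")
  invisible(x)
}

#' Write a convergence report as JSON
#'
#' @param rhats named numeric vector of per-quantity R-hats.
#' @param chain_report a `gmr_chain_report` from [select_chains()].
#' @param n_draws retained draw count.
#' @param path output file.
#' @export
write_convergence_report <- function(rhats, chain_report, n_draws, path) {
  jsonlite::write_json(list(rhat = as.list(rhats),
                            kept_chains = chain_report$kept,
                            dropped_chains = chain_report$dropped,
                            reasons = chain_report$reason,
                            failed = chain_report$failed,
                            n_draws = n_draws),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Thin retained draws
#'
#' Keeps, within each chain, iterations at positions that are multiples of
#' `step`, preserving order and chain labels.
#'
#' @param draws a `gmr_draws` object, or a list of per-chain vectors.
#' @param step thinning step (>= 1).
#' @return object of the same shape, thinned.
#' @export
thin_draws <- function(draws, step) {
  stopifnot(step >= 1)
  step <- as.integer(step)
  if (inherits(draws, "gmr_draws")) {
    keep <- unlist(lapply(split(seq_along(draws$chain), draws$chain),
                          function(ii) ii[seq_along(ii) %% step == 0]))
    keep <- sort(keep)
    if (length(keep) == 0)
      warning("thinning step exceeds chain length: no draws retained")
    return(subset_draws(draws, keep))
  }
  out <- lapply(draws, function(v) v[seq_along(v) %% step == 0])
  if (any(lengths(out) == 0))
    warning("thinning step exceeds chain length: empty chain(s)")
  out
}

# Subset a gmr_draws object by retained-draw index.
subset_draws <- function(draws, keep) {
  d <- draws
  for (nm in c("a", "b", "p", "q", "r", "beta", "hyper"))
    d[[nm]] <- d[[nm]][keep, , drop = FALSE]
  for (nm in c("u", "gamma")) d[[nm]] <- d[[nm]][keep, , , drop = FALSE]
  for (nm in c("ll", "iter", "chain", "u_constraint_max"))
    d[[nm]] <- d[[nm]][keep]
  d$n_draws <- length(keep)
  d
}
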