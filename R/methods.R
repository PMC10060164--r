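#' @export
print.gmr_fit <- function(x, ...) {
  cat("Hierarchical meta-regression fit (", x$spec$outcome, ", ",
      x$spec$sex, ")\n", sep = "")
  print(x$data)
  print(x$draws)
  invisible(x)
}

#' Posterior means of country-level parameters
#'
#' @param object a `gmr_fit`.
#' @param ... unused.
#' @return matrix with one row per country: intercept `a`, time slope `b`,
#'   urban-rural offset intercept `p`, its time slope `q` and age slope
#'   `r` (the urban-minus-rural gap is twice the offset).
#' @export
coef.gmr_fit <- function(object, ...) {
  dr <- object$draws
  out <- cbind(a = colMeans(dr$a), b = colMeans(dr$b),
               p = colMeans(dr$p), q = colMeans(dr$q), r = colMeans(dr$r))
  rownames(out) <- dr$countries
  out
}

#' Summarize a fit: hyperparameters, convergence, acceptance
#'
#' Posterior summaries of the variance hyperparameters, split R-hat of the
#' log likelihood and of each country intercept, and Metropolis acceptance
#' rates.
#'
#' @param object a `gmr_fit`.
#' @param ... unused.
#' @return object of class `summary.gmr_fit`.
#' @export
summary.gmr_fit <- function(object, ...) {
  dr <- object$draws
  hyp <- summarize_draws(dr$hyper)
  rownames(hyp) <- colnames(dr$hyper)
  by_chain <- function(v) split(v, dr$chain)
  rhats <- c(loglik = split_rhat(by_chain(dr$ll)),
             stats::setNames(vapply(seq_len(ncol(dr$a)), function(j)
               split_rhat(by_chain(dr$a[, j])), numeric(1)),
               paste0("a_", dr$countries)))
  structure(list(hyper = hyp, rhat = rhats,
                 acceptance = colMeans(dr$acc, na.rm = TRUE),
                 n_draws = dr$n_draws,
                 u_constraint_max = max(dr$u_constraint_max)),
            class = "summary.gmr_fit")
}

#' @export
print.summary.gmr_fit <- function(x, ...) {
  cat("Hyperparameter posteriors:\n")
  print(round(x$hyper, 4))
  cat("\nSplit R-hat: log-likelihood", round(x$rhat[["loglik"]], 3),
      "; country intercepts max",
      round(max(x$rhat[-1]), 3), "\n")
  cat("Metropolis acceptance:",
      paste(names(x$acceptance), round(x$acceptance, 2),
            sep = "=", collapse = ", "), "\n")
  cat("Max RW2 constraint residual:",
      format(x$u_constraint_max, digits = 3), "\n")
  invisible(x)
}

#' @export
logLik.gmr_fit <- function(object, ...) {
  structure(mean(object$draws$ll), class = "logLik",
            df = NA_integer_, nobs = nrow(object$data$obs))
}

#' Trace plot of the log likelihood
#'
#' @param x a `gmr_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.gmr_fit <- function(x, ...) {
  graphics::matplot(x$draws$ll_trace, type = "l", lty = 1,
                    xlab = "iteration", ylab = "log likelihood", ...)
  graphics::abline(v = x$draws$burnin, lty = 2)
  invisible(x)
}
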