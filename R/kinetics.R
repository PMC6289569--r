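# Pseudo-first-order ligation kinetics: least-squares fit of
# y(t) = plateau * (1 - exp(-k_obs * t)).

#' Fit pseudo-first-order ligation kinetics
#'
#' Fits yield-versus-time data to a single-exponential approach to plateau,
#' y(t) = plateau * (1 - exp(-k_obs * t)), by Levenberg-Marquardt least
#' squares with bounds plateau in \[0, 1\] and k_obs >= 0.
#'
#' @param timepoints numeric vector of times (>= 3 points).
#' @param yields ligated fractions in \[0, 1\], same length as `timepoints`.
#' @return a `kinetics_fit` object with elements `k_obs` (1/time unit),
#'   `plateau`, `residual_norm`, `converged` and `flag` (`NA` or a note,
#'   e.g. when all yields are zero and `k_obs` is indeterminate).
#' @export
fit_ligation_kinetics <- function(timepoints, yields) {
  stopifnot(length(timepoints) == length(yields))
  if (length(timepoints) < 3) abort("at least 3 timepoints are required")
  if (any(yields < -1e-9) || any(yields > 1 + 1e-9)) {
    abort("yields must be fractions in [0, 1]")
  }
  if (all(abs(yields) < 1e-12)) {
    out <- list(k_obs = NA_real_, plateau = 0, residual_norm = 0,
                converged = TRUE, flag = "all yields zero; k_obs indeterminate",
                fit = NULL, data = tibble(t = timepoints, y = yields))
    class(out) <- "kinetics_fit"
    return(out)
  }
  df <- data.frame(t = timepoints, y = yields)
  p0 <- min(max(max(yields), 1e-3), 1)
  # multi-start over rate scales: the SSE surface has a shallow local
  # optimum at (plateau -> 1, small k) that a single poor start can hit
  t_scale <- stats::median(timepoints[timepoints > 0])
  k0s <- 10^seq(-2.5, 1.5, length.out = 9) / max(t_scale, 1e-12)
  fits <- lapply(k0s, function(k0) {
    tryCatch(
      minpack.lm::nlsLM(y ~ plateau * (1 - exp(-k * t)), data = df,
                        start = list(plateau = p0, k = k0),
                        lower = c(0, 0), upper = c(1, Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0) abort("kinetics fit did not converge from any start")
  sse <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  fit <- fits[[which.min(sse)]]
  est <- coef(fit)
  flag <- NA_character_
  if (est[["plateau"]] >= 1 - 1e-9 || est[["k"]] <= 1e-12) {
    flag <- "estimate at parameter bound"
    warn(sprintf("kinetics fit hit a parameter bound (plateau = %.3g, k_obs = %.3g)",
                 est[["plateau"]], est[["k"]]))
  }
  out <- list(k_obs = unname(est[["k"]]), plateau = unname(est[["plateau"]]),
              residual_norm = sqrt(sum(resid(fit)^2)), converged = TRUE,
              flag = flag, fit = fit, data = as_tibble(df))
  class(out) <- "kinetics_fit"
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit> y(t) = plateau * (1 - exp(-k_obs t))\n")
  cat(sprintf("  k_obs = %s, plateau = %.4f, residual norm = %.3g\n",
              format(x$k_obs), x$plateau, x$residual_norm))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kinetics_fit <- function(x, ...) {
  tibble(term = c("k_obs", "plateau"),
         estimate = c(x$k_obs, x$plateau))
}

#' @exportS3Method generics::glance
glance.kinetics_fit <- function(x, ...) {
  tibble(k_obs = x$k_obs, plateau = x$plateau,
         residual_norm = x$residual_norm,
         n = nrow(x$data), converged = x$converged, flag = x$flag)
}

#' @exportS3Method ggplot2::autoplot
autoplot.kinetics_fit <- function(object, ...) {
  df <- object$data
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time", y = "ligated fraction")
  if (!is.na(object$k_obs)) {
    grid <- tibble(t = seq(min(df$t), max(df$t), length.out = 200))
    grid$y <- object$plateau * (1 - exp(-object$k_obs * grid$t))
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
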