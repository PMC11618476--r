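# Johnson SU distribution fitted by moment matching.  If Z ~ N(0,1), then
# X = xi + lambda * sinh((Z - gamma) / delta) is Johnson SU; with
# a = -gamma/delta and b = 1/delta, Y = sinh(a + bZ) has closed-form raw
# moments via E[exp(tZ)] = exp(t^2/2), which makes moment matching exact and
# cheap: skewness and kurtosis depend on (a, b) only, then lambda and xi are
# read off from the target sd and mean.

ju_y_moments <- function(a, b) {
  m1 <- exp(b^2 / 2) * sinh(a)
  m2 <- (exp(2 * b^2) * cosh(2 * a) - 1) / 2
  m3 <- (exp(9 * b^2 / 2) * sinh(3 * a) - 3 * exp(b^2 / 2) * sinh(a)) / 4
  m4 <- (exp(8 * b^2) * cosh(4 * a) - 4 * exp(2 * b^2) * cosh(2 * a) + 3) / 8
  var <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  list(mean = m1, var = var, skew = mu3 / var^1.5, kurt = mu4 / var^2)
}

#' Fit a Johnson SU distribution by moment matching
#'
#' Finds the SU member whose first four moments match the targets.  Shape is
#' solved numerically from skewness and kurtosis (closed-form moments of the
#' sinh-normal make the objective exact); location and scale follow
#' analytically.  The SU family only reaches kurtosis above the
#' skewness-dependent lower boundary (e.g. kurtosis > 3 at zero skewness);
#' when the targets fall outside, or the solver fails, `fit_ok` is `FALSE`
#' and callers should fall back to a normal with the target mean and sd.
#'
#' @param mean,sd,skew,kurt target moments (`kurt` is ordinary kurtosis,
#'   3 for a normal).
#' @return a `johnson_su` parameter object: list with `gamma`, `delta`,
#'   `xi`, `lambda`, `fit_ok`, plus the achieved `moments`.
#' @export
johnson_su_fit <- function(mean, sd, skew, kurt) {
  fail <- structure(list(gamma = NA_real_, delta = NA_real_, xi = mean,
                         lambda = sd, fit_ok = FALSE, moments = NULL),
                    class = "johnson_su")
  if (!all(is.finite(c(mean, sd, skew, kurt))) || sd <= 0) return(fail)
  if (kurt <= skew^2 + 1 + 1e-8) return(fail)  # outside any distribution
  obj <- function(par) {
    a <- par[1]; b <- exp(par[2])
    mom <- ju_y_moments(a, b)
    if (!all(is.finite(c(mom$skew, mom$kurt)))) return(1e10)
    (mom$skew - skew)^2 + (mom$kurt - kurt)^2
  }
  best <- NULL
  for (start in list(c(-sign(skew) * 0.5, log(0.5)),
                     c(-sign(skew) * 0.1, log(0.2)),
                     c(0, log(1)))) {
    fit <- try(stats::optim(start, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-14)),
               silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value > 1e-6) return(fail)
  a <- best$par[1]; b <- exp(best$par[2])
  mom <- ju_y_moments(a, b)
  lambda <- sd / sqrt(mom$var)
  xi <- mean - lambda * mom$mean
  delta <- 1 / b
  gamma <- -a * delta
  structure(list(gamma = gamma, delta = delta, xi = xi, lambda = lambda,
                 fit_ok = TRUE,
                 moments = list(mean = xi + lambda * mom$mean,
                                sd = lambda * sqrt(mom$var),
                                skew = mom$skew, kurt = mom$kurt)),
            class = "johnson_su")
}

#' Johnson SU distribution functions
#'
#' CDF, density and quantile for a fitted [johnson_su_fit()] parameter set.
#'
#' @param q,x,p usual distribution arguments.
#' @param par a `johnson_su` object with `fit_ok = TRUE`.
#' @return numeric vector.
#' @export
pjohnson_su <- function(q, par) {
  stats::pnorm(par$gamma + par$delta * asinh((q - par$xi) / par$lambda))
}

#' @rdname pjohnson_su
#' @export
djohnson_su <- function(x, par) {
  u <- (x - par$xi) / par$lambda
  par$delta / (par$lambda * sqrt(u^2 + 1)) *
    stats::dnorm(par$gamma + par$delta * asinh(u))
}

#' @rdname pjohnson_su
#' @export
qjohnson_su <- function(p, par) {
  par$xi + par$lambda * sinh((stats::qnorm(p) - par$gamma) / par$delta)
}

#' @export
print.johnson_su <- function(x, ...) {
  if (x$fit_ok)
    cat(sprintf("Johnson SU(gamma = %.3f, delta = %.3f, xi = %.3f, lambda = %.3f)\n",
                x$gamma, x$delta, x$xi, x$lambda))
  else
    cat("Johnson SU fit failed (moments outside SU region); normal fallback\n")
  invisible(x)
}
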