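#' Exponential and saturation least-squares fits
#'
#' Fits one of three functional forms by Levenberg-Marquardt least
#' squares:
#' \describe{
#'   \item{decay}{`y = y_inf + A * exp(-x / tau)`}
#'   \item{rise}{`y = y_inf - A * exp(-x / tau)`}
#'   \item{saturation}{`y = A * (1 - exp(-x / k))` (e.g. recovery versus
#'     co-illumination power density, `k` the saturation constant)}
#' }
#'
#' @param x Strictly increasing predictor (time or power).
#' @param y Response.
#' @param form One of `"decay"`, `"rise"`, `"saturation"`.
#' @return A `fit_result` list: `form`, `converged`, and on convergence
#'   `parameters` (named vector), `se` (1-sigma uncertainties),
#'   `residual_norm`, `fitted`.
#' @export
fit_exponential <- function(x, y, form = c("decay", "rise", "saturation")) {
  form <- match.arg(form)
  if (length(x) < 4) stop("need at least 4 points")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  failed <- function() structure(list(form = form, converged = FALSE),
                                 class = "fit_result")
  span <- diff(range(y))
  if (span < 1e-12 * max(abs(y), 1)) return(failed())  # flat: unidentifiable

  df <- data.frame(x = x, y = y)
  try_fit <- function(start) {
    tryCatch({
      f <- if (form == "saturation")
        minpack.lm::nlsLM(y ~ A * (1 - exp(-x / k)), data = df,
                          start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      else
        minpack.lm::nlsLM(y ~ yinf + s * A * exp(-x / tau),
                          data = cbind(df, s = if (form == "rise") -1 else 1),
                          start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      if (f$convInfo$isConv) f else NULL
    }, error = function(e) NULL)
  }
  if (form == "saturation") {
    starts <- list(list(A = max(y), k = max(x) / 3),
                   list(A = max(y) * 1.05, k = max(x) / 10),
                   list(A = max(y) * 1.05, k = max(x)))
  } else {
    yinf0 <- if (form == "rise") max(y) else min(y)
    ## data-driven time-constant guess: abscissa where the transient has
    ## covered half its range
    half <- (max(y) + min(y)) / 2
    ih <- if (form == "rise") which(y >= half)[1] else which(y <= half)[1]
    tau0 <- if (!is.na(ih) && ih > 1) x[ih] / log(2) else diff(range(x)) / 3
    starts <- list(list(yinf = yinf0, A = abs(span), tau = tau0),
                   list(yinf = yinf0, A = abs(span), tau = diff(range(x)) / 3),
                   list(yinf = yinf0, A = abs(span), tau = tau0 / 10))
  }
  fit <- NULL
  for (s in starts) { fit <- try_fit(s); if (!is.null(fit)) break }
  if (is.null(fit)) return(failed())
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(cf)))
  structure(list(form = form, converged = TRUE,
                 parameters = cf, se = se,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$form, if (!x$converged) "(did not converge)", "\n")
  if (x$converged)
    print(data.frame(estimate = x$parameters, se = x$se))
  invisible(x)
}

#' Write a fit result as JSON
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
fit_to_json <- function(fit, path) {
  jsonlite::write_json(list(form = fit$form, converged = fit$converged,
                            parameters = as.list(fit$parameters),
                            se = as.list(fit$se),
                            residual_norm = fit$residual_norm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
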