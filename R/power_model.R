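#' Cyclical power model predictions
#'
#' Predicted placing position for a two-digit target under the modified
#' cyclical power model. The target is decomposed into its decade part
#' \eqn{x_d} and unit digit \eqn{x_u}; the unit digit enters through a
#' power weight \eqn{\delta} (\eqn{\delta < 1} compresses its
#' contribution, the left-digit bias), and the transformed magnitude
#' \eqn{s = x_d + x_u^\delta} is bent around the segment anchors with
#' curvature \eqn{\beta}:
#' \deqn{y = \frac{(s - LB)^\beta}{(s - LB)^\beta + (UB - s)^\beta}
#'   (UB - LB) + LB}
#' In the two-cycle structure the line is split at its midpoint
#' (\eqn{LB = 0, UB = 50} for targets \eqn{\le 50}, else
#' \eqn{LB = 50, UB = 100}), so 0, 50 and 100 all act as anchors; the
#' one-cycle structure uses the single segment \eqn{LB = 0, UB = 100}.
#' At \eqn{\beta = 1, \delta = 1} the model is the identity.
#'
#' Segment membership is decided by the raw target value. If the
#' transformed \eqn{s} leaves its segment (possible only for
#' \eqn{\delta} well above 1, i.e. optimizer excursions), it is clamped
#' just inside the boundary.
#'
#' @param target numeric vector of targets in (0, 100].
#' @param beta curvature, > 0.
#' @param delta unit-digit power weight; recycled along `target`, so
#'   group-specific effective weights can be passed per observation.
#' @param cycles `"two"` (default) or `"one"`.
#' @return Numeric vector of predicted placing positions.
#' @examples
#' cpm_predict(28, beta = 1, delta = 1)       # 28 (identity)
#' cpm_predict(29, beta = 0.9, delta = 0.83)  # about 26.08
#' @export
cpm_predict <- function(target, beta, delta, cycles = c("two", "one")) {
  cycles <- match.arg(cycles)
  if (beta <= 0) stop("beta must be > 0")
  xd <- decade_part(target)
  xu <- target - xd
  s <- xd + ifelse(xu > 0, xu^delta, 0)
  if (cycles == "two") {
    LB <- ifelse(target <= 50, 0, 50)
    UB <- LB + 50
  } else {
    LB <- rep(0, length(target))
    UB <- rep(100, length(target))
  }
  eps <- 1e-9
  s <- pmin(pmax(s, LB + eps), UB - eps)
  a <- (s - LB)^beta
  b <- (UB - s)^beta
  a / (a + b) * (UB - LB) + LB
}

#' Median placing positions per language and target
#'
#' Pools all retained responses of all participants of a language (both
#' orientations) and takes the median per target; even response counts
#' yield the midpoint of the two central values. Teens are excluded by
#' default: the model is built on targets > 20. As an alternative pooling,
#' `"by_participant"` takes each participant's median first and then the
#' median of those.
#'
#' @param trials analysable trials (see [analysis_trials()]); an
#'   `nle_data` object is accepted.
#' @param min_target smallest target retained (default 21).
#' @param pooling `"pooled"` (default) or `"by_participant"`.
#' @return Data frame with columns `language`, `target`, `x_d`, `x_u`,
#'   `median_position`, `n_responses`, suitable for [fit_power_model()].
#' @export
prepare_medians <- function(trials, min_target = 21,
                            pooling = c("pooled", "by_participant")) {
  pooling <- match.arg(pooling)
  t <- analysis_trials(trials)
  t <- t[t$target >= min_target, , drop = FALSE]
  if (!nrow(t)) stop("no retained trials with target >= ", min_target)
  key <- interaction(t$language, t$target, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(t)), key), function(i) {
    med <- if (pooling == "pooled") {
      stats::median(t$placing_position[i])
    } else {
      stats::median(tapply(t$placing_position[i], t$participant_id[i],
                           stats::median))
    }
    data.frame(language = t$language[i[1]], target = t$target[i[1]],
               median_position = med, n_responses = length(i))
  })
  m <- do.call(rbind, rows)
  m <- m[order(m$language, m$target), , drop = FALSE]
  rownames(m) <- NULL
  m$x_d <- decade_part(m$target)
  m$x_u <- unit_part(m$target)
  m[, c("language", "target", "x_d", "x_u", "median_position", "n_responses")]
}

#' Fit the cyclical power model with a language modifier
#'
#' Nonlinear least squares over stacked per-language median placing
#' positions, with a shared curvature \eqn{\beta} and unit weight
#' \eqn{\delta}, and one additive language modifier \eqn{\lambda} per
#' non-reference language: the effective unit weight of language \eqn{g}
#' is \eqn{\delta + \lambda_g L_g} with indicator \eqn{L_g} (0 for the
#' reference). A \eqn{\lambda} significantly different from 0 reveals a
#' language-specific unit-digit contribution. Starting values are
#' \eqn{\beta = 1}, \eqn{\delta = 1}, \eqn{\lambda = 0}.
#'
#' The positivity constraint \eqn{\beta > 0} is enforced by optimizing
#' \eqn{\log\beta}; natural-scale standard errors are obtained by the
#' delta method from the finite-difference Jacobian at the optimum.
#' Wald t statistics use `n - k` residual degrees of freedom.
#'
#' @param medians output of [prepare_medians()] (two or more languages).
#' @param reference the reference language (indicator 0).
#' @param cycles `"two"` (default) or `"one"`.
#' @param control a [minpack.lm::nls.lm.control()] list; defaults to
#'   `ftol = ptol = 1e-10`, at most 500 iterations.
#' @return An object of class `cpm_fit` with methods [print.cpm_fit()],
#'   [summary.cpm_fit()], [coef.cpm_fit()], [vcov.cpm_fit()],
#'   [predict.cpm_fit()], [fitted.cpm_fit()], [residuals.cpm_fit()] and
#'   [plot.cpm_fit()]. The element `bic` holds the Gaussian
#'   \eqn{n\log(RSS/n) + k\log n} criterion used for cycle choice.
#' @seealso [compare_cycles()]
#' @export
fit_power_model <- function(medians, reference, cycles = c("two", "one"),
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-10, ptol = 1e-10, maxiter = 500)) {
  cycles <- match.arg(cycles)
  langs <- unique(as.character(medians$language))
  if (!reference %in% langs)
    stop("reference language '", reference, "' not present in the medians")
  others <- setdiff(langs, reference)
  if (!length(others)) stop("need at least two languages")
  counts <- table(medians$language)
  if (any(counts < 10))
    stop("fewer than 10 targets for language(s): ",
         paste(names(counts)[counts < 10], collapse = ", "))

  L <- vapply(others, function(g) as.numeric(medians$language == g),
              numeric(nrow(medians)))
  L <- matrix(L, nrow = nrow(medians),
              dimnames = list(NULL, paste0("lambda_", others)))
  y <- medians$median_position
  target <- medians$target

  pred_fun <- function(par) {
    beta <- exp(par[1])
    delta_eff <- par[2] + as.vector(L %*% par[-(1:2)])
    cpm_predict(target, beta, delta_eff, cycles)
  }
  resid_fun <- function(par) y - pred_fun(par)

  start <- c(log_beta = 0, delta = 1,
             stats::setNames(rep(0, length(others)), colnames(L)))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fun, control = control)
  if (!fit$info %in% 1:4)
    stop("nonlinear least squares did not converge: ", fit$message)
  par <- fit$par
  if (abs(par[1]) > 10)
    warning("beta driven to an extreme value (log beta = ",
            signif(par[1], 3), "); fit flagged")

  res <- resid_fun(par)
  n <- length(y)
  k <- length(par)
  rss <- sum(res^2)

  # central finite-difference Jacobian of the prediction vector
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    h <- 1e-6 * (abs(par[j]) + 1e-4)
    pp <- par; pp[j] <- par[j] + h
    pm <- par; pm[j] <- par[j] - h
    J[, j] <- (pred_fun(pp) - pred_fun(pm)) / (2 * h)
  }
  sigma2 <- rss / (n - k)
  vcov_t <- tryCatch(sigma2 * solve(crossprod(J)),
                     error = function(e) matrix(NA_real_, k, k))
  # delta method: beta = exp(log_beta)
  D <- diag(k)
  D[1, 1] <- exp(par[1])
  vcov_n <- D %*% vcov_t %*% D
  est <- c(beta = unname(exp(par[1])), delta = unname(par[2]), par[-(1:2)])
  names(est) <- c("beta", "delta", colnames(L))
  dimnames(vcov_n) <- list(names(est), names(est))
  se <- sqrt(pmax(diag(vcov_n), 0))
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = n - k)

  structure(list(
    coefficients = est, se = se, tval = tval, pval = pval,
    vcov = vcov_n, df_residual = n - k, n = n, rss = rss,
    sigma = sqrt(sigma2), bic = bic_rss(rss, n, k),
    cycles = cycles, reference = reference, comparison = others,
    data = medians, fitted = pred_fun(par), residuals = res,
    convergence = list(info = fit$info, message = fit$message,
                       niter = fit$niter),
    call = match.call()), class = "cpm_fit")
}

delta_eff_for <- function(object, language) {
  d <- unname(object$coefficients["delta"])
  if (language != object$reference) {
    lam <- object$coefficients[paste0("lambda_", language)]
    if (is.na(lam)) stop("language '", language, "' not in the fit")
    d <- d + unname(lam)
  }
  d
}

#' @export
print.cpm_fit <- function(x, ...) {
  cat(sprintf("%s-cycle power model, reference language %s\n",
              x$cycles, x$reference))
  print(round(x$coefficients, 4))
  cat(sprintf("RSS %.4g on %d df, BIC %.2f\n", x$rss, x$df_residual, x$bic))
  invisible(x)
}

#' Summarise a fitted cyclical power model
#'
#' @param object a `cpm_fit`.
#' @param ... unused.
#' @return A `summary.cpm_fit` with a coefficient matrix
#'   (Estimate, Std. Error, t value, Pr(>|t|)).
#' @export
summary.cpm_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `t value` = object$tval,
               `Pr(>|t|)` = object$pval)
  structure(list(coefficients = tab, rss = object$rss, n = object$n,
                 df_residual = object$df_residual, bic = object$bic,
                 cycles = object$cycles, reference = object$reference,
                 sigma = object$sigma, convergence = object$convergence),
            class = "summary.cpm_fit")
}

#' @export
print.summary.cpm_fit <- function(x, ...) {
  cat(sprintf("Modified %s-cycle power model (reference: %s)\n\n",
              x$cycles, x$reference))
  stats::printCoefmat(x$coefficients, digits = 4, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nResidual SE %.4g on %d df; n = %d; BIC = %.2f\n",
              x$sigma, x$df_residual, x$n, x$bic))
  invisible(x)
}

#' @export
coef.cpm_fit <- function(object, ...) object$coefficients

#' @export
vcov.cpm_fit <- function(object, ...) object$vcov

#' @export
fitted.cpm_fit <- function(object, ...) object$fitted

#' @export
residuals.cpm_fit <- function(object, ...) object$residuals

#' @export
deviance.cpm_fit <- function(object, ...) object$rss

#' Predict placing positions from a fitted model
#'
#' @param object a `cpm_fit`.
#' @param newdata data frame with columns `target` and `language`; when
#'   omitted, predictions at the fitted data.
#' @param ... unused.
#' @export
predict.cpm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  beta <- unname(object$coefficients["beta"])
  d_eff <- vapply(as.character(newdata$language), delta_eff_for,
                  numeric(1), object = object)
  cpm_predict(newdata$target, beta, d_eff, object$cycles)
}

#' Plot median placing positions and the fitted model curves
#'
#' @param x a `cpm_fit`.
#' @param grid targets at which the curves are drawn.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.cpm_fit <- function(x, grid = seq(21, 99, by = 0.5), ...) {
  langs <- c(x$reference, x$comparison)
  cols <- stats::setNames(seq_along(langs) + 1L, langs)
  graphics::plot(x$data$target, x$data$median_position,
                 col = cols[as.character(x$data$language)], pch = 16,
                 xlab = "target number", ylab = "median placing position",
                 ...)
  graphics::abline(0, 1, col = "grey", lty = 2)
  for (g in langs) {
    nd <- data.frame(target = grid, language = g)
    graphics::lines(grid, predict(x, nd), col = cols[g])
  }
  graphics::legend("topleft", legend = langs, col = cols, lty = 1, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Compare one- and two-cycle model structures by BIC
#'
#' Fits both cycle structures to the same medians and reports the
#' Gaussian BIC of each; the structure with the lower BIC is preferred.
#'
#' @inheritParams fit_power_model
#' @return List with both fits (`one`, `two`), a `bic` table, and
#'   `preferred` (`"one"` or `"two"`).
#' @export
compare_cycles <- function(medians, reference) {
  f1 <- fit_power_model(medians, reference, cycles = "one")
  f2 <- fit_power_model(medians, reference, cycles = "two")
  tab <- data.frame(cycles = c("one", "two"), rss = c(f1$rss, f2$rss),
                    bic = c(f1$bic, f2$bic))
  list(one = f1, two = f2, bic = tab,
       preferred = tab$cycles[which.min(tab$bic)])
}
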