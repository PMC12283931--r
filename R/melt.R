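#' A thermal denaturation curve
#'
#' Temperature–signal series, e.g. circular-dichroism mean residue
#' ellipticity at 222 nm recorded while heating. The signal sign is not
#' assumed (folded CD at 222 nm is negative; the fit is direction-agnostic).
#'
#' @param temperature °C, strictly increasing, at least 8 points spanning
#'   more than 10 °C.
#' @param signal one value per temperature (ellipticity or arbitrary units).
#' @return object of class `"melt_curve"`: data frame with columns
#'   `temperature` and `signal`.
#' @export
melt_curve <- function(temperature, signal) {
  if (length(temperature) != length(signal)) {
    stop("`temperature` and `signal` must have equal length")
  }
  if (length(temperature) < 8L) stop("a melt curve needs at least 8 points")
  if (any(!is.finite(temperature)) || any(!is.finite(signal))) {
    stop("non-finite values in melt curve")
  }
  if (any(diff(temperature) <= 0)) {
    stop("`temperature` must be strictly increasing")
  }
  if (diff(range(temperature)) <= 10) {
    stop("temperature range must span more than 10 degrees C")
  }
  out <- data.frame(temperature = temperature, signal = signal)
  class(out) <- c("melt_curve", "data.frame")
  out
}

#' Simulate a sigmoidal melt curve
#'
#' Four-parameter logistic
#' \eqn{f(T) = b_f + (b_u - b_f) / (1 + \exp(-(T - T_m)/k))}
#' evaluated at `temps`, plus i.i.d. Gaussian noise.
#'
#' @param tm melting midpoint (°C).
#' @param k transition slope scale (°C); larger is shallower.
#' @param baseline_folded,baseline_unfolded pre-/post-transition signal
#'   levels (defaults emulate CD ellipticity at 222 nm: strongly negative
#'   when folded, near zero unfolded).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param temps temperatures (°C), strictly increasing; default 20–70 °C in
#'   1 °C steps (a 1 °C/min ramp sampled per degree).
#' @param seed optional seed; the curve is reproducible from it.
#' @return a [melt_curve].
#' @export
simulate_melt_curve <- function(tm, k = 2, baseline_folded = -20,
                                baseline_unfolded = -2, noise_sd = 0,
                                temps = seq(20, 70, by = 1), seed = NULL) {
  if (k == 0) stop("`k` must be nonzero")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  mu <- baseline_folded +
    (baseline_unfolded - baseline_folded) / (1 + exp(-(temps - tm) / k))
  melt_curve(temps, mu + stats::rnorm(length(temps), 0, noise_sd))
}

#' Fit a melt curve with a four-parameter logistic to extract Tm
#'
#' Least-squares fit of
#' \eqn{f(T) = b_f + (b_u - b_f)/(1 + \exp(-(T - T_m)/k))}; the melting
#' midpoint Tm is the inflection temperature of the fitted sigmoid. Initial
#' guesses come from the data: baselines from the outer terciles of the
#' temperature range, Tm from the temperature nearest the half-transition.
#' Constant (not sloped) baselines are the default for identifiability on
#' typical 50-point curves; set `sloped_baselines = TRUE` to add linear
#' drift terms to both baselines.
#'
#' @param curve a [melt_curve] (or data frame with columns `temperature`,
#'   `signal`).
#' @param sloped_baselines add linear temperature terms to both baselines.
#' @return object of class `"tm_fit"`: list with `tm` (°C), `slope` (the
#'   logistic scale k, °C), `baseline_folded`, `baseline_unfolded`, `tm_se`
#'   (°C), `converged`, `extrapolated` (`TRUE` when the fitted Tm falls
#'   outside the data's temperature range, in which case `converged` is
#'   `FALSE`), `diagnostic` message, and the underlying `nls` fit.
#' @export
fit_sigmoid_tm <- function(curve, sloped_baselines = FALSE) {
  if (!inherits(curve, "melt_curve")) {
    curve <- melt_curve(curve[[1]], curve[[2]])
  }
  Tv <- curve$temperature
  y <- curve$signal
  n <- length(Tv)
  lo <- y[Tv <= stats::quantile(Tv, 1 / 3)]
  hi <- y[Tv >= stats::quantile(Tv, 2 / 3)]
  bf0 <- mean(lo)
  bu0 <- mean(hi)
  mid <- (bf0 + bu0) / 2
  tm0 <- Tv[which.min(abs(y - mid))]
  dat <- data.frame(T = Tv, y = y)
  form <- if (sloped_baselines) {
    y ~ (bf + mf * T) + ((bu + mu * T) - (bf + mf * T)) / (1 + exp(-(T - tm) / k))
  } else {
    y ~ bf + (bu - bf) / (1 + exp(-(T - tm) / k))
  }
  span <- diff(range(Tv))
  fit <- NULL
  # the optimum is start-sensitive in k; walk a ladder of slope guesses
  for (k0 in span / c(10, 25, 5, 50)) {
    start <- list(bf = bf0, bu = bu0, tm = tm0, k = k0)
    if (sloped_baselines) start <- c(start, list(mf = 0, mu = 0))
    fit <- try(
      minpack.lm::nlsLM(form, data = dat, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      silent = TRUE
    )
    if (!inherits(fit, "try-error")) break
  }
  fail <- function(msg) {
    out <- list(tm = NA_real_, slope = NA_real_,
                baseline_folded = NA_real_, baseline_unfolded = NA_real_,
                tm_se = NA_real_, converged = FALSE, extrapolated = FALSE,
                diagnostic = msg, fit = NULL)
    class(out) <- "tm_fit"
    out
  }
  if (inherits(fit, "try-error")) {
    return(fail("logistic fit failed: no transition resolved within range"))
  }
  co <- summary(fit)$coefficients
  est <- co[, "Estimate"]
  tm <- unname(est["tm"])
  amp <- abs(unname(est["bu"]) - unname(est["bf"]))
  rsd <- stats::sd(stats::resid(fit))
  diagnostic <- ""
  converged <- isTRUE(fit$convInfo$isConv)
  if (amp < 3 * rsd) {
    converged <- FALSE
    diagnostic <- "transition amplitude indistinguishable from noise"
  }
  extrapolated <- tm < min(Tv) || tm > max(Tv)
  if (extrapolated) {
    converged <- FALSE
    diagnostic <- "fitted Tm lies outside the measured temperature range"
  }
  out <- list(
    tm = tm,
    slope = unname(est["k"]),
    baseline_folded = unname(est["bf"]),
    baseline_unfolded = unname(est["bu"]),
    tm_se = unname(co["tm", "Std. Error"]),
    converged = converged,
    extrapolated = extrapolated,
    diagnostic = diagnostic,
    fit = fit
  )
  class(out) <- "tm_fit"
  out
}

#' @export
print.tm_fit <- function(x, ...) {
  cat("Four-parameter logistic melt fit\n")
  if (!isTRUE(x$converged)) {
    cat(sprintf("  [not converged: %s]\n", x$diagnostic))
  }
  cat(sprintf("  Tm = %.3f degC (SE %.3g), slope k = %.3g degC\n",
              x$tm, x$tm_se, x$slope))
  cat(sprintf("  baselines: folded %.4g, unfolded %.4g\n",
              x$baseline_folded, x$baseline_unfolded))
  invisible(x)
}

#' Read a two-column temperature/signal table
#'
#' Whitespace- or tab-separated, `#` comment lines allowed, optional header.
#'
#' @param path file path.
#' @return a [melt_curve].
#' @export
read_melt_table <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^\\s*#", first) & nzchar(trimws(first))]
  if (length(first) == 0L) stop("no data rows in ", path)
  header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first[1]), "[ \t,]+")[[1]][1])))
  tab <- utils::read.table(path, header = header, comment.char = "#")
  if (ncol(tab) < 2L) stop("need two columns: temperature, signal")
  melt_curve(tab[[1]], tab[[2]])
}
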