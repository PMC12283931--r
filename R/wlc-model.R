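#' Mean-square end-to-end distance of a 2D worm-like chain
#'
#' For a semiflexible filament whose shape fluctuations are driven thermally
#' and confined to two dimensions, the mean square of the end-to-end distance
#' \eqn{R} relates to the contour length \eqn{L} and the persistence length
#' \eqn{L_p} as
#' \deqn{\langle R^2 \rangle = 4 L_p^2 \left[ 2 \exp(-L / 2L_p) - 2 + L/L_p \right],}
#' which is the double arc-length integral of the 2D tangent autocorrelation
#' \eqn{\exp(-|s - s'| / 2L_p)} over \eqn{[0, L]^2}.
#'
#' For \eqn{L/L_p < 10^{-2}} the bracket suffers catastrophic cancellation in
#' double precision, so a fourth-order series
#' \eqn{L^2 (1 - x/6 + x^2/48 - x^3/480)} with \eqn{x = L/L_p} is used
#' instead; both branches agree to better than \eqn{10^{-11}} relative at the
#' switch point.
#'
#' @param L contour length (µm); vectorised, must be >= 0.
#' @param lp persistence length (µm); vectorised, must be > 0.
#' @return \eqn{\langle R^2 \rangle} in µm².
#' @examples
#' wlc_mean_r2(2, 1)   # 8/exp(1)
#' wlc_mean_r2(0, 5)   # 0
#' @export
wlc_mean_r2 <- function(L, lp) {
  if (any(!is.finite(lp)) || any(lp <= 0)) {
    stop("persistence length `lp` must be finite and > 0")
  }
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("contour length `L` must be finite and >= 0")
  }
  n <- max(length(L), length(lp))
  L <- rep_len(L, n)
  lp <- rep_len(lp, n)
  x <- L / lp
  out <- numeric(n)
  small <- x < 1e-2
  if (any(small)) {
    xs <- x[small]
    out[small] <- L[small]^2 * (1 - xs / 6 + xs^2 / 48 - xs^3 / 480)
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- 4 * lp[!small]^2 * (2 * exp(-xl / 2) - 2 + xl)
  }
  out
}

#' Fit the 2D worm-like-chain relation to per-filament fluctuation data
#'
#' Estimates the persistence length by unweighted nonlinear least squares of
#' [wlc_mean_r2()] against per-filament points \eqn{(L, \langle R^2 \rangle)},
#' one point per filament, as produced by [mechanics_table()]. An optional
#' weighted fit uses per-point standard errors of \eqn{\langle R^2 \rangle}.
#'
#' @param points data frame with numeric columns `L` (µm) and `msR` (µm²);
#'   columns `sd_R2` and `n_frames` are required only when `weighted = TRUE`.
#' @param weighted if `TRUE`, weight each point by
#'   `1 / (sd_R2^2 / n_frames)` (inverse squared standard error of the mean).
#' @param start optional starting value for the persistence length; by
#'   default `median(msR / (4 L))`, the asymptotic (long-chain) estimate,
#'   clamped positive.
#' @return an object of class `"wlc_fit"`: list with `lp_hat` (µm), `lp_se`
#'   (µm), `n_points`, `residual_norm` (µm²), `converged`, `beyond_support`
#'   (`TRUE` when `lp_hat > 10 * max(L)`, i.e. the data barely bend and the
#'   estimate is a lower bound in practice), and the underlying `nls` fit.
#' @export
fit_persistence_length <- function(points, weighted = FALSE, start = NULL) {
  points <- as.data.frame(points)
  if (!all(c("L", "msR") %in% names(points))) {
    stop("`points` must have columns `L` and `msR`")
  }
  pts <- points[is.finite(points$L) & is.finite(points$msR), , drop = FALSE]
  if (nrow(pts) < 2L) stop("need at least 2 finite (L, msR) points")
  if (length(unique(pts$L)) < 2L) {
    stop("all contour lengths are identical: the fit is rank-deficient")
  }
  bad <- pts$msR > pts$L^2 * (1 + 1e-12) | pts$msR < 0
  if (any(bad)) {
    stop(sprintf(
      "%d point(s) have msR outside [0, L^2]; mean-square end-to-end cannot exceed L^2",
      sum(bad)
    ))
  }
  w <- NULL
  if (weighted) {
    if (!all(c("sd_R2", "n_frames") %in% names(pts))) {
      stop("weighted fit needs `sd_R2` and `n_frames` columns")
    }
    se2 <- pts$sd_R2^2 / pts$n_frames
    if (any(!is.finite(se2)) || any(se2 <= 0)) {
      stop("weighted fit needs positive finite sd_R2 and n_frames")
    }
    w <- 1 / se2
  }
  if (is.null(start)) {
    start <- stats::median(pts$msR / (4 * pts$L))
    start <- min(max(start, 1e-3), 1e6)
  }
  args <- list(
    msR ~ wlc_mean_r2(L, lp),
    data = pts, start = list(lp = start),
    lower = 1e-9, upper = 1e12,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  if (!is.null(w)) args$weights <- w
  fit <- try(do.call(minpack.lm::nlsLM, args), silent = TRUE)
  if (inherits(fit, "try-error")) {
    out <- list(
      lp_hat = NA_real_, lp_se = NA_real_, n_points = nrow(pts),
      residual_norm = NA_real_, converged = FALSE, beyond_support = NA,
      fit = NULL
    )
    class(out) <- "wlc_fit"
    return(out)
  }
  co <- summary(fit)$coefficients
  lp_hat <- unname(co["lp", "Estimate"])
  out <- list(
    lp_hat = lp_hat,
    lp_se = unname(co["lp", "Std. Error"]),
    n_points = nrow(pts),
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    converged = isTRUE(fit$convInfo$isConv),
    beyond_support = lp_hat > 10 * max(pts$L),
    fit = fit
  )
  class(out) <- "wlc_fit"
  out
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat("2D worm-like-chain fit of <R^2>(L)\n")
  if (!isTRUE(x$converged)) cat("  [fit did not converge]\n")
  cat(sprintf("  persistence length: %.4g um (SE %.3g um)\n", x$lp_hat, x$lp_se))
  cat(sprintf("  points: %d   residual norm: %.4g um^2\n",
              x$n_points, x$residual_norm))
  if (isTRUE(x$beyond_support)) {
    cat("  note: lp exceeds 10 x max contour length; data barely bend,\n")
    cat("  treat the estimate as a lower bound\n")
  }
  invisible(x)
}

#' Persistence length from the tangent autocorrelation decay
#'
#' An estimator independent of the end-to-end fit: pools the tangent-angle
#' correlation \eqn{\langle \cos(\theta(s + \Delta) - \theta(s)) \rangle}
#' over all node pairs of all traces, bins it by arc separation, and fits a
#' single-exponential decay \eqn{\exp(-\Delta/\lambda)} by regression of the
#' log correlation through the origin. In 2D the decay length is
#' \eqn{\lambda = 2 L_p}, so the persistence length is returned as
#' \eqn{\lambda / 2}.
#'
#' @param stacks a list of [track_stack] objects (or a single one), traces in
#'   µm or with `pixel_size` supplied.
#' @param pixel_size µm per pixel, required when traces are in pixel units.
#' @param min_corr smallest pooled correlation used in the log-linear fit;
#'   bins below it are dominated by noise and dropped.
#' @param min_count smallest number of pooled pairs per arc-separation bin.
#' @return an object of class `"tangent_lp"`: list with `lp` (µm),
#'   `decay_length` (µm), `n_traces`, `n_pairs`, and `lower_bound` (`TRUE`
#'   when no decay is resolved, e.g. rigid straight traces, in which case
#'   `lp` is `Inf` and only usable as a lower bound).
#' @export
tangent_correlation_lp <- function(stacks, pixel_size = NULL,
                                   min_corr = 0.05, min_count = 30L) {
  traces <- .collect_traces(stacks)
  traces <- Filter(function(tr) nrow(tr$nodes) >= 10L, traces)
  if (length(traces) == 0L) {
    stop("no trace with >= 10 nodes: insufficient pairs for tangent correlation")
  }
  sums <- new.env(parent = emptyenv())
  n_pairs <- 0L
  for (tr in traces) {
    xy <- .nodes_um(tr, pixel_size)
    th <- atan2(diff(xy[, 2]), diff(xy[, 1]))
    seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    ds <- mean(seg)
    m <- length(th)
    for (k in seq_len(m - 1L)) {
      d <- cos(th[(1L + k):m] - th[1:(m - k)])
      key <- sprintf("%.6g", k * ds)
      prev <- if (exists(key, envir = sums)) get(key, envir = sums) else c(0, 0, 0)
      assign(key, prev + c(k * ds * length(d), sum(d), length(d)), envir = sums)
      n_pairs <- n_pairs + length(d)
    }
  }
  keys <- ls(envir = sums)
  acc <- t(vapply(keys, function(k) get(k, envir = sums), numeric(3)))
  sep <- acc[, 1] / acc[, 3]
  corr <- acc[, 2] / acc[, 3]
  cnt <- acc[, 3]
  keep <- cnt >= min_count & corr > min_corr
  if (sum(keep) < 3L) stop("fewer than 3 usable arc-separation bins")
  sep <- sep[keep]; corr <- corr[keep]; cnt <- cnt[keep]
  # C(0) = 1 exactly, so regress log C on separation through the origin;
  # var(log C_hat) ~ 1/(n C^2), hence weights n * C^2
  w <- cnt * corr^2
  slope <- sum(w * sep * log(corr)) / sum(w * sep^2)
  lower_bound <- FALSE
  if (slope >= -1e-9) {
    decay <- Inf
    lower_bound <- TRUE
  } else {
    decay <- -1 / slope
    if (decay > 20 * max(sep)) lower_bound <- TRUE
  }
  out <- list(
    lp = decay / 2, decay_length = decay,
    n_traces = length(traces), n_pairs = n_pairs,
    lower_bound = lower_bound
  )
  class(out) <- "tangent_lp"
  out
}

#' @export
print.tangent_lp <- function(x, ...) {
  cat("Tangent-correlation persistence length\n")
  cat(sprintf("  lp = %.4g um (decay length %.4g um)\n", x$lp, x$decay_length))
  cat(sprintf("  %d traces, %d node pairs\n", x$n_traces, x$n_pairs))
  if (isTRUE(x$lower_bound)) {
    cat("  no decay resolved within the data: lp is a lower bound\n")
  }
  invisible(x)
}
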