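#' Tube length from a closed outline by the half-perimeter rule
#'
#' A thin closed outline hugging a tube has perimeter approximately twice the
#' tube length, so the length is estimated as half the polygon perimeter. The
#' width contribution is not corrected.
#'
#' @param outline two-column numeric matrix of polygon vertices, in order.
#'   The polygon is treated as closed: if the first vertex is not repeated at
#'   the end, the closing edge is added implicitly.
#' @param check_self_intersection test non-adjacent edges for crossings and
#'   warn (the value is still returned); skipped for polygons with more than
#'   `1000` vertices.
#' @return half the perimeter, in the vertices' unit.
#' @export
half_perimeter_length <- function(outline, check_self_intersection = TRUE) {
  v <- as.matrix(outline)
  if (!is.numeric(v) || ncol(v) != 2L) stop("`outline` must be a 2-column numeric matrix")
  if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("a closed outline needs at least 3 distinct vertices")
  vc <- rbind(v, v[1, ])
  seg <- sqrt(diff(vc[, 1])^2 + diff(vc[, 2])^2)
  if (check_self_intersection && nrow(v) <= 1000L && .polygon_self_intersects(vc)) {
    warning("outline is self-intersecting; half-perimeter returned anyway")
  }
  sum(seg) / 2
}

# brute pairwise test over non-adjacent closed-polygon edges
.polygon_self_intersects <- function(vc) {
  n <- nrow(vc) - 1L
  segs <- lapply(seq_len(n), function(i) rbind(vc[i, ], vc[i + 1L, ]))
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- cross(q[1, ], q[2, ], p[1, ]); d2 <- cross(q[1, ], q[2, ], p[2, ])
    d3 <- cross(p[1, ], p[2, ], q[1, ]); d4 <- cross(p[1, ], p[2, ], q[2, ])
    ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (intersects(segs[[i]], segs[[j]])) return(TRUE)
    }
  }
  FALSE
}

#' Read closed tube outlines from a tab-separated vertex table
#'
#' Expected columns: `outline_id`, `vertex_index`, `x`, `y`, `unit`.
#'
#' @param path file path.
#' @return named list of vertex matrices (one per outline) with a `unit`
#'   attribute.
#' @export
read_outline_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("outline_id", "vertex_index", "x", "y", "unit")
  if (!all(need %in% names(tab))) {
    stop("outline table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(split(tab, tab$outline_id), function(ot) {
    ot <- ot[order(ot$vertex_index), ]
    v <- cbind(x = ot$x, y = ot$y)
    attr(v, "unit") <- ot$unit[1]
    v
  })
}

#' Keep the n longest tube lengths
#'
#' Reproduces the published selection step: only the `n` longest tubes enter
#' each data point (a deliberate selection bias of the original procedure,
#' reproduced as stated). Ties are kept in stable input order.
#'
#' @param lengths numeric vector of tube lengths (µm).
#' @param n how many to keep (default 150).
#' @param label optional condition label carried on the result.
#' @return object of class `"length_sample"`: list with `condition_label`,
#'   `lengths` (sorted descending) and `n_selected`. If fewer than `n`
#'   lengths are supplied, all are kept with a warning.
#' @export
select_longest <- function(lengths, n = 150L, label = "") {
  if (length(lengths) == 0L) stop("no lengths supplied")
  if (n < 1L) stop("`n` must be >= 1")
  if (any(!is.finite(lengths))) stop("lengths must be finite")
  if (length(lengths) < n) {
    warning(sprintf("only %d lengths available; keeping all (asked for %d)",
                    length(lengths), n))
    n <- length(lengths)
  }
  ord <- order(lengths, decreasing = TRUE)  # stable: ties keep input order
  out <- list(
    condition_label = label,
    lengths = lengths[ord][seq_len(n)],
    n_selected = as.integer(n)
  )
  class(out) <- "length_sample"
  out
}

#' @export
print.length_sample <- function(x, ...) {
  cat(sprintf("length_sample%s: n = %d, mean %.3g, range [%.3g, %.3g]\n",
              if (nzchar(x$condition_label)) paste0(" '", x$condition_label, "'") else "",
              x$n_selected, mean(x$lengths), min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Two-sided Welch's t test between two length samples
#'
#' Welch's unequal-variance t statistic with Welch–Satterthwaite degrees of
#' freedom and a two-sided p value, as used to compare tube-length
#' distributions between conditions. No multiple-testing correction is
#' applied: raw p values are reported. Degenerate input where both samples
#' have zero variance and equal means returns `p = 1` by convention (flagged);
#' zero variance otherwise is an error.
#'
#' @param a,b numeric vectors or [select_longest()] results.
#' @return object of class `"welch_test"`: list with `t`, `df`, `p`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b` and `degenerate`.
#' @export
welch_t_test <- function(a, b) {
  xa <- if (inherits(a, "length_sample")) a$lengths else as.numeric(a)
  xb <- if (inherits(b, "length_sample")) b$lengths else as.numeric(b)
  if (length(xa) < 2L || length(xb) < 2L) stop("each sample needs >= 2 values")
  va <- stats::var(xa); vb <- stats::var(xb)
  degenerate <- FALSE
  if (va == 0 && vb == 0) {
    if (mean(xa) == mean(xb)) {
      warning("both samples constant and equal: p = 1 by convention")
      degenerate <- TRUE
      res <- list(t = 0, df = NA_real_, p = 1)
    } else {
      stop("both samples have zero variance with different means")
    }
  } else if (va == 0 || vb == 0) {
    stop("one sample has zero variance: Welch's test is undefined")
  } else {
    ht <- stats::t.test(xa, xb, var.equal = FALSE, alternative = "two.sided")
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  out <- c(res, list(
    mean_a = mean(xa), mean_b = mean(xb),
    n_a = length(xa), n_b = length(xb),
    degenerate = degenerate
  ))
  class(out) <- "welch_test"
  out
}

#' @export
print.welch_test <- function(x, ...) {
  cat("Two-sided Welch's t test\n")
  cat(sprintf("  mean a = %.4g (n = %d), mean b = %.4g (n = %d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g\n", x$t, x$df, x$p))
  if (isTRUE(x$degenerate)) cat("  [degenerate: constant equal samples]\n")
  invisible(x)
}
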