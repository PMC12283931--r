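# numeric double-integral oracle for the 2D WLC mean-square end-to-end
# distance: integrate exp(-|s - s'|/(2 lp)) over [0, L]^2 as twice the
# integral over the smooth triangle s' < s
wlc_r2_integral_oracle <- function(L, lp) {
  inner <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(function(s) exp(-(ti - s) / (2 * lp)), 0, ti,
                       rel.tol = 1e-12, abs.tol = 0)$value
    }, numeric(1))
  }
  2 * stats::integrate(inner, 0, L, rel.tol = 1e-11, abs.tol = 0)$value
}

# a straight horizontal filament trace in um
straight_trace <- function(x0, x1, y, n = 51, id = "F1", frame = 1L) {
  filament_trace(id, frame, cbind(seq(x0, x1, length.out = n), rep(y, n)),
                 unit = "um")
}

# a stack repeating one trace over `n` frames
static_stack <- function(trace, n_frames) {
  track_stack(lapply(seq_len(n_frames), function(f) {
    trace$frame <- as.integer(f)
    trace
  }))
}

# small separated ensemble on a grid of anchors (traces in um)
separated_ensemble <- function(lp, Ls, n_frames, anchors, ds = 0.05) {
  lapply(seq_along(Ls), function(i) {
    trs <- lapply(seq_len(n_frames), function(f) {
      tr <- sample_wlc_chain(lp, Ls[i], ds, sprintf("F%03d", i), f)
      tr$nodes <- sweep(tr$nodes, 2, as.numeric(anchors[i, ]), "+")
      tr
    })
    track_stack(trs)
  })
}
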