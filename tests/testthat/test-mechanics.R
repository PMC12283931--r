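test_that("contour_length and end_to_end match hand geometry and brute force", {
  tr <- filament_trace("F", 1L, rbind(c(0, 0), c(1, 0), c(2, 0)), unit = "um")
  expect_equal(contour_length(tr), 2)
  expect_equal(end_to_end(tr), 2)
  tr2 <- filament_trace("F", 1L, rbind(c(0, 0), c(1, 0), c(1, 1)), unit = "um")
  expect_equal(contour_length(tr2), 2)
  expect_equal(end_to_end(tr2), sqrt(2))
  # closed loop: R = 0
  th <- seq(0, 2 * pi, length.out = 100)
  loop <- filament_trace("F", 1L, cbind(cos(th), sin(th)), unit = "um")
  expect_equal(end_to_end(loop), 0, tolerance = 1e-12)
  # brute-force pairwise re-summation on 1000 random nodes
  set.seed(2)
  nodes <- cbind(runif(1000), runif(1000))
  tr3 <- filament_trace("F", 1L, nodes, unit = "um")
  brute <- 0
  for (i in 2:1000) {
    brute <- brute + sqrt(sum((nodes[i, ] - nodes[i - 1, ])^2))
  }
  expect_equal(contour_length(tr3), brute, tolerance = 1e-12)
  # pixel traces convert through pixel_size
  trp <- filament_trace("F", 1L, rbind(c(0, 0), c(10, 0)), unit = "px")
  expect_equal(contour_length(trp, pixel_size = 0.267), 2.67)
  expect_error(contour_length(matrix(1, 1, 2)), "2 nodes")
})

test_that("mean_square_r2 averages per-frame geometry", {
  # no fluctuation: identical straight trace in every frame
  st <- static_stack(straight_trace(0, 5, 0), 10)
  expect_warning(row <- mean_square_r2(st), "100-200")
  expect_equal(row$L, 5)
  expect_equal(row$msR, 25)
  # two frames with R = 3 and R = 4 -> msR = 12.5
  t1 <- filament_trace("F", 1L, rbind(c(0, 0), c(1.5, 2), c(3, 0)), unit = "um")
  t2 <- filament_trace("F", 2L, rbind(c(0, 0), c(2, 2), c(4, 0)), unit = "um")
  row2 <- mean_square_r2(track_stack(list(t1, t2)), check_frames = FALSE)
  expect_equal(row2$msR, 12.5)
  expect_equal(row2$n_frames, 2L)
  expect_equal(row2$sd_R2, sd(c(9, 16)))
})

test_that("mechanics tables bind filaments and round-trip to disk", {
  cfg <- synthetic_config(5, c(4, 8), 2, 3, rng_seed = 5)
  tab <- mechanics_table(sample_ensemble(cfg), check_frames = FALSE)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$msR <= tab$L^2))
  path <- tempfile(fileext = ".tsv")
  write_mechanics_table(tab, path)
  back <- read_mechanics_table(path)
  expect_equal(back$msR, tab$msR, tolerance = 1e-12)
})

test_that("simulated stacks reproduce the closed form within 3 SE", {
  cfg <- synthetic_config(2, 8, 1, 150, ds = 0.05, rng_seed = 99)
  row <- mean_square_r2(sample_ensemble(cfg)[[1]])
  pred <- wlc_mean_r2(8, 2)
  se <- row$sd_R2 / sqrt(row$n_frames)
  expect_lt(abs(row$msR - pred), 3 * se)
})

test_that("tangent correlation estimator recovers lp and flags rigid traces", {
  set.seed(12)
  st <- lapply(1:40, function(i) {
    track_stack(lapply(1:25, function(f) {
      sample_wlc_chain(3, 8, 0.05, sprintf("F%02d", i), f)
    }))
  })
  est <- tangent_correlation_lp(st)
  expect_false(est$lower_bound)
  expect_lt(abs(est$lp - 3) / 3, 0.10)
  # straight rigid traces: no decay, flagged as a lower bound
  rigid <- lapply(1:5, function(i) static_stack(straight_trace(0, 10, i, n = 101), 3))
  est2 <- tangent_correlation_lp(rigid)
  expect_true(est2$lower_bound)
  expect_gt(est2$lp, 100)
  # too-short traces are rejected
  tiny <- static_stack(straight_trace(0, 1, 0, n = 5), 2)
  expect_error(tangent_correlation_lp(list(tiny)), "10 nodes")
})

test_that("parameter recovery holds across seeds and stiffness regimes", {
  # scaled-down replicate study: per regime, median relative error of the
  # end-to-end fit over seeded replicates stays within 10%
  for (lp_true in c(2, 12.5, 19.7)) {
    errs <- vapply(1:5, function(rep) {
      set.seed(1000 + rep)
      Ls <- runif(25, 2, 15)
      cfg <- synthetic_config(lp_true, Ls, 25, 100, ds = 0.05,
                              rng_seed = 1000 + rep)
      fit <- fit_persistence_length(mechanics_table(sample_ensemble(cfg)))
      abs(fit$lp_hat - lp_true) / lp_true
    }, numeric(1))
    expect_lt(median(errs), 0.10)
  }
})

test_that("track->mechanics->fit on rendered movies matches the trace path", {
  # fine spatial sampling (0.1 um/px) keeps sub-resolution undulation loss
  # small; at that sampling the image path tracks the ground-truth-trace path
  set.seed(55)
  anchors <- expand.grid(x = c(10, 26, 42), y = c(10, 26))
  Ls <- c(4, 6, 7, 8, 9, 10)
  st <- separated_ensemble(5, Ls, 40, anchors)
  opt <- optics_config(pixel_size = 0.1)
  img <- render_frames(st, opt, field_size = c(52, 36), seed = 55)
  s8 <- to_8bit(img)
  cfg <- tracking_config(threshold_method = "global-otsu", min_length_px = 6,
                         border_margin_px = 3)
  pf <- lapply(seq_len(dim(s8)[3]), function(f) {
    trace_filaments(s8[, , f], cfg, frame_index = f)
  })
  stacks <- link_frames(pf, max_disp = 30, min_frames = 30)
  tab <- mechanics_table(stacks, pixel_size = opt$pixel_size,
                         check_frames = FALSE)
  tab <- tab[tab$n_frames >= 30, ]
  truth <- mechanics_table(st, check_frames = FALSE)
  expect_gte(nrow(tab), 5)
  # tracked contour lengths within 2% of their nearest ground truth
  # (gentle curvature regime)
  rel_err <- vapply(tab$L, function(l) min(abs(l - truth$L) / truth$L),
                    numeric(1))
  expect_true(all(rel_err < 0.02))
  lp_img <- fit_persistence_length(tab)$lp_hat
  lp_tru <- fit_persistence_length(truth)$lp_hat
  expect_lt(abs(lp_img - lp_tru) / lp_tru, 0.10)
})
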