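test_that("to_8bit rescales the whole stack linearly", {
  # already full-range 8-bit input is unchanged
  m <- matrix(rep(c(0L, 100L, 255L), length.out = 64), 8, 8)
  expect_identical(to_8bit(m), m)
  # 16-bit ramp maps by the direct affine rule, monotone nondecreasing
  ramp <- matrix(seq(0L, 65535L, length.out = 128), 8, 16)
  out <- to_8bit(ramp)
  oracle <- round((ramp - 0) * 255 / 65535)
  expect_equal(as.vector(out), as.vector(oracle))
  expect_true(all(diff(sort(as.vector(out))) >= 0))
  expect_equal(range(out), c(0, 255))
  # constant stack degenerates to zeros with a warning
  expect_warning(z <- to_8bit(matrix(500, 4, 4)), "constant")
  expect_true(all(z == 0))
  # whole-stack (not per-frame) scaling
  stack <- array(c(matrix(0, 4, 4), matrix(100, 4, 4)), dim = c(4, 4, 2))
  out2 <- to_8bit(stack)
  expect_true(all(out2[, , 1] == 0) && all(out2[, , 2] == 255))
})

test_that("a rendered straight filament is traced to pixel accuracy", {
  opt <- optics_config(pixel_size = 1, psf_sigma = 1, background = 0,
                       read_noise_sd = 0)
  tr <- straight_trace(20, 70, 40)
  img <- render_frames(list(track_stack(list(tr))), opt,
                       field_size = c(100, 80), noise = FALSE)
  cfg <- tracking_config(threshold_method = "fixed", min_length_px = 10,
                         border_margin_px = 3)
  tt <- trace_filaments(to_8bit(img[, , 1]), cfg)
  expect_length(tt, 1)
  expect_equal(tt[[1]]$unit, "px")
  # truth: 50 px contour, endpoints at px columns 20.5 and 70.5, row 40.5
  expect_lt(abs(contour_length(tt[[1]]) - 50), 1)
  expect_lt(abs(end_to_end(tt[[1]]) - 50), 1)
  expect_true(all(abs(tt[[1]]$nodes[, 2] - 40.5) < 1))
})

test_that("a rendered semicircular arc is traced to its known arc length", {
  opt <- optics_config(pixel_size = 1, psf_sigma = 1, background = 0,
                       read_noise_sd = 0)
  th <- seq(0, pi, length.out = 200)
  arc <- filament_trace("A", 1L, cbind(50 + 20 * cos(th), 40 + 20 * sin(th)),
                        unit = "um")
  img <- render_frames(list(track_stack(list(arc))), opt,
                       field_size = c(100, 80), noise = FALSE)
  cfg <- tracking_config(threshold_method = "fixed", min_length_px = 10,
                         border_margin_px = 3)
  tt <- trace_filaments(to_8bit(img[, , 1]), cfg)
  expect_length(tt, 1)
  expect_lt(abs(contour_length(tt[[1]]) - pi * 20), 2)
  expect_lt(abs(end_to_end(tt[[1]]) - 40), 1)
})

test_that("blank frames yield no traces and border filaments are dropped", {
  cfg <- tracking_config()
  expect_length(trace_filaments(matrix(0L, 40, 40), cfg), 0)
  # a filament hugging the border is excluded by the margin rule
  opt <- optics_config(pixel_size = 1, background = 0, read_noise_sd = 0)
  tr <- straight_trace(10, 40, 2)
  img <- render_frames(list(track_stack(list(tr))), opt,
                       field_size = c(50, 30), noise = FALSE)
  expect_length(
    trace_filaments(to_8bit(img[, , 1]),
                    tracking_config(threshold_method = "fixed",
                                    border_margin_px = 5)),
    0
  )
})

test_that("traced node order is invariant to 180-degree image rotation", {
  opt <- optics_config(pixel_size = 1, psf_sigma = 1, background = 0,
                       read_noise_sd = 0)
  th <- seq(0, pi / 2, length.out = 100)
  arc <- filament_trace("A", 1L, cbind(30 + 25 * cos(th), 30 + 25 * sin(th)),
                        unit = "um")
  img <- render_frames(list(track_stack(list(arc))), opt,
                       field_size = c(80, 80), noise = FALSE)
  fr <- to_8bit(img[, , 1])
  cfg <- tracking_config(threshold_method = "fixed", border_margin_px = 3)
  t1 <- trace_filaments(fr, cfg)
  rot <- fr[rev(seq_len(nrow(fr))), rev(seq_len(ncol(fr)))]
  t2 <- trace_filaments(rot, cfg)
  expect_length(t1, 1)
  expect_length(t2, 1)
  # map rotated coordinates back: x' = W + 1 - x, y' = H + 1 - y
  back <- cbind(ncol(fr) + 1 - t2[[1]]$nodes[, 1],
                nrow(fr) + 1 - t2[[1]]$nodes[, 2])
  back <- back[rev(seq_len(nrow(back))), ]
  expect_equal(contour_length(t1[[1]]), contour_length(t2[[1]]),
               tolerance = 0.02)
  # endpoints agree after mapping back (canonical order fixes direction)
  a <- t1[[1]]$nodes
  d_ends <- min(
    sqrt(sum((a[1, ] - back[1, ])^2)) + sqrt(sum((a[nrow(a), ] - back[nrow(back), ])^2)),
    sqrt(sum((a[1, ] - back[nrow(back), ])^2)) + sqrt(sum((a[nrow(a), ] - back[1, ])^2))
  )
  expect_lt(d_ends, 2)
})

test_that("link_frames groups per-frame traces into coherent stacks", {
  # one object present in all frames -> a single stack
  one <- lapply(1:30, function(f) list(straight_trace(5, 15, 10, frame = f)))
  st <- link_frames(one, max_disp = 5, min_frames = 20)
  expect_length(st, 1)
  expect_length(st[[1]]$traces, 30)
  expect_false(attr(st[[1]], "flagged_short"))
  expect_equal(attr(st[[1]], "gaps"), 0L)

  # two well-separated static objects -> two stacks of 30
  two <- lapply(1:30, function(f) {
    list(straight_trace(5, 15, 10, id = "a", frame = f),
         straight_trace(5, 15, 40, id = "b", frame = f))
  })
  st2 <- link_frames(two, max_disp = 5, min_frames = 20)
  expect_length(st2, 2)
  expect_true(all(vapply(st2, function(s) length(s$traces), integer(1)) == 30L))

  # a missed detection in one middle frame -> same stack, one gap counted
  gap <- lapply(1:31, function(f) {
    if (f == 16) list() else list(straight_trace(5, 15, 10, frame = f))
  })
  st3 <- link_frames(gap, max_disp = 5, min_frames = 20)
  expect_length(st3, 1)
  expect_length(st3[[1]]$traces, 30)
  expect_equal(attr(st3[[1]], "gaps"), 1L)
})

test_that("linking respects the displacement gate", {
  # object jumps farther than the gate -> two stacks
  jump <- list(
    list(straight_trace(5, 15, 10, frame = 1)),
    list(straight_trace(45, 55, 50, frame = 2))
  )
  st <- link_frames(jump, max_disp = 10, min_frames = 1)
  expect_length(st, 2)
})
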