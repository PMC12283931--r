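#' Configuration for a synthetic worm-like-chain ensemble
#'
#' Describes the study conditions the simulator emulates: filaments of known
#' persistence length observed as independent equilibrium snapshots across
#' frames (as in time-lapse TIRFM of filaments freely fluctuating in 2D).
#'
#' @param lp_true ground-truth persistence length (µm), > 0.
#' @param contour_lengths contour length(s) (µm); recycled across filaments.
#' @param n_filaments number of filaments.
#' @param n_frames frames per filament (independent equilibrium draws);
#'   the fluctuation analysis typically uses 100–200.
#' @param ds arc-length discretisation step (µm); default
#'   `min(0.05, min(contour_lengths) / 200)` keeps discretisation error well
#'   below the fit tolerance. Must satisfy `ds <= min(contour_lengths) / 10`.
#' @param rng_seed integer seed; the whole ensemble is reproducible from it.
#' @param field_size optional `c(width, height)` in µm; when set, filaments
#'   are anchored uniformly in the field and re-anchored (same shape) while
#'   more than 10% of nodes fall outside, to limit clipping on rendering.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(lp_true, contour_lengths, n_filaments,
                             n_frames, ds = NULL, rng_seed = 1L,
                             field_size = NULL) {
  if (!is.numeric(lp_true) || length(lp_true) != 1L || lp_true <= 0) {
    stop("`lp_true` must be a single positive number")
  }
  if (any(contour_lengths <= 0)) stop("all `contour_lengths` must be > 0")
  if (n_filaments < 1L || n_frames < 1L) {
    stop("`n_filaments` and `n_frames` must be >= 1")
  }
  if (is.null(ds)) ds <- min(0.05, min(contour_lengths) / 200)
  if (ds <= 0 || ds > min(contour_lengths) / 10) {
    stop("`ds` must be positive and <= min(contour_lengths) / 10")
  }
  if (!is.null(field_size)) {
    if (length(field_size) != 2L || any(field_size <= 0)) {
      stop("`field_size` must be c(width, height) in um, both > 0")
    }
  }
  out <- list(
    lp_true = lp_true,
    contour_lengths = as.numeric(contour_lengths),
    n_filaments = as.integer(n_filaments),
    n_frames = as.integer(n_frames),
    ds = ds,
    rng_seed = as.integer(rng_seed),
    field_size = field_size
  )
  class(out) <- "synthetic_config"
  out
}

#' Sample one equilibrium 2D worm-like chain
#'
#' Builds a discretised chain of `floor(contour_length / ds)` segments of
#' length `ds` by integrating a tangent angle whose increments are
#' independent zero-mean Gaussians with variance `ds / lp`. For Gaussian
#' increments \eqn{\langle \cos\Delta\theta \rangle = \exp(-ds/2lp)} exactly,
#' so the ensemble tangent autocorrelation decays as
#' \eqn{\exp(-s / 2 L_p)} — the 2D worm-like chain. The chain is centred on
#' its centroid and given a uniformly random initial orientation; its
#' polyline contour length equals the requested length to within one `ds`.
#'
#' Uses the current R random number stream (seed it with [set.seed()], or go
#' through [sample_ensemble()] which seeds from its config).
#'
#' @param lp persistence length (µm), > 0.
#' @param contour_length contour length (µm), > ds.
#' @param ds discretisation step (µm); should be well below `lp`.
#' @param filament_id,frame identifiers stored on the returned trace.
#' @return a [filament_trace] in µm.
#' @export
sample_wlc_chain <- function(lp, contour_length, ds,
                             filament_id = "F1", frame = 1L) {
  if (lp <= 0 || contour_length <= 0 || ds <= 0) {
    stop("`lp`, `contour_length` and `ds` must all be > 0")
  }
  if (ds >= contour_length) stop("`ds` must be smaller than `contour_length`")
  n_steps <- max(1L, floor(contour_length / ds))
  theta0 <- stats::runif(1, 0, 2 * pi)
  dtheta <- stats::rnorm(n_steps - 1L, mean = 0, sd = sqrt(ds / lp))
  theta <- theta0 + c(0, cumsum(dtheta))
  x <- c(0, cumsum(ds * cos(theta)))
  y <- c(0, cumsum(ds * sin(theta)))
  x <- x - mean(x)
  y <- y - mean(y)
  filament_trace(filament_id, frame, cbind(x, y), unit = "um")
}

#' Sample a full synthetic ensemble of fluctuating filaments
#'
#' One track stack per filament, each holding `n_frames` independent
#' equilibrium chains of that filament's contour length. Frames are
#' independent draws, not Brownian dynamics: the downstream estimator
#' assumes only thermal-equilibrium shapes, and independence maximises the
#' information per frame. Each filament keeps a fixed anchor position across
#' frames (shapes fluctuate around it), so frame-to-frame linking sees a
#' quasi-static object.
#'
#' @param config a [synthetic_config].
#' @return list of [track_stack] objects, length `n_filaments`; ground-truth
#'   contour lengths are attached as `attr(, "contour_lengths")`.
#' @export
sample_ensemble <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  lens <- rep_len(config$contour_lengths, config$n_filaments)
  stacks <- vector("list", config$n_filaments)
  for (i in seq_len(config$n_filaments)) {
    id <- sprintf("F%03d", i)
    anchor <- c(0, 0)
    if (!is.null(config$field_size)) {
      anchor <- stats::runif(2, 0, config$field_size)
    }
    traces <- vector("list", config$n_frames)
    for (f in seq_len(config$n_frames)) {
      tr <- sample_wlc_chain(config$lp_true, lens[i], config$ds,
                             filament_id = id, frame = f)
      if (!is.null(config$field_size)) {
        a <- anchor
        for (attempt in 1:100) {
          nodes <- sweep(tr$nodes, 2, a, "+")
          outside <- nodes[, 1] < 0 | nodes[, 1] > config$field_size[1] |
            nodes[, 2] < 0 | nodes[, 2] > config$field_size[2]
          if (mean(outside) <= 0.10) break
          a <- stats::runif(2, 0, config$field_size)
        }
        tr$nodes <- sweep(tr$nodes, 2, a, "+")
      }
      traces[[f]] <- tr
    }
    stacks[[i]] <- track_stack(traces)
  }
  attr(stacks, "contour_lengths") <- lens
  stacks
}

#' Optical / camera parameters for the fluorescence renderer
#'
#' Defaults emulate a TIRFM setup with an EMCCD behind a 60x objective:
#' 16 µm camera pixels / 60x gives 0.267 µm/px, frames every 40 ms. The
#' point-spread function is an isotropic Gaussian in pixel units.
#'
#' @param pixel_size µm per pixel.
#' @param psf_sigma Gaussian PSF standard deviation (px).
#' @param peak_intensity expected photons at the brightest filament pixel.
#' @param background expected background photons per pixel.
#' @param read_noise_sd Gaussian read noise SD (photons).
#' @param bit_depth 8 or 16.
#' @param frame_interval seconds between frames.
#' @return object of class `"optics_config"`.
#' @export
optics_config <- function(pixel_size = 0.267, psf_sigma = 1.0,
                          peak_intensity = 200, background = 10,
                          read_noise_sd = 2, bit_depth = 16L,
                          frame_interval = 0.040) {
  if (pixel_size <= 0 || psf_sigma <= 0) {
    stop("`pixel_size` and `psf_sigma` must be > 0")
  }
  if (peak_intensity < 0 || background < 0 || read_noise_sd < 0) {
    stop("intensities and noise must be >= 0")
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (frame_interval <= 0) stop("`frame_interval` must be > 0")
  out <- list(
    pixel_size = pixel_size, psf_sigma = psf_sigma,
    peak_intensity = peak_intensity, background = background,
    read_noise_sd = read_noise_sd, bit_depth = as.integer(bit_depth),
    frame_interval = frame_interval
  )
  class(out) <- "optics_config"
  out
}

#' Render fluctuating filaments into a noisy fluorescence image stack
#'
#' Each filament is drawn by accumulating an isotropic Gaussian PSF along its
#' polyline at uniform sub-pixel arc sampling (so deposited intensity is
#' proportional to filament length), the noiseless frame is scaled so its
#' brightest pixel equals `peak_intensity`, then background, Poisson shot
#' noise and Gaussian read noise are added and the result quantised to the
#' camera bit depth. Pixel `(row r, col c)` is centred at physical position
#' `((c - 0.5) * pixel_size, (r - 0.5) * pixel_size)`.
#'
#' @param stacks list of [track_stack] objects with traces in µm.
#' @param optics an [optics_config].
#' @param field_size `c(width, height)` in µm; default is the traces'
#'   bounding box plus a 2 µm margin (traces are shifted to positive
#'   coordinates in that case). Nodes outside the field are clipped with a
#'   warning.
#' @param seed optional seed for the noise draws.
#' @param noise apply Poisson shot noise and Gaussian read noise; set
#'   `FALSE` for a deterministic noiseless render (signal + background only).
#' @return 3D array `[rows, cols, frames]` of integer camera counts, with
#'   attributes `optics`, `frames` (frame indices) and `field_size`.
#' @export
render_frames <- function(stacks, optics, field_size = NULL, seed = NULL,
                          noise = TRUE) {
  stopifnot(inherits(optics, "optics_config"))
  if (!is.null(seed)) set.seed(seed)
  traces <- .collect_traces(stacks)
  if (any(vapply(traces, function(t) t$unit, character(1)) != "um")) {
    stop("render_frames needs traces in um")
  }
  shift <- c(0, 0)
  if (is.null(field_size)) {
    allxy <- do.call(rbind, lapply(traces, function(t) t$nodes))
    shift <- 2 - apply(allxy, 2, min)
    field_size <- apply(allxy, 2, max) + shift + 2
  }
  px <- optics$pixel_size
  W <- max(8L, ceiling(field_size[1] / px))
  H <- max(8L, ceiling(field_size[2] / px))
  frames <- sort(unique(vapply(traces, function(t) t$frame, integer(1))))
  out <- array(0, dim = c(H, W, length(frames)))
  sigma <- optics$psf_sigma
  halfw <- ceiling(4 * sigma)
  step <- 0.25  # px of arc per PSF deposit
  maxval <- 2^optics$bit_depth - 1
  clipped <- FALSE
  for (fi in seq_along(frames)) {
    acc <- matrix(0, H, W)
    for (tr in traces) {
      if (tr$frame != frames[fi]) next
      nodes_px <- sweep(tr$nodes, 2, shift, "+") / px + 0.5
      pts <- .resample_polyline(nodes_px, step)
      inside <- pts[, 1] >= 0.5 - halfw & pts[, 1] <= W + 0.5 + halfw &
        pts[, 2] >= 0.5 - halfw & pts[, 2] <= H + 0.5 + halfw
      if (!all(inside)) clipped <- TRUE
      pts <- pts[inside, , drop = FALSE]
      for (p in seq_len(nrow(pts))) {
        cx <- pts[p, 1]; cy <- pts[p, 2]
        c0 <- max(1L, floor(cx - halfw)); c1 <- min(W, ceiling(cx + halfw))
        r0 <- max(1L, floor(cy - halfw)); r1 <- min(H, ceiling(cy + halfw))
        if (c0 > c1 || r0 > r1) next
        gx <- exp(-((c0:c1) - cx)^2 / (2 * sigma^2))
        gy <- exp(-((r0:r1) - cy)^2 / (2 * sigma^2))
        acc[r0:r1, c0:c1] <- acc[r0:r1, c0:c1] + step * outer(gy, gx)
      }
    }
    mx <- max(acc)
    signal <- if (mx > 0) acc * (optics$peak_intensity / mx) else acc
    lambda <- signal + optics$background
    img <- if (noise) {
      stats::rpois(length(lambda), lambda) +
        stats::rnorm(length(lambda), 0, optics$read_noise_sd)
    } else {
      lambda
    }
    img <- matrix(pmin(pmax(round(img), 0), maxval), H, W)
    out[, , fi] <- img
  }
  if (clipped) warning("some filament nodes fell outside the field and were clipped")
  attr(out, "optics") <- optics
  attr(out, "frames") <- frames
  attr(out, "field_size") <- field_size
  out
}

# resample a polyline (n x 2) at uniform arc spacing `by`, keeping endpoints
.resample_polyline <- function(xy, by) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(xy[1, , drop = FALSE])
  grid <- unique(c(seq(0, total, by = by), total))
  cbind(stats::approx(s, xy[, 1], xout = grid)$y,
        stats::approx(s, xy[, 2], xout = grid)$y)
}

#' Write an image stack as a multi-page TIFF
#'
#' @param frames 3D array `[rows, cols, frames]` (or a single matrix) of
#'   non-negative integer counts.
#' @param path output path.
#' @param bit_depth 8 or 16; taken from the stack's `optics` attribute when
#'   present.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bit_depth = NULL) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1))
  if (is.null(bit_depth)) {
    opt <- attr(frames, "optics")
    bit_depth <- if (!is.null(opt)) opt$bit_depth else 16L
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(frames)[3]), function(i) {
    frames[, , i] / maxval
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  invisible(path)
}

#' Read a multi-page TIFF into an integer image stack
#'
#' @param path TIFF file path.
#' @return 3D array `[rows, cols, frames]` of integer sample values.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse grey stored as RGB
    p
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}
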