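#' Configuration for image-based filament tracing
#'
#' @param smoothing_sigma Gaussian pre-smoothing SD (px).
#' @param threshold_method `"global-otsu"` (Otsu on the smoothed frame) or
#'   `"fixed"` (a fixed fraction of the smoothed intensity range).
#' @param fixed_threshold fraction of the smoothed `max - min` range used
#'   when `threshold_method = "fixed"`. The default 0.5 places the mask edge
#'   at the half-maximum contour, which for a Gaussian-profile filament runs
#'   through the true filament endpoint.
#' @param min_length_px traces shorter than this are dropped.
#' @param node_spacing_px arc spacing of the resampled skeleton nodes;
#'   default 1 px, the customary node spacing for skeleton-based filament
#'   tracking.
#' @param border_margin_px traces with any node within this margin of the
#'   image border are dropped (truncated filaments bias L and R jointly).
#' @param max_extension_px how far each trace end may be extended along its
#'   tangent to undo skeleton end retraction (see [trace_filaments()]).
#' @return object of class `"tracking_config"`.
#' @export
tracking_config <- function(smoothing_sigma = 1,
                            threshold_method = c("global-otsu", "fixed"),
                            fixed_threshold = 0.5,
                            min_length_px = 10,
                            node_spacing_px = 1,
                            border_margin_px = 5,
                            max_extension_px = 5) {
  threshold_method <- match.arg(threshold_method)
  if (node_spacing_px <= 0) stop("`node_spacing_px` must be > 0")
  if (min_length_px < 3) stop("`min_length_px` must be >= 3")
  if (fixed_threshold <= 0 || fixed_threshold >= 1) {
    stop("`fixed_threshold` must be in (0, 1)")
  }
  out <- list(
    smoothing_sigma = smoothing_sigma,
    threshold_method = threshold_method,
    fixed_threshold = fixed_threshold,
    min_length_px = min_length_px,
    node_spacing_px = node_spacing_px,
    border_margin_px = border_margin_px,
    max_extension_px = max_extension_px
  )
  class(out) <- "tracking_config"
  out
}

#' Rescale an image stack to 8-bit
#'
#' Linear min–max rescale of the whole stack (not per frame) to 0..255,
#' rounded. Using one affine map for all frames keeps intensities comparable
#' across time. Idempotent on an already full-range 8-bit stack. A constant
#' stack maps to all zeros with a warning.
#'
#' @param stack numeric matrix, 3D array or list of matrices.
#' @return same shape as the input, integer values 0..255.
#' @export
to_8bit <- function(stack) {
  was_list <- is.list(stack)
  x <- if (was_list) array(unlist(stack), dim = c(dim(stack[[1]]), length(stack))) else stack
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    warning("constant image stack: rescaled to all zeros")
    y <- array(0L, dim = dim(as.array(x)))
  } else {
    y <- round((x - lo) * (255 / (hi - lo)))
    storage.mode(y) <- "integer"
  }
  if (is.matrix(stack)) {
    y <- matrix(y, nrow(stack), ncol(stack))
  } else if (was_list) {
    y <- lapply(seq_along(stack), function(i) y[, , i])
  }
  y
}

#' Trace filament skeletons in one image frame
#'
#' Replaces interactive snake tracing with a deterministic pipeline:
#' Gaussian smoothing, global thresholding, morphological (Zhang–Suen)
#' skeletonisation, extraction of each connected skeleton's longest
#' endpoint-to-endpoint path (ties broken by total intensity along the
#' path), smoothing-spline fit of the path coordinates against arc length,
#' resampling at uniform node spacing, and finally extension of both ends
#' along the local tangent while they remain inside the binary mask (thinning
#' retracts skeleton ends by roughly the stroke half-width; with a half-
#' maximum threshold the mask boundary sits at the true filament end, so the
#' extension removes that bias). Traces shorter than `min_length_px` or
#' touching the border margin are dropped; node order is canonicalised so the
#' first node is the lexicographically smaller endpoint.
#'
#' @param frame numeric image matrix (rows = y, columns = x), typically 8-bit
#'   from [to_8bit()].
#' @param cfg a [tracking_config].
#' @param frame_index frame index stored on the returned traces.
#' @return list of [filament_trace] objects in pixel units (possibly empty).
#'   Coordinates: `x` is the column index, `y` the row index, pixel centres
#'   at integers.
#' @export
trace_filaments <- function(frame, cfg = tracking_config(), frame_index = 1L) {
  stopifnot(is.matrix(frame), inherits(cfg, "tracking_config"))
  sm <- if (cfg$smoothing_sigma > 0) {
    EBImage::gblur(frame, sigma = cfg$smoothing_sigma)
  } else frame
  rng <- range(sm)
  if (rng[2] <= rng[1]) return(list())
  th <- if (cfg$threshold_method == "global-otsu") {
    .otsu_threshold(sm)
  } else {
    rng[1] + cfg$fixed_threshold * (rng[2] - rng[1])
  }
  mask <- sm > th
  if (!any(mask) || all(mask)) return(list())
  bg_level <- stats::median(sm[!mask])
  skel <- .thin_zhang_suen(mask)
  comps <- .skeleton_components(skel)
  H <- nrow(frame); W <- ncol(frame)
  traces <- list()
  for (comp in comps) {
    path <- .longest_skeleton_path(comp, sm)
    if (is.null(path) || nrow(path) < 3L) next
    nodes <- .spline_resample(path, cfg$node_spacing_px)
    nodes <- .refine_ridge(nodes, sm, bg_level)
    nodes <- .spline_resample(nodes, cfg$node_spacing_px, px_per_df = 3)
    nodes <- .extend_into_mask(nodes, sm, bg_level, cfg$node_spacing_px,
                               cfg$max_extension_px)
    if (nrow(nodes) < 2L) next
    clen <- sum(sqrt(diff(nodes[, 1])^2 + diff(nodes[, 2])^2))
    if (clen < cfg$min_length_px) next
    m <- cfg$border_margin_px
    if (any(nodes[, 1] <= m | nodes[, 1] > W - m |
            nodes[, 2] <= m | nodes[, 2] > H - m)) next
    nodes <- .canonical_order(nodes)
    id <- sprintf("X%03d", length(traces) + 1L)
    traces[[length(traces) + 1L]] <-
      filament_trace(id, frame_index, nodes, unit = "px")
  }
  traces
}

# Otsu threshold via EBImage on an intensity range normalised to [0, 1]
.otsu_threshold <- function(img) {
  rng <- range(img)
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  rng[1] + t01 * (rng[2] - rng[1])
}

# Zhang-Suen morphological thinning, vectorised over the whole mask
.thin_zhang_suen <- function(mask) {
  m <- mask
  storage.mode(m) <- "integer"
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  shift <- function(p, dr, dc) p[(2L + dr):(H + 1L + dr), (2L + dc):(W + 1L + dc)]
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      ctr <- pad[2:(H + 1L), 2:(W + 1L)]
      p2 <- shift(pad, -1L, 0L); p3 <- shift(pad, -1L, 1L)
      p4 <- shift(pad, 0L, 1L);  p5 <- shift(pad, 1L, 1L)
      p6 <- shift(pad, 1L, 0L);  p7 <- shift(pad, 1L, -1L)
      p8 <- shift(pad, 0L, -1L); p9 <- shift(pad, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (step == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- ctr == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        changed <- TRUE
        ctr[del] <- 0L
        pad[2:(H + 1L), 2:(W + 1L)] <- ctr
      }
    }
    if (!changed) break
  }
  pad[2:(H + 1L), 2:(W + 1L)] == 1L
}

# connected components of skeleton pixels under 8-connectivity;
# returns a list of per-component edge lists + pixel coordinates
.skeleton_components <- function(skel) {
  idx <- which(skel)
  if (length(idx) == 0L) return(list())
  H <- nrow(skel)
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  key <- idx
  pos <- seq_along(idx)
  names(pos) <- as.character(key)
  edges <- list(); weights <- list()
  # four forward directions cover all 8-neighbour pairs once
  dirs <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)), c(-1L, 1L, sqrt(2)))
  for (d in dirs) {
    r2 <- r + d[1]; c2 <- c + d[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= ncol(skel)
    nb <- (c2[ok] - 1L) * H + r2[ok]
    hit <- !is.na(pos[as.character(nb)])
    if (any(hit)) {
      from <- pos[as.character(key[ok][hit])]
      to <- pos[as.character(nb[hit])]
      edges[[length(edges) + 1L]] <- rbind(from, to)
      weights[[length(weights) + 1L]] <- rep(d[3], sum(hit))
    }
  }
  n <- length(idx)
  if (length(edges) == 0L) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    w <- numeric(0)
  } else {
    ev <- do.call(cbind, edges)
    w <- unlist(weights)
    g <- igraph::graph_from_edgelist(t(ev), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::E(g)$weight <- w
  }
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(n), memb), function(vs) {
    sub <- igraph::induced_subgraph(g, vs)
    list(graph = sub, xy = cbind(x = c[vs], y = r[vs]))
  })
}

# longest endpoint-to-endpoint geodesic through one skeleton component;
# ties broken by total image intensity along the path
.longest_skeleton_path <- function(comp, intensity) {
  g <- comp$graph
  n <- igraph::vcount(g)
  if (n < 3L) return(NULL)
  deg <- igraph::degree(g)
  ends <- which(deg <= 1L)
  if (length(ends) < 2L) {
    # closed loop: split at an arbitrary vertex pair (farthest apart)
    d <- igraph::distances(g, v = 1, weights = igraph::E(g)$weight)
    ends <- c(1L, which.max(d))
    if (length(unique(ends)) < 2L) return(NULL)
  }
  dmat <- igraph::distances(g, v = ends, to = ends,
                            weights = igraph::E(g)$weight)
  dmat[!is.finite(dmat)] <- -Inf
  best <- max(dmat)
  cand <- which(dmat >= best - 1e-9, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  best_path <- NULL
  best_int <- -Inf
  for (i in seq_len(nrow(cand))) {
    vp <- igraph::shortest_paths(
      g, from = ends[cand[i, 1]], to = ends[cand[i, 2]],
      weights = igraph::E(g)$weight
    )$vpath[[1]]
    vs <- as.integer(vp)
    if (length(vs) < 2L) next
    xy <- comp$xy[vs, , drop = FALSE]
    tot <- sum(intensity[cbind(xy[, 2], xy[, 1])])
    if (tot > best_int) {
      best_int <- tot
      best_path <- xy
    }
  }
  best_path
}

# smoothing-spline fit of (x, y) against arc length, resampled uniformly
.spline_resample <- function(path, spacing, px_per_df = 6) {
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) return(path)
  grid <- unique(c(seq(0, total, by = spacing), total))
  n <- nrow(path)
  if (n >= 8L) {
    # ~one basis function per `px_per_df` px of arc: 6 px irons out raw
    # skeleton jaggedness, 3 px tracks curvature of ridge-refined nodes
    df <- max(4, min(n - 2, ceiling(total / px_per_df)))
    fx <- stats::smooth.spline(s, path[, 1], df = df)
    fy <- stats::smooth.spline(s, path[, 2], df = df)
    cbind(stats::predict(fx, grid)$y, stats::predict(fy, grid)$y)
  } else {
    cbind(stats::approx(s, path[, 1], xout = grid)$y,
          stats::approx(s, path[, 2], xout = grid)$y)
  }
}

# pull each node to the sub-pixel intensity centroid along the local normal:
# skeleton pixels are quantised to the grid, the PSF ridge is not
.refine_ridge <- function(nodes, sm, bg, halfwidth = 3, step = 0.5,
                          iters = 2L) {
  H <- nrow(sm); W <- ncol(sm)
  offs <- seq(-halfwidth, halfwidth, by = step)
  n <- nrow(nodes)
  if (n < 3L) return(nodes)
  for (it in seq_len(iters)) {
    tang <- rbind(nodes[2, ] - nodes[1, ],
                  nodes[3:n, ] - nodes[1:(n - 2), ],
                  nodes[n, ] - nodes[n - 1, ])
    len <- sqrt(rowSums(tang^2))
    len[len == 0] <- 1
    nx <- -tang[, 2] / len
    ny <- tang[, 1] / len
    for (i in seq_len(n)) {
      px <- nodes[i, 1] + offs * nx[i]
      py <- nodes[i, 2] + offs * ny[i]
      ok <- px >= 1 & px <= W & py >= 1 & py <= H
      if (sum(ok) < 3L) next
      c0 <- floor(px[ok]); r0 <- floor(py[ok])
      c1 <- pmin(c0 + 1L, W); r1 <- pmin(r0 + 1L, H)
      fx <- px[ok] - c0; fy <- py[ok] - r0
      v <- (1 - fy) * ((1 - fx) * sm[cbind(r0, c0)] + fx * sm[cbind(r0, c1)]) +
        fy * ((1 - fx) * sm[cbind(r1, c0)] + fx * sm[cbind(r1, c1)])
      w <- pmax(v - bg, 0)
      if (sum(w) <= 0) next
      shift <- sum(w * offs[ok]) / sum(w)
      shift <- max(min(shift, 1), -1)
      nodes[i, 1] <- nodes[i, 1] + shift * nx[i]
      nodes[i, 2] <- nodes[i, 2] + shift * ny[i]
    }
  }
  nodes
}

# extend both trace ends along the local tangent up to the sub-pixel
# half-maximum crossing of the smoothed image. Thinning retracts skeleton
# ends by roughly the stroke half-width; for a Gaussian-profile filament the
# intensity at the true end is background + half the local ridge height, so
# marching to that level relocates the end without overshoot even when the
# global threshold sits below half-max.
.extend_into_mask <- function(nodes, sm, bg, spacing, max_ext) {
  if (max_ext <= 0 || nrow(nodes) < 2L) return(nodes)
  H <- nrow(sm); W <- ncol(sm)
  value_at <- function(p) {
    cx <- p[1]; cy <- p[2]
    if (cx < 1 || cx > W || cy < 1 || cy > H) return(-Inf)
    c0 <- floor(cx); r0 <- floor(cy)
    c1 <- min(c0 + 1L, W); r1 <- min(r0 + 1L, H)
    fx <- cx - c0; fy <- cy - r0
    (1 - fy) * ((1 - fx) * sm[r0, c0] + fx * sm[r0, c1]) +
      fy * ((1 - fx) * sm[r1, c0] + fx * sm[r1, c1])
  }
  fine <- spacing / 4
  grow <- function(tip, prev, ridge_ref) {
    v <- tip - prev
    v <- v / sqrt(sum(v^2))
    # ridge height is sampled a few px inside the trace: the tip itself sits
    # in the end roll-off, which would bias the half-max level low
    level <- bg + 0.5 * (value_at(ridge_ref) - bg)
    out <- NULL
    p <- tip
    for (i in seq_len(ceiling(max_ext / fine))) {
      q <- p + fine * v
      if (value_at(q) < level) break
      p <- q
      out <- rbind(out, p)
    }
    if (is.null(out)) return(NULL)
    keep <- unique(c(seq_len(nrow(out))[seq_len(nrow(out)) %% 4L == 0L],
                     nrow(out)))
    out[keep, , drop = FALSE]
  }
  n <- nrow(nodes)
  arc <- c(0, cumsum(sqrt(diff(nodes[, 1])^2 + diff(nodes[, 2])^2)))
  ih <- which.min(abs(arc - min(4 * spacing, arc[n] / 2)))
  it <- which.min(abs(arc - max(arc[n] - 4 * spacing, arc[n] / 2)))
  head_ext <- grow(nodes[1, ], nodes[2, ], nodes[ih, ])
  tail_ext <- grow(nodes[n, ], nodes[n - 1, ], nodes[it, ])
  if (!is.null(head_ext)) {
    nodes <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], nodes)
  }
  if (!is.null(tail_ext)) nodes <- rbind(nodes, tail_ext)
  unname(nodes)
}

# first node = lexicographically smaller endpoint (x, then y)
.canonical_order <- function(nodes) {
  a <- round(nodes[1, ], 3)
  b <- round(nodes[nrow(nodes), ], 3)
  if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) {
    nodes <- nodes[rev(seq_len(nrow(nodes))), , drop = FALSE]
  }
  nodes
}

#' Link per-frame traces into track stacks
#'
#' Greedy nearest-centroid linking: frames are processed in order and each
#' trace is assigned to the open stack whose last centroid is nearest, if
#' within `max_disp`; otherwise it opens a new stack. Distance ties are
#' broken deterministically towards the stack with the smaller id. Stacks
#' covering fewer than `min_frames` frames are flagged (attribute
#' `"flagged_short"`), and skipped frames are counted (attribute `"gaps"`).
#'
#' @param per_frame_traces either a list of lists of [filament_trace] (one
#'   inner list per frame) or a flat list of traces carrying frame indices.
#' @param max_disp maximum centroid displacement (same unit as the traces)
#'   allowed between consecutive detections.
#' @param min_frames stacks with fewer frames are flagged, default 100 (the
#'   lower end of the customary 100–200 frame averaging window).
#' @return list of [track_stack] objects with ids `T001`, `T002`, ... in
#'   order of first appearance.
#' @export
link_frames <- function(per_frame_traces, max_disp = 15, min_frames = 100L) {
  traces <- .collect_traces(per_frame_traces)
  if (length(traces) == 0L) return(list())
  frames <- vapply(traces, function(t) t$frame, integer(1))
  ord <- order(frames)
  traces <- traces[ord]
  frames <- frames[ord]
  cent <- t(vapply(traces, function(t) colMeans(t$nodes), numeric(2)))
  stacks <- list()      # each: list(traces =, cent =, last_frame =, gaps =)
  for (f in sort(unique(frames))) {
    id_here <- which(frames == f)
    open <- seq_along(stacks)
    taken_stack <- logical(length(stacks))
    # all candidate (stack, trace) pairs within the gate, greedy by distance
    if (length(stacks) > 0L && length(id_here) > 0L) {
      dm <- outer(seq_along(stacks), id_here, Vectorize(function(si, ti) {
        sqrt(sum((stacks[[si]]$cent - cent[ti, ])^2))
      }))
      assigned <- logical(length(id_here))
      repeat {
        dmin <- suppressWarnings(min(dm[!taken_stack, !assigned, drop = FALSE]))
        if (!is.finite(dmin) || dmin > max_disp) break
        hit <- which(dm == dmin & outer(!taken_stack, !assigned, "&"),
                     arr.ind = TRUE)
        hit <- hit[order(hit[, 1]), , drop = FALSE]  # tie-break: smaller stack id
        si <- hit[1, 1]; tj <- hit[1, 2]
        ti <- id_here[tj]
        st <- stacks[[si]]
        if (st$last_frame < f - 1L) st$gaps <- st$gaps + (f - 1L - st$last_frame)
        st$traces[[length(st$traces) + 1L]] <- traces[[ti]]
        st$cent <- cent[ti, ]
        st$last_frame <- f
        stacks[[si]] <- st
        taken_stack[si] <- TRUE
        assigned[tj] <- TRUE
        dm[si, ] <- Inf
        dm[, tj] <- Inf
      }
      id_here <- id_here[!assigned]
    }
    for (ti in id_here) {
      stacks[[length(stacks) + 1L]] <- list(
        traces = list(traces[[ti]]), cent = cent[ti, ],
        last_frame = f, gaps = 0L
      )
    }
  }
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    id <- sprintf("T%03d", i)
    trs <- lapply(stacks[[i]]$traces, function(t) {
      t$filament_id <- id
      t
    })
    st <- track_stack(trs, filament_id = id)
    attr(st, "flagged_short") <- length(trs) < min_frames
    attr(st, "gaps") <- stacks[[i]]$gaps
    out[[i]] <- st
  }
  out
}
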