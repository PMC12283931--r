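#' Contour length of a filament trace
#'
#' Sum of Euclidean distances between consecutive nodes.
#'
#' @param trace a [filament_trace], or a two-column numeric matrix of nodes.
#' @param pixel_size µm per pixel; required to convert pixel-unit traces,
#'   ignored for µm traces. When `NULL` and the trace is in px, the length is
#'   returned in px.
#' @return contour length (µm, or px for an unconverted pixel trace).
#' @export
contour_length <- function(trace, pixel_size = NULL) {
  nodes <- .as_nodes(trace, pixel_size)
  sum(sqrt(diff(nodes[, 1])^2 + diff(nodes[, 2])^2))
}

#' End-to-end distance of a filament trace
#'
#' Euclidean distance between the first and the last node.
#'
#' @inheritParams contour_length
#' @return end-to-end distance (same unit rules as [contour_length()]).
#' @export
end_to_end <- function(trace, pixel_size = NULL) {
  nodes <- .as_nodes(trace, pixel_size)
  n <- nrow(nodes)
  unname(sqrt((nodes[n, 1] - nodes[1, 1])^2 + (nodes[n, 2] - nodes[1, 2])^2))
}

.as_nodes <- function(trace, pixel_size = NULL) {
  if (inherits(trace, "filament_trace")) {
    nodes <- trace$nodes
    if (trace$unit == "px" && !is.null(pixel_size)) nodes <- nodes * pixel_size
  } else {
    nodes <- as.matrix(trace)
    if (!is.null(pixel_size)) nodes <- nodes * pixel_size
  }
  if (!is.numeric(nodes) || ncol(nodes) != 2L || nrow(nodes) < 2L) {
    stop("a trace needs at least 2 nodes of (x, y) coordinates")
  }
  nodes
}

#' Frame-averaged fluctuation summary of one filament
#'
#' Reduces a track stack to the single datum used by the worm-like-chain
#' fit: the frame-averaged contour length `L` and the frame-averaged squared
#' end-to-end distance `msR` (\eqn{\langle R^2 \rangle}). Contour length is
#' averaged across frames as well, since for an inextensible filament it
#' varies only by tracking noise. A warning is raised outside the customary
#' 100–200 frame range, where \eqn{\langle R^2 \rangle} is either noisy or
#' wastefully oversampled.
#'
#' @param stack a [track_stack].
#' @param pixel_size µm per pixel for pixel-unit traces.
#' @param check_frames warn when the number of frames is outside 100–200.
#' @return one-row data frame: `filament_id`, `L` (µm), `msR` (µm²),
#'   `n_frames`, `sd_R2` (µm², sample SD of per-frame R²; `NA` for a single
#'   frame).
#' @export
mean_square_r2 <- function(stack, pixel_size = NULL, check_frames = TRUE) {
  stopifnot(inherits(stack, "track_stack"))
  n <- length(stack$traces)
  if (n < 1L) stop("empty track stack")
  if (check_frames && (n < 100L || n > 200L)) {
    warning(sprintf("stack %s has %d frames (customary range 100-200)",
                    stack$filament_id, n))
  }
  Ls <- vapply(stack$traces, contour_length, numeric(1), pixel_size = pixel_size)
  R2 <- vapply(stack$traces, end_to_end, numeric(1), pixel_size = pixel_size)^2
  data.frame(
    filament_id = stack$filament_id,
    L = mean(Ls),
    msR = mean(R2),
    n_frames = n,
    sd_R2 = if (n > 1L) stats::sd(R2) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Fluctuation summary table for many filaments
#'
#' Applies [mean_square_r2()] to each stack and binds the rows; the result
#' feeds [fit_persistence_length()] directly.
#'
#' @param stacks list of [track_stack] objects.
#' @inheritParams mean_square_r2
#' @return data frame with one row per filament.
#' @export
mechanics_table <- function(stacks, pixel_size = NULL, check_frames = TRUE) {
  if (inherits(stacks, "track_stack")) stacks <- list(stacks)
  do.call(rbind, lapply(stacks, mean_square_r2,
                        pixel_size = pixel_size, check_frames = check_frames))
}

#' Write / read the per-filament mechanics table
#'
#' Tab-separated with columns `filament_id`, `L`, `msR`, `n_frames`, `sd_R2`.
#'
#' @param table data frame from [mechanics_table()].
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_mechanics_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mechanics_table
#' @export
read_mechanics_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
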