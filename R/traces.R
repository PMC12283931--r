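#' Ordered node coordinates of one filament in one frame
#'
#' The unit of all filament geometry: an ordered polyline of 2D node
#' positions, with cumulative arc length, in either microns (`"um"`) or
#' pixels (`"px"`).
#'
#' @param filament_id identifier (character or coercible).
#' @param frame frame index (integer >= 1).
#' @param nodes two-column numeric matrix (x, y), at least 2 rows.
#' @param unit `"um"` or `"px"`.
#' @return object of class `"filament_trace"`: list with `filament_id`,
#'   `frame`, `nodes`, `arc` (cumulative arc length from 0) and `unit`.
#' @export
filament_trace <- function(filament_id, frame, nodes, unit = c("um", "px")) {
  unit <- match.arg(unit)
  nodes <- as.matrix(nodes)
  if (!is.numeric(nodes) || ncol(nodes) != 2L || nrow(nodes) < 2L) {
    stop("`nodes` must be a numeric matrix with 2 columns and >= 2 rows")
  }
  if (any(!is.finite(nodes))) stop("`nodes` contains non-finite coordinates")
  colnames(nodes) <- c("x", "y")
  seg <- sqrt(diff(nodes[, 1])^2 + diff(nodes[, 2])^2)
  if (any(seg == 0)) stop("consecutive duplicate nodes: arc length must be strictly increasing")
  out <- list(
    filament_id = as.character(filament_id),
    frame = as.integer(frame),
    nodes = nodes,
    arc = c(0, cumsum(seg)),
    unit = unit
  )
  class(out) <- "filament_trace"
  out
}

#' @export
print.filament_trace <- function(x, ...) {
  cat(sprintf("filament_trace %s frame %d: %d nodes, contour %.3f %s\n",
              x$filament_id, x$frame, nrow(x$nodes),
              max(x$arc), x$unit))
  invisible(x)
}

#' All traces of one filament across frames
#'
#' @param traces list of [filament_trace] objects sharing one `filament_id`,
#'   with unique frame indices.
#' @param filament_id optional identifier; defaults to the traces' common id.
#' @return object of class `"track_stack"`: list with `filament_id` and
#'   `traces` sorted by frame.
#' @export
track_stack <- function(traces, filament_id = NULL) {
  if (length(traces) < 1L) stop("a track stack needs at least one trace")
  ids <- vapply(traces, function(t) t$filament_id, character(1))
  if (is.null(filament_id)) filament_id <- ids[1]
  if (!all(ids == filament_id)) stop("all traces must share one filament_id")
  frames <- vapply(traces, function(t) t$frame, integer(1))
  if (anyDuplicated(frames)) stop("frame indices must be unique within a stack")
  out <- list(filament_id = as.character(filament_id),
              traces = traces[order(frames)])
  class(out) <- "track_stack"
  out
}

#' @export
print.track_stack <- function(x, ...) {
  fr <- vapply(x$traces, function(t) t$frame, integer(1))
  cat(sprintf("track_stack %s: %d frames (%d..%d)\n",
              x$filament_id, length(fr), min(fr), max(fr)))
  invisible(x)
}

# flatten stacks / traces / single objects into a plain list of traces
.collect_traces <- function(x) {
  if (inherits(x, "filament_trace")) return(list(x))
  if (inherits(x, "track_stack")) return(x$traces)
  if (is.list(x)) return(unlist(lapply(x, .collect_traces), recursive = FALSE))
  stop("expected filament_trace / track_stack objects")
}

# node matrix in microns; pixel traces need a pixel size
.nodes_um <- function(trace, pixel_size = NULL) {
  if (trace$unit == "um") return(trace$nodes)
  if (is.null(pixel_size)) {
    stop("trace is in pixel units: supply `pixel_size` (um/px)")
  }
  trace$nodes * pixel_size
}

#' Write traces to a tab-separated trace table
#'
#' One node per row with columns `filament_id`, `frame`, `node_index`, `x`,
#' `y`, `unit`; the exchange format between the simulator, the tracker and
#' the mechanics functions.
#'
#' @param x a track stack, a list of stacks, a trace, or a list of traces.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(x, path) {
  traces <- .collect_traces(x)
  tabs <- lapply(traces, function(tr) {
    data.frame(
      filament_id = tr$filament_id,
      frame = tr$frame,
      node_index = seq_len(nrow(tr$nodes)),
      x = tr$nodes[, 1], y = tr$nodes[, 2],
      unit = tr$unit,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace table into track stacks
#'
#' @param path tab-separated file written by [write_trace_table()] (columns
#'   `filament_id`, `frame`, `node_index`, `x`, `y`, `unit`).
#' @return list of [track_stack] objects, one per filament id.
#' @export
read_trace_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("filament_id", "frame", "node_index", "x", "y", "unit")
  if (!all(need %in% names(tab))) {
    stop("trace table must have columns: ", paste(need, collapse = ", "))
  }
  stacks <- lapply(split(tab, tab$filament_id), function(ft) {
    traces <- lapply(split(ft, ft$frame), function(fr) {
      fr <- fr[order(fr$node_index), ]
      filament_trace(fr$filament_id[1], fr$frame[1],
                     cbind(fr$x, fr$y), unit = fr$unit[1])
    })
    track_stack(unname(traces))
  })
  unname(stacks)
}

#' Read snake-style filament traces exported as plain text
#'
#' Tolerant reader for snake/active-contour exports (e.g. JFilament-style
#' text files), so externally tracked traces can bypass the image-based
#' tracker. Blocks of whitespace-separated numeric rows are interpreted by
#' column count: 2 columns as `x y` (frame taken from `frame`), 3 columns as
#' `frame x y`, 4+ columns as `id frame x y`. A comment line starting with
#' `#` starts a new snake; its first token after `#`, if any, names it.
#'
#' @param path text file path.
#' @param unit coordinate unit of the file, `"px"` (default) or `"um"`.
#' @param frame frame index used for 2-column rows.
#' @return list of [track_stack] objects.
#' @export
read_snakes <- function(path, unit = c("px", "um"), frame = 1L) {
  unit <- match.arg(unit)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  snake <- 0L
  snake_name <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "#")) {
      snake <- snake + 1L
      tok <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]]
      snake_name <- if (length(tok) >= 1L && nzchar(tok[1])) tok[1] else NULL
      next
    }
    v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t,]+")[[1]]))
    if (any(is.na(v)) || length(v) < 2L) next
    if (snake == 0L) snake <- 1L
    id <- if (!is.null(snake_name)) snake_name else sprintf("S%03d", snake)
    rows[[length(rows) + 1L]] <- switch(
      min(length(v), 4L) - 1L,
      data.frame(id = id, frame = as.integer(frame), x = v[1], y = v[2]),
      data.frame(id = id, frame = as.integer(v[1]), x = v[2], y = v[3]),
      data.frame(id = as.character(v[1]), frame = as.integer(v[2]),
                 x = v[3], y = v[4])
    )
  }
  if (length(rows) == 0L) stop("no numeric snake rows found in ", path)
  tab <- do.call(rbind, rows)
  stacks <- lapply(split(tab, tab$id), function(ft) {
    traces <- lapply(split(ft, ft$frame), function(fr) {
      filament_trace(fr$id[1], fr$frame[1], cbind(fr$x, fr$y), unit = unit)
    })
    track_stack(unname(traces))
  })
  unname(stacks)
}
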