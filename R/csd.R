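#' Current source density from laminar LFP
#'
#' Averages the local field potential across trials and applies the
#' second-spatial-difference stencil `(V[i-1] - 2 V[i] + V[i+1]) / h^2`
#' along the probe, dropping the two edge channels that lack a neighbor.
#' Under the default sink-positive orientation the map's maximum marks the
#' strongest current sink (the hallmark of the granular input layer); the
#' map is normalized to `[-1, 1]` by its maximum absolute value.
#'
#' @param lfp numeric array channels x time x trials (a channels x time
#'   matrix is treated as a single trial).
#' @param spacing inter-channel spacing (e.g. micrometres); uniform.
#' @param time_axis optional time axis in ms (default `0, 1, ...`).
#' @param sign_convention `"sink_positive"` (default) orients the map so
#'   that a focal negative LFP deflection (an extracellular sink) appears
#'   as a positive CSD peak; `"source_positive"` negates the map.
#' @return Object of class `"csd_map"`: `values` (depth x time, normalized),
#'   `depth_positions` (distances of the interior channels along the
#'   probe, `spacing * (1..N-2)` for channels `2..N-1`), `time_axis`,
#'   `spacing`, `sign_convention`, `scale` (the normalization constant).
#' @export
compute_csd <- function(lfp, spacing, time_axis = NULL,
                        sign_convention = c("sink_positive",
                                            "source_positive")) {
  sign_convention <- match.arg(sign_convention)
  if (is.matrix(lfp)) lfp <- array(lfp, dim = c(dim(lfp), 1L))
  d <- dim(lfp)
  if (length(d) != 3L) stop("`lfp` must be channels x time x trials")
  if (d[1L] < 3L) stop("need at least 3 channels for the CSD stencil")
  if (spacing <= 0) stop("`spacing` must be positive")
  V <- rowMeans(lfp, dims = 2L)  # trial-averaged, channels x time
  i <- 2:(d[1L] - 1L)
  second_diff <- (V[i - 1L, , drop = FALSE] - 2 * V[i, , drop = FALSE] +
                    V[i + 1L, , drop = FALSE]) / spacing^2
  vals <- if (sign_convention == "sink_positive") second_diff else -second_diff
  scale <- max(abs(vals))
  if (scale > 0) vals <- vals / scale
  structure(list(values = vals,
                 depth_positions = spacing * (i - 1L),
                 time_axis = if (is.null(time_axis)) seq_len(d[2L]) - 1
                             else time_axis,
                 spacing = spacing, sign_convention = sign_convention,
                 scale = scale),
            class = "csd_map")
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("CSD map: %d depths x %d time points, spacing %g (%s)\n",
              nrow(x$values), ncol(x$values), x$spacing,
              x$sign_convention))
  invisible(x)
}

#' Locate the strongest current sink
#'
#' Finds the point of maximal current inflow in the CSD map within a time
#' window (default 20-100 ms after stimulus onset, the time of the initial
#' stimulus-evoked sink in the granular layer).
#'
#' @param csd a `"csd_map"` (sink-positive orientation assumed).
#' @param window half-open time window `[from, to)` in ms.
#' @return List with `depth_index`, `time_index` (indices into the map),
#'   `depth` and `time` (physical coordinates), and `value`.
#' @export
locate_strongest_sink <- function(csd, window = c(20, 100)) {
  stopifnot(inherits(csd, "csd_map"))
  tt <- csd$time_axis
  jj <- which(tt >= window[1] & tt < window[2])
  if (length(jj) == 0L) stop("window outside the time axis")
  sub <- csd$values[, jj, drop = FALSE]
  if (all(sub == 0)) stop("all-zero CSD map; no sink to locate")
  am <- arrayInd(which.max(sub), dim(sub))
  list(depth_index = am[1L], time_index = jj[am[2L]],
       depth = csd$depth_positions[am[1L]], time = tt[jj[am[2L]]],
       value = sub[am[1L], am[2L]])
}

#' Granular-layer borders from the spatial covariance of the CSD
#'
#' Computes the spatial covariance of the CSD map,
#' `C = (1/N_time) A A^T` (raw Gram form over time), takes the covariance
#' vector through the strongest sink channel, and walks outward from the
#' sink peak on each side to the first sign change. The zero crossings
#' (linearly interpolated between channels) are the upper and lower border
#' of the granular (G) layer: channels above the upper border are
#' supragranular (SG), channels below the lower border infragranular (IG).
#'
#' @param csd a `"csd_map"`.
#' @param window sink-search time window in ms, see
#'   [locate_strongest_sink()].
#' @param mean_subtract if `TRUE`, use the mean-subtracted covariance
#'   instead of the raw Gram matrix (off by default).
#' @return Object of class `"layer_assignment"`: `borders`
#'   (`upper`/`lower` depths), `channel_layers` (per interior channel),
#'   `sink`, `c_max` (the covariance vector), `covariance`,
#'   `depth_positions`, `border_warning` (`TRUE` when a side had no zero
#'   crossing and the border was set to the probe end).
#' @export
layer_borders <- function(csd, window = c(20, 100), mean_subtract = FALSE) {
  stopifnot(inherits(csd, "csd_map"))
  sink <- locate_strongest_sink(csd, window)
  A <- csd$values
  if (mean_subtract) A <- A - rowMeans(A)
  C <- tcrossprod(A) / ncol(A)
  c_max <- C[, sink$depth_index]
  dpos <- csd$depth_positions
  i0 <- sink$depth_index
  warn <- FALSE
  cross_out <- function(dir) {  # dir = -1 up, +1 down
    i <- i0
    while (TRUE) {
      nxt <- i + dir
      if (nxt < 1L || nxt > length(c_max)) {
        warn <<- TRUE
        return(dpos[i])  # no sign change before the probe end
      }
      if (sign(c_max[nxt]) != sign(c_max[i0]) || c_max[nxt] == 0) {
        # linear interpolation of the zero crossing between i and nxt
        f <- c_max[i] / (c_max[i] - c_max[nxt])
        return(dpos[i] + f * (dpos[nxt] - dpos[i]))
      }
      i <- nxt
    }
  }
  upper <- cross_out(-1L)
  lower <- cross_out(+1L)
  channel_layers <- ifelse(dpos < upper, "SG",
                           ifelse(dpos > lower, "IG", "G"))
  if (warn)
    warning("no zero crossing on one side of the sink; border set to probe end")
  structure(list(borders = c(upper = upper, lower = lower),
                 channel_layers = channel_layers, sink = sink,
                 c_max = c_max, covariance = C, depth_positions = dpos,
                 border_warning = warn, neuron_layers = NULL),
            class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  cat(sprintf(
    "Layer assignment: G layer between depths %.1f and %.1f (sink at %.1f)\n",
    x$borders["upper"], x$borders["lower"], x$sink$depth))
  if (!is.null(x$neuron_layers)) {
    tab <- table(factor(x$neuron_layers, levels = c("SG", "G", "IG")))
    cat(sprintf("  neurons: %d SG, %d G, %d IG\n", tab[1], tab[2], tab[3]))
  }
  invisible(x)
}

#' Assign neurons to cortical layers by recording depth
#'
#' Partitions neurons by their probe depth relative to the granular-layer
#' borders: above the upper border supragranular (SG), below the lower
#' border infragranular (IG), otherwise granular (G). Depths exactly on a
#' border go to G (deterministic tie rule).
#'
#' @param depths per-neuron depth along the probe (same units as the
#'   border depths); must lie within the probe span.
#' @param assignment a `"layer_assignment"` from [layer_borders()].
#' @param probe_span optional length-2 span of valid depths; defaults to
#'   the full probe (0 to one spacing beyond the deepest interior
#'   channel).
#' @return The `"layer_assignment"` with `neuron_layers` filled in
#'   (character vector of `"SG"`/`"G"`/`"IG"`).
#' @export
assign_neurons <- function(depths, assignment, probe_span = NULL) {
  stopifnot(inherits(assignment, "layer_assignment"))
  dpos <- assignment$depth_positions
  spacing <- diff(dpos[1:2])
  if (is.null(probe_span)) probe_span <- c(0, max(dpos) + spacing)
  if (any(depths < probe_span[1] | depths > probe_span[2]))
    stop("neuron depth outside the probe span")
  b <- assignment$borders
  assignment$neuron_layers <- ifelse(depths < b["upper"], "SG",
                                     ifelse(depths > b["lower"], "IG", "G"))
  assignment
}

#' Write layer borders and assignments as delimited text
#'
#' @param assignment a `"layer_assignment"` (with or without neuron
#'   assignments).
#' @param path output file path.
#' @param session_id session identifier.
#' @return `path`, invisibly.
#' @export
write_layers <- function(assignment, path, session_id = "session") {
  rows <- data.frame(session = session_id,
                     item = c("border_upper", "border_lower", "sink_depth"),
                     value = c(assignment$borders["upper"],
                               assignment$borders["lower"],
                               assignment$sink$depth))
  if (!is.null(assignment$neuron_layers))
    rows <- rbind(rows, data.frame(
      session = session_id,
      item = paste0("neuron_", seq_along(assignment$neuron_layers)),
      value = assignment$neuron_layers))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
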