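#' Write a spike train set as plain-text files
#'
#' Portable text layout: one spike-times file per neuron
#' (`spikes_<neuron_id>.txt`, lines of `trial_id time_ms`), a
#' `labels.txt` (lines of `trial_id label`), and a `meta.json` carrying
#' bin width, window start, epoch, bin count, session id and optional
#' neuron depths.
#'
#' @param x a [spike_train_set()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_spike_session <- function(x, dir) {
  stopifnot(inherits(x, "spike_train_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tt <- time_axis(x)
  for (n in seq_len(x$n_neurons)) {
    idx <- which(x$spikes[n, , ] == 1L, arr.ind = TRUE)
    df <- data.frame(trial_id = idx[, 1L], time_ms = tt[idx[, 2L]])
    df <- df[order(df$trial_id, df$time_ms), ]
    utils::write.table(df, file.path(dir, paste0("spikes_", x$neuron_ids[n],
                                                 ".txt")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(data.frame(trial_id = seq_len(x$n_trials),
                                label = x$labels),
                     file.path(dir, "labels.txt"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(bin_width_ms = x$bin_width,
                            window_start_ms = x$window_start,
                            n_bins = x$n_bins, epoch = x$epoch,
                            session_id = x$session_id,
                            neuron_ids = x$neuron_ids,
                            depths = x$depths),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a spike train set from plain-text files
#'
#' Inverse of [write_spike_session()].
#'
#' @param dir directory written by [write_spike_session()].
#' @return A [spike_train_set()].
#' @export
read_spike_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  lab <- utils::read.table(file.path(dir, "labels.txt"), header = TRUE)
  J <- nrow(lab); K <- meta$n_bins
  ids <- meta$neuron_ids
  spk <- array(0L, dim = c(length(ids), J, K))
  for (n in seq_along(ids)) {
    f <- file.path(dir, paste0("spikes_", ids[n], ".txt"))
    df <- utils::read.table(f, header = TRUE)
    if (nrow(df) > 0L) {
      bins <- round((df$time_ms - meta$window_start_ms) / meta$bin_width_ms) + 1L
      spk[cbind(n, df$trial_id, bins)] <- 1L
    }
  }
  spike_train_set(spk, lab$label[order(lab$trial_id)],
                  bin_width = meta$bin_width_ms,
                  window_start = meta$window_start_ms, epoch = meta$epoch,
                  neuron_ids = ids, session_id = meta$session_id,
                  depths = meta$depths)
}
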