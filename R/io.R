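# File interfaces: epoch readers (headered CSV/TSV, one column per
# channel), event tables, and JSON provenance records. The command-line
# front end (inst/cli/rnb) is a thin wrapper over these functions.

#' Read a recording and segment it into epochs
#'
#' Reads a single- or multi-channel numeric table (header row, one column
#' per channel, '.' decimal) and cuts the selected channel into
#' non-overlapping epochs of `epoch_s` seconds. A trailing partial epoch is
#' dropped with a message.
#'
#' @param path File path.
#' @param fs Sampling rate in Hz (required; text tables carry no rate).
#' @param epoch_s Epoch length in seconds.
#' @param channel Column name or index (default 1).
#' @param format `"csv"` or `"tsv"`; default guessed from the extension.
#' @return A list with `epochs` (epochs-by-samples matrix), `fs`,
#'   `n_dropped_s` (seconds dropped from the tail), `channel`.
#' @export
read_epochs <- function(path, fs, epoch_s, channel = 1L, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (missing(fs) || !is.numeric(fs) || fs <= 0) {
    stop("`fs` (Hz) is required for text recordings", call. = FALSE)
  }
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  sep <- if (format == "tsv") "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("malformed table in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.character(channel)) {
    if (!channel %in% names(tab)) stop("unknown channel: ", channel,
                                       call. = FALSE)
  } else if (channel < 1L || channel > ncol(tab)) {
    stop("unknown channel index: ", channel, call. = FALSE)
  }
  x <- tab[[channel]]
  if (!is.numeric(x)) stop("channel is not numeric", call. = FALSE)
  n_ep <- round(epoch_s * fs)
  n_full <- length(x) %/% n_ep
  if (n_full == 0L) stop("recording shorter than one epoch", call. = FALSE)
  dropped <- (length(x) - n_full * n_ep) / fs
  if (dropped > 0) {
    message(sprintf("dropped %.3g s of trailing partial epoch", dropped))
  }
  list(epochs = matrix(x[seq_len(n_full * n_ep)], nrow = n_full,
                       byrow = TRUE),
       fs = fs, n_dropped_s = dropped,
       channel = if (is.character(channel)) channel else names(tab)[channel])
}

#' Write an event table as TSV
#'
#' @param events An `ssw_events` or `tb_events` data.frame.
#' @param path Output path.
#' @param type Event type recorded in the `type` column (default from the
#'   object class).
#' @return Invisibly, `path`.
#' @export
write_events <- function(events, path, type = NULL) {
  if (is.null(type)) {
    type <- if (inherits(events, "tb_events")) "theta_burst" else "slow_wave"
  }
  out <- cbind(event_id = seq_len(nrow(events)), type = type,
               as.data.frame(events))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON provenance record
#'
#' Records the configuration, seed and package version next to an output
#' file so any run can be regenerated bit-identically.
#'
#' @param path Output path of the record (conventionally
#'   `<output>.provenance.json`).
#' @param config A list of the parameters that produced the output.
#' @param seed The seed used (may be `NULL` for deterministic stages).
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(path, config, seed = NULL) {
  rec <- list(
    package = "rnb",
    version = as.character(utils::packageVersion("rnb")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
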