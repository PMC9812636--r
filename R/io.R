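#' Read and write epoched recordings as delimited text
#'
#' The delimited interchange format is plain UTF-8, comma-separated with `.`
#' decimal, and self-describing:
#'
#' ```
#' n_trials,n_channels,samples_per_trial,sampling_rate_hz
#' # channels: <name>,<name>,...
#' <label of trial 1>
#' <channel 1 row of trial 1: samples_per_trial values>
#' ...
#' <label of trial 2>
#' ...
#' ```
#'
#' Values are serialized at full double precision (`%.17g`), so a
#' write/read round trip is bit-exact for finite values.
#'
#' @param path file path.
#' @param format `"delimited"` (the text format above). `"mat"` (the MATLAB
#'   v5 container the BCI-competition distributions use) is recognised but
#'   not supported by this build and raises an error.
#' @return `read_epoched()` returns an [epoched_recording()];
#'   `write_epoched()` returns `path` invisibly.
#' @examples
#' rec <- simulate_recording(synthetic_config(n_trials_per_class = 2,
#'                                            n_channels = 3, seed = 4))
#' f <- tempfile(fileext = ".csv")
#' write_epoched(rec, f)
#' rec2 <- read_epoched(f)
#' identical(rec$trials, rec2$trials)
#' @export
read_epoched <- function(path, format = c("delimited", "mat")) {
  format <- match.arg(format)
  if (format == "mat") {
    abort(paste("MAT container reading is not supported by this build;",
                "convert to the delimited format instead."),
          class = "cssdelm_format_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cssdelm_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) {
    abort("File too short to hold a header and one trial.",
          class = "cssdelm_parse_error")
  }
  hdr <- suppressWarnings(as.numeric(strsplit(lines[1L], ",", fixed = TRUE)[[1L]]))
  if (length(hdr) != 4L || anyNA(hdr)) {
    abort("Malformed header: expected n_trials,n_channels,samples_per_trial,sampling_rate_hz.",
          class = "cssdelm_parse_error")
  }
  nt <- as.integer(hdr[1L]); nc <- as.integer(hdr[2L])
  ns <- as.integer(hdr[3L]); fs <- hdr[4L]
  cursor <- 2L
  channel_names <- NULL
  if (startsWith(lines[2L], "# channels:")) {
    channel_names <- strsplit(trimws(sub("^# channels:", "", lines[2L])),
                              ",", fixed = TRUE)[[1L]]
    cursor <- 3L
  }
  expected <- cursor - 1L + nt * (nc + 1L)
  if (length(lines) < expected) {
    abort(sprintf("Truncated file: expected %d lines, found %d.",
                  expected, length(lines)),
          class = "cssdelm_parse_error")
  }
  trials <- vector("list", nt)
  labels <- integer(nt)
  for (k in seq_len(nt)) {
    lab <- suppressWarnings(as.numeric(lines[cursor]))
    if (is.na(lab)) {
      abort(sprintf("Trial %d: unreadable label line '%s'.", k, lines[cursor]),
            class = "cssdelm_parse_error")
    }
    if (!(lab %in% c(1, 2))) {
      abort(sprintf("Trial %d: invalid label value %s; labels must be 1 or 2.",
                    k, format(lab)),
            class = "cssdelm_validation_error")
    }
    labels[k] <- as.integer(lab)
    rows <- strsplit(lines[(cursor + 1L):(cursor + nc)], ",", fixed = TRUE)
    lens <- lengths(rows)
    if (any(lens != ns)) {
      bad <- which(lens != ns)[1L]
      abort(sprintf(
        "Trial %d, channel %d: %d samples found, header declares %d.",
        k, bad, lens[bad], ns),
        class = "cssdelm_parse_error")
    }
    m <- matrix(suppressWarnings(as.numeric(unlist(rows, use.names = FALSE))),
                nrow = nc, ncol = ns, byrow = TRUE)
    if (anyNA(m)) {
      abort(sprintf("Trial %d contains unreadable numeric values.", k),
            class = "cssdelm_parse_error")
    }
    trials[[k]] <- m
    cursor <- cursor + nc + 1L
  }
  epoched_recording(trials, labels, fs, channel_names)
}

#' @param recording an [epoched_recording()].
#' @rdname read_epoched
#' @export
write_epoched <- function(recording, path) {
  stopifnot(inherits(recording, "epoched_recording"))
  if (n_trials(recording) == 0L) {
    abort("Nothing to serialize: the recording has no trials.",
          class = "cssdelm_validation_error")
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d,%d,%d,%s",
                     n_trials(recording), n_channels(recording),
                     samples_per_trial(recording),
                     num_full(recording$sampling_rate_hz)), con)
  writeLines(paste0("# channels: ",
                    paste(recording$channel_names, collapse = ",")), con)
  for (k in seq_len(n_trials(recording))) {
    tr <- recording$trials[[k]]
    body <- matrix(num_full(tr), nrow = nrow(tr))
    writeLines(c(as.character(recording$labels[k]),
                 apply(body, 1L, paste, collapse = ",")), con)
  }
  invisible(path)
}

# full-precision decimal rendering; round-trips doubles exactly
num_full <- function(x) sprintf("%.17g", x)
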