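#' Construct an SEEG recording
#'
#' A recording holds one patient-period block of multichannel SEEG data as a
#' channels-by-samples matrix together with its sampling rate, ordered
#' channel names and period label.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of unique channel labels, one per
#'   row of `data`.
#' @param period `"pre"` or `"post"` (relative to the thermocoagulation
#'   procedure).
#' @param patient_id Patient identifier.
#'
#' @return An object of class `seeg_recording`: a list with elements
#'   `data`, `fs`, `channel_names`, `period`, `patient_id`.
#' @export
#' @examples
#' rec <- seeg_recording(matrix(rnorm(200), 2, 100), fs = 100,
#'                       channel_names = c("A1", "A2"),
#'                       period = "pre", patient_id = "P01")
#' n_channels(rec)
seeg_recording <- function(data, fs, channel_names, period = c("pre", "post"),
                           patient_id = "P01") {
  period <- match.arg(period)
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` length (", length(channel_names),
         ") must equal the number of rows of `data` (", nrow(data), ")")
  }
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = as.character(channel_names),
         period = period, patient_id = as.character(patient_id)),
    class = "seeg_recording"
  )
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> patient %s, period %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$patient_id, x$period, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.null(attr(x, "band"))) {
    b <- attr(x, "band")
    cat(sprintf("  band: %s (%g-%g Hz)\n", b$name, b$low_hz, b$high_hz))
  }
  invisible(x)
}

#' @rdname seeg_recording
#' @export
n_channels <- function(rec) nrow(rec$data)

#' @rdname seeg_recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

is_recording <- function(x) inherits(x, "seeg_recording")

assert_recording <- function(x) {
  if (!is_recording(x)) stop("expected a `seeg_recording` object")
  invisible(x)
}
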