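#' Line length of a signal window
#'
#' The summed absolute first difference, `sum(|x[i] - x[i-1]|)`, a
#' amplitude- and frequency-sensitive activity measure. Reported as the raw
#' sum (all windows share one length, and within-subject normalization
#' removes constant factors).
#'
#' @param x Numeric vector (one window), length >= 2.
#' @return Non-negative scalar (microvolts); 0 iff `x` is constant.
#' @export
#' @examples
#' line_length(c(0, 1, 0, 1, 0))  # 4
line_length <- function(x) {
  if (length(x) < 2) stop("line length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Approximate entropy of a signal window
#'
#' Classic approximate entropy (self-matches included):
#' `ApEn = Phi^m(r) - Phi^{m+1}(r)`, where `Phi^m(r)` is the mean log
#' fraction of m-length templates within Chebyshev distance `r`. The
#' tolerance is `r = r_factor * sd(x)`, making the statistic invariant to
#' adding a constant and to positive rescaling. Higher values indicate a
#' more irregular, less predictable signal.
#'
#' A constant window (zero standard deviation) carries no pattern
#' information; its entropy is defined as 0.
#'
#' @param x Numeric vector (one window), length > m + 1.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a multiple of the window's sample standard
#'   deviation (default 0.2).
#' @return Non-negative scalar (nats, up to numerical tolerance).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(1000)
#' approximate_entropy(x)
#' approximate_entropy(5 * x + 3)  # identical: affine-invariant
approximate_entropy <- function(x, m = 2, r_factor = 0.2) {
  if (m < 1) stop("embedding dimension m must be >= 1")
  if (length(x) <= m + 1) {
    stop("approximate entropy needs more than m + 1 = ", m + 1, " samples")
  }
  if (r_factor <= 0) stop("r_factor must be positive")
  s <- stats::sd(x)
  if (s == 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r_factor * s)
}

#' Approximate-entropy parameter set
#'
#' @param m Embedding dimension, >= 1.
#' @param r_factor Tolerance multiplier of the window standard deviation.
#' @return A list with class `apen_params`.
#' @export
apen_params <- function(m = 2, r_factor = 0.2) {
  if (m < 1) stop("m must be >= 1")
  if (r_factor <= 0) stop("r_factor must be positive")
  structure(list(m = as.integer(m), r_factor = r_factor),
            class = "apen_params")
}

#' Compute biomarkers for one preprocessed recording
#'
#' Evaluates line length and approximate entropy on every (channel, band,
#' window) cell of a preprocessed recording and returns a tidy feature
#' table.
#'
#' @param ws_by_band Named list of `windowed_signal` objects, one per
#'   canonical band (the output of [preprocess_recording()]).
#' @param params [apen_params()].
#' @param features Which features to compute (subset of `c("ll", "apen")`);
#'   both by default.
#' @return Tibble with columns `patient_id`, `channel_name`, `period`,
#'   `band`, `window_index` and feature columns `ll` and/or `apen`, plus a
#'   `normalized` attribute set to `FALSE`.
#' @export
compute_features <- function(ws_by_band, params = apen_params(),
                             features = c("ll", "apen")) {
  features <- match.arg(features, several.ok = TRUE)
  missing_bands <- setdiff(band_names(), names(ws_by_band))
  if (length(missing_bands)) {
    stop("missing band(s): ", paste(missing_bands, collapse = ", "))
  }
  rows <- list()
  for (bn in names(ws_by_band)) {
    ws <- ws_by_band[[bn]]
    for (ch in names(ws$windows)) {
      mat <- ws$windows[[ch]]
      nw <- nrow(mat)
      row <- tibble::tibble(
        patient_id = ws$patient_id,
        channel_name = ch,
        period = ws$period,
        band = bn,
        window_index = ws$window_index[[ch]]
      )
      if ("ll" %in% features) {
        row$ll <- vapply(seq_len(nw), function(i) line_length(mat[i, ]),
                         numeric(1))
      }
      if ("apen" %in% features) {
        row$apen <- vapply(seq_len(nw), function(i) {
          approximate_entropy(mat[i, ], m = params$m,
                              r_factor = params$r_factor)
        }, numeric(1))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "normalized") <- FALSE
  out
}

feature_cols <- function(ft) intersect(c("ll", "apen"), names(ft))

#' Within-subject z-scoring of a feature table
#'
#' For each (patient, band, feature) group, subtracts the pooled mean and
#' divides by the pooled standard deviation computed over all of that
#' patient's rows -- both periods, all contacts, all windows -- so that
#' inter-individual scale differences are removed while pre/post contrasts
#' within a patient are preserved.
#'
#' @param ft Feature table from [compute_features()] (rows from several
#'   recordings may be bound together first).
#' @return The normalized table (attribute `normalized = TRUE`).
#' @export
zscore_within_subject <- function(ft) {
  fcols <- feature_cols(ft)
  if (!length(fcols)) stop("no feature columns (ll, apen) in table")
  out <- ft
  grp <- paste(ft$patient_id, ft$band, sep = "\r")
  for (fc in fcols) {
    mu <- tapply(ft[[fc]], grp, mean)
    sdv <- tapply(ft[[fc]], grp, stats::sd)
    bad <- names(sdv)[!is.finite(sdv) | sdv == 0]
    if (length(bad)) {
      stop("zero or undefined pooled SD for feature '", fc, "' in group(s): ",
           paste(gsub("\r", "/", bad), collapse = ", "))
    }
    out[[fc]] <- as.numeric((ft[[fc]] - mu[grp]) / sdv[grp])
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Per-contact feature averages
#'
#' Averages the windowed features of each contact, yielding one value per
#' (patient, channel, period, band, feature); these contact means feed the
#' paired statistics and the delta features of the outcome predictor.
#'
#' @param ft A (normalized) feature table.
#' @return Tibble keyed by `patient_id`, `channel_name`, `period`, `band`
#'   with the mean feature columns.
#' @export
contact_average <- function(ft) {
  fcols <- feature_cols(ft)
  out <- dplyr::group_by(ft, .data$patient_id, .data$channel_name,
                         .data$period, .data$band)
  out <- dplyr::summarise(
    out, dplyr::across(dplyr::all_of(fcols), mean), .groups = "drop")
  attr(out, "normalized") <- attr(ft, "normalized")
  out
}
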