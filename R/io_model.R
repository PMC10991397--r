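#' @importFrom stats median approx prcomp varimax rnorm runif rlnorm rbinom sd
#'   var setNames complete.cases aggregate as.formula anova logLik AIC BIC
#'   pchisq confint poly quantile cor terms
#' @importFrom utils read.csv write.csv head tail
NULL

# Internal column contract for a sample stream. Gaze is in normalized screen
# coordinates (origin top-left, y downward); pupil diameters in mm; t in ms.
.stream_cols <- c("t", "pupil_left", "pupil_right",
                  "gaze_left_x", "gaze_left_y", "gaze_right_x", "gaze_right_y")

#' Read a raw eye-tracker sample log
#'
#' Reads a delimited sample log (one row per 300 Hz sample) into a sample
#' stream `data.frame`. Tracker sentinel values (negative pupil diameters,
#' gaze coordinates at the sentinel value) are normalized to `NA`, rows with
#' unparseable timestamps are dropped and counted, and the stream is sorted
#' by time (with a warning if the file was out of order). An `onscreen`
#' column is derived: `TRUE` when at least one eye's gaze falls inside the
#' unit square.
#'
#' @param path file path of a CSV (`dialect = "csv"`) or TSV (`"tsv"`) file
#'   with a header containing columns `t`, `pupil_left`, `pupil_right`,
#'   `gaze_left_x`, `gaze_left_y`, `gaze_right_x`, `gaze_right_y`.
#' @param dialect delimiter dialect, `"csv"` or `"tsv"`.
#' @param sentinel numeric sentinel used by the tracker for missing values
#'   (default -1); any pupil value <= 0 is also treated as missing.
#' @return a `data.frame` of class `sample_stream`, time-sorted, with
#'   attribute `n_malformed` counting dropped rows.
#' @export
read_samples <- function(path, dialect = c("csv", "tsv"), sentinel = -1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("sample log not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(.stream_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("sample log lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  for (cc in .stream_cols) raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  bad <- !is.finite(raw$t)
  n_malformed <- sum(bad)
  raw <- raw[!bad, , drop = FALSE]
  if (nrow(raw) == 0) stop("sample log contains no valid rows: ", path)
  # sentinel normalization: one missing representation (NA) internally
  for (cc in c("pupil_left", "pupil_right")) {
    v <- raw[[cc]]
    v[!is.finite(v) | v == sentinel | v <= 0] <- NA_real_
    raw[[cc]] <- v
  }
  for (cc in c("gaze_left_x", "gaze_left_y", "gaze_right_x", "gaze_right_y")) {
    v <- raw[[cc]]
    v[!is.finite(v) | v == sentinel] <- NA_real_
    raw[[cc]] <- v
  }
  if (is.unsorted(raw$t)) {
    warning("sample timestamps out of order; re-sorting stream")
    raw <- raw[order(raw$t), , drop = FALSE]
  }
  raw <- raw[, .stream_cols, drop = FALSE]
  raw$onscreen <- .onscreen_flag(raw)
  rownames(raw) <- NULL
  attr(raw, "n_malformed") <- n_malformed
  class(raw) <- c("sample_stream", "data.frame")
  raw
}

.onscreen_flag <- function(s) {
  inside <- function(x, y) !is.na(x) & !is.na(y) & x >= 0 & x <= 1 & y >= 0 & y <= 1
  inside(s$gaze_left_x, s$gaze_left_y) | inside(s$gaze_right_x, s$gaze_right_y)
}

#' Write a sample stream to a delimited log
#'
#' Inverse of [read_samples()]: finite values round-trip bit-for-bit
#' (full precision), `NA` is written as the tracker sentinel.
#'
#' @param stream a `sample_stream`.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param sentinel value written for missing fields.
#' @export
write_samples <- function(stream, path, dialect = c("csv", "tsv"),
                          sentinel = -1) {
  dialect <- match.arg(dialect)
  out <- as.data.frame(stream)[, .stream_cols]
  for (cc in .stream_cols) {
    v <- out[[cc]]
    v[is.na(v)] <- sentinel
    out[[cc]] <- sprintf("%.17g", v)
  }
  utils::write.table(out, path, sep = if (dialect == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cut a session stream into per-trial sample sets
#'
#' Each trial receives exactly the samples with
#' `onset <= t < onset + window_ms` (half-open window, so adjacent trials
#' never share a sample). Samples outside all trial windows are dropped.
#'
#' @param stream a `sample_stream`.
#' @param trials trial table with columns `participant_id`, `group`,
#'   `emotion`, `actor`, `trial_index`, `onset` (ms, session time).
#' @param window_ms analysis window length (default 4500 ms, the analysed
#'   portion of each video).
#' @return named list of per-trial `data.frame`s with `t` re-expressed
#'   relative to trial onset; each element carries the trial row as
#'   attribute `meta`.
#' @export
segment_trials <- function(stream, trials, window_ms = 4500) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  on <- trials$onset
  if (any(diff(sort(on)) < window_ms))
    stop("overlapping trial windows: trial onsets closer than ", window_ms, " ms")
  tmax <- max(stream$t)
  if (any(on > tmax))
    stop("trial onset beyond stream end (onset ", max(on), " > ", tmax, ")")
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    sel <- stream$t >= on[i] & stream$t < on[i] + window_ms
    tr <- as.data.frame(stream)[sel, , drop = FALSE]
    tr$t <- tr$t - on[i]
    rownames(tr) <- NULL
    attr(tr, "meta") <- trials[i, , drop = FALSE]
    out[[i]] <- tr
  }
  names(out) <- paste(trials$participant_id, trials$trial_index, sep = ".")
  out
}

#' Load an AOI map from YAML
#'
#' The map defines, per stimulus, named rectangles (`eyes`, `mouth`, and
#' optionally `body`/`background`) in normalized screen coordinates as
#' `[x0, y0, width, height]`. Under the fixed-size policy the eye and mouth
#' rectangles must each span 0.23 of both axes, share their x-extent
#' ("aligned on the x-axis"), be disjoint, and be identical in size across
#' stimuli.
#'
#' @param path YAML file path.
#' @param fixed_size enforce the 0.23 x 0.23 matched-size policy (default).
#' @return an `aoi_map`: named list of stimuli, each a named list of
#'   rectangles `c(x0, y0, w, h)`.
#' @export
load_aoi_map <- function(path, fixed_size = TRUE) {
  if (!file.exists(path)) stop("AOI map not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$stimuli)) stop("AOI map must contain a 'stimuli' block")
  map <- lapply(raw$stimuli, function(stim) {
    lapply(stim, function(r) {
      r <- as.numeric(r)
      if (length(r) != 4 || any(!is.finite(r)))
        stop("malformed AOI rectangle (need [x0, y0, w, h])")
      if (r[3] <= 0 || r[4] <= 0)
        stop("AOI rectangle with nonpositive width/height")
      r
    })
  })
  validate_aoi_map(map, fixed_size = fixed_size)
  class(map) <- "aoi_map"
  map
}

#' Validate an AOI map against the fixed-size policy
#' @param map named list of stimuli, each with `eyes` and `mouth` rectangles.
#' @param fixed_size check the 0.23 span and cross-stimulus equality.
#' @param span required axis span under the fixed-size policy.
#' @return the map, invisibly; errors on violation.
#' @export
validate_aoi_map <- function(map, fixed_size = TRUE, span = 0.23) {
  sizes <- NULL
  for (nm in names(map)) {
    stim <- map[[nm]]
    for (need in c("eyes", "mouth"))
      if (is.null(stim[[need]]))
        stop("stimulus '", nm, "' lacks required AOI '", need, "'")
    e <- stim$eyes; m <- stim$mouth
    if (fixed_size) {
      if (any(abs(c(e[3:4], m[3:4]) - span) > 1e-9))
        stop("stimulus '", nm, "': eye/mouth rectangles must span ",
             span, " of each axis")
      if (any(abs(e[c(1, 3)] - m[c(1, 3)]) > 1e-9))
        stop("stimulus '", nm, "': eye and mouth rectangles must be aligned ",
             "on the x-axis")
      sz <- c(e[3:4], m[3:4])
      if (is.null(sizes)) sizes <- sz
      else if (any(abs(sizes - sz) > 1e-9))
        stop("AOI sizes differ across stimuli under fixed-size policy")
    }
    # disjoint rectangles (no overlap area)
    overlap <- max(0, min(e[1] + e[3], m[1] + m[3]) - max(e[1], m[1])) *
               max(0, min(e[2] + e[4], m[2] + m[4]) - max(e[2], m[2]))
    if (overlap > 0) stop("stimulus '", nm, "': eye and mouth AOIs overlap")
  }
  invisible(map)
}

#' Default AOI map used by the simulator
#'
#' Eye and mouth regions matched in size (23% of each screen axis) and
#' aligned on the x-axis, eyes above mouth, identical for every stimulus.
#'
#' @param stimuli character vector of stimulus names.
#' @return an `aoi_map`.
#' @export
default_aoi_map <- function(stimuli = paste0("stim", 1:12)) {
  rects <- list(eyes  = c(0.385, 0.22, 0.23, 0.23),
                mouth = c(0.385, 0.52, 0.23, 0.23))
  map <- setNames(rep(list(rects), length(stimuli)), stimuli)
  class(map) <- "aoi_map"
  map
}

#' Write an AOI map to YAML
#' @param map an `aoi_map`.
#' @param path output path.
#' @export
write_aoi_map <- function(map, path) {
  yaml::write_yaml(list(stimuli = lapply(unclass(map), function(stim)
    lapply(stim, as.numeric))), path)
  invisible(path)
}

# nominal inter-sample interval (ms) estimated from the data, never assumed
.nominal_dt <- function(t) {
  if (length(t) < 2) return(1000 / 300)
  stats::median(diff(t))
}
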