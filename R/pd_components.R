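# Temporal decomposition of trial-wise pupil traces: PCA on the pooled
# trial x time matrix, varimax rotation of the retained loadings, and
# derivation of serial time windows (T-RC) from the highest-loading time
# points. Pupil dilation measures are window means of the trace.

#' Build the trial x time matrix for PCA
#'
#' Resamples each non-excluded trace onto a common coarser grid (cell means
#' over `grid_ms` cells spanning the analysis window) and stacks trials as
#' rows. Rows with any missing cell are dropped under the default policy.
#'
#' @param traces list of `pupil_trace` objects (see [preprocess_trial()]).
#' @param grid_ms resampling cell width (default 10 ms: 400 columns for the
#'   500-4500 ms window).
#' @param window_start,window_end analysis window (ms).
#' @return numeric matrix (trials x time points) with attributes
#'   `grid` (cell start times) and `trial_keys`.
#' @export
build_trial_matrix <- function(traces, grid_ms = 10,
                               window_start = 500, window_end = 4500) {
  grid <- seq(window_start, window_end - grid_ms, by = grid_ms)
  rows <- list()
  keys <- character(0)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (isTRUE(tr$excluded)) next
    sel <- tr$t >= window_start & tr$t < window_end
    cell <- pmin(floor((tr$t[sel] - window_start) / grid_ms),
                 length(grid) - 1)
    mm <- tapply(tr$response[sel], factor(cell, levels = seq_along(grid) - 1),
                 mean, na.rm = TRUE)
    v <- as.numeric(mm)
    v[is.nan(v)] <- NA_real_
    if (anyNA(v)) next  # default policy: drop incomplete rows
    rows[[nm]] <- v
    keys <- c(keys, nm)
  }
  if (length(rows) < 2)
    stop("fewer than 2 complete traces; cannot build PCA matrix")
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  attr(m, "grid") <- grid
  attr(m, "trial_keys") <- keys
  m
}

#' PCA with varimax rotation of the temporal loadings
#'
#' Column-centered PCA of the trial x time matrix (covariance-based by
#' default). The top `n_components` loading vectors (eigenvector x singular
#' value, i.e. correlation-scaled when `use_correlation`) are
#' varimax-rotated with Kaiser normalization; per-component explained
#' variance is recomputed after rotation. The full eigenvalue spectrum is
#' returned so the component count can be chosen from the scree.
#'
#' @param m matrix from [build_trial_matrix()].
#' @param n_components number of retained components (default 3).
#' @param use_correlation scale columns to unit variance first (default
#'   FALSE: covariance PCA).
#' @return list of class `component_windows` (loadings part): `loadings`,
#'   `rotated`, `explained` (share of total variance per rotated component),
#'   `explained_unrotated`, `scree` (all eigenvalue shares), `grid`,
#'   `rotation` (the orthogonal rotation matrix).
#' @export
extract_rotated_components <- function(m, n_components = 3,
                                       use_correlation = FALSE) {
  pc <- stats::prcomp(m, center = TRUE, scale. = use_correlation)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= 0 || ev[n_components] < .Machine$double.eps * total)
    stop("degenerate covariance: fewer informative dimensions than components")
  if (n_components > sum(ev > 1e-12 * total))
    stop("n_components exceeds matrix rank")
  L <- pc$rotation[, seq_len(n_components), drop = FALSE] %*%
    diag(pc$sdev[seq_len(n_components)], n_components)
  if (n_components == 1) {
    rot <- L
    rotmat <- matrix(1, 1, 1)
  } else {
    vm <- stats::varimax(L, normalize = TRUE)
    rot <- L %*% vm$rotmat
    rotmat <- vm$rotmat
  }
  structure(list(
    loadings = L, rotated = rot,
    explained = colSums(rot^2) / total,
    explained_unrotated = ev[seq_len(n_components)] / total,
    scree = ev / total, grid = attr(m, "grid"), rotation = rotmat),
    class = "component_windows")
}

#' Derive serial time windows from rotated loadings
#'
#' Each time point is assigned to the component with the maximal absolute
#' rotated loading; enclaves shorter than `min_run_ms` are absorbed by the
#' surrounding assignment until every run is long enough; if a component
#' still owns several runs, only its longest is kept and the rest are
#' absorbed. The resulting runs partition the analysis grid into contiguous
#' windows, relabelled in temporal order (T-RC1 earliest).
#'
#' @param cw `component_windows` from [extract_rotated_components()].
#' @param min_run_ms minimum run length (default 50 ms).
#' @return the `component_windows` with a `windows` `data.frame` added:
#'   `component` (T-RC1..), `source_component` (pre-relabel index),
#'   `start_ms`, `end_ms` (half-open, end exclusive; the last window ends at
#'   the grid end), `explained`.
#' @export
define_windows <- function(cw, min_run_ms = 50) {
  grid <- cw$grid
  step <- if (length(grid) > 1) grid[2] - grid[1] else min_run_ms
  assign <- apply(abs(cw$rotated), 1, which.max)
  k <- ncol(cw$rotated)
  if (length(unique(assign)) < k)
    stop("a component has no highest-loading time points; ",
         "consider fewer components")
  min_run <- max(1L, ceiling(min_run_ms / step))
  squeeze <- function(a, min_len) {
    repeat {
      r <- rle(a)
      if (length(r$lengths) == 1) break
      short <- which(r$lengths < min_len)
      if (length(short) == 0) break
      j <- short[which.min(r$lengths[short])]
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      # absorb into the longer flanking run (ties: the earlier one)
      left <- if (j > 1) r$lengths[j - 1] else -1L
      right <- if (j < length(r$lengths)) r$lengths[j + 1] else -1L
      take <- if (left >= right) r$values[j - 1] else r$values[j + 1]
      a[starts[j]:ends[j]] <- take
      if (length(unique(a)) < length(unique(r$values))) {
        # absorbing must not erase a component entirely
        a[starts[j]:ends[j]] <- r$values[j]
        break
      }
    }
    a
  }
  assign <- squeeze(assign, min_run)
  # keep only each component's longest run; absorb the others
  repeat {
    r <- rle(assign)
    dup <- duplicated(r$values) | duplicated(r$values, fromLast = TRUE)
    if (!any(dup)) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    changed <- FALSE
    for (comp in unique(r$values[dup])) {
      runs <- which(r$values == comp)
      drop <- runs[-which.max(r$lengths[runs])]
      for (j in drop) {
        left <- if (j > 1) r$lengths[j - 1] else -1L
        right <- if (j < length(r$lengths)) r$lengths[j + 1] else -1L
        take <- if (left >= right) r$values[j - 1] else r$values[j + 1]
        assign[starts[j]:ends[j]] <- take
        changed <- TRUE
      }
      break
    }
    if (!changed) break
  }
  r <- rle(assign)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  win <- data.frame(source_component = r$values,
                    start_ms = grid[starts],
                    end_ms = c(grid[starts[-1]], grid[length(grid)] + step))
  win <- win[order(win$start_ms), , drop = FALSE]
  win$component <- paste0("T-RC", seq_len(nrow(win)))
  win$explained <- cw$explained[win$source_component]
  cw$windows <- win[, c("component", "source_component", "start_ms",
                        "end_ms", "explained")]
  cw
}

#' Per-window pupil dilation measures
#'
#' Mean baseline-corrected pupil response over the valid samples of each
#' window, on the trace's native grid. Windows with no valid samples yield
#' NA; excluded traces yield a row of NAs.
#'
#' @param trace a `pupil_trace`.
#' @param windows `windows` table from [define_windows()].
#' @return named numeric vector, one mean per window (names `pd_trc1`, ...).
#' @export
window_means <- function(trace, windows) {
  out <- setNames(rep(NA_real_, nrow(windows)),
                  paste0("pd_trc", seq_len(nrow(windows))))
  if (isTRUE(trace$excluded)) return(out)
  for (i in seq_len(nrow(windows))) {
    sel <- trace$t >= windows$start_ms[i] & trace$t < windows$end_ms[i]
    v <- trace$response[sel]
    if (any(!is.na(v))) out[i] <- mean(v, na.rm = TRUE)
  }
  out
}

#' Pupil-dilation measures for all trials
#'
#' Applies [window_means()] to every trace and joins trial metadata.
#'
#' @param traces named list of `pupil_trace` objects.
#' @param windows `windows` table from [define_windows()].
#' @return `data.frame`: trial metadata plus `pd_trc1..k` columns; excluded
#'   trials are omitted.
#' @export
pd_measures <- function(traces, windows) {
  rows <- list()
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    if (isTRUE(tr$excluded)) next
    wm <- window_means(tr, windows)
    meta <- tr$meta
    rows[[nm]] <- cbind(
      data.frame(participant_id = meta$participant_id,
                 trial_index = meta$trial_index,
                 group = meta$group, emotion = meta$emotion),
      as.data.frame(as.list(wm)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
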