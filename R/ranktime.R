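#' Rank x time matrix of normalized responses
#'
#' The lingua franca between data, the synthetic generator and the inference
#' pipeline: normalized firing rates indexed by stimulus rank (rows, sorted
#' ascending so the last row is the preferred stimulus) and time bin
#' (columns, uniform grid of width `dt` ms with stimulus onset at bin
#' `onset_index + 1`).
#'
#' @param values numeric matrix, ranks x time bins; all finite.
#' @param dt bin width in ms (the recordings use 5 ms).
#' @param onset_index number of pre-onset bins (0 means the first bin is at
#'   0 ms).
#' @param condition optional label, e.g. "novel" or "familiar".
#' @return object of class `"rank_time_matrix"` (a matrix with attributes).
#' @export
rank_time_matrix <- function(values, dt = 5, onset_index = 0,
                             condition = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("rank-time matrix must be all finite")
  stopifnot(dt > 0, onset_index >= 0, onset_index < ncol(values))
  structure(values, dt = dt, onset_index = as.integer(onset_index),
            condition = condition,
            class = c("rank_time_matrix", "matrix", "array"))
}

#' Bin times of a rank-time matrix
#'
#' @param x a `"rank_time_matrix"`.
#' @return numeric vector of bin times in ms (onset at 0).
#' @export
bin_times <- function(x) {
  stopifnot(inherits(x, "rank_time_matrix"))
  (seq_len(ncol(x)) - 1L - attr(x, "onset_index")) * attr(x, "dt")
}

#' @export
print.rank_time_matrix <- function(x, ...) {
  tm <- bin_times(x)
  cat(sprintf("Rank-time matrix: %d ranks x %d bins (dt = %g ms, %g..%g ms)%s\n",
              nrow(x), ncol(x), attr(x, "dt"), min(tm), max(tm),
              if (is.null(attr(x, "condition"))) ""
              else paste0(", condition: ", attr(x, "condition"))))
  invisible(x)
}

#' Write / read a rank-time matrix as CSV plus JSON sidecar
#'
#' The CSV holds a header row of bin times in ms (onset at 0) and one row per
#' rank; a sidecar `<path>.json` records `dt`, `onset_index` and `condition`.
#' The reader validates the dialect strictly (comma-separated, '.' decimal)
#' and reports ragged rows, a non-monotone time header, or non-numeric cells
#' with row/column identification.
#'
#' @param x a `"rank_time_matrix"`.
#' @param path CSV file path.
#' @return `write_rank_time_csv` returns `path` invisibly;
#'   `read_rank_time_csv` returns the `"rank_time_matrix"`.
#' @export
write_rank_time_csv <- function(x, path) {
  stopifnot(inherits(x, "rank_time_matrix"))
  tm <- bin_times(x)
  hdr <- paste(formatC(tm, format = "g", digits = 15), collapse = ",")
  rows <- apply(unclass(x), 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = ","))
  writeLines(c(hdr, rows), path)
  meta <- list(dt = attr(x, "dt"), onset_index = attr(x, "onset_index"),
               condition = attr(x, "condition"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_rank_time_csv
#' @export
read_rank_time_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("rank-time CSV needs a header and >= 1 row")
  fields <- strsplit(lines, ",", fixed = TRUE)
  n_col <- length(fields[[1L]])
  for (i in seq_along(fields)[-1L]) {
    if (length(fields[[i]]) != n_col)
      stop(sprintf("ragged CSV: row %d has %d fields, expected %d",
                   i - 1L, length(fields[[i]]), n_col))
  }
  parse_row <- function(fl, label) {
    v <- suppressWarnings(as.numeric(fl))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric cell in %s, column %d: '%s'",
                   label, bad[1L], fl[bad[1L]]))
    v
  }
  tm <- parse_row(fields[[1L]], "header")
  if (n_col > 1L && any(diff(tm) <= 0))
    stop("non-monotone time header at column ",
         which(diff(tm) <= 0)[1L] + 1L)
  vals <- t(vapply(seq_along(fields)[-1L], function(i)
    parse_row(fields[[i]], paste0("row ", i - 1L)), numeric(n_col)))
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    dt <- meta$dt
    onset_index <- meta$onset_index
    condition <- meta$condition
  } else {
    dt <- if (n_col > 1L) tm[2L] - tm[1L] else 1
    onset_index <- sum(tm < 0)
    condition <- NULL
  }
  rank_time_matrix(vals, dt = dt, onset_index = onset_index,
                   condition = condition)
}

#' Normalize raw responses and average by stimulus rank
#'
#' Implements the passive-viewing preprocessing: per neuron, all firing rates
#' (both conditions) are z-scored by the mean and standard deviation of the
#' time-averaged activities over *novel* stimuli within `z_window` after
#' onset; then, within each condition, stimuli are rank-ordered by their
#' time-averaged activity (ascending, ties broken by first occurrence) and the
#' normalized responses are averaged over neurons at each rank.
#'
#' @param novel_raw,familiar_raw numeric arrays, neuron x stimulus x time bin.
#' @param dt bin width in ms.
#' @param onset_index number of pre-onset bins.
#' @param z_window ms window (after onset) over which activities are
#'   time-averaged for the z-scoring; default 80-200 ms.
#' @param avg_window ms window used for the rank-ordering time average;
#'   defaults to `z_window`.
#' @return list with elements `novel` and `familiar`, each a
#'   `"rank_time_matrix"`.
#' @export
normalize_and_rank <- function(novel_raw, familiar_raw, dt = 5,
                               onset_index = 0, z_window = c(80, 200),
                               avg_window = z_window) {
  stopifnot(length(dim(novel_raw)) == 3L, length(dim(familiar_raw)) == 3L,
            dim(novel_raw)[1L] == dim(familiar_raw)[1L],
            dim(novel_raw)[3L] == dim(familiar_raw)[3L],
            dim(novel_raw)[2L] >= 2L, dim(familiar_raw)[2L] >= 2L)
  n_neuron <- dim(novel_raw)[1L]
  n_bin <- dim(novel_raw)[3L]
  tm <- (seq_len(n_bin) - 1L - onset_index) * dt
  zw <- which(tm >= z_window[1L] & tm <= z_window[2L])
  aw <- which(tm >= avg_window[1L] & tm <= avg_window[2L])
  if (!length(zw)) stop("z_window contains no time bins")
  if (!length(aw)) stop("avg_window contains no time bins")

  avg_rank <- function(arr, mu, sd, cond) {
    n_stim <- dim(arr)[2L]
    out <- matrix(0, n_stim, n_bin)
    for (nn in seq_len(n_neuron)) {
      z <- (arr[nn, , , drop = TRUE] - mu[nn]) / sd[nn]   # stim x time
      ta <- rowMeans(z[, aw, drop = FALSE])
      ord <- order(ta)                                    # stable, ascending
      out <- out + z[ord, , drop = FALSE]
    }
    rank_time_matrix(out / n_neuron, dt = dt, onset_index = onset_index,
                     condition = cond)
  }

  mu <- numeric(n_neuron); sd <- numeric(n_neuron)
  for (nn in seq_len(n_neuron)) {
    ta_nov <- rowMeans(matrix(novel_raw[nn, , zw],
                              dim(novel_raw)[2L], length(zw)))
    mu[nn] <- mean(ta_nov)
    sd[nn] <- stats::sd(ta_nov)
    if (!is.finite(sd[nn]) || sd[nn] <= 0)
      stop("neuron ", nn, " has zero variance of time-averaged novel ",
           "activities; cannot z-score")
  }
  list(novel = avg_rank(novel_raw, mu, sd, "novel"),
       familiar = avg_rank(familiar_raw, mu, sd, "familiar"))
}

#' Rebound strength of the damped oscillation
#'
#' Ordinary least-squares slope of a response trace over a late post-onset
#' window (default 230-320 ms), quantifying the return of activity after the
#' adaptation-driven trough. For a rank-time matrix, one slope per rank is
#' returned.
#'
#' @param trace numeric vector (with `times` supplied) or a
#'   `"rank_time_matrix"`.
#' @param window ms window over which the slope is fitted.
#' @param times bin times in ms, required when `trace` is a bare vector.
#' @return slope(s) in rate units per ms.
#' @export
rebound_strength <- function(trace, window = c(230, 320), times = NULL) {
  if (inherits(trace, "rank_time_matrix")) {
    tm <- bin_times(trace)
    mat <- unclass(trace)
  } else {
    if (is.null(times)) stop("supply `times` for a bare numeric trace")
    stopifnot(length(times) == length(trace))
    tm <- times
    mat <- matrix(trace, nrow = 1L)
  }
  sel <- which(tm >= window[1L] & tm <= window[2L])
  if (length(sel) < 2L)
    stop("rebound window [", window[1L], ", ", window[2L],
         "] ms contains fewer than 2 bins of the trace")
  tt <- tm[sel]
  tc <- tt - mean(tt)
  slopes <- drop(mat[, sel, drop = FALSE] %*% tc) / sum(tc^2)
  if (inherits(trace, "rank_time_matrix")) slopes else unname(slopes)
}
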