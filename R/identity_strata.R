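# Windowed neo-W/neo-Z pairwise identity and segmentation of the identity
# series into candidate evolutionary strata.
#
# Orthology between the two pseudomolecules is consumed as a table of
# paired intervals (from synthetic truth, or an external alignment table
# for real data); homologous-interval discovery is out of scope here.
# Windows tile the neo-Z sequence, matching the convention of reporting
# strata on neo-Z coordinates.

#' Pairwise identity in non-overlapping windows
#'
#' For each window on the neo-Z sequence, the orthologous neo-W pieces
#' (from `orthology_map`, assumed collinear within each paired interval)
#' are globally aligned with affine gap penalties and identity is
#' 100 x matches / alignment columns. Windows without a partner are
#' returned unscored.
#'
#' @param neoz_seq,neow_seq Sequence strings (e.g. the two pseudomolecule
#'   versions of the fused chromosome).
#' @param orthology_map data.frame with columns z_start, z_end, w_start,
#'   w_end (0-based half-open intervals; collinear pairs).
#' @param window Window size in bp (default 1e4).
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-1/-4/-1; a gap run of length L costs gap_open + L * gap_extend).
#' @param band Half-width of the banded global alignment (default 32
#'   columns; use `window` for the full quadratic DP).
#' @return data.frame: start, end (neo-Z window), w_start, w_end (partner
#'   span), identity (percent), aligned_columns, gap_columns, scored.
#' @export
window_identity <- function(neoz_seq, neow_seq, orthology_map,
                            window = 1e4, match = 1, mismatch = -1,
                            gap_open = 4, gap_extend = 1, band = 32L) {
  stopifnot(window >= 1, nrow(orthology_map) >= 1)
  om <- orthology_map
  need <- c("z_start", "z_end", "w_start", "w_end")
  if (!all(need %in% names(om)))
    stop("orthology_map needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(om$z_end - om$z_start != om$w_end - om$w_start))
    stop("orthology_map intervals must pair equal spans (collinear map)",
         call. = FALSE)
  n <- nchar(neoz_seq)
  starts <- seq(0, n - 1, by = window)
  ends <- pmin(starts + window, n)
  rows <- lapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- ends[i]
    ov <- om[om$z_start < b & om$z_end > a, , drop = FALSE]
    if (!nrow(ov))
      return(data.frame(start = a, end = b, w_start = NA_real_,
                        w_end = NA_real_, identity = NA_real_,
                        aligned_columns = 0L, gap_columns = 0L,
                        scored = FALSE, stringsAsFactors = FALSE))
    matches <- 0L; columns <- 0L; gaps <- 0L
    w_lo <- Inf; w_hi <- -Inf
    for (j in seq_len(nrow(ov))) {
      zs <- max(a, ov$z_start[j]); ze <- min(b, ov$z_end[j])
      ws <- ov$w_start[j] + (zs - ov$z_start[j])
      we <- ws + (ze - zs)
      aln <- nw_align_cpp(substr(neoz_seq, zs + 1, ze),
                          substr(neow_seq, ws + 1, we),
                          match, mismatch, gap_open, gap_extend,
                          as.integer(band))
      matches <- matches + aln$matches
      columns <- columns + aln$columns
      gaps <- gaps + aln$gap_columns
      w_lo <- min(w_lo, ws); w_hi <- max(w_hi, we)
    }
    data.frame(start = a, end = b, w_start = w_lo, w_end = w_hi,
               identity = 100 * matches / columns,
               aligned_columns = columns, gap_columns = gaps,
               scored = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Centered moving average, width w, ends shortened symmetrically.
smooth_series <- function(x, w = 5L) {
  half <- w %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Segment a windowed identity series into candidate strata
#'
#' Greedy change-point segmentation: each segment is recursively split at
#' the boundary maximizing the between-segment mean difference, as long
#' as that difference exceeds `merge_tol` percentage points and both
#' sides keep at least `min_windows` windows; adjacent segments whose
#' means differ by at most `merge_tol` are then merged.
#'
#' @param rows Window-identity table from [window_identity()] (unscored
#'   rows are ignored).
#' @param min_windows Minimum windows per stratum (default 3).
#' @param merge_tol Minimum mean-identity difference between adjacent
#'   strata, in percentage points (default 1.5).
#' @param smooth_width Moving-average width for the smoothed series
#'   returned alongside (default 5 windows).
#' @return List with `strata` (data.frame: stratum, start, end on neo-Z,
#'   first_window, last_window, mean_identity, n_windows) and `smoothed`
#'   (the smoothed identity series over scored windows).
#' @export
segment_strata <- function(rows, min_windows = 3L, merge_tol = 1.5,
                           smooth_width = 5L) {
  sc <- rows[rows$scored, , drop = FALSE]
  y <- sc$identity
  n <- length(y)
  if (n < 1) stop("no scored windows to segment", call. = FALSE)
  cs <- cumsum(y)
  seg_mean <- function(i, j) (cs[j] - if (i > 1) cs[i - 1] else 0) / (j - i + 1)
  boundaries <- integer(0)   # last window index of each closed segment
  split_rec <- function(lo, hi) {
    if (hi - lo + 1L < 2L * min_windows) return(invisible(NULL))
    cand <- (lo + min_windows - 1L):(hi - min_windows)
    diffs <- vapply(cand, function(b)
      abs(seg_mean(lo, b) - seg_mean(b + 1L, hi)), numeric(1))
    best <- which.max(diffs)
    if (diffs[best] > merge_tol) {
      b <- cand[best]
      split_rec(lo, b)
      boundaries <<- c(boundaries, b)
      split_rec(b + 1L, hi)
    }
    invisible(NULL)
  }
  if (n >= 2L * min_windows) split_rec(1L, n)
  bounds <- sort(unique(c(boundaries, n)))
  starts <- c(1L, head(bounds, -1) + 1L)
  segs <- data.frame(first_window = starts, last_window = bounds)
  segs$mean_identity <- vapply(seq_len(nrow(segs)), function(i)
    seg_mean(segs$first_window[i], segs$last_window[i]), numeric(1))
  # merge adjacent segments closer than merge_tol
  repeat {
    if (nrow(segs) < 2) break
    d <- abs(diff(segs$mean_identity))
    if (all(d > merge_tol)) break
    i <- which.min(d)
    segs$last_window[i] <- segs$last_window[i + 1]
    segs <- segs[-(i + 1), , drop = FALSE]
    segs$mean_identity <- vapply(seq_len(nrow(segs)), function(j)
      seg_mean(segs$first_window[j], segs$last_window[j]), numeric(1))
  }
  strata <- data.frame(
    stratum = seq_len(nrow(segs)),
    start = sc$start[segs$first_window],
    end = sc$end[segs$last_window],
    first_window = segs$first_window,
    last_window = segs$last_window,
    mean_identity = segs$mean_identity,
    n_windows = segs$last_window - segs$first_window + 1L,
    row.names = NULL, stringsAsFactors = FALSE)
  list(strata = strata, smoothed = smooth_series(y, smooth_width))
}
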