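#' F/F0 trace with a sliding-minimum baseline
#'
#' Computes the baseline `F0` of a calcium-indicator intensity trace as
#' the minimum of `F` over the window preceding each frame (5 min by
#' default) and returns the fold change `F/F0`. Frames early in the
#' recording that lack a full preceding window use the partial window up
#' to and including the current frame, so `F0` is always defined and
#' positive.
#'
#' @param F mean indicator intensity per frame (strictly positive).
#' @param times frame times (s); default a regular grid from
#'   `frame_interval`.
#' @param frame_interval time between frames (s), used when `times` is
#'   missing.
#' @param window baseline window length (s), default 300.
#' @return An object of class `calcium_trace`: data frame with columns
#'   `time`, `F`, `F0`, `ratio`.
#' @export
#' @examples
#' tr <- compute_f_over_f0(c(rep(100, 12), 250, rep(100, 5)),
#'                         frame_interval = 60)
#' max(tr$ratio)  # 2.5
compute_f_over_f0 <- function(F, times = NULL, frame_interval = 1,
                              window = 300) {
  F <- as.numeric(F)
  if (any(!is.finite(F)) || any(F <= 0))
    stop("intensities must be finite and strictly positive", call. = FALSE)
  if (is.null(times)) times <- (seq_along(F) - 1) * frame_interval
  if (length(times) != length(F) || any(diff(times) <= 0))
    stop("'times' must match 'F' and be strictly increasing", call. = FALSE)
  if (window <= 0) stop("'window' must be positive", call. = FALSE)
  if (utils::tail(times, 1) - times[1] < window)
    stop("the trace must cover at least one full baseline window",
         call. = FALSE)
  n <- length(F)
  F0 <- numeric(n)
  for (i in seq_len(n)) {
    if (times[i] - times[1] >= window) {
      sel <- times >= times[i] - window & times < times[i]
    } else {
      sel <- times <= times[i]
    }
    F0[i] <- min(F[sel])
  }
  structure(data.frame(time = times, F = F, F0 = F0, ratio = F / F0),
            class = c("calcium_trace", "data.frame"))
}

#' Detect calcium transients in an F/F0 trace
#'
#' A transient is a contiguous run of frames with `ratio >= peak_fold`;
#' each run contributes one peak, at the frame of its maximum ratio.
#'
#' @param trace a [compute_f_over_f0()] result.
#' @param peak_fold fold-change threshold (> 1), default 1.5.
#' @return A data frame with one row per transient: `peak_time`,
#'   `peak_frame`, `peak_ratio`.
#' @export
detect_transients <- function(trace, peak_fold = 1.5) {
  stopifnot(inherits(trace, "calcium_trace"))
  if (peak_fold <= 1) stop("'peak_fold' must exceed 1", call. = FALSE)
  above <- trace$ratio >= peak_fold
  if (!any(above))
    return(data.frame(peak_time = numeric(0), peak_frame = integer(0),
                      peak_ratio = numeric(0)))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  peaks <- vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    idx[which.max(trace$ratio[idx])]
  }, integer(1))
  data.frame(peak_time = trace$time[peaks], peak_frame = peaks,
             peak_ratio = trace$ratio[peaks])
}

#' Count transients, merging simultaneous peaks of adjacent cells
#'
#' Two or more adjacent cells peaking in the same frame are one calcium
#' transient (the discharge is attributed to a single source); the same
#' cell peaking in different frames counts each time. Within each frame,
#' connected groups of peaking cells under the adjacency relation are
#' counted once.
#'
#' @param peaks a data frame with columns `cell` and `frame`, one row per
#'   per-cell peak (e.g. assembled from [detect_transients()] results).
#' @param adjacency a two-column matrix or data frame of undirected
#'   cell-id pairs; may be empty.
#' @return Integer transient count.
#' @export
#' @examples
#' peaks <- data.frame(cell = c("a", "b"), frame = c(3, 3))
#' merge_simultaneous(peaks, adjacency = cbind("a", "b"))  # 1
merge_simultaneous <- function(peaks, adjacency = NULL) {
  stopifnot(is.data.frame(peaks), all(c("cell", "frame") %in% names(peaks)))
  if (nrow(peaks) == 0L) return(0L)
  adj <- if (is.null(adjacency) || NROW(adjacency) == 0L) {
    matrix(character(0), ncol = 2)
  } else {
    am <- as.matrix(adjacency)
    if (ncol(am) != 2L) stop("'adjacency' needs two columns", call. = FALSE)
    matrix(as.character(am), ncol = 2)
  }
  total <- 0L
  for (f in unique(peaks$frame)) {
    cells <- unique(as.character(peaks$cell[peaks$frame == f]))
    # union-find over the cells peaking in this frame
    parent <- stats::setNames(cells, cells)
    find <- function(a) {
      while (parent[[a]] != a) a <- parent[[a]]
      a
    }
    for (k in seq_len(nrow(adj))) {
      a <- adj[k, 1]; b <- adj[k, 2]
      if (a %in% cells && b %in% cells) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[[ra]] <- rb
      }
    }
    total <- total + length(unique(vapply(cells, find, character(1))))
  }
  total
}
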