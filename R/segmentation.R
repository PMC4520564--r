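#' Least-squares changepoint segmentation of an LT series
#'
#' Fits a piecewise-constant model to a time series by exact dynamic
#' programming: for each candidate number of breakpoints the placement
#' minimizing the total within-segment sum of squared deviations is found
#' (the Bai–Perron least-squares segmentation family), subject to a minimum
#' segment length, and the number of breaks is then selected by BIC. For a
#' forced break count the optimum is exact, not a greedy approximation.
#'
#' Segments are classified `"high"` when the segment mean is at or above
#' `high_threshold`, `"low"` at or below `low_threshold`, and
#' `"intermediate"` otherwise. The high threshold 0.775 defines an emerged
#' leader LT; 0.225, its mirror image about the sigmoid center, defines a
#' follower.
#'
#' @param series Numeric vector (an LT trajectory, or any series to
#'   segment).
#' @param max_breaks Maximum number of breakpoints considered (default 5;
#'   LT trajectories show at most a few plateaus).
#' @param min_segment_fraction Minimum segment length as a fraction of the
#'   series length (default 0.05, i.e. 5% trimming).
#' @param high_threshold,low_threshold Segment-mean classification bounds.
#' @param n_breaks Force this exact number of breakpoints instead of BIC
#'   selection (used mainly for cross-checking against exhaustive search).
#' @return An object of class `lt_segmentation`: a list with
#'   `breakpoints` (indices of the last observation of each non-final
#'   segment, strictly increasing, possibly empty), `segment_start`,
#'   `segment_end`, `segment_means`, `segment_classes`, `rss`,
#'   `model_selection` (tibble of break count, RSS, BIC), the thresholds,
#'   and the input `series`.
#' @examples
#' seg <- segment_series(c(rep(0.2, 50), rep(0.8, 50)), max_breaks = 2)
#' seg$breakpoints # 50
#' seg$segment_means # 0.2, 0.8
#' @export
segment_series <- function(series, max_breaks = 5,
                           min_segment_fraction = 0.05,
                           high_threshold = 0.775,
                           low_threshold = 0.225,
                           n_breaks = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (anyNA(y)) stop("`series` must not contain missing values.", call. = FALSE)
  h <- max(2L, as.integer(ceiling(min_segment_fraction * n)))
  if (n < 2L * h) {
    stop("series of length ", n, " is shorter than two minimum segments (2 x ",
      h, ").",
      call. = FALSE
    )
  }
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y * y))
  # RSS of fitting one constant over observations i..j (vectorized in i or j)
  rss_seg <- function(i, j) {
    len <- j - i + 1
    pmax(cs2[j + 1] - cs2[i] - (cs[j + 1] - cs[i])^2 / len, 0)
  }

  max_m <- min(max_breaks + 1L, n %/% h) # segments that can physically fit
  if (!is.null(n_breaks)) {
    if (n_breaks + 1L > max_m) {
      stop("`n_breaks` = ", n_breaks, " does not fit with minimum segment ",
        "length ", h, ".",
        call. = FALSE
      )
    }
    max_m <- n_breaks + 1L
  }
  cost <- matrix(Inf, max_m, n)
  path <- matrix(NA_integer_, max_m, n)
  j_all <- seq_len(n)
  cost[1L, j_all >= h] <- rss_seg(1L, j_all[j_all >= h])
  if (max_m >= 2L) {
    for (m in 2:max_m) {
      for (j in seq.int(m * h, n)) {
        t <- seq.int((m - 1L) * h, j - h)
        v <- cost[m - 1L, t] + rss_seg(t + 1L, j)
        b <- which.min(v)
        cost[m, j] <- v[b]
        path[m, j] <- t[b]
      }
    }
  }

  rss_by_m <- cost[, n]
  n_breaks_grid <- seq_len(max_m) - 1L
  # floor the RSS at a scale-aware epsilon so that exact fits (zero residual)
  # are compared by the penalty term alone, not by floating-point noise
  rss_floor <- max(rss_seg(1L, n) * 1e-10, 1e-12)
  bic <- n * log(pmax(rss_by_m, rss_floor) / n) + 2 * (n_breaks_grid + 1) * log(n)
  best_m <- if (is.null(n_breaks)) which.min(bic) else n_breaks + 1L
  if (!is.finite(cost[best_m, n])) {
    stop("no feasible segmentation for the requested break count.", call. = FALSE)
  }

  bps <- integer(0)
  j <- n
  if (best_m >= 2L) {
    for (m in seq.int(best_m, 2L)) {
      b <- path[m, j]
      bps <- c(b, bps)
      j <- b
    }
  }
  starts <- c(1L, bps + 1L)
  ends <- c(bps, n)
  means <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  classes <- dplyr::case_when(
    means >= high_threshold ~ "high",
    means <= low_threshold ~ "low",
    .default = "intermediate"
  )
  structure(
    list(
      breakpoints = bps,
      segment_start = starts,
      segment_end = ends,
      segment_means = means,
      segment_classes = classes,
      rss = cost[best_m, n],
      model_selection = tibble::tibble(
        n_breaks = n_breaks_grid, rss = rss_by_m, bic = bic
      ),
      high_threshold = high_threshold,
      low_threshold = low_threshold,
      min_segment_length = h,
      series = y
    ),
    class = "lt_segmentation"
  )
}

#' @export
print.lt_segmentation <- function(x, ...) {
  cat(sprintf(
    "<lt_segmentation> %d observations, %d breakpoint(s) at {%s}\n",
    length(x$series), length(x$breakpoints),
    paste(x$breakpoints, collapse = ", ")
  ))
  cat(sprintf(
    "  segment means: %s\n  classes:       %s\n",
    paste(signif(x$segment_means, 4), collapse = ", "),
    paste(x$segment_classes, collapse = ", ")
  ))
  invisible(x)
}

#' First emergence of a high LT segment
#'
#' Finds the earliest segment whose mean reaches the high threshold and
#' returns the number of observations preceding it — 0 when the very first
#' segment is already high, `NA` when no segment is high. In LT terms this
#' is the experience (initiation attempts) required for the individual's
#' LT to differentiate as high.
#'
#' @param segmentation An `lt_segmentation`.
#' @param high_threshold Overrides the threshold stored in `segmentation`
#'   (default 0.775: high enough that runs started at the 0.8 initial value
#'   do not register as instantly differentiated).
#' @return Integer index (in observation units of the segmented series), or
#'   `NA_integer_` if no segment is high.
#' @export
first_high_emergence <- function(segmentation, high_threshold = NULL) {
  stopifnot(inherits(segmentation, "lt_segmentation"))
  thr <- high_threshold %||% segmentation$high_threshold
  hit <- which(segmentation$segment_means >= thr)
  if (length(hit) == 0L) {
    return(NA_integer_)
  }
  segmentation$segment_start[hit[1L]] - 1L
}

#' Count post-differentiation LT class transitions
#'
#' Counts consecutive segment pairs whose class flips low-to-high or
#' high-to-low, considering only breakpoints at or after the
#' differentiation index; transitions involving an intermediate segment are
#' counted in neither direction.
#'
#' @param segmentation An `lt_segmentation`.
#' @param differentiation_index Observation index of initial
#'   differentiation; breaks before it are ignored (default 0: count all).
#' @return A named list with `low_to_high` and `high_to_low` counts.
#' @export
count_transitions <- function(segmentation, differentiation_index = 0) {
  stopifnot(inherits(segmentation, "lt_segmentation"))
  cls <- segmentation$segment_classes
  bps <- segmentation$breakpoints
  l2h <- 0L
  h2l <- 0L
  for (i in seq_along(bps)) {
    if (bps[i] < differentiation_index) next
    from <- cls[i]
    to <- cls[i + 1L]
    if (from == "low" && to == "high") l2h <- l2h + 1L
    if (from == "high" && to == "low") h2l <- h2l + 1L
  }
  list(low_to_high = l2h, high_to_low = h2l)
}
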