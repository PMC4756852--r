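#' Rectangular pixel region
#'
#' Rectangles are 0-based, row-major and half-open: `roi_rect(x0, y0, x1,
#' y1)` covers columns `x0 <= x < x1` and rows `y0 <= y < y1` of the image
#' (row 0 is the top row). A logical mask of the image size may be used
#' anywhere a rectangle is accepted and takes precedence when both are
#' possible.
#'
#' @param x0,y0 inclusive upper-left corner (0-based).
#' @param x1,y1 exclusive lower-right corner.
#' @return A list of class `roi_rect`.
#' @export
roi_rect <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0, x0 >= 0, y0 >= 0)
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "roi_rect")
}

roi_mask <- function(region, dim_hw) {
  if (is.matrix(region) && is.logical(region)) {
    if (!all(dim(region) == dim_hw)) {
      stop("ROI mask dimensions do not match the image", call. = FALSE)
    }
    return(region)
  }
  if (!inherits(region, "roi_rect")) {
    stop("ROI region must be an roi_rect or a logical mask", call. = FALSE)
  }
  if (region$x1 > dim_hw[2] || region$y1 > dim_hw[1]) {
    stop("ROI rectangle extends outside the image bounds", call. = FALSE)
  }
  m <- matrix(FALSE, dim_hw[1], dim_hw[2])
  m[(region$y0 + 1):region$y1, (region$x0 + 1):region$x1] <- TRUE
  m
}

#' ROI specification for trace extraction
#'
#' @param damage region covering the irradiated stripe ([roi_rect()] or
#'   logical mask).
#' @param background region within the nucleoplasm excluding the damage
#'   site, used as the normalisation reference.
#' @param pre_damage_frames number of frames acquired before irradiation
#'   (>= 0).
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(damage, background, pre_damage_frames = 0L) {
  stopifnot(pre_damage_frames >= 0)
  structure(list(damage = damage, background = background,
                 pre_damage_frames = as.integer(pre_damage_frames)),
            class = "roi_spec")
}

as_stack_array <- function(stack) {
  if (is.list(stack) && !is.array(stack)) {
    stack <- simplify2array(stack)
  }
  if (!(is.array(stack) && length(dim(stack)) == 3L)) {
    stop("`stack` must be an H x W x T array or a list of frames", call. = FALSE)
  }
  stack
}

#' Extract a normalised recruitment trace from an image stack
#'
#' Computes per-frame arithmetic means over the damage and background
#' ROIs and normalises the damage signal as the ratio to the nucleoplasmic
#' background minus one: `normalized = damage_mean / background_mean - 1`.
#' The ratio cancels global intensity scaling (detector gain,
#' photobleaching applied uniformly), so a normalised value of `A` means
#' the damage site is `A` times brighter than the surrounding
#' nucleoplasm, above it.
#'
#' @param stack H x W x T numeric array (or list of H x W frames) of a
#'   grayscale time series with at least 2 frames.
#' @param roi a [roi_spec()]; damage and background regions must be
#'   non-empty, disjoint and inside the image.
#' @param times frame times in minutes post-irradiation (pre-damage
#'   frames negative); defaults to `0:(T-1)`.
#' @return A tibble with columns `frame`, `time_min`, `damage_mean`,
#'   `background_mean`, `normalized`.
#' @export
extract_trace <- function(stack, roi, times = NULL) {
  stopifnot(inherits(roi, "roi_spec"))
  stack <- as_stack_array(stack)
  n_frames <- dim(stack)[3]
  if (n_frames < 2L) stop("`stack` must have >= 2 frames", call. = FALSE)
  dm <- roi_mask(roi$damage, dim(stack)[1:2])
  bm <- roi_mask(roi$background, dim(stack)[1:2])
  if (!any(dm) || !any(bm)) stop("ROI regions must be non-empty", call. = FALSE)
  if (any(dm & bm)) {
    stop("damage and background ROIs must be disjoint", call. = FALSE)
  }
  times <- times %||% (seq_len(n_frames) - 1)
  if (length(times) != n_frames || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with one value per frame",
         call. = FALSE)
  }
  damage_mean <- apply(stack, 3, function(f) mean(f[dm]))
  background_mean <- apply(stack, 3, function(f) mean(f[bm]))
  if (any(background_mean <= 0)) {
    stop("background mean is <= 0 on some frame; cannot normalise",
         call. = FALSE)
  }
  tibble::tibble(
    frame = seq_len(n_frames),
    time_min = as.numeric(times),
    damage_mean = damage_mean,
    background_mean = background_mean,
    normalized = damage_mean / background_mean - 1
  )
}

#' Relative increase of the damage-site signal
#'
#' `(peak post-damage value - pre-damage value) / pre-damage value`, where
#' the pre-damage value is the mean damage-ROI intensity over the
#' pre-damage frames and the peak is the maximum over all later frames.
#'
#' @param trace a trace tibble from [extract_trace()].
#' @param pre_damage_frames number of leading frames acquired before
#'   irradiation (>= 1); at least one post-damage frame must remain.
#' @return A single dimensionless number.
#' @export
relative_increase <- function(trace, pre_damage_frames) {
  stopifnot(is.data.frame(trace), "damage_mean" %in% names(trace))
  pre_damage_frames <- as.integer(pre_damage_frames)
  if (pre_damage_frames < 1L || pre_damage_frames >= nrow(trace)) {
    stop("need >= 1 pre-damage frame and >= 1 post-damage frame", call. = FALSE)
  }
  before <- mean(trace$damage_mean[seq_len(pre_damage_frames)])
  if (before == 0) stop("pre-damage mean is zero", call. = FALSE)
  peak <- max(trace$damage_mean[-seq_len(pre_damage_frames)])
  (peak - before) / before
}

#' Call recruitment within a detection window
#'
#' A cell is called recruited when the normalised damage-site signal
#' exceeds `detection_level` on at least `k` consecutive frames within
#' the first `window_min` minutes post-irradiation. The onset is the time
#' of the first frame of the first such run; peak time and value are
#' taken over the window. Raising `detection_level` can only remove
#' calls, never add them.
#'
#' @param trace a trace tibble from [extract_trace()].
#' @param window_min detection window in minutes (> 0); frames with
#'   `0 <= time_min <= window_min` are considered.
#' @param detection_level normalised-signal threshold (default 0.1).
#' @param k minimum run length of supra-threshold frames (default 2).
#' @return A one-row tibble with columns `recruited`, `onset_min`,
#'   `peak_min`, `peak_value`, `window_min`.
#' @export
call_recruitment <- function(trace, window_min, detection_level = 0.1, k = 2L) {
  stopifnot(is.data.frame(trace), window_min > 0, k >= 1)
  idx <- which(trace$time_min >= 0 & trace$time_min <= window_min)
  if (length(idx) == 0L) {
    stop("trace does not cover any of the detection window", call. = FALSE)
  }
  x <- trace$normalized[idx]
  t <- trace$time_min[idx]
  above <- x > detection_level
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= k)
  recruited <- length(hit) > 0L
  onset <- if (recruited) t[starts[hit[1]]] else NA_real_
  peak_i <- which.max(x)
  tibble::tibble(
    recruited = recruited,
    onset_min = onset,
    peak_min = t[peak_i],
    peak_value = x[peak_i],
    window_min = window_min
  )
}

#' Detection-threshold power from per-cell recruitment calls
#'
#' The threshold is the lowest tabulated power at which the factor is
#' recruited in strictly more than `majority_rule` of the damaged cells
#' (the ">50% of cells" rule by default). Exactly half the cells does not
#' qualify.
#'
#' @param calls data frame with one row per cell and columns `power`
#'   (setting) and `recruited` (logical).
#' @param majority_rule required recruited fraction, strict (default 0.5).
#' @return The threshold power, or `NA` if no power qualifies.
#' @export
threshold_power <- function(calls, majority_rule = 0.5) {
  if (!is.data.frame(calls) || nrow(calls) == 0L ||
      !all(c("power", "recruited") %in% names(calls))) {
    stop("`calls` must be a non-empty data frame with columns `power` and ",
         "`recruited`", call. = FALSE)
  }
  frac <- calls |>
    dplyr::group_by(.data$power) |>
    dplyr::summarise(frac = mean(.data$recruited), .groups = "drop") |>
    dplyr::arrange(.data$power)
  hit <- frac$power[frac$frac > majority_rule]
  if (length(hit) == 0L) NA_real_ else min(hit)
}

#' Two-sided permutation test on a difference of means
#'
#' Randomisation test for a difference between two groups of per-cell
#' measurements. The observed absolute difference of means is compared
#' against `n_permutations` random relabellings; the p-value uses the
#' add-one estimator `(1 + #{|perm| >= |obs|}) / (n_permutations + 1)` so
#' it is never exactly zero. If every value is identical across both
#' groups the p-value is 1.
#'
#' @param values_a,values_b numeric vectors with >= 2 values each.
#' @param n_permutations number of random relabellings (default 1e4).
#' @param seed integer seed for reproducibility (optional).
#' @return The two-sided p-value.
#' @export
compare_groups <- function(values_a, values_b, n_permutations = 1e4,
                           seed = NULL) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("both groups need >= 2 values", call. = FALSE)
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1L) return(1)
  n_a <- length(values_a)
  obs <- abs(mean(values_a) - mean(values_b))
  perm <- local_seeded(seed, {
    vapply(seq_len(n_permutations), function(i) {
      idx <- sample.int(length(pooled), n_a)
      abs(mean(pooled[idx]) - mean(pooled[-idx]))
    }, numeric(1))
  })
  (1 + sum(perm >= obs - 1e-12)) / (n_permutations + 1)
}

# evaluate expr under a local RNG state; seed = NULL uses the current state
local_seeded <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
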