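#' Read and write grayscale multi-page TIFF stacks
#'
#' Stacks are stored as 16-bit grayscale multi-page TIFFs with one page
#' per frame. Intensities are integer counts in 0..65535; writing rounds
#' to the nearest count.
#'
#' @param stack H x W x T numeric array of counts.
#' @param path file path.
#' @return `write_stack()` returns the path invisibly; `read_stack()`
#'   returns an H x W x T array of counts.
#' @export
write_stack <- function(stack, path) {
  stack <- as_stack_array(stack)
  if (any(stack < 0) || any(stack > 65535)) {
    stop("counts must be within 0..65535 for 16-bit output", call. = FALSE)
  }
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(i) round(stack[, , i]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  simplify2array(pages)
}

#' Read an ROI specification from YAML or JSON
#'
#' The file holds `damage` and `background` entries, each either a
#' rectangle `[x0, y0, x1, y1]` (0-based, half-open) or a path to a mask,
#' plus optional `pre_damage_frames`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return An [roi_spec()].
#' @export
read_roi <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_region <- function(x, key) {
    if (is.numeric(x) && length(x) == 4L) {
      roi_rect(x[1], x[2], x[3], x[4])
    } else {
      stop(sprintf("`%s` must be a rectangle [x0, y0, x1, y1]", key),
           call. = FALSE)
    }
  }
  roi_spec(
    damage = as_region(spec$damage, "damage"),
    background = as_region(spec$background, "background"),
    pre_damage_frames = spec$pre_damage_frames %||% 0L
  )
}

#' Read a frame-time table
#'
#' @param path CSV with a `time_min` column (minutes post-irradiation).
#' @return Numeric vector of frame times.
#' @export
read_frame_times <- function(path) {
  tab <- utils::read.csv(path)
  if (!"time_min" %in% names(tab)) {
    stop("frame-time CSV needs a `time_min` column", call. = FALSE)
  }
  tab$time_min
}

# numeric CSV writer: 6 significant digits, locale-independent
write_table_csv <- function(x, path) {
  x <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) signif(col, 6) else col
  }), check.names = FALSE)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
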