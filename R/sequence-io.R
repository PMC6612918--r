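#' Write / read a stereo sequence
#'
#' A sequence is stored as a long-format CSV of dot records (columns `frame`,
#' `time_s`, `eye`, `dot_id`, `x_deg`, `y_deg`, `polarity`, `role`, `stripe`,
#' `age`) plus a JSON sidecar holding the stimulus parameters, cue label,
#' coherence, seed, and the binocular pairing map. The round trip is exact
#' for integer columns and stable to 1e-9 for floating-point columns.
#'
#' @param seq A `stereo_sequence`.
#' @param path Output stem: `<path>.csv` and `<path>.json` are written.
#' @return `write_sequence()`: the stem, invisibly. `read_sequence()`: the
#'   reconstructed `stereo_sequence`.
#' @export
write_sequence <- function(seq, path) {
  df <- data.frame(
    frame = seq$frames$frame, time_s = seq$frames$time, eye = seq$frames$eye,
    dot_id = seq$frames$id, x_deg = seq$frames$x, y_deg = seq$frames$y,
    polarity = seq$frames$polarity, role = seq$frames$role,
    stripe = seq$frames$stripe, age = seq$frames$age,
    vx = seq$frames$vx %||% NA_real_
  )
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  side <- list(
    params = unclass(seq$params), cue = seq$cue, coherence = seq$coherence,
    seed = seq$seed,
    pairing = list(left_id = seq$pairing$left_id,
                   right_id = seq$pairing$right_id)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  df <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- side$params
  class(params) <- "stimulus_params"
  validate_stimulus_params(params)
  frames <- data.frame(
    frame = as.integer(df$frame), time = df$time_s, eye = df$eye,
    id = as.integer(df$dot_id), x = df$x_deg, y = df$y_deg,
    polarity = as.integer(df$polarity), role = df$role,
    age = as.integer(df$age),
    stripe = if (all(is.na(df$stripe))) NA_integer_ else as.integer(df$stripe),
    vx = df$vx %||% NA_real_,
    stringsAsFactors = FALSE
  )
  pairing <- data.frame(left_id = as.integer(side$pairing$left_id %||% integer(0)),
                        right_id = as.integer(side$pairing$right_id %||% integer(0)))
  new_stereo_sequence(params, side$cue, side$coherence, frames, pairing,
                      as.integer(side$seed))
}

#' Rasterize one frame of a stereo sequence
#'
#' Renders the dots of a single frame/eye as a grayscale image: each dot is a
#' disc with a raised-cosine edge of width `cosine_edge`, positive-polarity
#' dots brighter than the background and negative-polarity dots darker, seen
#' through the annular aperture with its Gaussian-smoothed edge. Intended for
#' visual inspection, not for photometrically calibrated presentation.
#'
#' @param seq A `stereo_sequence`.
#' @param frame Frame number to render.
#' @param eye `"left"` or `"right"`.
#' @param px Image size in pixels (square).
#' @param file Optional path to write an 8-bit grayscale PNG (requires the
#'   `png` package).
#' @return Invisibly, the `px` x `px` matrix of values in `[0, 1]`.
#' @export
render_frame <- function(seq, frame = 1, eye = "left", px = 256, file = NULL) {
  p <- seq$params
  sub <- seq$frames[seq$frames$frame == frame & seq$frames$eye == eye, ]
  half <- p$aperture_outer + p$dot_diameter
  ax <- seq(-half, half, length.out = px)
  img <- matrix(0.5, px, px)
  rad <- p$dot_diameter / 2
  edge <- p$cosine_edge
  for (i in seq_len(nrow(sub))) {
    ix <- which(abs(ax - sub$x[i]) <= rad)
    iy <- which(abs(ax - sub$y[i]) <= rad)
    if (!length(ix) || !length(iy)) next
    dx <- ax[ix] - sub$x[i]
    dy <- ax[iy] - sub$y[i]
    d <- sqrt(outer(dy^2, dx^2, "+"))
    prof <- ifelse(d <= rad - edge, 1,
                   ifelse(d >= rad, 0, 0.5 + 0.5 * cos(pi * (d - (rad - edge)) / edge)))
    img[iy, ix] <- img[iy, ix] + 0.5 * sub$polarity[i] * prof
  }
  ## aperture window: hard annulus with Gaussian-smoothed edges
  sd <- p$aperture_edge_fwhm / 2.3548
  r <- sqrt(outer(ax^2, ax^2, "+"))
  w <- stats::pnorm((r - p$aperture_inner) / sd) *
    (1 - stats::pnorm((r - p$aperture_outer) / sd))
  img <- 0.5 + (img - 0.5) * w
  img <- pmin(pmax(img, 0), 1)
  if (!is.null(file)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required to write image files", call. = FALSE)
    }
    png::writePNG(img, file)
  }
  invisible(img)
}
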