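#' Render a snapshot of the tissue or a mediator layer
#'
#' Tissue rendering follows the model's colour scheme: perfect health is
#' peach, declining health shades linearly towards red, and dead cells
#' leave a white empty space. Mediator layers render as single-channel
#' intensity images (black = 0, layer maximum = full channel). One pixel
#' block per grid cell; output is deterministic given the state.
#'
#' @param state a `sim_state`.
#' @param path output PNG path.
#' @param what `"tissue"` or one of the layer names
#'   (`oxygen, damp, tnf, il1, tgf, ros, steroid, antidamp, antiox`).
#' @param scale integer pixel-block edge per cell.
#' @param healthy_col,damaged_col,dead_col RGB anchor colours for the
#'   tissue ramp (defaults: peach, red, white).
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, what = "tissue", scale = 1L,
                            healthy_col = c(255, 218, 185),
                            damaged_col = c(204, 0, 0),
                            dead_col = c(255, 255, 255)) {
  stopifnot(inherits(state, "sim_state"))
  W <- state$width; H <- state$height
  img <- array(0, dim = c(H, W, 3))
  if (identical(what, "tissue")) {
    lifef <- t(state$life) / 100       # rows = y for the image
    deadm <- t(state$alive) == 0L
    for (ch in 1:3) {
      plane <- (damaged_col[ch] + (healthy_col[ch] - damaged_col[ch]) *
                  lifef) / 255
      plane[deadm] <- dead_col[ch] / 255
      img[, , ch] <- plane
    }
  } else {
    if (!what %in% names(state$layers))
      stop("unknown snapshot selector: ", what)
    v <- t(state$layers[[what]])
    mx <- max(v)
    if (mx > 0) v <- v / mx
    for (ch in 1:3) img[, , ch] <- v
  }
  if (scale > 1) {
    idx_r <- rep(seq_len(H), each = scale)
    idx_c <- rep(seq_len(W), each = scale)
    img <- img[idx_r, idx_c, , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}
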