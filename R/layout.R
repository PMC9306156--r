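# Electrode geometry: four 8x8 grids, 10 mm inter-electrode distance.
# Grid 1 lies on the distal ventral forearm; grids 2-4 ring the proximal
# forearm and tile 24 circumferential columns without overlap.
#
# Conventions (fixed, documented constants):
#  * channel index = (grid-1)*64 + (row-1)*8 + (col-1), i.e. 0..255;
#  * row 1 is the distal edge of each grid; z grows toward the elbow,
#    10 mm per row (proximal grids: z = (row-1)*ied; grid 1: z = (row-9)*ied
#    so its row 8 sits one pitch distal to the ring);
#  * ring column r = (grid-2)*8 + col for grids 2-4, anchored at grid 2
#    column 1; theta = (r-1) * 2*pi/24. Grid 1 shares grid 2's theta arc.

RING_COLS <- 24L
N_CHANNELS <- 256L

#' Build the canonical four-grid HD-EMG electrode layout
#'
#' Returns the 256-channel monopolar montage used throughout the package:
#' four 8 x 8 grids with 10 mm inter-electrode distance, one on the distal
#' ventral forearm (grid 1) and three ringing the proximal forearm
#' (grids 2-4, jointly spanning 24 circumferential columns). Each channel
#' carries its `(grid, row, col)` address and cylindrical forearm coordinates
#' `(theta, z)` used by the simulator's hot-spot geometry.
#'
#' @param corrupted integer vector of channel indices (0-based, in 0..255)
#'   flagged as corrupted by poor skin contact; they stay in the layout but
#'   are excluded from analysis and substituted in CIRC selection.
#' @param ied_mm inter-electrode distance in millimetres.
#' @return an object of class `emg_layout`: a list with `channels` (data frame
#'   of `index`, `grid`, `row`, `col`, `ring_col`, `theta`, `z`), `ied_mm`,
#'   `corrupted`, `n_ring_cols` and the cylinder `radius_mm`.
#' @examples
#' lay <- build_default_layout()
#' nrow(lay$channels)   # 256
#' @export
build_default_layout <- function(corrupted = integer(), ied_mm = 10) {
  corrupted <- as.integer(corrupted)
  bad <- corrupted[corrupted < 0L | corrupted > (N_CHANNELS - 1L)]
  if (length(bad))
    stop("corrupted channel index out of range 0..255: ",
         paste(bad, collapse = ", "))
  grid <- rep(1:4, each = 64L)
  row <- rep(rep(1:8, each = 8L), times = 4L)
  col <- rep.int(1:8, 32L)
  index <- (grid - 1L) * 64L + (row - 1L) * 8L + (col - 1L)
  ring_col <- ifelse(grid >= 2L, (grid - 2L) * 8L + col, col)
  theta <- (ring_col - 1L) * 2 * pi / RING_COLS
  z <- ifelse(grid >= 2L, (row - 1L) * ied_mm, (row - 9L) * ied_mm)
  structure(list(
    channels = data.frame(index = index, grid = grid, row = row, col = col,
                          ring_col = ring_col, theta = theta, z = z),
    ied_mm = ied_mm,
    corrupted = sort(unique(corrupted)),
    n_ring_cols = RING_COLS,
    radius_mm = RING_COLS * ied_mm / (2 * pi)
  ), class = "emg_layout")
}

#' @export
print.emg_layout <- function(x, ...) {
  cat("HD-EMG layout:", nrow(x$channels), "channels, 4 grids,",
      x$ied_mm, "mm IED,", length(x$corrupted), "corrupted\n")
  invisible(x)
}

#' Map a grid address to a channel index
#'
#' @param grid,row,col grid 1..4, row 1..8 (row 1 distal), column 1..8.
#' @return 0-based channel index.
#' @export
layout_index <- function(grid, row, col) {
  stopifnot(all(grid %in% 1:4), all(row %in% 1:8), all(col %in% 1:8))
  as.integer((grid - 1L) * 64L + (row - 1L) * 8L + (col - 1L))
}

#' Look up the channel reference for an index
#'
#' @param layout an `emg_layout`.
#' @param index 0-based channel index.
#' @return one-row data frame with the channel's address and coordinates.
#' @export
layout_ref <- function(layout, index) {
  stopifnot(inherits(layout, "emg_layout"))
  i <- match(as.integer(index), layout$channels$index)
  if (anyNA(i)) stop("unknown channel index: ", index[is.na(i)][1])
  layout$channels[i, , drop = FALSE]
}

# Geodesic distance (mm) on the forearm cylinder from each channel to a point.
cyl_distance <- function(layout, theta0, z0) {
  ch <- layout$channels
  dth <- abs(((ch$theta - theta0 + pi) %% (2 * pi)) - pi)
  sqrt((layout$radius_mm * dth)^2 + (ch$z - z0)^2)
}

#' An ordered channel subset with its selection method
#'
#' @param channels integer vector of 0-based channel indices, no duplicates.
#' @param method `"SFS"`, `"CIRC"` or `"ALL"`.
#' @return an object of class `channel_set`.
#' @export
channel_set <- function(channels, method = c("SFS", "CIRC", "ALL")) {
  method <- match.arg(method)
  channels <- as.integer(channels)
  if (anyDuplicated(channels)) stop("duplicate channels in channel set")
  structure(list(channels = channels, method = method), class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(x$method, " channel set (", length(x$channels), "): ",
      paste(x$channels, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Substitute a corrupted ring channel by the one immediately below
#'
#' Pure geometry: for a channel in row 4 of a proximal grid, returns the
#' row-5 channel of the same grid and column (one row toward the elbow), the
#' fallback the circumferential placement uses when a selected channel is
#' corrupted. Only one fallback level exists: if the substitute is itself
#' corrupted, an error is raised.
#'
#' @param layout an `emg_layout`.
#' @param channel 0-based channel index, or a one-row channel reference as
#'   returned by [layout_ref()]; must lie in row 4 of grids 2-4.
#' @return the substitute's channel reference (one-row data frame).
#' @export
substitute_corrupted <- function(layout, channel) {
  ref <- if (is.numeric(channel)) layout_ref(layout, channel) else channel
  if (ref$grid < 2L || ref$row != 4L)
    stop("channel ", ref$index, " is not in row 4 of a proximal grid")
  sub <- layout_ref(layout, layout_index(ref$grid, 5L, ref$col))
  if (sub$index %in% layout$corrupted)
    stop("substitute channel ", sub$index, " (below channel ", ref$index,
         ") is also corrupted")
  sub
}

#' Circumferential evenly distributed channel selection (CIRC)
#'
#' Selects 8 channels from row 4 of the proximal grids, taken at every third
#' of the 24 ring columns (ring columns 1, 4, ..., 22, anchored at grid 2
#' column 1), i.e. equidistant points 30 mm apart around the forearm.
#' Corrupted members are replaced by the channel immediately below
#' (see [substitute_corrupted()]).
#'
#' @param layout an `emg_layout`.
#' @return a `channel_set` with method `"CIRC"` and exactly 8 channels.
#' @export
circ_select <- function(layout) {
  stopifnot(inherits(layout, "emg_layout"))
  ring <- seq(1L, 22L, by = 3L)
  idx <- vapply(ring, function(r) {
    g <- 2L + (r - 1L) %/% 8L
    cc <- (r - 1L) %% 8L + 1L
    ch <- layout_index(g, 4L, cc)
    if (ch %in% layout$corrupted)
      ch <- substitute_corrupted(layout, ch)$index
    ch
  }, integer(1))
  channel_set(idx, "CIRC")
}

# Generalised equidistant ring selection (n evenly spaced row-4 channels).
# The canonical placement is n = 8; other n are available behind an explicit
# flag in accuracy_vs_channels().
circ_select_n <- function(layout, n) {
  stopifnot(n >= 1, n <= RING_COLS)
  ring <- (floor(seq(0, RING_COLS - RING_COLS / n, length.out = n)) %% RING_COLS) + 1L
  idx <- vapply(ring, function(r) {
    g <- 2L + (r - 1L) %/% 8L
    cc <- (r - 1L) %% 8L + 1L
    ch <- layout_index(g, 4L, cc)
    if (ch %in% layout$corrupted)
      ch <- substitute_corrupted(layout, ch)$index
    ch
  }, integer(1))
  channel_set(idx, "CIRC")
}
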