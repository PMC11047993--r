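#' Electrode-array geometry
#'
#' Describes the DRAM-like function array: `n_rows` x `n_cols` electrode units,
#' addressed by a single row decoder and `n_blocks` column sub-decoders that
#' share one within-block offset bus.  The decoder sizing is derived from the
#' array dimensions by ceiling division, so small test geometries exercise the
#' same code paths as the full-size default (3163 x 3163 units at a 3.16 um
#' pitch, i.e. ten million electrodes on ~1 cm^2).
#'
#' All rows, columns, blocks and offsets are 0-based.  The block decode space
#' (`n_blocks * cols_per_block`) may exceed `n_cols`; the surplus outputs are
#' treated as unconnected (selecting them is a silent no-op, see
#' [decode_columns()]).
#'
#' @param n_rows,n_cols array dimensions (units).
#' @param n_blocks number of column sub-decoders, each with its own enable pin.
#' @param pitch_um centre-to-centre unit pitch in micrometres.
#' @return An object of class `"array_geometry"`: a list with fields `n_rows`,
#'   `n_cols`, `n_blocks`, `cols_per_block`, `pitch_um`, `row_bits`,
#'   `offset_bits` and `n_pins`.
#' @examples
#' g <- array_geometry()
#' g$cols_per_block   # 25
#' g$n_pins           # 145
#' @export
array_geometry <- function(n_rows = 3163L, n_cols = 3163L, n_blocks = 128L,
                           pitch_um = 3.16) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n_blocks <- as.integer(n_blocks)
  stopifnot(n_rows >= 1L, n_cols >= 1L, n_blocks >= 1L, pitch_um > 0)
  cpb <- cols_per_block_required(n_cols, n_blocks)
  g <- list(
    n_rows = n_rows, n_cols = n_cols, n_blocks = n_blocks,
    cols_per_block = cpb, pitch_um = pitch_um,
    row_bits = bits_needed(n_rows), offset_bits = bits_needed(cpb))
  g$n_pins <- g$row_bits + g$n_blocks + g$offset_bits
  structure(g, class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "<array_geometry> %d x %d units (%.2f um pitch, %.3g units/cm^2)\n",
    x$n_rows, x$n_cols, x$pitch_um, unit_density(x$pitch_um)))
  cat(sprintf("  row decoder: %d-to-%d; %d column blocks x %d offsets; %d external pins\n",
              x$row_bits, x$n_rows, x$n_blocks, x$cols_per_block, x$n_pins))
  invisible(x)
}

# smallest number of binary address bits covering n outputs
bits_needed <- function(n) {
  if (n <= 1L) return(1L)
  as.integer(ceiling(log2(n)))
}

#' Column sub-decoder width required to cover an array
#'
#' With `n_blocks` column sub-decoders sharing one offset bus, each must span
#' `ceiling(n_cols / n_blocks)` columns (25 for the default 3163-column array
#' split over 128 blocks).
#'
#' @param n_cols number of array columns.
#' @param n_blocks number of column sub-decoders.
#' @return integer count of columns per block.
#' @examples
#' cols_per_block_required(3163, 128)  # 25
#' @export
cols_per_block_required <- function(n_cols, n_blocks) {
  stopifnot(n_cols >= 1, n_blocks >= 1)
  as.integer(ceiling(n_cols / n_blocks))
}

#' Lower bound on the number of addressing instances for a mask
#'
#' Each addressing instance can raise at most `width` units (one per enabled
#' block, default 128), so `n_active` activations need at least
#' `ceiling(n_active / width)` instances.  Perfect packing is rarely achievable
#' because every instance is confined to one row and one offset.
#'
#' @param n_active number of units to activate.
#' @param width maximum units per instance.
#' @return integer group count.
#' @examples
#' group_lower_bound(2.5e6)  # 19532
#' @export
group_lower_bound <- function(n_active, width = 128L) {
  if (width <= 0) stop("width must be positive")
  stopifnot(n_active >= 0)
  as.integer(ceiling(n_active / width))
}

#' Areal unit density for a given pitch
#'
#' @param pitch_um unit pitch in micrometres.
#' @return units per square centimetre, `(1e4 / pitch_um)^2`.
#' @examples
#' unit_density(3.16)  # ~1.0014e7 / cm^2
#' @export
unit_density <- function(pitch_um) {
  stopifnot(pitch_um > 0)
  (1e4 / pitch_um)^2
}
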