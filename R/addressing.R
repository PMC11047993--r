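#' Bit-code helpers
#'
#' Pin codes travel either as plain non-negative integers or as MSB-first 0/1
#' vectors (also accepted as strings such as `"0b001010011010"`).  `as_code()`
#' normalises any of these to an integer value; `int_to_bits()` renders a value
#' as an MSB-first bit vector of a given width.
#'
#' @param x integer scalar, 0/1 vector (MSB first), or `"0b..."` string.
#' @return `as_code()`: non-negative integer value.
#' @examples
#' as_code("0b001010011010")  # 666
#' int_to_bits(666, 12)
#' @export
as_code <- function(x) {
  if (is.character(x)) {
    s <- sub("^0b", "", x)
    if (!grepl("^[01]+$", s)) stop("malformed bit string: ", x)
    x <- as.integer(strsplit(s, "")[[1]])
  }
  if (length(x) == 1L && x >= 2) return(as.integer(x))
  if (any(!x %in% c(0, 1))) stop("bit vectors must contain only 0 and 1")
  as.integer(sum(x * 2^(rev(seq_along(x)) - 1L)))
}

#' @rdname as_code
#' @param value non-negative integer.
#' @param width number of bits.
#' @export
int_to_bits <- function(value, width) {
  stopifnot(value >= 0, value < 2^width)
  as.integer(rev((value %/% 2^(0:(width - 1L))) %% 2L))
}

#' External pin-state vector
#'
#' The full external input state of the addressing fabric: the row-address
#' code, one enable line per column block, and the shared within-block offset
#' code.  For the default geometry this is 12 + 128 + 5 = 145 pins.
#'
#' @param row_bits row address (integer, bit vector or `"0b..."` string).
#' @param block_enable logical vector of length `geometry$n_blocks`, or an
#'   integer vector of enabled 0-based block indices.
#' @param offset_bits shared offset code (same forms as `row_bits`).
#' @param geometry an [array_geometry()].
#' @return object of class `"pin_vector"`.
#' @examples
#' g <- array_geometry()
#' pv <- pin_vector("0b001010011010", 44, "0b01011", g)
#' select_units(pv, g)  # unit (666, 1111)
#' @export
pin_vector <- function(row_bits, block_enable, offset_bits, geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  if (!is.logical(block_enable)) {
    idx <- as.integer(block_enable)
    if (length(idx) && (any(idx < 0L) || any(idx >= geometry$n_blocks)))
      stop("block index out of range")
    block_enable <- (seq_len(geometry$n_blocks) - 1L) %in% idx
  }
  if (length(block_enable) != geometry$n_blocks)
    stop("block_enable must have one entry per block")
  structure(list(row_code = as_code(row_bits),
                 block_enable = block_enable,
                 offset_code = as_code(offset_bits)),
            class = "pin_vector")
}

#' @export
print.pin_vector <- function(x, ...) {
  cat(sprintf("<pin_vector> row=%d, offset=%d, %d block(s) enabled\n",
              x$row_code, x$offset_code, sum(x$block_enable)))
  invisible(x)
}

#' Decode the row-address code
#'
#' The row decoder maps its binary input directly to a single selected row.
#' Codes at or beyond `n_rows` fall in the unused part of the decode space and
#' signal an addressing error.
#'
#' @inheritParams pin_vector
#' @return 0-based row index.
#' @examples
#' decode_row("0b001010011010", array_geometry())  # 666
#' @export
decode_row <- function(row_bits, geometry) {
  v <- as_code(row_bits)
  if (is.character(row_bits) || length(row_bits) > 1L) {
    nb <- if (is.character(row_bits)) nchar(sub("^0b", "", row_bits)) else length(row_bits)
    if (nb != geometry$row_bits)
      stop(sprintf("row code must be %d bits, got %d", geometry$row_bits, nb))
  }
  if (v >= geometry$n_rows)
    stop(sprintf("addressing error: decoded row %d >= n_rows = %d", v, geometry$n_rows))
  v
}

#' Decode the column addressing state
#'
#' Each enabled block `b` drives its output `b * cols_per_block + offset`.
#' Offsets at or beyond `cols_per_block` are invalid decoder inputs.  Enabled
#' blocks whose implied column falls beyond `n_cols - 1` (the surplus of the
#' 128 x 25 = 3200 decode space over 3163 physical columns) are unconnected
#' outputs and are silently dropped.
#'
#' @inheritParams pin_vector
#' @return sorted integer vector of selected 0-based columns.
#' @examples
#' g <- array_geometry()
#' decode_columns(44, "0b01011", g)  # 1111
#' @export
decode_columns <- function(block_enable, offset_bits, geometry) {
  off <- as_code(offset_bits)
  if (off >= geometry$cols_per_block)
    stop(sprintf("invalid decoder input: offset %d >= cols_per_block = %d",
                 off, geometry$cols_per_block))
  if (!is.logical(block_enable)) {
    idx <- as.integer(block_enable)
    if (length(idx) && (any(idx < 0L) || any(idx >= geometry$n_blocks)))
      stop("block index out of range")
  } else {
    if (length(block_enable) != geometry$n_blocks)
      stop("block_enable must have one entry per block")
    idx <- which(block_enable) - 1L
  }
  cols <- idx * geometry$cols_per_block + off
  sort(cols[cols < geometry$n_cols])
}

#' Units selected by a pin state
#'
#' Cross product of the single decoded row with the decoded column set; at most
#' one unit per block (<= 128 for the default geometry).
#'
#' @param pins a [pin_vector()].
#' @inheritParams pin_vector
#' @return data.frame with 0-based `row`, `col` columns, one row per unit.
#' @export
select_units <- function(pins, geometry) {
  stopifnot(inherits(pins, "pin_vector"))
  r <- decode_row(pins$row_code, geometry)
  cols <- decode_columns(pins$block_enable, pins$offset_code, geometry)
  data.frame(row = rep(r, length(cols)), col = cols)
}

#' A single timed addressing instance
#'
#' One legal drive state of the fabric: one row, one shared offset, a set of
#' enabled blocks, held for `t_charge_ns`.  Every implied column must exist;
#' surplus decode outputs cannot be part of an instance.
#'
#' @param row 0-based row index.
#' @param offset 0-based within-block offset.
#' @param blocks integer vector of 0-based enabled block indices.
#' @param t_charge_ns charge duration in nanoseconds.
#' @param geometry an [array_geometry()]; if supplied the instance is validated.
#' @return object of class `"instance"`.
#' @export
instance <- function(row, offset, blocks, t_charge_ns = 80, geometry = NULL) {
  ins <- structure(list(row = as.integer(row), offset = as.integer(offset),
                        blocks = sort(unique(as.integer(blocks))),
                        t_charge_ns = t_charge_ns),
                   class = "instance")
  if (!is.null(ins$blocks) && length(ins$blocks) && any(ins$blocks < 0L))
    stop("illegal instance: negative block index")
  if (!is.null(geometry)) validate_instance(ins, geometry)
  ins
}

validate_instance <- function(ins, geometry) {
  if (ins$row < 0L || ins$row >= geometry$n_rows)
    stop("illegal instance: row out of range")
  if (ins$offset < 0L || ins$offset >= geometry$cols_per_block)
    stop("illegal instance: offset out of range")
  if (length(ins$blocks) > geometry$n_blocks)
    stop("illegal instance: too many blocks")
  if (length(ins$blocks) && any(ins$blocks >= geometry$n_blocks))
    stop("illegal instance: block index out of range")
  cols <- ins$blocks * geometry$cols_per_block + ins$offset
  if (length(cols) && any(cols >= geometry$n_cols))
    stop("illegal instance: enabled block implies a column beyond the array")
  invisible(ins)
}

#' Encode an instance back into a pin state
#'
#' Inverse of decoding: `select_units(encode_instance(i))` reproduces exactly
#' the units implied by `i`.  Instances are single-row/single-offset by
#' construction, so any representable unit set round-trips.
#'
#' @param ins an [instance()].
#' @inheritParams pin_vector
#' @return a [pin_vector()].
#' @export
encode_instance <- function(ins, geometry) {
  stopifnot(inherits(ins, "instance"))
  validate_instance(ins, geometry)
  enable <- (seq_len(geometry$n_blocks) - 1L) %in% ins$blocks
  pin_vector(int_to_bits(ins$row, geometry$row_bits), enable,
             int_to_bits(ins$offset, geometry$offset_bits), geometry)
}

units_of_instance <- function(ins, geometry) {
  cols <- ins$blocks * geometry$cols_per_block + ins$offset
  data.frame(row = rep(ins$row, length(cols)), col = cols)
}

#' Schedule an activation mask into legal addressing instances
#'
#' Iterates (row, offset) pairs lexicographically; each pair with at least one
#' active unit becomes one instance enabling exactly the blocks whose unit at
#' `(row, block * cols_per_block + offset)` is active.  The union of the
#' instances' unit sets equals the mask exactly and no unit is selected twice,
#' matching the sequential group activation of the refresh logic.
#'
#' @param mask activation mask: a logical/numeric dense matrix or a
#'   `Matrix` sparse pattern matrix of dimension `n_rows x n_cols`.
#' @param t_charge_ns per-instance charge duration (ns).
#' @inheritParams pin_vector
#' @return object of class `"chip_schedule"`: a list with `instances`
#'   (data.table of `row`, `offset`, `t_charge_ns` and a `blocks` list-column)
#'   and `t_charge_default`.
#' @examples
#' g <- array_geometry(10, 10, 4)    # 4 blocks x 3 offsets
#' m <- Matrix::sparseMatrix(i = 1, j = 1, dims = c(10, 10))
#' schedule_mask(m, geometry = g)
#' @export
schedule_mask <- function(mask, t_charge_ns = 80, geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  ij <- mask_sites(mask, geometry)
  cpb <- geometry$cols_per_block
  if (nrow(ij) == 0L) return(new_schedule(empty_instance_table(), t_charge_ns))
  dt <- data.table::data.table(row = ij$row, block = ij$col %/% cpb,
                               offset = ij$col %% cpb)
  grp <- dt[, .(blocks = list(sort(block))), keyby = .(row, offset)]
  tab <- data.table::data.table(row = grp$row, offset = grp$offset,
                                t_charge_ns = t_charge_ns, blocks = grp$blocks)
  new_schedule(tab, t_charge_ns)
}

# normalise any accepted mask representation into 0-based (row, col) sites
mask_sites <- function(mask, geometry) {
  if (inherits(mask, "Matrix") || inherits(mask, "sparseMatrix")) {
    if (nrow(mask) != geometry$n_rows || ncol(mask) != geometry$n_cols)
      stop("mask shape does not match geometry")
    ij <- Matrix::which(mask != 0, arr.ind = TRUE)
    return(data.frame(row = ij[, 1L] - 1L, col = ij[, 2L] - 1L))
  }
  if (is.matrix(mask)) {
    if (nrow(mask) != geometry$n_rows || ncol(mask) != geometry$n_cols)
      stop("mask shape does not match geometry")
    ij <- which(mask != 0, arr.ind = TRUE)
    return(data.frame(row = ij[, 1L] - 1L, col = ij[, 2L] - 1L))
  }
  if (is.data.frame(mask)) {
    stopifnot(all(c("row", "col") %in% names(mask)))
    if (nrow(mask) && (max(mask$row) >= geometry$n_rows || max(mask$col) >= geometry$n_cols))
      stop("mask site out of range")
    return(mask[c("row", "col")])
  }
  stop("unsupported mask representation")
}

empty_instance_table <- function() {
  data.table::data.table(row = integer(), offset = integer(),
                         t_charge_ns = numeric(), blocks = list())
}

new_schedule <- function(tab, t_charge_default) {
  structure(list(instances = tab, t_charge_default = t_charge_default),
            class = "chip_schedule")
}

#' @export
print.chip_schedule <- function(x, ...) {
  cat(sprintf("<chip_schedule> %d instance(s), total scan time %.4g s\n",
              nrow(x$instances), scan_time(x)))
  invisible(x)
}

#' @export
length.chip_schedule <- function(x) nrow(x$instances)

#' Full-array refresh schedule
#'
#' The schedule that sweeps every (row, offset) pair with all valid blocks
#' enabled: `n_rows * cols_per_block` instances (79,075 for the default
#' geometry), the maximum-length refresh pass of the addressing fabric.
#'
#' @inheritParams pin_vector
#' @inheritParams schedule_mask
#' @return a `"chip_schedule"`.
#' @export
full_scan_schedule <- function(geometry, t_charge_ns = 80) {
  cpb <- geometry$cols_per_block
  offs <- 0:(cpb - 1L)
  blocks_by_offset <- lapply(offs, function(o) {
    b <- 0:(geometry$n_blocks - 1L)
    b[b * cpb + o < geometry$n_cols]
  })
  rows <- rep(0:(geometry$n_rows - 1L), each = cpb)
  offv <- rep(offs, times = geometry$n_rows)
  tab <- data.table::data.table(
    row = rows, offset = offv, t_charge_ns = t_charge_ns,
    blocks = rep(blocks_by_offset, times = geometry$n_rows))
  new_schedule(tab, t_charge_ns)
}

#' Total scan time of a schedule
#'
#' Sum of per-instance charge durations.  The full-array pass at 80 ns per
#' instance takes 79,075 x 80 ns = 6.326 ms (6.3 ms to two significant
#' figures), which bounds the refresh period of every held voltage.
#'
#' @param schedule a `"chip_schedule"`.
#' @param signif_digits optionally round the result to this many significant
#'   figures (`NULL` = exact).
#' @return scan time in seconds.
#' @examples
#' scan_time(full_scan_schedule(array_geometry()))             # 6.326e-3
#' scan_time(full_scan_schedule(array_geometry()), signif = 2) # 6.3e-3
#' @export
scan_time <- function(schedule, signif_digits = NULL) {
  stopifnot(inherits(schedule, "chip_schedule"))
  t <- sum(schedule$instances$t_charge_ns) * 1e-9
  if (!is.null(signif_digits)) t <- signif(t, signif_digits)
  t
}

#' All units selected by a schedule
#'
#' @param schedule a `"chip_schedule"`.
#' @inheritParams pin_vector
#' @return data.frame of 0-based `row`, `col` pairs (with multiplicity, in
#'   activation order).
#' @export
schedule_units <- function(schedule, geometry) {
  tab <- schedule$instances
  if (nrow(tab) == 0L) return(data.frame(row = integer(), col = integer()))
  cpb <- geometry$cols_per_block
  n <- lengths(tab$blocks)
  data.frame(row = rep(tab$row, n),
             col = unlist(tab$blocks) * cpb + rep(tab$offset, n))
}
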