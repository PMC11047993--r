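test_that("row decoding reproduces the worked address and rejects out-of-range codes", {
  g <- array_geometry()
  expect_identical(decode_row("0b001010011010", g), 666L)
  expect_identical(decode_row("0b000000000000", g), 0L)
  # 0b110001011011 = 3163 falls outside the 3163-row array
  expect_identical(as_code("0b110001011011"), 3163L)
  expect_error(decode_row("0b110001011011", g), "addressing error")
  expect_error(decode_row(int_to_bits(5, 11), g), "12 bits")
})

test_that("column decoding follows block*cols_per_block + offset with surplus outputs dropped", {
  g <- array_geometry()
  expect_identical(decode_columns(44, "0b01011", g), 1111L)
  expect_identical(decode_columns(integer(0), 0, g), integer(0))
  # offset 24: blocks 126 (col 3174) and 127 (col 3199) exceed the array
  cols <- decode_columns(rep(TRUE, 128), 24, g)
  oracle <- (0:127) * 25L + 24L
  expect_identical(cols, sort(oracle[oracle < 3163]))
  expect_length(cols, 126L)
  # offset 0 keeps blocks 0..126
  expect_length(decode_columns(rep(TRUE, 128), 0, g), 127L)
  expect_error(decode_columns(0, 25, g), "invalid decoder input")
})

test_that("unit selection is the cross product of one row and the decoded columns", {
  g <- array_geometry()
  pv <- pin_vector("0b001010011010", 44, "0b01011", g)
  sel <- select_units(pv, g)
  expect_equal(sel, data.frame(row = 666L, col = 1111L))
  sel0 <- select_units(pin_vector(0, rep(TRUE, 128), 0, g), g)
  expect_identical(nrow(sel0), 127L)
  expect_true(all(sel0$row == 0))
  expect_identical(nrow(select_units(pin_vector(0, logical(128), 0, g), g)), 0L)
})

test_that("encode/decode round-trips on seeded random legal instances", {
  g <- array_geometry()
  set.seed(42)
  for (k in 1:100) {
    row <- sample(0:(g$n_rows - 1L), 1)
    off <- sample(0:(g$cols_per_block - 1L), 1)
    valid_blocks <- which((0:(g$n_blocks - 1L)) * g$cols_per_block + off < g$n_cols) - 1L
    blocks <- sample(valid_blocks, sample(0:20, 1))
    ins <- instance(row, off, blocks, geometry = g)
    pins <- encode_instance(ins, g)
    sel <- select_units(pins, g)
    expect_identical(site_key(sel),
                     site_key(data.frame(row = rep(row, length(blocks)),
                                         col = blocks * 25 + off)))
    expect_lte(nrow(sel), 128L)
  }
  # the printed example, inverted
  pv <- encode_instance(instance(666, 11, 44), g)
  expect_identical(pv$row_code, 666L)
  expect_identical(which(pv$block_enable) - 1L, 44L)
  expect_identical(pv$offset_code, 11L)
  expect_error(encode_instance(instance(0, 11, 127), g), "illegal instance")
})

test_that("schedule_mask is an exact cover, verified against per-unit enumeration", {
  g <- array_geometry(10, 10, 4)   # 4 blocks x 3 offsets
  expect_identical(g$cols_per_block, 3L)
  for (seed in 1:20) {
    m <- gen_random_mask(10, 10, 0.3, seed = seed)
    sch <- schedule_mask(m, geometry = g)
    got <- schedule_units(sch, g)
    ij <- Matrix::which(m != 0, arr.ind = TRUE)
    want <- data.frame(row = ij[, 1] - 1L, col = ij[, 2] - 1L)
    expect_identical(site_key(got), site_key(want))          # exact cover
    expect_identical(anyDuplicated(paste(got$row, got$col)), 0L)  # no unit twice
    # every instance: one row, one offset, <= n_blocks units
    expect_true(all(lengths(sch$instances$blocks) <= g$n_blocks))
    expect_gte(length(sch), group_lower_bound(nrow(want), g$n_blocks))
  }
  expect_identical(length(schedule_mask(matrix(FALSE, 10, 10), geometry = g)), 0L)
  single <- schedule_mask(data.frame(row = 3, col = 7), geometry = g)
  expect_identical(length(single), 1L)
})

test_that("schedule_mask agrees with full_scan_schedule when everything is active", {
  g <- array_geometry(10, 10, 4)
  full <- schedule_mask(matrix(TRUE, 10, 10), geometry = g)
  direct <- full_scan_schedule(g)
  expect_identical(length(full), g$n_rows * g$cols_per_block)
  expect_identical(site_key(schedule_units(full, g)), site_key(schedule_units(direct, g)))
})

test_that("full-array scan arithmetic reproduces the design numbers", {
  g <- array_geometry()
  sch <- full_scan_schedule(g)
  expect_identical(length(sch), 3163L * 25L)       # 79,075 instances
  expect_equal(scan_time(sch), 79075 * 80e-9)      # 6.326 ms exact
  expect_equal(scan_time(sch, signif_digits = 2), 6.3e-3)
  expect_equal(scan_time(full_scan_schedule(g, t_charge_ns = 40)), 3.163e-3)
  one <- schedule_mask(data.frame(row = 0, col = 0), geometry = g)
  expect_equal(scan_time(one), 80e-9)
})

test_that("decoder sizing, group bound, pin count and density match the platform design", {
  expect_identical(cols_per_block_required(3163, 128), 25L)
  expect_identical(cols_per_block_required(128, 128), 1L)
  expect_identical(cols_per_block_required(3163, 64), 50L)
  expect_identical(group_lower_bound(2.5e6, 128), 19532L)
  expect_identical(group_lower_bound(0), 0L)
  expect_identical(group_lower_bound(129), 2L)
  expect_error(group_lower_bound(5, width = 0), "width")
  g <- array_geometry()
  expect_identical(g$n_pins, 145L)
  expect_gte(g$n_rows * as.numeric(g$n_cols), 1e7)
  expect_equal(unit_density(3.16), (1e4 / 3.16)^2)
  expect_gte(unit_density(3.16), 1e7)
  expect_equal(unit_density(10), 1e6)
  expect_equal(unit_density(1), 1e8)
})

test_that("small geometries derive consistent decoder sizes", {
  g <- array_geometry(10, 10, 4)
  expect_identical(g$cols_per_block, 3L)
  expect_identical(g$n_pins, g$row_bits + 4L + g$offset_bits)
  # enumeration oracle on the small fabric
  sel <- select_units(pin_vector(int_to_bits(7, g$row_bits), c(0L, 2L),
                                 int_to_bits(1, g$offset_bits), g), g)
  expect_identical(site_key(sel), site_key(brute_select(7, c(0, 2), 1, g)))
})
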