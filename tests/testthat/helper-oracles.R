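# brute-force oracles used across the suite

# enumerate every unit a pin state selects, by scanning the whole array
brute_select <- function(row_code, enabled_blocks, offset, geometry) {
  hits <- list()
  for (r in 0:(geometry$n_rows - 1L)) {
    if (r != row_code) next
    for (cc in 0:(geometry$n_cols - 1L)) {
      b <- cc %/% geometry$cols_per_block
      o <- cc %% geometry$cols_per_block
      if (o == offset && b %in% enabled_blocks)
        hits[[length(hits) + 1L]] <- c(r, cc)
    }
  }
  if (!length(hits)) return(data.frame(row = integer(), col = integer()))
  m <- do.call(rbind, hits)
  data.frame(row = m[, 1], col = m[, 2])
}

# explicit-Euler integration of the single-pole RC circuit
euler_rc <- function(segments, params, n_sub = 20000) {
  # segments: data.frame(duration_s, on = logical)
  V <- 0
  for (k in seq_len(nrow(segments))) {
    dt <- segments$duration_s[k] / n_sub
    tau <- if (segments$on[k]) params$R_on * params$C else params$R_off * params$C
    target <- if (segments$on[k]) params$V_dd else 0
    for (i in seq_len(n_sub)) V <- V + dt * (target - V) / tau
  }
  V
}

# reference sites of a mask as a sorted key vector
site_key <- function(df) sort(paste(df$row, df$col, sep = ","))
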