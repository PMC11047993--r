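#' Seeded random activation mask
#'
#' Reproducible Bernoulli mask over an `n_rows x n_cols` array, emulating the
#' ~25 % per-base activation regime of a synthesis cycle.  Pure function of its
#' arguments: the caller's RNG state is left untouched.
#'
#' @param n_rows,n_cols mask dimensions.
#' @param fraction activation probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a sparse logical pattern matrix (`Matrix::sparseMatrix`).
#' @export
gen_random_mask <- function(n_rows, n_cols, fraction = 0.25, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  with_local_seed(seed, {
    on <- stats::runif(n_rows * n_cols) < fraction
    idx <- which(on)
    Matrix::sparseMatrix(i = (idx - 1L) %% n_rows + 1L,
                         j = (idx - 1L) %/% n_rows + 1L,
                         dims = c(n_rows, n_cols))
  })
}

#' Seeded random oligonucleotide set
#'
#' `n` uniform-random A/C/G/T sequences of the given length, deterministic per
#' seed, as a `Biostrings::DNAStringSet` named `oligo_00001` ...
#'
#' @param n number of records.
#' @param length sequence length (nt).
#' @param seed integer seed.
#' @return a `DNAStringSet`.
#' @export
gen_random_oligos <- function(n, length, seed = 1L) {
  stopifnot(n >= 1, length >= 1)
  with_local_seed(seed, {
    chars <- matrix(sample(c("A", "C", "G", "T"), n * length, replace = TRUE),
                    nrow = n)
    seqs <- apply(chars, 1L, paste0, collapse = "")
    names(seqs) <- sprintf("oligo_%05d", seq_len(n))
    Biostrings::DNAStringSet(seqs)
  })
}

# run code under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Activation-mask CSV I/O
#'
#' Masks are stored as a two-column CSV of 0-based `row,col` pairs (header
#' line included, LF or CRLF line endings accepted).  Writing then reading
#' reproduces the mask exactly.
#'
#' @param mask mask accepted by [schedule_mask()].
#' @param path file path.
#' @param geometry an [array_geometry()] giving the mask shape on read.
#' @return `read_mask_csv()`: sparse pattern matrix; `write_mask_csv()`: the
#'   path, invisibly.
#' @export
write_mask_csv <- function(mask, path, geometry) {
  ij <- mask_sites(mask, geometry)
  utils::write.csv(ij[order(ij$row, ij$col), , drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path, geometry) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("malformed mask CSV (expected 'row,col' header): ", path)
  bad <- which(df$row < 0 | df$row >= geometry$n_rows |
                 df$col < 0 | df$col >= geometry$n_cols)
  if (length(bad))
    stop(sprintf("mask CSV site out of range at data line %d: (%d, %d)",
                 bad[1L], df$row[bad[1L]], df$col[bad[1L]]))
  Matrix::sparseMatrix(i = df$row + 1L, j = df$col + 1L,
                       dims = c(geometry$n_rows, geometry$n_cols))
}

#' Schedule JSONL I/O
#'
#' One instance per line as a JSON object with fields `row`, `offset`,
#' `blocks` (array) and `t_charge_ns`.  Round-trips losslessly.
#'
#' @param schedule a `"chip_schedule"`.
#' @param path file path.
#' @return `read_schedule_jsonl()`: a `"chip_schedule"`.
#' @export
write_schedule_jsonl <- function(schedule, path) {
  tab <- schedule$instances
  lines <- vapply(seq_len(nrow(tab)), function(k) {
    jsonlite::toJSON(list(row = tab$row[k], offset = tab$offset[k],
                          blocks = I(tab$blocks[[k]]),   # always a JSON array
                          t_charge_ns = tab$t_charge_ns[k]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schedule_jsonl
#' @param t_charge_default default dwell recorded in the schedule object.
#' @export
read_schedule_jsonl <- function(path, t_charge_default = 80) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(new_schedule(empty_instance_table(), t_charge_default))
  recs <- lapply(seq_along(lines), function(k) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[k]]),
                    error = function(e) stop(sprintf(
                      "malformed schedule record at line %d: %s", k, conditionMessage(e))))
    if (!all(c("row", "offset", "blocks", "t_charge_ns") %in% names(rec)))
      stop(sprintf("malformed schedule record at line %d: missing field", k))
    rec
  })
  tab <- data.table::data.table(
    row = vapply(recs, function(r) as.integer(r$row), integer(1)),
    offset = vapply(recs, function(r) as.integer(r$offset), integer(1)),
    t_charge_ns = vapply(recs, function(r) as.numeric(r$t_charge_ns), numeric(1)),
    blocks = lapply(recs, function(r) as.integer(r$blocks)))
  new_schedule(tab, t_charge_default)
}

#' Waveform CSV I/O
#'
#' Two-column CSV `time_s,voltage_V`.
#'
#' @param wf a `"waveform"` data.frame.
#' @param path file path.
#' @export
write_waveform_csv <- function(wf, path) {
  utils::write.csv(as.data.frame(wf)[c("time_s", "voltage_V")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "voltage_V") %in% names(df)))
    stop("malformed waveform CSV: ", path)
  structure(df, class = c("waveform", "data.frame"))
}

#' Droplet-census CSV I/O
#'
#' Long-format CSV `t,unit_x,unit_y,area_um2,confined` with one line per
#' chamber per census time.
#'
#' @param census data.frame as produced by [droplet_census()] history.
#' @param path file path.
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(as.data.frame(census), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  utils::read.csv(path)
}

#' FASTA I/O for oligo sets
#'
#' Thin wrappers over `Biostrings`; reading validates the A/C/G/T alphabet
#' (ambiguity codes such as N are rejected with the offending record named).
#'
#' @param x a `DNAStringSet` or named character vector.
#' @param path file path.
#' @export
write_oligos_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_oligos_fasta
#' @export
read_oligos_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  freq <- Biostrings::alphabetFrequency(set)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(extra > 0))
    stop("non-ACGT character in record '", names(set)[which(extra > 0)[1L]], "'")
  if (any(Biostrings::width(set) == 0))
    stop("empty sequence in record '", names(set)[which(Biostrings::width(set) == 0)[1L]], "'")
  set
}

#' Platform configuration
#'
#' A nested configuration covering the array geometry, RC circuit, fluid pair,
#' SDA geometry and synthesis sections, plus the single global `seed` from
#' which every stochastic component derives its stream.  Round-trips
#' losslessly through YAML; unknown keys are rejected.
#'
#' @param geometry,rc,fluids,sda,synthesis named lists of overrides for the
#'   corresponding constructors ([array_geometry()], [rc_params()],
#'   [fluid_pair()], [sda_geometry()]).
#' @param seed global integer seed.
#' @return object of class `"chip_config"`.
#' @export
chip_config <- function(geometry = list(), rc = list(), fluids = list(),
                        sda = list(), synthesis = list(), seed = 1L) {
  check_keys <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop(sprintf("unknown key '%s' in config section '%s'", bad[1L], section))
  }
  check_keys(geometry, c("n_rows", "n_cols", "n_blocks", "pitch_um"), "geometry")
  check_keys(rc, c("C", "V_dd", "R_on", "R_off", "V_target", "t_on_cal"), "rc")
  check_keys(fluids, c("mu_c", "rho_c", "mu_d", "rho_d", "sigma", "theta_wall_deg"), "fluids")
  check_keys(sda, c("unit_pitch", "valve_width", "chamber_width", "chamber_height",
                    "neck_width", "neck_length", "channel_width", "n_units_x", "n_units_y",
                    "mirrored", "inlet_length", "outlet_length", "plug_gap",
                    "inlet_channel_width", "cell_um"), "sda")
  check_keys(synthesis, c("t_charge_ns", "t_hold_s"), "synthesis")
  structure(list(geometry = geometry, rc = rc, fluids = fluids, sda = sda,
                 synthesis = synthesis, seed = as.integer(seed)),
            class = "chip_config")
}

#' @rdname chip_config
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "chip_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname chip_config
#' @param config a `"chip_config"` (for `save_config`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("geometry", "rc", "fluids", "sda", "synthesis", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config section '", bad[1L], "'")
  raw <- lapply(raw, function(x) if (is.null(x)) list() else x)
  do.call(chip_config, raw[intersect(known, names(raw))])
}

#' Run manifest
#'
#' Writes a machine-readable JSON manifest (config hash, seed, package
#' version, timestamp) next to simulation outputs so runs can be traced back
#' to their exact configuration.
#'
#' @param config a `"chip_config"`.
#' @param path output JSON path.
#' @param seed the seed actually used.
#' @export
write_manifest <- function(config, path, seed = config$seed) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  man <- list(config_md5 = unname(tools::md5sum(tmp)), seed = seed,
              package = "synthchip",
              version = as.character(utils::packageVersion("synthchip")),
              written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Gridded field snapshot CSV
#'
#' Writes the phase fraction, cell-centred velocity and pressure of a flow
#' state as a long-format CSV `x_um,y_um,phi,u,v,p` (fluid cells only).
#'
#' @param state an `"sda_state"`.
#' @param path file path.
#' @export
write_fields_csv <- function(state, path) {
  df <- as.data.frame(state)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
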