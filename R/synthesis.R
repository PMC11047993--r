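#' Per-site synthesis jobs
#'
#' Maps electrode sites to target oligonucleotide sequences.  Records are
#' assigned row-major starting at (0, 0) unless a FASTA header carries an
#' explicit `site=row,col` annotation (any record with an annotation is placed
#' there; annotated and positional records may be mixed, collisions are
#' errors).
#'
#' @param fasta path to a FASTA file, or a `DNAStringSet`/named character
#'   vector of A/C/G/T sequences.
#' @param geometry an [array_geometry()].
#' @return object of class `"oligo_job"`: data.table with 0-based `row`,
#'   `col` and `seq` columns.
#' @examples
#' g <- array_geometry(4, 4, 2)
#' load_jobs(c(s1 = "ACGT", s2 = "GGTA"), g)
#' @export
load_jobs <- function(fasta, geometry) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    set <- read_oligos_fasta(fasta)
  } else if (methods::is(fasta, "DNAStringSet")) {
    set <- fasta
  } else {
    set <- Biostrings::DNAStringSet(fasta)
  }
  seqs <- as.character(set)
  if (length(seqs) == 0L) stop("no records")
  if (length(seqs) > geometry$n_rows * geometry$n_cols)
    stop("more records than array sites")
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) stop("non-ACGT character in record '", names(seqs)[which(bad)[1L]], "'")
  if (any(nchar(seqs) == 0L)) stop("empty sequence")

  hdr <- names(seqs)
  if (is.null(hdr)) hdr <- rep("", length(seqs))
  m <- regmatches(hdr, regexec("site=([0-9]+),([0-9]+)", hdr))
  has_site <- lengths(m) == 3L
  row <- col <- rep(NA_integer_, length(seqs))
  row[has_site] <- vapply(m[has_site], function(x) as.integer(x[2L]), integer(1))
  col[has_site] <- vapply(m[has_site], function(x) as.integer(x[3L]), integer(1))

  # fill unannotated records row-major over the free sites
  taken <- row * geometry$n_cols + col
  linear <- setdiff(0:(geometry$n_rows * geometry$n_cols - 1L), taken[has_site])
  need <- sum(!has_site)
  row[!has_site] <- linear[seq_len(need)] %/% geometry$n_cols
  col[!has_site] <- linear[seq_len(need)] %% geometry$n_cols

  if (any(row >= geometry$n_rows | col >= geometry$n_cols))
    stop("site outside geometry")
  key <- row * geometry$n_cols + col
  if (anyDuplicated(key)) stop("duplicate site assignment")
  jobs <- data.table::data.table(row = row, col = col, seq = seqs)
  data.table::setkey(jobs, row, col)
  structure(jobs, class = c("oligo_job", class(jobs)))
}

#' Cycle state of a synthesis run
#'
#' Tracks, per site, how many bases of the target have been synthesised.
#'
#' @param jobs an [load_jobs()] result.
#' @return object of class `"cycle_state"`: list with `done` (integer vector
#'   aligned to `jobs`) and `cycle` counter.
#' @export
cycle_state <- function(jobs) {
  structure(list(done = integer(nrow(jobs)), cycle = 0L), class = "cycle_state")
}

#' Per-base activation masks for the next cycle
#'
#' Splits the unfinished sites into four disjoint activation masks, one per
#' nucleotide: each site appears in exactly the mask of the next base its
#' target requires; finished sites appear in none.  Only one of the four
#' bases is coupled per sub-step, so on uniform-random targets each mask holds
#' about a quarter of the unfinished sites (the ~2.5 million-unit regime for a
#' full ten-million-site array).
#'
#' @param state a [cycle_state()].
#' @param jobs an [load_jobs()] result.
#' @param geometry an [array_geometry()].
#' @return named list of four sparse pattern masks (`A`, `C`, `G`, `T`).
#' @export
cycle_plan <- function(state, jobs, geometry) {
  unfinished <- state$done < nchar(jobs$seq)
  nxt <- substr(jobs$seq, state$done + 1L, state$done + 1L)
  masks <- lapply(c(A = "A", C = "C", G = "G", T = "T"), function(b) {
    sel <- unfinished & nxt == b
    Matrix::sparseMatrix(i = jobs$row[sel] + 1L, j = jobs$col[sel] + 1L,
                         dims = c(geometry$n_rows, geometry$n_cols))
  })
  masks
}

#' Run a full synthesis campaign
#'
#' Loops phosphoramidite cycles until every site has reached its target
#' length.  Each cycle issues four base sub-steps (fixed A, C, G, T order);
#' a sub-step with any active site is scheduled through [schedule_mask()] and
#' held for the electrochemical deprotection time `t_hold_s`, during which the
#' addressing fabric refreshes the held voltages once per scan pass.
#'
#' @param jobs an [load_jobs()] result.
#' @param geometry an [array_geometry()].
#' @param rc an [rc_params()] (used to report refresh ripple at the hold).
#' @param t_charge_ns per-instance dwell (ns).
#' @param t_hold_s electrochemical hold per non-empty sub-step (s).
#' @return object of class `"synthesis_report"`: list with `n_cycles`,
#'   `base_counts` (cycle x base matrix of activated-site counts),
#'   `n_instances` (cycle x base), `addressing_time_s`, `hold_time_s`,
#'   `refreshes_per_hold`, `ripple` and the final `state`.
#' @export
run_synthesis <- function(jobs, geometry, rc = rc_params(), t_charge_ns = 80,
                          t_hold_s = 60) {
  st <- cycle_state(jobs)
  bases <- c("A", "C", "G", "T")
  n_cycles <- max(nchar(jobs$seq))
  base_counts <- matrix(0L, n_cycles, 4L, dimnames = list(NULL, bases))
  n_instances <- matrix(0L, n_cycles, 4L, dimnames = list(NULL, bases))
  addressing_time <- 0
  hold_time <- 0
  for (cyc in seq_len(n_cycles)) {
    masks <- cycle_plan(st, jobs, geometry)
    for (b in bases) {
      cnt <- Matrix::nnzero(masks[[b]])
      base_counts[cyc, b] <- cnt
      if (cnt == 0L) next
      sch <- schedule_mask(masks[[b]], t_charge_ns, geometry)
      n_instances[cyc, b] <- length(sch)
      addressing_time <- addressing_time + scan_time(sch)
      hold_time <- hold_time + t_hold_s
      # the sites in this mask receive one base
      sel <- masks[[b]][cbind(jobs$row + 1L, jobs$col + 1L)]
      st$done <- st$done + as.integer(sel)
    }
    st$cycle <- cyc
  }
  stopifnot(all(st$done == nchar(jobs$seq)))  # bookkeeping identity
  full_pass <- scan_time(full_scan_schedule(geometry, t_charge_ns))
  structure(list(
    n_cycles = n_cycles, base_counts = base_counts, n_instances = n_instances,
    addressing_time_s = addressing_time, hold_time_s = hold_time,
    refreshes_per_hold = ceiling(t_hold_s / full_pass),
    ripple = steady_state_ripple(t_charge_ns * 1e-9, full_pass, rc),
    state = st), class = "synthesis_report")
}

#' @export
print.synthesis_report <- function(x, ...) {
  cat(sprintf("<synthesis_report> %d cycles, %d base couplings over %d sub-steps\n",
              x$n_cycles, sum(x$base_counts), sum(x$n_instances > 0)))
  cat(sprintf("  addressing %.4g s; electrochemical hold %.4g s (%d refreshes per hold, droop %.3g%%)\n",
              x$addressing_time_s, x$hold_time_s, x$refreshes_per_hold,
              x$ripple$droop_pct))
  invisible(x)
}

#' Droplet-confinement audit of an activation mask
#'
#' Crosses an activation mask with a droplet census.  In `"confined"` mode a
#' site deprotects iff it is activated AND its chamber holds a confined
#' droplet (no reaction medium, no reaction; protons stay in the droplet, so
#' no site is ever at risk).  In `"unconfined"` mode — the qualitative
#' counterfactual without droplet isolation — every activated site
#' additionally flags its 4-neighbours as at-risk of spurious deprotection by
#' proton diffusion.
#'
#' @param mask activation mask over the audited sites (any form accepted by
#'   [schedule_mask()], sized `n_units_y x n_units_x`).
#' @param census a [droplet_census()] (or a data.frame with `unit_x`,
#'   `unit_y`, `area_um2`, `confined`).
#' @param mode `"confined"` or `"unconfined"`.
#' @return data.table with 0-based `row`, `col`, and logical `activated`,
#'   `deprotected`, `at_risk` per site.
#' @export
confinement_audit <- function(mask, census, mode = c("confined", "unconfined")) {
  mode <- match.arg(mode)
  cen <- as.data.frame(census)
  stopifnot(all(c("unit_x", "unit_y", "area_um2", "confined") %in% names(cen)))
  nx <- max(cen$unit_x) + 1L; ny <- max(cen$unit_y) + 1L
  g <- array_geometry(ny, nx, n_blocks = 1L)
  act <- mask_sites(mask, g)
  grid <- data.table::data.table(row = cen$unit_y, col = cen$unit_x,
                                 area = cen$area_um2, confined = cen$confined)
  grid$activated <- interaction(grid$row, grid$col) %in%
    interaction(act$row, act$col)
  grid$deprotected <- grid$activated & grid$confined & grid$area > 0
  grid$at_risk <- FALSE
  if (mode == "unconfined") {
    for (k in which(grid$activated)) {
      nb <- cbind(row = grid$row[k] + c(-1L, 1L, 0L, 0L),
                  col = grid$col[k] + c(0L, 0L, -1L, 1L))
      hit <- interaction(grid$row, grid$col) %in% interaction(nb[, 1], nb[, 2])
      grid$at_risk <- grid$at_risk | hit
    }
    grid$at_risk <- grid$at_risk & !grid$activated
  }
  grid[, c("row", "col", "activated", "deprotected", "at_risk")]
}
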