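test_that("FASTA jobs load row-major with optional explicit site headers", {
  g <- array_geometry(4, 4, 2)
  jobs <- load_jobs(c(a = "ACGT", b = "GGTA", c = "TT"), g)
  expect_equal(jobs$row, c(0L, 0L, 0L))
  expect_equal(jobs$col, c(0L, 1L, 2L))
  jobs2 <- load_jobs(c("x site=2,3" = "ACG", y = "TTT"), g)
  expect_true(any(jobs2$row == 2L & jobs2$col == 3L))
  expect_true(any(jobs2$row == 0L & jobs2$col == 0L))
  expect_error(load_jobs(c(a = "ACNT"), g), "non-ACGT")
  expect_error(load_jobs(c("p site=0,0" = "AC", "q site=0,0" = "GT"), g),
               "duplicate site")
  expect_error(load_jobs(c("p site=9,0" = "AC"), g), "outside geometry")
})

test_that("FASTA round-trips through disk including CRLF line endings", {
  g <- array_geometry(4, 4, 2)
  set <- gen_random_oligos(3, 12, seed = 5)
  fa <- tempfile(fileext = ".fa")
  write_oligos_fasta(set, fa)
  expect_identical(as.character(read_oligos_fasta(fa)), as.character(set))
  # CRLF version parses identically
  crlf <- tempfile(fileext = ".fa")
  writeLines(gsub("\n$", "", readLines(fa)), crlf, sep = "\r\n")
  expect_identical(as.character(read_oligos_fasta(crlf)), as.character(set))
  jobs <- load_jobs(fa, g)
  expect_identical(nrow(jobs), 3L)
})

test_that("cycle masks are pairwise disjoint and exactly cover the unfinished sites", {
  g <- array_geometry(6, 6, 2)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("s", seq_len(n))
    jobs <- load_jobs(seqs, g)
    st <- cycle_state(jobs)
    st$done <- vapply(nchar(jobs$seq), function(L) sample(0:L, 1), integer(1))
    masks <- cycle_plan(st, jobs, g)
    # brute-force expectation
    unfinished <- st$done < nchar(jobs$seq)
    nxt <- substr(jobs$seq, st$done + 1L, st$done + 1L)
    tot <- Reduce(`+`, lapply(masks, function(m) as(m, "dMatrix") * 1))
    expect_true(all(tot@x == 1))                    # disjoint
    expect_equal(Matrix::nnzero(tot), sum(unfinished))  # exact cover
    for (b in c("A", "C", "G", "T")) {
      sel <- unfinished & nxt == b
      expect_equal(Matrix::nnzero(masks[[b]]), sum(sel))
      if (any(sel))
        expect_true(all(masks[[b]][cbind(jobs$row[sel] + 1, jobs$col[sel] + 1)]))
    }
  }
  # worked micro-example: next bases (A, C, A)
  jobs <- load_jobs(c(s1 = "A", s2 = "C", s3 = "AT"), g)
  masks <- cycle_plan(cycle_state(jobs), jobs, g)
  counts <- vapply(masks, Matrix::nnzero, numeric(1))
  expect_equal(unname(counts), c(2, 1, 0, 0))
})

test_that("base-mask counts for uniform random sequences concentrate at N/4", {
  n <- 400L; len <- 1L
  g <- array_geometry(20, 20, 4)
  jobs <- load_jobs(gen_random_oligos(n, len, seed = 3), g)
  masks <- cycle_plan(cycle_state(jobs), jobs, g)
  counts <- vapply(masks, Matrix::nnzero, numeric(1))
  expect_equal(sum(counts), n)
  sd4 <- sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(counts - n / 4) <= 4 * sd4))
})

test_that("run_synthesis terminates at the longest target with faithful bookkeeping", {
  g <- array_geometry(8, 8, 2)
  # identical sequences: one non-empty base mask per cycle
  jobs <- load_jobs(setNames(rep("ACGT", 5), paste0("s", 1:5)), g)
  rep1 <- run_synthesis(jobs, g, t_hold_s = 10)
  expect_identical(rep1$n_cycles, 4L)
  expect_true(all(rowSums(rep1$base_counts > 0) == 1))
  expect_equal(unname(diag(rep1$base_counts)), rep(5L, 4))  # A,C,G,T in order
  # mixed lengths: short sites idle after completion
  jobs2 <- load_jobs(c(s1 = "AC", s2 = "ACGTA"), g)
  rep2 <- run_synthesis(jobs2, g)
  expect_identical(rep2$n_cycles, 5L)
  expect_equal(sum(rep2$base_counts), 2L + 5L)
  expect_true(all(rep2$state$done == nchar(jobs2$seq)))
  # property: n_cycles equals the max length over seeded random job sets
  for (seed in 1:10) {
    set <- gen_random_oligos(6, sample(2:9, 1), seed = seed)
    jobs3 <- load_jobs(set, g)
    expect_identical(run_synthesis(jobs3, g)$n_cycles,
                     max(nchar(as.character(set))))
  }
})

test_that("confinement audit separates confined deprotection from diffusion risk", {
  cen <- expand.grid(unit_x = 0:3, unit_y = 0:3)
  cen$area_um2 <- 1.8
  cen$confined <- TRUE
  cen$area_um2[cen$unit_x == 2 & cen$unit_y == 2] <- 0   # dry chamber
  mask <- data.frame(row = c(1, 2), col = c(1, 2))       # activate (1,1) and (2,2)
  aud <- confinement_audit(mask, cen, mode = "confined")
  expect_identical(nrow(aud), 16L)
  expect_true(aud$deprotected[aud$row == 1 & aud$col == 1])
  expect_false(aud$deprotected[aud$row == 2 & aud$col == 2])  # no medium
  expect_true(all(!aud$at_risk))                          # headline claim
  # unconfined counterfactual: the 4-neighbours are flagged
  aud2 <- confinement_audit(data.frame(row = 1, col = 1), cen, mode = "unconfined")
  risk <- aud2[aud2$at_risk, ]
  expect_identical(site_key(data.frame(row = risk$row, col = risk$col)),
                   site_key(data.frame(row = c(0, 2, 1, 1), col = c(1, 1, 0, 2))))
})
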