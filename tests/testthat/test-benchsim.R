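test_that("protein mutation hits the exact substitution count", {
  set.seed(42)
  prot <- rand_protein(200)
  expect_identical(mutate_protein(prot, 100), prot)
  for (id in c(90, 60, 40)) {
    mut <- mutate_protein(prot, id)
    a <- strsplit(prot, "")[[1]]
    b <- strsplit(mut, "")[[1]]
    expect_identical(sum(a != b), as.integer(round((1 - id / 100) * 200)))
  }
  expect_error(mutate_protein(prot, 0), "target_identity")
  expect_error(mutate_protein(prot, 101), "target_identity")
})

test_that("replacement residues are never the original residue", {
  set.seed(43)
  for (i in 1:20) {
    prot <- rand_protein(50)
    mut <- mutate_protein(prot, 50)
    a <- strsplit(prot, "")[[1]]
    b <- strsplit(mut, "")[[1]]
    expect_true(all(nchar(b) == 1))
    expect_identical(sum(a != b), 25L)  # changed positions really changed
  }
})

test_that("the noiseless simulator reproduces the template exactly", {
  set.seed(44)
  tpl <- random_coding_seq(40)
  sim <- simulate_read(tpl, sd_intercept = 1e-9, sd_slope = 0,
                       sd_zero = 1e-9)
  expect_identical(sim$read$sequence, tpl)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("the simulator is deterministic under a fixed seed", {
  tpl <- "TGGTGGAAATTTCCCGGGAAATTTTGGTGGCCAATTGGCA"
  set.seed(7); a <- simulate_read(tpl)
  set.seed(7); b <- simulate_read(tpl)
  expect_identical(a$read$sequence, b$read$sequence)
  expect_identical(a$read$flow_values, b$read$flow_values)
  expect_identical(a$truth, b$truth)
})

test_that("truth events reconstruct the template from the read", {
  set.seed(45)
  for (i in 1:25) {
    tpl <- random_coding_seq(30)
    sim <- simulate_read(tpl, sd_slope = 0.2)  # noisy: force some events
    chars <- strsplit(sim$read$sequence, "")[[1]]
    tt <- sim$truth[order(sim$truth$flow, decreasing = TRUE), ]
    for (r in seq_len(nrow(tt))) {
      if (tt$type[r] == "overcall") {
        drop <- tt$lo[r] + seq_len(tt$count[r]) - 1L + 1L
        chars <- chars[-drop]
      } else {
        at <- tt$lo[r]
        chars <- append(chars, rep(tt$nt[r], tt$count[r]), after = at)
      }
    }
    expect_identical(paste(chars, collapse = ""), tpl)
  }
})

test_that("overcall frequency matches the closed-form normal tail", {
  set.seed(46)
  n <- 3L
  sd <- 0.05 + 0.065 * n
  draws <- 2e4
  peaks <- rnorm(draws, n, sd)
  emp <- mean(floor(pmax(peaks, 0) + 0.5) >= n + 1L)
  expected <- pnorm(n + 0.5, mean = n, sd = sd, lower.tail = FALSE)
  # binomial tolerance at 2e4 draws (4 sigma)
  tol <- 4 * sqrt(expected * (1 - expected) / draws)
  expect_lt(abs(emp - expected), tol + 1e-12)
  # and through the simulator itself on a fixed 3-mer template
  tpl <- paste(rep("TGGAAAC", 300), collapse = "")  # many independent 3-runs
  sim <- simulate_read(tpl)
  over <- sum(sim$truth$type == "overcall" & sim$truth$nt == "A" &
                sim$truth$n_true == 3)
  n_runs <- 300
  p_over <- pnorm(3.5, 3, sd, lower.tail = FALSE)
  expect_lt(abs(over / n_runs - p_over),
            4 * sqrt(p_over * (1 - p_over) / n_runs) + 0.01)
})

test_that("MCC follows the closed formula and conventions", {
  expect_equal(mcc(list(TP = 5, FP = 0, TN = 95, FN = 0)), 1)
  expect_equal(mcc(list(TP = 1, FP = 1, TN = 1, FN = 1)), 0)
  expect_equal(mcc(list(TP = 3, FP = 1, TN = 90, FN = 2)),
               268 / sqrt(4 * 5 * 91 * 92))
  expect_equal(mcc(list(TP = 0, FP = 3, TN = 90, FN = 0)), 0)  # zero factor
  expect_warning(v <- mcc(list(TP = 0, FP = 0, TN = 0, FN = 0)), "undefined")
  expect_equal(v, 0)
})

test_that("prediction scoring matches events by kind, place and base", {
  set.seed(47)
  # perfect recovery: a read whose only event the aligner must correct
  tpl <- "TGGTGGAAAAGTTGGTGGTGCTGGTGG"        # WW K S WW C WW
  # inject one overcall by hand into the A-run (positions 6..9)
  read <- flow_read(paste0(substr(tpl, 1, 9), "A", substr(tpl, 10, nchar(tpl))),
                    id = "simread")
  truth <- structure(list(
    read = read,
    truth = data.frame(type = "overcall", nt = "A", lo = 6L, hi = 10L,
                       count = 1L, flow = NA_integer_, peak = NA_real_,
                       n_true = 4L, stringsAsFactors = FALSE),
    template = tpl), class = "benchmark_truth")
  prot <- translate_cds(tpl)
  aln <- align_read(read, prot, align_params("fasta454"))
  cc <- score_predictions(aln, truth)
  expect_identical(c(cc$TP, cc$FP, cc$FN), c(1L, 0L, 0L))
  expect_equal(mcc(cc), 1)
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN,
                   aln$q_range[2] - aln$q_range[1])
  # an event at the adjacent homopolymer scores one FP and one FN
  truth_shift <- truth
  truth_shift$truth$nt <- "G"            # pretend the G-run was overcalled
  truth_shift$truth$lo <- 3L
  truth_shift$truth$hi <- 5L
  cc2 <- score_predictions(aln, truth_shift)
  expect_identical(c(cc2$TP, cc2$FP, cc2$FN), c(0L, 1L, 1L))
  # truth outside the aligned region is ignored
  truth_out <- truth
  truth_out$truth$lo <- nchar(read$sequence) + 5L
  truth_out$truth$hi <- nchar(read$sequence) + 6L
  cc3 <- score_predictions(aln, truth_out)
  expect_identical(cc3$FN, 0L)
  # id mismatch is an error
  read2 <- read; read2$id <- "other"
  aln2 <- align_read(read2, prot, align_params("fasta454"))
  expect_error(score_predictions(aln2, truth), "different reads")
})

test_that("noiseless reads against the identity-100 target yield no
           frame-shifts and no positives", {
  tab <- run_benchmark(identities = 100, n_reads = 6, seed = 12,
                       template_codons = 100, read_len = 120,
                       sd_intercept = 1e-9, sd_slope = 0, sd_zero = 1e-9)
  expect_true(all(tab$TP == 0 & tab$FP == 0 & tab$FN == 0))
  expect_true(all(tab$MCC == 0))  # undefined-safe: no positives anywhere
  expect_true(all(tab$TN > 0))    # reads aligned cleanly
})

test_that("the benchmark table is seeded, shaped and deterministic", {
  t0 <- run_benchmark(identities = c(100, 60), n_reads = 0)
  expect_identical(nrow(t0), 0L)
  t1 <- run_benchmark(identities = c(100, 60), n_reads = 15, seed = 9,
                      template_codons = 120, read_len = 120)
  t2 <- run_benchmark(identities = c(100, 60), n_reads = 15, seed = 9,
                      template_codons = 120, read_len = 120)
  expect_identical(t1, t2)
  expect_identical(nrow(t1), 6L)  # 3 modes x 2 identities
  expect_true(all(t1$MCC >= -1 & t1$MCC <= 1))
  expect_true(all(t1$TP + t1$FP + t1$TN + t1$FN > 0))
})
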