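test_that("simple codon-exact alignments score as BLOSUM sums", {
  a <- align_read("ATGAAA", "MK", align_params("neutral"))
  expect_equal(a$score, 10)
  expect_identical(nrow(a$events), 0L)
  expect_equal(a$coverage, 1)
  expect_equal(a$identities, 2L)
  expect_equal(brute_force_align("ATGAAA", "MK", align_params("neutral")), 10)
})

test_that("pure-mismatch pairs return the empty alignment at the 0 floor", {
  a <- align_read("AAAAAAAAA", "WWW", align_params("neutral"))
  expect_equal(a$score, 0)
  expect_identical(a$ncols, 0L)
  expect_equal(a$q_range[2] - a$q_range[1], 0)
  expect_equal(brute_force_align("AAAAAAAAA", "WWW",
                                 align_params("neutral")), 0)
})

test_that("frame-shift matches are found and priced per mode", {
  # reads with a forced single overcall inside an A-run; flanking W codons
  # pin the alignment so the frame-shift must be crossed
  read <- "TGGTGGAAAAAGTTGGTGG"  # WW-K-S-WW template with an A overcall
  prot <- "WWKSWW"
  neutral <- align_params("neutral")
  a <- align_read(read, prot, neutral)
  b <- brute_force_align(read, prot, neutral)
  expect_equal(a$score, b)
  expect_identical(a$events$type, "del1")
  expect_gte(a$events$pos1, 6L)  # deleted base inside the A-run
  expect_lte(a$events$pos1, 10L)
  # homopolymer model pays less for the same correction
  fasta <- align_params("fasta454")
  af <- align_read(read, prot, fasta)
  expect_equal(af$score, brute_force_align(read, prot, fasta))
  expect_lt(af$events$penalty, fasta$S)
  expect_gte(af$events$penalty, fasta$S * fasta$h)
})

test_that("alignment score is reproduced from the traceback events", {
  set.seed(19)
  for (i in 1:12) {
    mode <- c("neutral", "fasta454", "flow454")[(i %% 3) + 1]
    params <- rand_params(mode)
    read <- rand_mode_read(sample(12:20, 1), mode)
    prot <- rand_protein(sample(3:6, 1))
    a <- align_read(read, prot, params)
    expect_equal(flowalign:::rescore_alignment(a), a$score,
                 tolerance = 1e-9)
    expect_identical(a$ngaps,
                     if (nrow(a$events)) sum(ifelse(
                       a$events$type %in% c("del2s", "ins2s"), 2L, 1L))
                     else 0L)
  }
})

test_that("score is invariant under unalignable flanking sequence", {
  # stop-codon flanks (TAA repeats) cannot contribute positive columns
  # against this target, and do not merge homopolymer runs at the joins
  params <- align_params("fasta454")
  core <- "TGGTGGAAAAAGTTGGTGG"
  prot <- "WWKSWW"
  s0 <- align_read(core, prot, params)$score
  s_right <- align_read(paste0(core, "TAATAATAA"), prot, params)$score
  s_both <- align_read(paste0("TAATAATAAC", core, "TAATAATAA"), prot,
                       params)$score
  expect_equal(s_right, s0)
  expect_equal(s_both, s0)
  # and byte-level determinism of repeated runs
  expect_equal(align_read(core, prot, params)$score, s0)
})

test_that("flow-aware scoring never falls below the neutral score at
           integer flowpeaks", {
  set.seed(29)
  for (i in 1:8) {
    seq <- rand_nt_seq(18)
    prot <- rand_protein(5)
    S <- 12; D <- 24
    neutral <- align_params("neutral", S = S, D = D)
    fasta <- align_params("fasta454", S = S, D = D, h = 0.5, k = 0.6)
    flow <- align_params("flow454", S = S, D = D, h = 0.5, k = 0.6,
                         V = FALSE)
    s_neutral <- align_read(seq, prot, neutral)$score
    s_fasta <- align_read(seq, prot, fasta)$score
    # flowpeaks exactly at the homopolymer integers = FASTA annotation
    s_flow <- align_read(annotate_fasta(seq), prot, flow)$score
    expect_gte(s_fasta, s_neutral - 1e-9)
    expect_gte(s_flow, s_fasta - 1e-9)
  }
})

test_that("alignment statistics and text rendering are self-consistent", {
  read <- "TGGTGGAAAAAGTTGGTGG"
  a <- align_read(read, "WWKSWW", align_params("fasta454"),
                  target_id = "demo")
  st <- alignment_stats(a)
  expect_identical(st$identities_fmt,
                   pct <- sprintf("%d/%d (%d%%)", st$identities, st$columns,
                                  round(100 * st$identities / st$columns)))
  txt <- format_alignment(a)
  hdr <- parse_alignment_header(txt)
  expect_equal(hdr$score, a$score, tolerance = 5e-6)
  expect_equal(hdr$identities$x, st$identities)
  expect_equal(hdr$positives$x, st$positives)
  expect_equal(hdr$gaps, st$gaps)
  expect_equal(hdr$ngaps, st$ngaps)
  # exactly one lowercase character per single-base frame-shift
  qrow <- sub("^Query\\s+\\d+ ", "",
              grep("^Query\\s+\\d+ ", txt, value = TRUE))
  n_lower <- sum(vapply(strsplit(qrow, ""), function(ch)
    sum(ch %in% letters), integer(1)))
  expect_identical(n_lower, 1L)
  # deterministic byte-exact rendering
  expect_identical(txt, format_alignment(align_read(read, "WWKSWW",
                                                    align_params("fasta454"),
                                                    target_id = "demo")))
})

test_that("insertion predictions substitute the maximum-likelihood base", {
  # undercalled lysine run: AAA -> AA; K vs "AA?" best insert is A
  read <- "TGGTGGAATTTTGGTGG"  # WW-K-F-WW template with the K-run undercalled
  a <- align_read(read, "WWKFWW", align_params("fasta454"))
  ins <- a$events[startsWith(a$events$type, "ins"), ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$nt1, "A")
  txt <- format_alignment(a)
  qrow <- paste(sub("^Query\\s+\\d+ ", "",
                    grep("^Query\\s+\\d+ ", txt, value = TRUE)),
                collapse = "")
  expect_true(grepl("a", qrow, fixed = TRUE))
})

test_that("reverse-complement alignment recovers the forward score", {
  set.seed(31)
  params <- align_params("fasta454")
  for (i in 1:5) {
    seq <- rand_nt_seq(20)
    prot <- rand_protein(5)
    fwd <- align_read(seq, prot, params)$score
    rc <- rc_flow_read(annotate_fasta(seq))
    # aligning the reverse complement of the reverse complement == forward
    back <- rc_flow_read(rc)
    expect_identical(back$sequence, seq)
    expect_equal(align_read(back, prot, params)$score, fwd)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(align_read("ATGAAA", "", align_params("neutral")),
               "length >= 1")
  expect_error(align_read("ATGAAA", "M1K", align_params("neutral")),
               "invalid character")
  expect_error(brute_force_align(rand_nt_seq(40), "MK",
                                 align_params("neutral")), "tiny")
})
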