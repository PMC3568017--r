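test_that("deletion windows enumerate 4-choose-1 and 5-choose-2 candidates", {
  c4 <- enumerate_deletions("AACG")
  expect_identical(nrow(c4), 4L)
  expect_identical(c4$triplet, c("ACG", "ACG", "AAG", "AAC"))
  c5 <- enumerate_deletions("TACGT")
  expect_identical(nrow(c5), 10L)
  expect_identical(sum(c5$event == "del2g"), 4L)  # grouped adjacent pairs
  expect_identical(sum(c5$event == "del2s"), 6L)  # split pairs
  ch <- enumerate_deletions("AAAA")
  expect_true(all(ch$triplet == "AAA"))
  expect_length(unique(ch$penalty), 1L)  # homopolymer symmetry
  expect_error(enumerate_deletions("ACG"), "4 or 5")
})

test_that("insertion windows enumerate 12 and 48 combinations", {
  ci <- enumerate_insertions("TC")
  expect_identical(nrow(ci), 12L)
  expect_identical(length(unique(ci$triplet)), 10L)  # 4 + 3 + 3
  cd <- enumerate_insertions("A")
  expect_identical(nrow(cd), 48L)
  expect_identical(length(unique(cd$triplet)), 37L)  # 16 + 12 + 9
  expect_identical(sum(cd$event == "ins2g"), 32L)
  expect_identical(sum(cd$event == "ins2s"), 16L)
  expect_error(enumerate_insertions("ACG"), "1 or 2")
})

test_that("candidate counts hold over random windows and parameter draws", {
  set.seed(101)
  for (i in 1:25) {
    mode <- c("neutral", "fasta454", "flow454")[(i %% 3) + 1]
    params <- rand_params(mode)
    read <- rand_mode_read(12, mode)
    L <- nchar(read$sequence)
    novalid <- params
    novalid$V <- FALSE
    expect_identical(nrow(fs_candidates(read, 5, 4, novalid)), 4L)
    expect_identical(nrow(fs_candidates(read, 6, 5, novalid)), 10L)
    ci <- fs_candidates(read, 4, 2, novalid)
    expect_identical(nrow(ci), 12L)
    expect_lte(length(unique(ci$triplet)), 10L)
    cd <- fs_candidates(read, 4, 1, novalid)
    expect_identical(nrow(cd), 48L)
    expect_lte(length(unique(cd$triplet)), 37L)
    # with validation the candidate set only shrinks
    withv <- params
    withv$V <- TRUE
    expect_lte(nrow(fs_candidates(read, 4, 2, withv)), 12L)
    expect_lte(nrow(fs_candidates(read, 4, 1, withv)), 48L)
  }
})

test_that("candidate penalties respect the homopolymer floors", {
  set.seed(55)
  for (i in 1:10) {
    mode <- c("fasta454", "flow454")[(i %% 2) + 1]
    params <- rand_params(mode)
    read <- rand_mode_read(14, mode)
    for (w in c(1L, 2L, 4L, 5L)) {
      cand <- fs_candidates(read, 9, w, params)
      if (!nrow(cand)) next
      floor1 <- params$S * params$h - 1e-9
      floor2g <- params$D * params$h - 1e-9
      floor2s <- 2 * params$S * params$h - 1e-9
      expect_true(all(
        cand$penalty >= ifelse(cand$event %in% c("del1", "ins1"), floor1,
                        ifelse(cand$event %in% c("del2g", "ins2g"), floor2g,
                               floor2s))))
    }
  }
})

test_that("restricting the insertion alphabet enumerates the allowed set", {
  # force a single allowed nucleotide at every internal gap via flow data:
  # "TC" with only an A zero-flow between -- with V, internal inserts are
  # restricted to {T, A, C}
  r <- flow_read("TC", flowpeaks = c(1, 1), flow_values = c(1, 0, 1),
                 flow_index = c(0L, 2L))
  params <- align_params("flow454")
  ci <- fs_candidates(r, 1, 2, params)
  mid <- ci[ci$gap1 == 1L, ]
  expect_setequal(mid$ins1, c("T", "A", "C"))  # no G flowed between
})

test_that("profile cells equal the brute-force candidate maximum", {
  set.seed(77)
  m <- substitution_matrix()
  for (i in 1:8) {
    mode <- c("neutral", "fasta454", "flow454")[(i %% 3) + 1]
    params <- rand_params(mode)
    read <- rand_mode_read(sample(8:14, 1), mode)
    prof <- build_profile(read, params)
    L <- nchar(read$sequence)
    for (w in c(1L, 2L, 4L, 5L)) {
      for (at in (w - 1L):(L - 1L)) {
        cand <- fs_candidates(read, at, w, params)
        for (aa in sample(rownames(m)[1:20], 3)) {
          ref <- if (nrow(cand)) {
            max(vapply(seq_len(nrow(cand)), function(r) {
              m3_score(aa, cand$triplet[r], m) - cand$penalty[r]
            }, numeric(1)))
          } else -Inf
          expect_equal(profile_cell(prof, aa, at, w), ref, tolerance = 1e-12)
        }
      }
    }
    # width 3 is the plain codon score with no penalty
    at <- sample(2:(L - 1L), 1)
    trip <- substr(read$sequence, at - 1L, at + 1L)
    expect_equal(profile_cell(prof, "K", at, 3), m3_score("K", trip, m))
    # cells whose window extends past the read start are unusable
    expect_identical(profile_cell(prof, "K", 2, 4), -Inf)
  }
})

test_that("tightening insertion validation never increases profile cells", {
  set.seed(88)
  for (i in 1:5) {
    params_off <- rand_params("flow454")
    params_off$V <- FALSE
    params_on <- params_off
    params_on$V <- TRUE
    read <- rand_mode_read(12, "flow454")
    p_off <- build_profile(read, params_off)
    p_on <- build_profile(read, params_on)
    for (w in c(1L, 2L)) {
      off <- p_off$m[[w]]
      on <- p_on$m[[w]]
      expect_true(all(on <= off + 1e-12))
    }
  }
})
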