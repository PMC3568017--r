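# Synthetic benchmark: coding-seed generation, BLOSUM-guided protein
# mutation to a fixed identity, flow-space read simulation with ground-truth
# homopolymer over/undercalls, indel-recovery scoring and MCC.

SENSE_CODONS <- local({
  codons <- NULL
  function() {
    if (is.null(codons)) {
      gc <- codon_table()
      codons <<- names(gc)[gc != "*"]
    }
    codons
  }
})

#' Generate a random coding nucleotide sequence
#'
#' Uniform draw over the 61 sense codons (no internal stop codons).
#'
#' @param n_codons number of codons.
#' @return a nucleotide string of length `3 * n_codons`.
#' @export
random_coding_seq <- function(n_codons = 650) {
  paste(sample(SENSE_CODONS(), n_codons, replace = TRUE), collapse = "")
}

#' Translate a coding nucleotide sequence
#'
#' @param dna in-frame nucleotide string (length divisible by 3).
#' @return amino-acid string.
#' @export
translate_cds <- function(dna) {
  stopifnot(nchar(dna) %% 3 == 0)
  starts <- seq(1, nchar(dna), by = 3)
  paste(vapply(starts, function(s) translate_codon(substr(dna, s, s + 2)),
               character(1)), collapse = "")
}

# BLOSUM clustering level nearest to the target identity, among the levels
# available (ties resolved towards the lower, more permissive level).
blosum_for_identity <- function(identity) {
  levels <- c(45, 50, 62, 80, 100)
  d <- abs(levels - identity)
  lv <- levels[which(d == min(d))][1]
  substitution_matrix(paste0("BLOSUM", lv))
}

#' Mutate a protein down to a target identity
#'
#' Substitutes exactly `round((1 - identity/100) * nchar(protein))`
#' positions, chosen uniformly without replacement.  The replacement residue
#' is drawn over the 19 other standard residues with probability
#' proportional to `2^(s/2)` where `s` is the substitution score of the
#' BLOSUM matrix whose clustering level is nearest the target identity
#' (inverted log-odds under a uniform background).
#'
#' @param protein amino-acid string.
#' @param target_identity percent identity in (0, 100].
#' @return the mutated protein string.
#' @export
mutate_protein <- function(protein, target_identity) {
  if (target_identity <= 0 || target_identity > 100) {
    stop("target_identity must lie in (0, 100]", call. = FALSE)
  }
  protein <- check_protein(protein)
  L <- nchar(protein)
  n_sub <- round((1 - target_identity / 100) * L)
  if (n_sub == 0L) return(protein)
  mat <- blosum_for_identity(target_identity)
  std <- AA_ALPHABET[1:20]
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  pos <- sample.int(L, n_sub)
  for (p in pos) {
    orig <- aa[p]
    if (!orig %in% std) next  # non-standard residues left untouched
    others <- setdiff(std, orig)
    w <- 2^(mat[orig, others] / 2)
    aa[p] <- sample(others, 1, prob = w)
  }
  paste(aa, collapse = "")
}

#' Simulate a flow-space read from a template
#'
#' Decomposes the template into flows over the repeating cycle; each
#' positive flow's peak is drawn from `Normal(n, sd_intercept + sd_slope*n)`
#' truncated at 0 and each zero flow from `|Normal(0, sd_zero)|`.  Peaks are
#' called by rounding; every called length differing from the template run
#' length is recorded as a ground-truth overcall or undercall in read
#' coordinates.
#'
#' @param template nucleotide string.
#' @param sd_intercept,sd_slope flowpeak noise for an n-mer:
#'   `sd = sd_intercept + sd_slope * n`.
#' @param sd_zero noise of zero flows.
#' @param flow_order repeating flow cycle.
#' @return a `benchmark_truth` list: `read` (a [flow_read()] with flowgram),
#'   `truth` (data.frame of events: type, nucleotide, acceptance span
#'   `lo..hi` in read coordinates, count), and the `template`.
#' @export
simulate_read <- function(template, sd_intercept = 0.05, sd_slope = 0.065,
                          sd_zero = 0.12, flow_order = "TACG") {
  codes <- nt_encode(template)
  if (any(codes == 4L)) stop("template must not contain N", call. = FALSE)
  runs <- run_decompose(codes)
  fidx <- simulate_flow_index(codes, flow_order)
  run_start <- which(c(TRUE, diff(runs$id) != 0))
  run_nt <- codes[run_start]
  run_len <- runs$length[run_start]
  run_flow <- fidx[run_start]
  n_flows <- max(run_flow) + 1L
  n_true <- integer(n_flows)
  n_true[run_flow + 1L] <- run_len
  ord <- nt_encode(flow_order)
  nt_flow <- ord[(seq_len(n_flows) - 1L) %% length(ord) + 1L]
  sds <- ifelse(n_true > 0, sd_intercept + sd_slope * n_true, sd_zero)
  peaks <- rnorm(n_flows, mean = n_true, sd = sds)
  peaks <- ifelse(n_true > 0, pmax(peaks, 0), abs(peaks))
  called <- pmax(as.integer(floor(peaks + 0.5)), 0L)
  # assemble read
  keep <- called > 0L
  read_nt <- rep(nt_flow[keep], called[keep])
  read_peak <- rep(peaks[keep], called[keep])
  read_fidx <- rep(which(keep) - 1L, called[keep])
  if (!length(read_nt)) stop("simulated read is empty", call. = FALSE)
  seq <- paste(NT_ALPHABET[read_nt + 1L], collapse = "")
  read <- flow_read(seq, id = "simread", flowpeaks = read_peak,
                    flow_order = flow_order, flow_values = peaks,
                    flow_index = read_fidx)
  # ground truth in read coordinates
  start_of_flow <- c(0L, cumsum(called))  # read offset before each flow
  ev <- which(called != n_true)
  truth <- if (length(ev)) {
    do.call(rbind, lapply(ev, function(fl) {
      m <- called[fl]; n <- n_true[fl]
      pos <- start_of_flow[fl]
      if (m > n) {
        data.frame(type = "overcall", nt = NT_ALPHABET[nt_flow[fl] + 1L],
                   lo = pos, hi = pos + m - 1L, count = m - n,
                   flow = fl - 1L, peak = peaks[fl], n_true = n,
                   stringsAsFactors = FALSE)
      } else {
        # acceptable insertion gaps: around the remaining called run, or
        # the exact gap when the run vanished
        data.frame(type = "undercall", nt = NT_ALPHABET[nt_flow[fl] + 1L],
                   lo = pos, hi = if (m > 0) pos + m else pos,
                   count = n - m, flow = fl - 1L, peak = peaks[fl],
                   n_true = n, stringsAsFactors = FALSE)
      }
    }))
  } else {
    data.frame(type = character(), nt = character(), lo = integer(),
               hi = integer(), count = integer(), flow = integer(),
               peak = numeric(), n_true = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(read = read, truth = truth, template = template),
            class = "benchmark_truth")
}

#' Score predicted homopolymer indels against the simulation truth
#'
#' A true positive is a predicted deletion inside the called span of a
#' truth overcall, or a predicted insertion of the correct nucleotide at a
#' gap adjacent to (or replacing) a truth undercall.  Unmatched predictions
#' are false positives; unmatched truth events inside the aligned query
#' region are false negatives (events outside the alignment are ignored);
#' true negatives are the remaining aligned query positions.
#'
#' @param alignment an [align_read()] result for `truth$read`.
#' @param truth a [simulate_read()] result.
#' @return a `confusion_counts` list (TP, FP, TN, FN).
#' @export
score_predictions <- function(alignment, truth) {
  stopifnot(inherits(alignment, "fs_alignment"),
            inherits(truth, "benchmark_truth"))
  if (!identical(alignment$query_id, truth$read$id)) {
    stop("alignment and truth refer to different reads", call. = FALSE)
  }
  qs <- alignment$q_range[1]
  qe <- alignment$q_range[2]
  preds <- alignment_indels(alignment)
  tt <- truth$truth
  cap <- tt$count
  TP <- 0L; FP <- 0L
  if (nrow(preds)) {
    for (r in seq_len(nrow(preds))) {
      kind <- if (preds$type[r] == "del") "overcall" else "undercall"
      hit <- which(tt$type == kind & tt$nt == preds$nt[r] & cap > 0L &
                     preds$pos[r] >= tt$lo & preds$pos[r] <= tt$hi)
      if (length(hit)) {
        cap[hit[1]] <- cap[hit[1]] - 1L
        TP <- TP + 1L
      } else {
        FP <- FP + 1L
      }
    }
  }
  inside <- tt$lo >= qs & tt$hi <= qe
  FN <- sum(cap[inside])
  aligned <- qe - qs
  TN <- max(aligned - TP - FP - FN, 0L)
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN),
            class = "confusion_counts")
}

#' Matthews Correlation Coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero factor yields 0.
#'
#' @param counts a list/vector with elements TP, FP, TN, FN.
#' @return value in `[-1, 1]`.
#' @examples
#' mcc(list(TP = 5, FP = 0, TN = 95, FN = 0))  # 1
#' @export
mcc <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  if (TP + FP + TN + FN == 0) {
    warning("all confusion counts are zero; MCC undefined, returning 0")
    return(0)
  }
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den == 0) return(0)
  (TP * TN - FP * FN) / sqrt(den)
}

#' Run the homopolymer indel-recovery benchmark
#'
#' Generates a random coding seed sequence, derives mutated protein targets
#' at each identity level, simulates flow-space reads over uniformly placed
#' template windows, aligns every read to every target under each alignment
#' model, scores the predicted homopolymer indels against the simulation
#' truth, and tabulates pooled confusion counts and MCC per (mode,
#' identity).
#'
#' @param identities percent identities of the protein targets.
#' @param n_reads number of simulated reads.
#' @param modes alignment models to evaluate.
#' @param params_by_mode optional named list of [align_params()] overriding
#'   the per-mode defaults.
#' @param seed RNG seed (all randomness is derived from it).
#' @param template_codons length of the coding seed in codons.
#' @param read_len simulated read length (template window, nt).
#' @param sd_intercept,sd_slope,sd_zero noise schedule, see
#'   [simulate_read()].
#' @return a data.frame with one row per (mode, identity): parameters,
#'   pooled TP/FP/TN/FN and MCC.
#' @export
run_benchmark <- function(identities = c(100, 80, 60, 40), n_reads = 1000,
                          modes = c("neutral", "fasta454", "flow454"),
                          params_by_mode = NULL, seed = 1,
                          template_codons = 650, read_len = 350,
                          sd_intercept = 0.05, sd_slope = 0.065,
                          sd_zero = 0.12) {
  set.seed(seed)
  out_cols <- c("mode", "identity", "S", "D", "h", "k", "V",
                "TP", "FP", "TN", "FN", "MCC")
  if (n_reads == 0L) {
    return(stats::setNames(
      data.frame(character(), numeric(), numeric(), numeric(), numeric(),
                 numeric(), logical(), integer(), integer(), integer(),
                 integer(), numeric(), stringsAsFactors = FALSE), out_cols))
  }
  template <- random_coding_seq(template_codons)
  seed_protein <- translate_cds(template)
  targets <- lapply(identities, function(id) mutate_protein(seed_protein, id))
  tlen <- nchar(template)
  sims <- lapply(seq_len(n_reads), function(i) {
    start <- sample.int(tlen - read_len + 1L, 1L)
    sim <- simulate_read(substr(template, start, start + read_len - 1L),
                         sd_intercept = sd_intercept, sd_slope = sd_slope,
                         sd_zero = sd_zero)
    sim$read$id <- sprintf("simread%05d", i)
    sim
  })
  rows <- list()
  for (mode in modes) {
    params <- if (!is.null(params_by_mode) && !is.null(params_by_mode[[mode]]))
      params_by_mode[[mode]] else align_params(mode)
    counts <- lapply(identities, function(id)
      list(TP = 0L, FP = 0L, TN = 0L, FN = 0L))
    for (sim in sims) {
      read <- if (mode == "flow454") sim$read else
        annotate_fasta(sim$read$sequence, id = sim$read$id)
      profile <- build_profile(read, params)
      for (ti in seq_along(identities)) {
        aln <- align_read(profile, targets[[ti]],
                          target_id = sprintf("target%d", identities[ti]))
        cc <- score_predictions(aln, sim)
        counts[[ti]] <- Map(`+`, counts[[ti]], cc)
      }
    }
    for (ti in seq_along(identities)) {
      cc <- counts[[ti]]
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, identity = identities[ti], S = params$S, D = params$D,
        h = params$h, k = params$k, V = params$V,
        TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
        MCC = mcc(cc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
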