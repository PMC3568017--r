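# Shared generators for randomised property tests.

rand_nt_seq <- function(n) {
  paste(sample(c("T", "A", "C", "G"), n, replace = TRUE,
               prob = c(0.3, 0.3, 0.2, 0.2)), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# Parameter draw constrained by validate_params (D <= 2S, S*h + D*h > G0).
rand_params <- function(mode) {
  repeat {
    S <- sample(6:30, 1)
    D <- round(S * runif(1, 1.4, 2), 1)
    h <- round(runif(1, 0.2, 1), 2)
    k <- round(runif(1, 0.2, 1), 2)
    V <- sample(c(TRUE, FALSE), 1)
    p <- try(align_params(mode, S = S, D = D, h = h, k = k, V = V),
             silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
}

# A random read for the given mode: plain FASTA annotation, or a simulated
# flow-space read carrying a full flowgram.
rand_mode_read <- function(n, mode) {
  seq <- rand_nt_seq(n)
  if (mode != "flow454") return(annotate_fasta(seq))
  simulate_read(seq, sd_intercept = 0.05, sd_slope = 0.1)$read
}

# Best of the three forward-frame protein local alignments of the translated
# read, computed with the Biostrings aligner (reference for the frame-limit
# property).  Gap mapping: this package prices a protein gap of length g as
# G0 + (g-1)*Ge, Biostrings as opening + g*extension.
ref_three_frame_score <- function(seq, protein, G0, Ge, stop_score = -16) {
  bmat <- unclass(substitution_matrix())
  bmat["*", ] <- stop_score
  bmat[, "*"] <- stop_score
  best <- 0
  for (f in 1:3) {
    len <- nchar(seq) - f + 1L
    sub <- substr(seq, f, f + len - (len %% 3) - 1L)
    if (nchar(sub) < 3) next
    tr <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             if.fuzzy.codon = "X"))
    sc <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(tr), Biostrings::AAString(protein),
      type = "local", substitutionMatrix = bmat,
      gapOpening = G0 - Ge, gapExtension = Ge, scoreOnly = TRUE)
    best <- max(best, sc)
  }
  best
}
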