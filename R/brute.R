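# Independent scoring oracle for small instances.
#
# Enumerates local alignments directly as sequences of building blocks --
# width-1/2/3/4/5 matches, protein-space gap runs of explicit length g
# (cost G0 + (g-1)*Ge), codon-space gap runs consuming 3g nucleotides --
# with free ends, maximising over every start and end cell.  Match values
# come from the R-level candidate enumeration ([fs_candidates()]), not from
# the query profile, so this path shares no code with the C++ aligner.

#' Exhaustive best local alignment score (test oracle)
#'
#' @param read a [flow_read()] or nucleotide string (at most 24 nt).
#' @param protein amino-acid string (at most 8 residues).
#' @param params an [align_params()].
#' @return the optimal local alignment score.
#' @export
brute_force_align <- function(read, protein, params) {
  read <- as_window_read(read)
  protein <- check_protein(protein)
  Lq <- length(read$seq_codes)
  Lp <- nchar(protein)
  if (Lp > 8L || Lq > 24L) {
    stop("brute_force_align is restricted to tiny instances ",
         "(protein <= 8 aa, read <= 24 nt)", call. = FALSE)
  }
  validate_params(params)
  paa <- strsplit(protein, "", fixed = TRUE)[[1]]
  mat <- params$matrix
  # match value tables: mw[[w]][ai, last+1] for window of width w ending at
  # 0-based position `last`, residue index ai into paa
  mw <- vector("list", 5)
  for (w in c(1L, 2L, 4L, 5L)) {
    tab <- matrix(-Inf, Lp, Lq)
    if (Lq >= w) {
      for (last in (w - 1L):(Lq - 1L)) {
        cand <- fs_candidates(read, last, w, params)
        if (!nrow(cand)) next
        res <- vapply(cand$triplet, translate_codon, character(1))
        for (ai in seq_len(Lp)) {
          sc <- ifelse(res == "*", STOP_SCORE, mat[paa[ai], res]) -
            cand$penalty
          tab[ai, last + 1L] <- max(sc)
        }
      }
    }
    mw[[w]] <- tab
  }
  m3tab <- matrix(-Inf, Lp, Lq)
  if (Lq >= 3L) {
    for (last in 2L:(Lq - 1L)) {
      trip <- substr(read$sequence, last - 1L, last + 1L)
      res <- translate_codon(trip)
      for (ai in seq_len(Lp)) {
        m3tab[ai, last + 1L] <- if (res == "*") STOP_SCORE else
          mat[paa[ai], res]
      }
    }
  }
  mw[[3]] <- m3tab
  gap_cost <- function(g) params$G0 + (g - 1) * params$Ge
  # best(i, j) = best score of an alignment starting with i residues and j
  # nucleotides already consumed; filled backwards.
  best <- matrix(0, Lp + 1L, Lq + 1L)
  for (i in Lp:0) {
    for (j in Lq:0) {
      v <- 0
      if (i < Lp) {
        for (w in 1:5) {
          if (j + w <= Lq) {
            val <- mw[[w]][i + 1L, j + w] + best[i + 2L, j + w + 1L]
            if (val > v) v <- val
          }
        }
        for (g in 1:(Lp - i)) {
          val <- -gap_cost(g) + best[i + g + 1L, j + 1L]
          if (val > v) v <- val
        }
      }
      if (j + 3L <= Lq) {
        for (g in 1:((Lq - j) %/% 3L)) {
          val <- -gap_cost(g) + best[i + 1L, j + 3L * g + 1L]
          if (val > v) v <- val
        }
      }
      best[i + 1L, j + 1L] <- v
    }
  }
  max(best)
}
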