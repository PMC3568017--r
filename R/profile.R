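# Query profile: pre-computed composite match scores m1..m5.

# codon -> residue-index lookup over codes 0..4 (N = 4), flattened as
# c1*25 + c2*5 + c3.  Any N-containing triplet maps to X; stops map to the
# stop sentinel index.
codon_aa_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t0 <- integer(125)
      gc <- codon_table()
      for (c1 in 0:4) for (c2 in 0:4) for (c3 in 0:4) {
        idx <- c1 * 25L + c2 * 5L + c3 + 1L
        if (c1 == 4L || c2 == 4L || c3 == 4L) {
          t0[idx] <- match("X", AA_ALPHABET) - 1L
        } else {
          trip <- paste(NT_ALPHABET[c(c1, c2, c3) + 1L], collapse = "")
          t0[idx] <- match(unname(gc[trip]), AA_ALPHABET) - 1L
        }
      }
      tab <<- t0
    }
    tab
  }
})

# Flat read-context list consumed by the C++ kernel.
encode_read_ctx <- function(read) {
  ctx <- build_ins_context(read)
  allowed <- ctx$allowed
  storage.mode(allowed) <- "integer"
  list(seq = read$seq_codes,
       run_p = read$flowpeaks,
       run_n = read$run_length,
       run_id = read$run_id,
       ins_kind = ctx$kind,
       ins_p = ctx$p,
       ins_n = ctx$n,
       ins_allowed = allowed,
       codon_aa = codon_aa_table())
}

encode_par <- function(params) {
  list(S = params$S, D = params$D, h = params$h, k = params$k,
       G0 = params$G0, Ge = params$Ge, V = isTRUE(params$V),
       neutral = identical(params$mode, "neutral"),
       stop_score = STOP_SCORE)
}

#' Build the query profile for a read
#'
#' Pre-computes, for every query position and residue, the best composite
#' match score of matching 1, 2, 3, 4 or 5 query nucleotides (window ending
#' at that position) to the residue: the width-3 entry is the plain codon
#' substitution score, the other widths maximise
#' `m3(aa, T_k) - P_k` over all frame-shift candidates `T_k` of the window.
#' Cells whose window extends past the read start are unusable (-Inf).
#'
#' @param read a [flow_read()] or nucleotide string.
#' @param params an [align_params()].
#' @return a `query_profile` holding the five score matrices (residues x
#'   positions) plus the read and parameters they were built for.
#' @export
build_profile <- function(read, params = align_params("fasta454")) {
  read <- as_window_read(read)
  validate_params(params)
  ctx <- encode_read_ctx(read)
  m <- cpp_build_profile(ctx, encode_par(params), unclass(params$matrix))
  structure(list(read = read, params = params, ctx = ctx, m = m),
            class = "query_profile")
}

#' Look up one profile cell
#'
#' @param profile a [build_profile()] result.
#' @param aa single-letter residue.
#' @param at 0-based query position of the window end.
#' @param width match width in 1..5.
#' @return the composite score (`-Inf` for unusable cells).
#' @export
profile_cell <- function(profile, aa, at, width) {
  stopifnot(inherits(profile, "query_profile"))
  i <- match(toupper(aa), AA_ALPHABET)
  if (is.na(i)) i <- match("X", AA_ALPHABET)
  v <- profile$m[[width]][i, at + 1L]
  if (v <= -1e29) -Inf else v
}

#' @export
print.query_profile <- function(x, ...) {
  cat(sprintf("query_profile: read '%s' (%d nt), mode %s\n",
              x$read$id, length(x$read$seq_codes), x$params$mode))
  invisible(x)
}
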