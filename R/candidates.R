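# Frame-shifting candidate enumeration.
#
# A frame-breaking match of width w in {1, 2, 4, 5} aligns w query
# nucleotides to one amino acid by inserting (w < 3) or deleting (w > 3)
# nucleotides until a triplet remains.  Each concrete way of doing so is a
# candidate: a triplet T_k plus the penalty P_k of the indel event(s) that
# produced it.  Enumeration order encodes the tie-break preference used by
# the aligner: fewer events first (grouped before split doubles), then
# leftmost event position, then alphabetical inserted nucleotide.

# Reduction factor for deleting one base of the run containing 0-based
# position t (m = n - 1), or, with m_off = 2, a grouped within-run double.
del_factor <- function(read, t, params, m_off = 1L) {
  if (params$mode == "neutral") return(0)
  p <- read$flowpeaks[t + 1L]
  n <- read$run_length[t + 1L]
  penalty_factor(p, n, n - m_off, params$k)
}

# Reduction factor for inserting nucleotide code a (0-based) at gap g,
# given the read's insertion context; count = 1 or 2 inserted copies.
ins_factor <- function(ctx, g, a, params, count = 1L) {
  if (params$mode == "neutral") return(0)
  kind <- ctx$kind[a + 1L, g + 1L]
  if (kind == 1L) {
    n <- ctx$n[a + 1L, g + 1L]
    penalty_factor(ctx$p[a + 1L, g + 1L], n, n + count, params$k)
  } else if (kind == 2L) {
    penalty_factor(ctx$p[a + 1L, g + 1L], 0, count, params$k)
  } else 0
}

as_window_read <- function(window) {
  if (inherits(window, "flow_read")) window else annotate_fasta(window)
}

empty_candidates <- function() {
  data.frame(width = integer(), event = character(), triplet = character(),
             pos1 = integer(), pos2 = integer(), gap1 = integer(),
             gap2 = integer(), ins1 = character(), ins2 = character(),
             penalty = numeric(), stringsAsFactors = FALSE)
}

cand_row <- function(width, event, triplet, penalty, pos1 = NA_integer_,
                     pos2 = NA_integer_, gap1 = NA_integer_,
                     gap2 = NA_integer_, ins1 = NA_character_,
                     ins2 = NA_character_) {
  data.frame(width = width, event = event, triplet = triplet, pos1 = pos1,
             pos2 = pos2, gap1 = gap1, gap2 = gap2, ins1 = ins1, ins2 = ins2,
             penalty = penalty, stringsAsFactors = FALSE)
}

#' Enumerate frame-shifting candidates for one window
#'
#' Lists every way of matching the window of `width` query nucleotides
#' ending at 0-based position `at` to a single amino acid, together with the
#' frame-shift penalty of each: 4 single deletions for width 4, 10 double
#' deletions for width 5 (4 grouped adjacent priced from D, 6 split priced
#' from 2S), up to 12 single-insertion and 48 double-insertion combinations
#' for widths 2 and 1.  With insertion validation (`params$V`) the inserted
#' nucleotides are restricted to [valid_insertions()] at each gap.
#'
#' @param read a [flow_read()] (or plain sequence string).
#' @param at 0-based index of the last window base.
#' @param width window width, one of 1, 2, 4, 5.
#' @param params an [align_params()] object.
#' @return a data.frame of candidates in tie-break preference order with
#'   columns `width`, `event`, `triplet`, deleted positions `pos1`/`pos2`
#'   (0-based), insertion gaps `gap1`/`gap2`, inserted nucleotides
#'   `ins1`/`ins2`, and `penalty`.
#' @export
fs_candidates <- function(read, at, width, params) {
  read <- as_window_read(read)
  L <- length(read$seq_codes)
  stopifnot(width %in% c(1L, 2L, 4L, 5L), at >= width - 1L, at < L)
  if (width > 3L) {
    fs_del_candidates(read, at, width, params)
  } else {
    fs_ins_candidates(read, at, width, params)
  }
}

fs_del_candidates <- function(read, at, width, params) {
  s <- at - width + 1L
  win <- read$seq_codes[(s:at) + 1L]
  chars <- strsplit(read$sequence, "", fixed = TRUE)[[1]]
  out <- list()
  if (width == 4L) {
    for (t in s:(s + 3L)) {
      keep <- setdiff(s:at, t)
      pen <- frameshift_penalty(params$S, params$h,
                                del_factor(read, t, params))
      out[[length(out) + 1L]] <- cand_row(
        4L, "del1", paste(chars[keep + 1L], collapse = ""), pen, pos1 = t)
    }
  } else {
    for (t in s:(s + 3L)) {  # grouped adjacent pairs, leftmost first
      keep <- setdiff(s:at, c(t, t + 1L))
      f <- if (read$run_id[t + 1L] == read$run_id[t + 2L]) {
        del_factor(read, t, params, m_off = 2L)
      } else 0
      pen <- frameshift_penalty(params$D, params$h, f)
      out[[length(out) + 1L]] <- cand_row(
        5L, "del2g", paste(chars[keep + 1L], collapse = ""), pen,
        pos1 = t, pos2 = t + 1L)
    }
    for (t1 in s:(s + 2L)) {  # split pairs (two separate single deletions)
      for (t2 in seq(t1 + 2L, s + 4L)) {
        keep <- setdiff(s:at, c(t1, t2))
        pen <- frameshift_penalty(params$S, params$h,
                                  del_factor(read, t1, params)) +
               frameshift_penalty(params$S, params$h,
                                  del_factor(read, t2, params))
        out[[length(out) + 1L]] <- cand_row(
          5L, "del2s", paste(chars[keep + 1L], collapse = ""), pen,
          pos1 = t1, pos2 = t2)
      }
    }

  }
  do.call(rbind, out)
}

ALPHA_NT <- c("A", "C", "G", "T")  # alphabetical tie-break order

fs_ins_candidates <- function(read, at, width, params) {
  ctx <- build_ins_context(read)
  validate <- isTRUE(params$V) && params$mode != "neutral"
  chars <- strsplit(read$sequence, "", fixed = TRUE)[[1]]
  out <- list()
  single_pen <- function(g, a) {
    frameshift_penalty(params$S, params$h, ins_factor(ctx, g, a, params))
  }
  if (width == 2L) {
    s <- at - 1L
    for (g in s:(s + 2L)) {
      for (al in ALPHA_NT) {
        a <- nt_encode(al)
        if (validate && !ctx$allowed[a + 1L, g + 1L]) next
        trip <- switch(as.character(g - s),
          "0" = c(al, chars[s + 1L], chars[at + 1L]),
          "1" = c(chars[s + 1L], al, chars[at + 1L]),
          "2" = c(chars[s + 1L], chars[at + 1L], al))
        out[[length(out) + 1L]] <- cand_row(
          2L, "ins1", paste(trip, collapse = ""), single_pen(g, a),
          gap1 = g, ins1 = al)
      }
    }
  } else {  # width 1: double insertion around base `at`
    s <- at
    for (g in s:(s + 1L)) {  # grouped: both nucleotides at one gap
      for (al1 in ALPHA_NT) for (al2 in ALPHA_NT) {
        a1 <- nt_encode(al1); a2 <- nt_encode(al2)
        if (validate && (!ctx$allowed[a1 + 1L, g + 1L] ||
                         !ctx$allowed[a2 + 1L, g + 1L])) next
        f <- if (al1 == al2) ins_factor(ctx, g, a1, params, count = 2L) else 0
        pen <- frameshift_penalty(params$D, params$h, f)
        trip <- if (g == s) c(al1, al2, chars[s + 1L]) else
                            c(chars[s + 1L], al1, al2)
        out[[length(out) + 1L]] <- cand_row(
          1L, "ins2g", paste(trip, collapse = ""), pen,
          gap1 = g, gap2 = g, ins1 = al1, ins2 = al2)
      }
    }
    for (al1 in ALPHA_NT) for (al2 in ALPHA_NT) {  # split: one each side
      a1 <- nt_encode(al1); a2 <- nt_encode(al2)
      if (validate && (!ctx$allowed[a1 + 1L, s + 1L] ||
                       !ctx$allowed[a2 + 1L, s + 2L])) next
      pen <- single_pen(s, a1) + single_pen(s + 1L, a2)
      out[[length(out) + 1L]] <- cand_row(
        1L, "ins2s", paste(c(al1, chars[s + 1L], al2), collapse = ""), pen,
        gap1 = s, gap2 = s + 1L, ins1 = al1, ins2 = al2)
    }
  }
  if (!length(out)) return(empty_candidates())
  do.call(rbind, out)
}

#' Enumerate single or double deletions over a window
#'
#' @param window a 4-nucleotide (single deletion) or 5-nucleotide (double
#'   deletion) string or [flow_read()].
#' @param params an [align_params()]; defaults to the neutral model.
#' @return candidate data.frame, see [fs_candidates()].
#' @examples
#' enumerate_deletions("AACG")$triplet  # "ACG" "ACG" "AAG" "AAC"
#' @export
enumerate_deletions <- function(window, params = align_params("neutral")) {
  read <- as_window_read(window)
  w <- length(read$seq_codes)
  if (!w %in% c(4L, 5L)) stop("deletion window must be 4 or 5 nucleotides",
                              call. = FALSE)
  fs_candidates(read, w - 1L, w, params)
}

#' Enumerate single or double insertions over a window
#'
#' @param window a 2-nucleotide (single insertion) or 1-nucleotide (double
#'   insertion) string or [flow_read()].
#' @param params an [align_params()]; defaults to the neutral model.
#' @return candidate data.frame, see [fs_candidates()].
#' @export
enumerate_insertions <- function(window, params = align_params("neutral")) {
  read <- as_window_read(window)
  w <- length(read$seq_codes)
  if (!w %in% c(1L, 2L)) stop("insertion window must be 1 or 2 nucleotides",
                              call. = FALSE)
  fs_candidates(read, w - 1L, w, params)
}
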