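# Alignment driver, result object, statistics and text rendering.

check_protein <- function(protein) {
  if (inherits(protein, "AAString") || inherits(protein, "AAStringSet")) {
    protein <- as.character(protein)[1]
  }
  stopifnot(is.character(protein), length(protein) == 1L)
  protein <- toupper(protein)
  protein <- sub("\\*+$", "", protein)  # tolerate trailing stop
  if (nchar(protein) < 1L) stop("protein must have length >= 1", call. = FALSE)
  if (grepl("[^A-Z]", protein)) {
    stop("invalid character in protein sequence", call. = FALSE)
  }
  protein
}

#' Align a nucleotide read against a protein sequence
#'
#' Optimal local alignment under the frame-shift-capable
#' Smith-Waterman-Gotoh model: one amino acid may consume 1, 2, 3, 4 or 5
#' query nucleotides (the non-3 widths opening frame-shift gaps priced by
#' the position-specific homopolymer penalty model), alongside ordinary
#' affine protein-space gaps.  Traceback starts at the global maximum cell;
#' when no cell scores above zero the empty alignment (score 0) is
#' returned.
#'
#' @param query a [flow_read()], nucleotide string, or a pre-built
#'   [build_profile()] (which fixes read and parameters).
#' @param protein amino-acid string (or `AAString`).
#' @param params an [align_params()]; defaults to `"flow454"` when the read
#'   carries a flowgram, else `"fasta454"`.
#' @param target_id label for the protein sequence.
#' @return an object of class `fs_alignment`: score, 0-based half-open
#'   query/protein ranges, per-column `steps`, frame-shift `events`, and
#'   alignment statistics.
#' @examples
#' r <- align_read("ATGAAA", "MK", align_params("neutral"))
#' r$score  # 10
#' @export
align_read <- function(query, protein, params = NULL, target_id = "target") {
  if (inherits(query, "query_profile")) {
    profile <- query
  } else {
    read <- as_window_read(query)
    if (is.null(params)) {
      params <- align_params(
        if (!is.null(read$flow_values)) "flow454" else "fasta454")
    }
    profile <- build_profile(read, params)
  }
  params <- profile$params
  protein <- check_protein(protein)
  pcodes <- aa_encode(protein)
  raw <- cpp_align(profile$m, profile$ctx, encode_par(params),
                   unclass(params$matrix), pcodes)
  build_result(raw, profile, protein, target_id)
}

build_result <- function(raw, profile, protein, target_id) {
  steps <- raw$steps
  pcodes <- aa_encode(protein)
  mat <- unclass(profile$params$matrix)
  ncols <- nrow(steps)
  ident <- pos <- 0L
  if (ncols) {
    is_match <- steps[, "kind"] == 0
    mi <- which(is_match)
    trans <- codon_aa_table()[steps[mi, "t1"] * 25 + steps[mi, "t2"] * 5 +
                                steps[mi, "t3"] + 1L]
    aa <- pcodes[steps[mi, "i"]]
    stopi <- match("*", AA_ALPHABET) - 1L
    sc <- ifelse(trans == stopi, STOP_SCORE,
                 mat[cbind(aa + 1L, trans + 1L)])
    ident <- sum(aa == trans & trans != stopi)
    pos <- sum(sc > 0)
  }
  events <- extract_events(steps)
  ngaps <- if (nrow(events)) {
    sum(ifelse(events$type %in% c("del2s", "ins2s"), 2L, 1L))
  } else 0L
  gapcols <- if (ncols) sum(steps[, "kind"] != 0) else 0L
  Lq <- length(profile$read$seq_codes)
  structure(list(
    query_id = profile$read$id,
    target_id = target_id,
    score = raw$score,
    q_range = c(raw$j_start, raw$j_end),
    p_range = c(raw$i_start, raw$i_end),
    steps = steps,
    events = events,
    ncols = ncols,
    identities = ident,
    positives = pos,
    gaps = gapcols,
    ngaps = ngaps,
    query_len = Lq,
    protein_len = nchar(protein),
    coverage = (raw$j_end - raw$j_start) / Lq,
    read = profile$read,
    protein = protein,
    params = profile$params
  ), class = "fs_alignment")
}

EVENT_NAMES <- c("del1", "del2g", "del2s", "ins1", "ins2g", "ins2s")

extract_events <- function(steps) {
  empty <- data.frame(step = integer(), type = character(),
                      pos1 = integer(), pos2 = integer(),
                      gap1 = integer(), gap2 = integer(),
                      nt1 = character(), nt2 = character(),
                      penalty = numeric(), stringsAsFactors = FALSE)
  if (!nrow(steps)) return(empty)
  ev <- which(steps[, "kind"] == 0 & steps[, "event"] > 0)
  if (!length(ev)) return(empty)
  ntc <- function(x) ifelse(x < 0, NA_character_, c(NT_ALPHABET, "N")[x + 1])
  iv <- function(x) ifelse(x < 0, NA_integer_, as.integer(x))
  data.frame(step = ev,
             type = EVENT_NAMES[steps[ev, "event"]],
             pos1 = iv(steps[ev, "pos1"]), pos2 = iv(steps[ev, "pos2"]),
             gap1 = iv(steps[ev, "gap1"]), gap2 = iv(steps[ev, "gap2"]),
             nt1 = ntc(steps[ev, "nt1"]), nt2 = ntc(steps[ev, "nt2"]),
             penalty = steps[ev, "penalty"], stringsAsFactors = FALSE)
}

# Atomic indels of an alignment: one row per deleted base (type "del",
# 0-based read position) or inserted nucleotide (type "ins", 0-based gap).
#' @export
alignment_indels <- function(result) {
  ev <- result$events
  out <- data.frame(type = character(), pos = integer(), nt = character(),
                    stringsAsFactors = FALSE)
  if (!nrow(ev)) return(out)
  seqc <- strsplit(result$read$sequence, "", fixed = TRUE)[[1]]
  rows <- list()
  for (r in seq_len(nrow(ev))) {
    e <- ev[r, ]
    if (startsWith(e$type, "del")) {
      ps <- c(e$pos1, e$pos2)
      ps <- ps[!is.na(ps)]
      for (p in ps) rows[[length(rows) + 1L]] <-
        data.frame(type = "del", pos = p, nt = seqc[p + 1L],
                   stringsAsFactors = FALSE)
    } else {
      gs <- c(e$gap1, e$gap2)
      ns <- c(e$nt1, e$nt2)
      keep <- !is.na(ns)
      for (q in which(keep)) rows[[length(rows) + 1L]] <-
        data.frame(type = "ins", pos = gs[q], nt = ns[q],
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Recompute the alignment score from the traceback steps (independent of
# the DP matrices): sum of match-column scores minus gap costs.
rescore_alignment <- function(result) {
  steps <- result$steps
  if (!nrow(steps)) return(0)
  pcodes <- aa_encode(result$protein)
  mat <- unclass(result$params$matrix)
  stopi <- match("*", AA_ALPHABET) - 1L
  total <- 0
  for (r in seq_len(nrow(steps))) {
    k <- steps[r, "kind"]
    if (k == 0) {
      trans <- codon_aa_table()[steps[r, "t1"] * 25 + steps[r, "t2"] * 5 +
                                  steps[r, "t3"] + 1L]
      aa <- pcodes[steps[r, "i"]]
      m3 <- if (trans == stopi) STOP_SCORE else mat[aa + 1L, trans + 1L]
      total <- total + m3 - steps[r, "penalty"]
    } else {
      total <- total - if (steps[r, "spare"] == 1) result$params$G0 else
        result$params$Ge
    }
  }
  unname(total)
}

pct_fmt <- function(x, y) {
  sprintf("%d/%d (%d%%)", x, y, if (y > 0) round(100 * x / y) else 0L)
}

#' Alignment statistics
#'
#' Identities (columns whose translated codon equals the protein residue),
#' positives (columns with a positive substitution score), protein-space gap
#' columns, frame-shift gap count (`nGaps`) and query coverage, with the
#' conventional `"x/y (z%)"` renderings.
#'
#' @param result an [align_read()] result.
#' @return a list of counts and formatted strings.
#' @export
alignment_stats <- function(result) {
  stopifnot(inherits(result, "fs_alignment"))
  qa <- result$q_range[2] - result$q_range[1]
  list(score = result$score,
       identities = result$identities,
       positives = result$positives,
       columns = result$ncols,
       gaps = result$gaps,
       ngaps = result$ngaps,
       coverage = result$coverage,
       identities_fmt = pct_fmt(result$identities, result$ncols),
       positives_fmt = pct_fmt(result$positives, result$ncols),
       coverage_fmt = pct_fmt(qa, result$query_len))
}

#' @export
print.fs_alignment <- function(x, ...) {
  cat(format_alignment(x), sep = "\n")
  invisible(x)
}

#' Render an alignment as text
#'
#' Three-row blocks (query nucleotides, match line, protein residues) under
#' a header with score and statistics.  Frame-shift positions are lowercase
#' in the query row: inserted nucleotides are the maximum-likelihood
#' prediction substituted into the codon, deleted nucleotides sit above a
#' `-` in the protein row.  Output is deterministic and byte-exact for a
#' fixed input.
#'
#' @param result an [align_read()] result.
#' @param block_width characters of alignment per block.
#' @return character vector of lines.
#' @export
format_alignment <- function(result, block_width = 60) {
  st <- alignment_stats(result)
  hdr <- c(
    sprintf("Query: %s (%d nt)", result$query_id, result$query_len),
    sprintf("Target: %s (%d aa)", result$target_id, result$protein_len),
    sprintf("Score: %.6g  Identities: %s  Positives: %s",
            st$score, st$identities_fmt, st$positives_fmt),
    sprintf("Coverage: %s  Gaps: %d  nGaps: %d",
            st$coverage_fmt, st$gaps, st$ngaps))
  if (!result$ncols) return(c(hdr, "", "(no alignment)"))
  rows <- render_columns(result)
  lines <- character(0)
  n <- nchar(rows$q)
  qc <- rows$qcoord
  pc <- rows$pcoord
  for (s in seq(1, n, by = block_width)) {
    e <- min(s + block_width - 1L, n)
    lines <- c(lines,
      sprintf("Query  %6d %s", qc[s], substr(rows$q, s, e)),
      sprintf("       %6s %s", "", substr(rows$m, s, e)),
      sprintf("Target %6d %s", pc[s], substr(rows$p, s, e)),
      "")
  }
  c(hdr, "", lines)
}

render_columns <- function(result) {
  steps <- result$steps
  seqc <- strsplit(result$read$sequence, "", fixed = TRUE)[[1]]
  prot <- strsplit(result$protein, "", fixed = TRUE)[[1]]
  pcodes <- aa_encode(result$protein)
  mat <- unclass(result$params$matrix)
  stopi <- match("*", AA_ALPHABET) - 1L
  q <- m <- p <- character(0)
  qcoord <- pcoord <- integer(0)
  qpos <- result$q_range[1]  # 0-based nts consumed so far
  for (r in seq_len(nrow(steps))) {
    k <- steps[r, "kind"]
    i <- steps[r, "i"]
    if (k == 1) {        # protein-consuming gap
      qch <- c("-", "-", "-")
      pch <- c(" ", prot[i], " ")
      mch <- c(" ", " ", " ")
      consumed <- 0L
    } else if (k == 2) { # codon-consuming gap
      qch <- seqc[qpos + 1:3]
      pch <- c("-", "-", "-")
      mch <- c(" ", " ", " ")
      consumed <- 3L
    } else {
      w <- steps[r, "w"]
      trans <- codon_aa_table()[steps[r, "t1"] * 25 + steps[r, "t2"] * 5 +
                                  steps[r, "t3"] + 1L]
      aa <- pcodes[i]
      msc <- if (trans == stopi) STOP_SCORE else mat[aa + 1L, trans + 1L]
      mc <- if (aa == trans && trans != stopi) "|" else {
        if (msc > 0) "+" else " "
      }
      if (w >= 4) {
        win <- seqc[qpos + seq_len(w)]
        del <- c(steps[r, "pos1"], steps[r, "pos2"])
        del <- del[del >= 0] - qpos + 1L
        win[del] <- tolower(win[del])
        kept <- setdiff(seq_len(w), del)
        pch <- rep(" ", w)
        pch[del] <- "-"
        pch[kept[2]] <- prot[i]
        mch <- rep(" ", w)
        mch[kept[2]] <- mc
        qch <- win
      } else {
        trip <- c(NT_ALPHABET, "N")[c(steps[r, "t1"], steps[r, "t2"],
                                      steps[r, "t3"]) + 1L]
        s0 <- qpos  # 0-based first consumed base = j - w
        low <- integer(0)
        ev <- steps[r, "event"]
        if (w == 3) {
          low <- integer(0)
        } else if (ev == 4) {          # single insertion
          low <- steps[r, "gap1"] - s0 + 1L
        } else if (ev == 5) {          # grouped double insertion
          low <- if (steps[r, "gap1"] == s0) c(1L, 2L) else c(2L, 3L)
        } else if (ev == 6) {          # split double insertion
          low <- c(1L, 3L)
        }
        trip[low] <- tolower(trip[low])
        qch <- trip
        pch <- c(" ", prot[i], " ")
        mch <- c(" ", mc, " ")
      }
      consumed <- w
    }
    qcoord <- c(qcoord, rep(qpos + 1L, length(qch)))
    pcoord <- c(pcoord, rep(max(i, 1L), length(qch)))
    q <- c(q, qch)
    m <- c(m, mch)
    p <- c(p, pch)
    qpos <- qpos + consumed
  }
  list(q = paste(q, collapse = ""), m = paste(m, collapse = ""),
       p = paste(p, collapse = ""), qcoord = qcoord, pcoord = pcoord)
}

#' Parse the header of a rendered alignment
#'
#' Inverse of the [format_alignment()] header: recovers score, identities,
#' positives, coverage, gap and frame-shift counts.
#'
#' @param lines character vector as returned by [format_alignment()].
#' @return a list of the header statistics.
#' @export
parse_alignment_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  gx <- function(pat) {
    m <- regmatches(txt, regexec(pat, txt, perl = TRUE))[[1]]
    if (length(m) < 2L) stop("header field not found: ", pat, call. = FALSE)
    m[-1]
  }
  frac <- function(v) list(x = as.numeric(v[1]), y = as.numeric(v[2]))
  list(score = as.numeric(gx("Score: ([-0-9.e+]+)")),
       identities = frac(gx("Identities: ([0-9]+)/([0-9]+)")),
       positives = frac(gx("Positives: ([0-9]+)/([0-9]+)")),
       coverage = frac(gx("Coverage: ([0-9]+)/([0-9]+)")),
       gaps = as.numeric(gx("Gaps: ([0-9]+)")),
       ngaps = as.numeric(gx("nGaps: ([0-9]+)")))
}
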