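# Flow-space read model.
#
# A flow_read carries, per base: the flowpeak p of the homopolymer run the
# base belongs to, the run length n, and (when flow data exist) the index of
# the flow that called the base.  Gap positions are 0-based throughout:
# gap g lies between base g and base g+1 (1-based R indexing of the
# sequence), so g = 0 is the read start and g = nchar(sequence) the end.

#' Construct a flow-space read
#'
#' @param sequence called nucleotide sequence (T/A/C/G/N).
#' @param id read identifier.
#' @param flowpeaks optional per-base flowpeak values (every base of a run
#'   shares the run's peak); defaults to the run length (FASTA convention).
#' @param flow_order repeating nucleotide flow cycle (default `"TACG"`).
#' @param flow_values optional full flowgram (all flows, zero flows
#'   included), signal units.
#' @param flow_index optional 0-based per-base index into `flow_values`
#'   (non-decreasing); reconstructed by simulating `flow_order` over the
#'   sequence when absent.
#' @return an object of class `flow_read` with per-base annotation columns
#'   `flowpeaks`, `run_length`, `run_id`, `run_end`, `flow_index`.
#' @examples
#' r <- flow_read("TTTAA")
#' r$flowpeaks   # 3 3 3 2 2
#' @export
flow_read <- function(sequence, id = "read", flowpeaks = NULL,
                      flow_order = "TACG", flow_values = NULL,
                      flow_index = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string", call. = FALSE)
  }
  codes <- nt_encode(sequence)
  L <- length(codes)
  runs <- run_decompose(codes)
  if (is.null(flowpeaks)) {
    flowpeaks <- runs$length
  } else {
    if (length(flowpeaks) != L) {
      stop("flowpeaks must have one value per base", call. = FALSE)
    }
    if (any(!is.finite(flowpeaks)) || any(flowpeaks < 0)) {
      stop("flowpeaks must be finite and >= 0", call. = FALSE)
    }
  }
  if (is.null(flow_index)) {
    flow_index <- simulate_flow_index(codes, flow_order)
  } else if (length(flow_index) != L || is.unsorted(flow_index)) {
    stop("flow_index must be a non-decreasing per-base vector", call. = FALSE)
  }
  structure(list(
    id = as.character(id),
    sequence = toupper(sequence),
    seq_codes = codes,
    flowpeaks = as.numeric(flowpeaks),
    run_length = runs$length,
    run_id = runs$id,
    run_end = runs$end,
    flow_order = toupper(flow_order),
    flow_values = flow_values,
    flow_index = as.integer(flow_index)
  ), class = "flow_read")
}

# Maximal-run decomposition: per-base run id, run length, end-of-run flag.
run_decompose <- function(codes) {
  L <- length(codes)
  new_run <- c(TRUE, codes[-1] != codes[-L])
  id <- cumsum(new_run)
  len <- as.integer(ave(codes, id, FUN = length))
  end <- c(id[-1] != id[-L], TRUE)
  list(id = as.integer(id), length = len, end = end)
}

# 0-based flow index per base obtained by walking the repeating flow order
# over the called sequence.  N bases consume a flow of their own (treated as
# matching no reagent; the walk simply advances one cycle position).
simulate_flow_index <- function(codes, flow_order = "TACG") {
  ord <- nt_encode(flow_order)
  cl <- length(ord)
  idx <- integer(length(codes))
  cur <- 0L  # next flow to consider
  prev <- -1L
  for (b in seq_along(codes)) {
    nt <- codes[b]
    if (b > 1L && nt == codes[b - 1L]) {
      idx[b] <- idx[b - 1L]
      next
    }
    repeat {
      if (ord[(cur %% cl) + 1L] == nt || nt == 4L) break
      cur <- cur + 1L
    }
    idx[b] <- cur
    cur <- cur + 1L
  }
  idx
}

#' Annotate a plain nucleotide sequence as a flow-space read
#'
#' For FASTA input no flowpeaks are available; the flowpeak of every base is
#' set equal to its homopolymer run length, which makes the deviation model
#' symmetric around integer peaks (insertion and deletion penalties
#' coincide).
#'
#' @param sequence nucleotide string.
#' @param id read identifier.
#' @return a [flow_read()] with `flowpeaks == run_length` and no flowgram.
#' @export
annotate_fasta <- function(sequence, id = "read") {
  flow_read(sequence, id = id)
}

flow_nt <- function(read, t) {
  ord <- nt_encode(read$flow_order)
  ord[(t %% length(ord)) + 1L]
}

#' Nucleotides insertable at a gap position
#'
#' Flow-order insertion validation: an insert between two bases is plausible
#' only if its reagent was flowed between the two bases' flows (a missed
#' weak peak), or if it extends one of the flanking homopolymer runs.  Read
#' ends permit all four nucleotides.
#'
#' @param read a [flow_read()].
#' @param gap_position 0-based gap index in `0..nchar(sequence)`.
#' @return character vector of permitted nucleotides.
#' @examples
#' r <- flow_read("TTTCCC")
#' valid_insertions(r, 3)  # T, A, C -- no G flowed between the T and C peaks
#' @export
valid_insertions <- function(read, gap_position) {
  L <- length(read$seq_codes)
  stopifnot(gap_position >= 0, gap_position <= L)
  if (gap_position == 0L || gap_position == L) return(NT_ALPHABET)
  fi_l <- read$flow_index[gap_position]
  fi_r <- read$flow_index[gap_position + 1L]
  ok <- logical(4)
  left_nt <- read$seq_codes[gap_position]
  right_nt <- read$seq_codes[gap_position + 1L]
  if (left_nt < 4L) ok[left_nt + 1L] <- TRUE
  if (right_nt < 4L) ok[right_nt + 1L] <- TRUE
  ts <- seq_len(max(fi_r - fi_l - 1L, 0L)) + fi_l  # flows strictly between
  for (t in ts) {
    nt <- flow_nt(read, t)
    if (nt < 4L) ok[nt + 1L] <- TRUE
  }
  NT_ALPHABET[ok]
}

#' Flowpeak of the zero-flow backing an insertion
#'
#' When flow data are present, an insertion of `nucleotide` at a gap is
#' priced by the (zero-call) flowpeak of that nucleotide's flow between the
#' flanking bases' flows.  Returns `NA` when no such flow exists or when the
#' read carries no flowgram (FASTA input).
#'
#' @inheritParams valid_insertions
#' @param nucleotide single nucleotide character.
#' @return flowpeak value, or `NA_real_`.
#' @export
insertion_flowpeak <- function(read, gap_position, nucleotide) {
  if (is.null(read$flow_values)) return(NA_real_)
  L <- length(read$seq_codes)
  stopifnot(gap_position >= 0, gap_position <= L)
  nt <- nt_encode(nucleotide)
  nflow <- length(read$flow_values)
  lo <- if (gap_position == 0L) -1L else read$flow_index[gap_position]
  hi <- if (gap_position == L) nflow else read$flow_index[gap_position + 1L]
  ts <- seq_len(max(hi - lo - 1L, 0L)) + lo  # flows in (lo, hi)
  ts <- ts[ts >= 0L & ts < nflow]
  hits <- ts[vapply(ts, function(t) flow_nt(read, t) == nt, logical(1))]
  if (!length(hits)) return(NA_real_)
  # closest flow to the gap (relevant at read ends, unique internally)
  t <- if (gap_position == 0L) max(hits) else min(hits)
  read$flow_values[t + 1L]
}

# Per-gap, per-nucleotide insertion context consumed by the profile builder
# and the candidate enumerator:
#   kind 0 = no homopolymer support (full penalty),
#   kind 1 = extends a flanking run (p, n = that run's peak and length),
#   kind 2 = backed by a zero flow (p = its value, n = 0).
# allowed = flow-order validation verdict (applied only when V is on).
build_ins_context <- function(read) {
  pre <- attr(read, "ins_context")
  if (!is.null(pre)) return(pre)
  L <- length(read$seq_codes)
  kind <- matrix(0L, 4, L + 1L)
  ctx_p <- matrix(0, 4, L + 1L)
  ctx_n <- matrix(0L, 4, L + 1L)
  allowed <- matrix(FALSE, 4, L + 1L)
  for (g in 0:L) {
    allowed[match(valid_insertions(read, g), NT_ALPHABET), g + 1L] <- TRUE
    for (a in 0:3) {
      ext <- 0L
      if (g > 0L && read$seq_codes[g] == a) ext <- g
      if (g < L && read$seq_codes[g + 1L] == a) ext <- g + 1L
      if (ext > 0L) {
        kind[a + 1L, g + 1L] <- 1L
        ctx_p[a + 1L, g + 1L] <- read$flowpeaks[ext]
        ctx_n[a + 1L, g + 1L] <- read$run_length[ext]
      } else if (!is.null(read$flow_values)) {
        p0 <- insertion_flowpeak(read, g, NT_ALPHABET[a + 1L])
        if (!is.na(p0)) {
          kind[a + 1L, g + 1L] <- 2L
          ctx_p[a + 1L, g + 1L] <- p0
        }
      }
    }
  }
  list(kind = kind, p = ctx_p, n = ctx_n, allowed = allowed)
}

#' Reverse-complement a flow-space read
#'
#' The per-base annotation (flowpeaks, run structure) is reversed and
#' complemented; flow-derived insertion contexts are transformed from the
#' forward read so that flow-order validation and zero-flow pricing remain
#' those measured on the sequenced strand.
#'
#' @param read a [flow_read()].
#' @return a `flow_read` for the opposite strand.
#' @export
rc_flow_read <- function(read) {
  comp <- c(1L, 0L, 3L, 2L, 4L)  # T<->A, C<->G, N->N
  codes <- rev(comp[read$seq_codes + 1L])
  rc <- flow_read(nt_decode(codes), id = read$id,
                  flowpeaks = rev(read$flowpeaks),
                  flow_order = read$flow_order)
  fwd <- build_ins_context(read)
  L <- length(codes)
  tr <- function(m) m[comp[1:4] + 1L, (L:0) + 1L, drop = FALSE]
  attr(rc, "ins_context") <- list(kind = tr(fwd$kind), p = tr(fwd$p),
                                  n = tr(fwd$n), allowed = tr(fwd$allowed))
  rc
}

#' @export
print.flow_read <- function(x, ...) {
  cat(sprintf("flow_read '%s': %d nt%s\n", x$id, length(x$seq_codes),
              if (is.null(x$flow_values)) "" else
                sprintf(", %d flows (order %s)", length(x$flow_values),
                        x$flow_order)))
  invisible(x)
}
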