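# Position-specific frame-shift penalty model.
#
# A homopolymer called as an n-mer from flowpeak p can be re-called as an
# m-mer (|m - n| <= 2).  The relative flowpeak deviation that re-call
# requires, scaled by 1/k and the homopolymer length, reduces the base
# frame-shift penalty P0 down to (at most) P0 * h.

#' Flowpeak deviation required to call an n-mer as an m-mer
#'
#' Piecewise distance between the observed flowpeak and the nearest signal
#' value that would have been called as `m`: `p - (m + 0.5)` for an
#' undercall re-call (`m < n`), `(m - 0.5) - p` for an overcall re-call
#' (`m > n`), and 0 for `m == n`.  Clamped at 0 so boundary flowpeaks never
#' go negative.
#'
#' @param p observed flowpeak (signal units, 1.0 = one incorporation).
#' @param n called homopolymer length (the rounding of `p`).
#' @param m alternative length, with `abs(m - n) <= 2`.
#' @return non-negative deviation, vectorised over the inputs.
#' @examples
#' deviation(0.49, 0, 1)  # 0.01
#' deviation(1.50, 2, 1)  # 0
#' deviation(1.50, 2, 3)  # 1
#' @export
deviation <- function(p, n, m) {
  stopifnot(all(p >= 0), all(abs(m - n) <= 2))
  len <- max(length(p), length(n), length(m))
  p <- rep_len(p, len)
  n <- rep_len(n, len)
  m <- rep_len(m, len)
  dev <- ifelse(m < n, p - (m + 0.5), ifelse(m > n, (m - 0.5) - p, 0))
  pmax(dev, 0)
}

#' Penalty reduction factor
#'
#' `f = 1 - deviation(p, n, m) / (k * max(n, 1))`, clamped to `[0, 1]`.
#' `f = 1` means the re-call is fully supported by the flowpeak (maximal
#' penalty reduction); `f = 0` applies the full frame-shift penalty.  The
#' `k` parameter is therefore the relative deviation at which the full
#' penalty is reached.
#'
#' @inheritParams deviation
#' @param k deviation scale, > 0.
#' @return factor in `[0, 1]`, vectorised.
#' @export
penalty_factor <- function(p, n, m, k) {
  if (any(k <= 0)) stop("k must be > 0", call. = FALSE)
  f <- 1 - deviation(p, n, m) / (k * pmax(n, 1))
  pmin(pmax(f, 0), 1)
}

#' Frame-shift penalty after homopolymer reduction
#'
#' `P = P0 - P0 * (1 - h) * f`: the full penalty `P0` at `f = 0`, shrinking
#' linearly to the floor `P0 * h` at `f = 1`.
#'
#' @param P0 base single (S) or double (D) frame-shift penalty, >= 0.
#' @param h penalty floor fraction in (0, 1].
#' @param f reduction factor in `[0, 1]` from [penalty_factor()].
#' @return penalty in `[P0 * h, P0]`, vectorised.
#' @export
frameshift_penalty <- function(P0, h, f) {
  stopifnot(all(P0 >= 0), all(h > 0), all(h <= 1), all(f >= -1e-12),
            all(f <= 1 + 1e-12))
  P0 - P0 * (1 - h) * pmin(pmax(f, 0), 1)
}

#' Alignment parameter set
#'
#' Bundles every tunable of the alignment model.  The three modes select
#' both defaults and behaviour: `"neutral"` is a frame-shift-capable but
#' homopolymer-blind model (constant penalties, validation off),
#' `"fasta454"` applies the homopolymer model with flowpeaks equal to the
#' called run lengths, `"flow454"` uses measured flowpeaks from SFF input.
#'
#' @param mode one of `"flow454"`, `"fasta454"`, `"neutral"`.
#' @param S single frame-shift gap penalty (>= 0).
#' @param D grouped double frame-shift gap penalty (>= 0, `D <= 2 * S`).
#' @param h homopolymer penalty floor fraction in (0, 1].
#' @param k flowpeak deviation scale (> 0).
#' @param V logical, flow-order insertion validation.
#' @param G0 protein-space minimum (open) gap penalty.
#' @param Ge protein-space gap extension penalty.
#' @param matrix a [substitution_matrix()].
#' @param validate check the parameter constraints (see
#'   [validate_params()]).
#' @return an `align_params` list.
#' @examples
#' align_params("flow454")  # S=20 D=40 h=0.3 k=0.4 V=TRUE
#' @export
align_params <- function(mode = c("flow454", "fasta454", "neutral"),
                         S = NULL, D = NULL, h = NULL, k = NULL, V = NULL,
                         G0 = 8, Ge = 2, matrix = substitution_matrix(),
                         validate = TRUE) {
  mode <- match.arg(mode)
  def <- switch(mode,
    flow454  = list(S = 20, D = 40, h = 0.3, k = 0.4, V = TRUE),
    fasta454 = list(S = 12, D = 24, h = 0.5, k = 0.6, V = FALSE),
    neutral  = list(S = 8,  D = 15, h = 1.0, k = 1.0, V = FALSE))
  p <- structure(list(
    mode = mode,
    S = if (is.null(S)) def$S else S,
    D = if (is.null(D)) def$D else D,
    h = if (is.null(h)) def$h else h,
    k = if (is.null(k)) def$k else k,
    V = if (is.null(V)) def$V else V,
    G0 = G0, Ge = Ge, matrix = matrix), class = "align_params")
  if (validate) validate_params(p)
  p
}

#' Validate an alignment parameter set
#'
#' Rejects penalty combinations under which the model degenerates: a grouped
#' double gap must never cost more than two single gaps (`D <= 2 * S`,
#' otherwise two singles would always be favoured), and the cheapest
#' single-plus-double frame-shift correction must stay above the
#' protein-space gap open penalty (`S * h + D * h > G0`, otherwise protein
#' gaps would be substituted by homopolymer corrections).
#'
#' @param params an [align_params()] object.
#' @return `params`, invisibly, when valid; otherwise an error naming the
#'   violated constraint.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "align_params"))
  with(params, {
    if (S < 0 || D < 0) stop("S and D must be >= 0", call. = FALSE)
    if (h <= 0 || h > 1) stop("h must lie in (0, 1]", call. = FALSE)
    if (k <= 0) stop("k must be > 0", call. = FALSE)
    if (Ge < 0 || G0 < Ge) stop("need G0 >= Ge >= 0", call. = FALSE)
    if (D > 2 * S) {
      stop("invalid penalties: D > 2*S -- two single frame-shift gaps ",
           "would be favoured over every grouped double", call. = FALSE)
    }
    if (S * h + D * h <= G0) {
      stop("invalid penalties: S*h + D*h <= G0 -- frame-shift corrections ",
           "must cost more than opening a protein-space gap", call. = FALSE)
    }
  })
  invisible(params)
}

#' @export
print.align_params <- function(x, ...) {
  cat(sprintf("alignment parameters [%s]: S=%g D=%g h=%g k=%g V=%s G0=%g Ge=%g matrix=%s\n",
              x$mode, x$S, x$D, x$h, x$k, x$V, x$G0, x$Ge,
              attr(x$matrix, "name") %||% "custom"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
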