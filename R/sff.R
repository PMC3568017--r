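# Standard Flowgram Format (SFF) v1.00, big-endian.
#
# Only the features the aligner needs are implemented: the common header,
# per-read headers with quality/adapter clipping, flowgram values (uint16,
# signal x 100) and the per-base flow index.  Index blocks are skipped.  The
# writer exists to build test fixtures and round-trip checks.

read_u16 <- function(con) readBin(con, "integer", size = 2, signed = FALSE,
                                  endian = "big")
read_u32 <- function(con) readBin(con, "integer", size = 4, endian = "big")
read_u8  <- function(con, n) as.integer(readBin(con, "raw", n = n))

#' Read an SFF file
#'
#' Parses Roche SFF v1.00: flow values are decoded as unsigned 16-bit
#' big-endian divided by 100, per-base flow indices are rebuilt from the
#' cumulative index-per-flow bytes, and quality/adapter clipping is applied
#' so each returned sequence covers only the clipped region.
#'
#' @param path SFF file path.
#' @return a list of [flow_read()] objects carrying per-base flowpeaks, the
#'   full flowgram and per-base flow indices.
#' @export
read_sff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  version <- read_u8(con, 4)
  if (!identical(magic, ".sff") || !identical(version, c(0L, 0L, 0L, 1L))) {
    stop("not an SFF v1.00 file: ", path, call. = FALSE)
  }
  idx_off_hi <- read_u32(con)
  idx_off_lo <- read_u32(con)
  index_offset <- idx_off_hi * 2^32 + idx_off_lo
  index_length <- read_u32(con)
  n_reads <- read_u32(con)
  header_length <- read_u16(con)
  key_length <- read_u16(con)
  n_flows <- read_u16(con)
  fmt <- read_u8(con, 1)
  if (fmt != 1L) stop("unsupported flowgram format code: ", fmt,
                      call. = FALSE)
  flow_chars <- readChar(con, n_flows, useBytes = TRUE)
  readChar(con, key_length, useBytes = TRUE)
  pad <- header_length - (31L + n_flows + key_length)
  if (pad < 0L) stop("corrupt SFF common header", call. = FALSE)
  read_u8(con, pad)
  cycle <- substr(flow_chars, 1, 4)
  reads <- vector("list", n_reads)
  for (r in seq_len(n_reads)) {
    if (index_offset > 0 && seek(con, NA) == index_offset) {
      read_u8(con, index_length)  # skip index section
    }
    rh_len <- read_u16(con)
    if (!length(rh_len)) stop("truncated SFF file at record ", r,
                              call. = FALSE)
    name_len <- read_u16(con)
    n_bases <- read_u32(con)
    clip_ql <- read_u16(con)
    clip_qr <- read_u16(con)
    clip_al <- read_u16(con)
    clip_ar <- read_u16(con)
    name <- readChar(con, name_len, useBytes = TRUE)
    read_u8(con, rh_len - (16L + name_len))
    flows <- readBin(con, "integer", n = n_flows, size = 2, signed = FALSE,
                     endian = "big") / 100
    fidx_delta <- read_u8(con, n_bases)
    bases <- readChar(con, n_bases, useBytes = TRUE)
    read_u8(con, n_bases)  # quality scores, unused
    dpad <- (8L - (n_flows * 2L + 3L * n_bases) %% 8L) %% 8L
    read_u8(con, dpad)
    if (length(flows) < n_flows || nchar(bases) < n_bases) {
      stop("truncated SFF record '", name, "'", call. = FALSE)
    }
    fidx <- cumsum(fidx_delta) - 1L  # 0-based flow index per base
    first <- max(1L, clip_ql, clip_al)
    last <- min(if (clip_qr == 0L) n_bases else clip_qr,
                if (clip_ar == 0L) n_bases else clip_ar)
    if (last < first) stop("record '", name, "' fully clipped",
                           call. = FALSE)
    keep <- first:last
    seq <- substr(bases, first, last)
    reads[[r]] <- flow_read(seq, id = name,
                            flowpeaks = flows[fidx[keep] + 1L],
                            flow_order = cycle,
                            flow_values = flows,
                            flow_index = fidx[keep])
  }
  reads
}

write_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2,
                                       endian = "big")
write_u32 <- function(con, x) writeBin(as.integer(x), con, size = 4,
                                       endian = "big")
write_u8  <- function(con, x) writeBin(as.raw(x), con)

# Flowgram of a read over the repeating cycle: positive flows carry the
# run's flowpeak, intervening flows are zero (or taken from read$flow_values
# when present).
read_flowgram <- function(read, cycle = "TACG") {
  if (!is.null(read$flow_values)) {
    return(list(flows = read$flow_values, fidx = read$flow_index))
  }
  codes <- read$seq_codes
  if (any(codes == 4L)) stop("cannot write N bases to SFF", call. = FALSE)
  fidx <- simulate_flow_index(codes, cycle)
  nflow <- max(fidx) + 1L
  flows <- numeric(nflow)
  ends <- which(run_decompose(codes)$end)
  flows[fidx[ends] + 1L] <- read$flowpeaks[ends]
  list(flows = flows, fidx = fidx)
}

#' Write reads to an SFF file (fixture writer)
#'
#' Minimal SFF v1.00 writer used to build test inputs: no index section,
#' constant quality scores, optional clip columns.
#'
#' @param reads list of [flow_read()] objects (no N bases).
#' @param path output path.
#' @param flow_order repeating flow cycle.
#' @param clip optional matrix/data.frame with one row per read and columns
#'   `qual_left`, `qual_right`, `adapter_left`, `adapter_right` (0 = unset).
#' @return `path`, invisibly.
#' @export
write_sff <- function(reads, path, flow_order = "TACG", clip = NULL) {
  if (inherits(reads, "flow_read")) reads <- list(reads)
  fg <- lapply(reads, read_flowgram, cycle = flow_order)
  n_flows <- max(vapply(fg, function(f) length(f$flows), integer(1)))
  n_flows <- as.integer(ceiling(n_flows / 4) * 4)
  flow_chars <- paste(rep(strsplit(flow_order, "")[[1]],
                          n_flows / nchar(flow_order)), collapse = "")
  key <- ""
  con <- file(path, "wb")
  on.exit(close(con))
  base_hlen <- 31L + n_flows + nchar(key)
  hlen <- as.integer(ceiling(base_hlen / 8) * 8)
  writeChar(".sff", con, eos = NULL, useBytes = TRUE)
  write_u8(con, c(0, 0, 0, 1))
  write_u32(con, 0); write_u32(con, 0)      # no index
  write_u32(con, 0)                         # index length
  write_u32(con, length(reads))
  write_u16(con, hlen)
  write_u16(con, nchar(key))
  write_u16(con, n_flows)
  write_u8(con, 1)                          # flowgram format code
  writeChar(flow_chars, con, eos = NULL, useBytes = TRUE)
  if (nchar(key)) writeChar(key, con, eos = NULL, useBytes = TRUE)
  write_u8(con, rep(0, hlen - base_hlen))
  for (ri in seq_along(reads)) {
    read <- reads[[ri]]
    f <- fg[[ri]]
    n_bases <- length(read$seq_codes)
    name <- read$id
    rh_base <- 16L + nchar(name)
    rh_len <- as.integer(ceiling(rh_base / 8) * 8)
    cl <- if (is.null(clip)) c(0L, 0L, 0L, 0L) else as.integer(clip[ri, ])
    write_u16(con, rh_len)
    write_u16(con, nchar(name))
    write_u32(con, n_bases)
    write_u16(con, cl[1]); write_u16(con, cl[2])
    write_u16(con, cl[3]); write_u16(con, cl[4])
    writeChar(name, con, eos = NULL, useBytes = TRUE)
    write_u8(con, rep(0, rh_len - rh_base))
    flows100 <- as.integer(round(c(f$flows,
                                   rep(0, n_flows - length(f$flows))) * 100))
    write_u16(con, flows100)
    write_u8(con, diff(c(-1L, f$fidx)))     # cumulative deltas, 1-based start
    writeChar(read$sequence, con, eos = NULL, useBytes = TRUE)
    write_u8(con, rep(40L, n_bases))
    dpad <- (8L - (n_flows * 2L + 3L * n_bases) %% 8L) %% 8L
    write_u8(con, rep(0, dpad))
  }
  invisible(path)
}
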