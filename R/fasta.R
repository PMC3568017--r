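# FASTA input with role-aware alphabet checks.

#' Read a FASTA file
#'
#' Wraps the Biostrings reader, normalises case, tolerates wrapping, and
#' checks the sequences against their expected role.
#'
#' @param path FASTA file path.
#' @param role `"nucleotide"` (T/A/C/G/N, U converted to T) or `"protein"`.
#' @return a named character vector of sequences in file order.
#' @export
read_fasta <- function(path, role = c("nucleotide", "protein")) {
  role <- match.arg(role)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  names(seqs) <- ids
  if (role == "nucleotide") {
    seqs <- chartr("U", "T", seqs)
    bad <- grepl("[^TACGN]", seqs)
    if (any(bad)) {
      stop("non-nucleotide characters in ", paste(ids[bad], collapse = ", "),
           call. = FALSE)
    }
  } else {
    core <- sub("\\*+$", "", seqs)
    bad <- grepl("[^A-Z]", core) | grepl("\\*", core)
    if (any(bad)) {
      stop("invalid protein characters in ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
    seqs <- core
  }
  seqs
}
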