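# Substitution matrices, codon translation and the elementary codon-vs-amino
# acid score.  Residue order is fixed package-wide; the last two symbols are
# the unknown residue X and the stop sentinel "*".

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")

#' Score for any codon that translates to a stop
#'
#' A fixed constant strictly below every BLOSUM entry, so that optimal local
#' alignments never pass through a stop codon while the dynamic-programming
#' total order stays well defined.
#' @export
STOP_SCORE <- -16

#' Load a built-in substitution matrix
#'
#' Returns an amino-acid substitution matrix over the 20 standard residues
#' plus B, Z, the unknown residue X and the stop sentinel `*`, in half-bit
#' (or the matrix's native) integer units.  Matrices are taken from the
#' standard BLOSUM series as distributed with Biostrings.
#'
#' @param name one of "BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80",
#'   "BLOSUM100".
#' @return a numeric matrix of class `substitution_matrix` with symmetric
#'   scores and dimnames over [AA_ALPHABET].
#' @examples
#' m <- substitution_matrix("BLOSUM62")
#' m["M", "M"]  # 5
#' @export
substitution_matrix <- function(name = "BLOSUM62") {
  choices <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100")
  name <- match.arg(toupper(name), choices)
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  raw <- get(name, envir = env)
  as_substitution_matrix(raw, name)
}

as_substitution_matrix <- function(raw, name) {
  m <- matrix(0, length(AA_ALPHABET), length(AA_ALPHABET),
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  common <- intersect(AA_ALPHABET, rownames(raw))
  m[common, common] <- raw[common, common]
  missing_std <- setdiff(AA_ALPHABET[1:20], common)
  if (length(missing_std)) {
    stop("matrix '", name, "' lacks standard residues: ",
         paste(missing_std, collapse = ", "), call. = FALSE)
  }
  # Symbols absent from the source matrix fall back to the X column.
  for (s in setdiff(AA_ALPHABET, common)) {
    m[s, ] <- m["X", ]
    m[, s] <- m[, "X"]
    m[s, s] <- m["X", "X"]
  }
  if (!isTRUE(all.equal(m, t(m)))) {
    stop("substitution matrix '", name, "' is not symmetric", call. = FALSE)
  }
  structure(m, name = name, class = c("substitution_matrix", "matrix"))
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses whitespace-separated matrix text as distributed by NCBI: comment
#' lines start with `#`, the first non-comment line holds the column
#' residues, each following line a row residue and its scores.
#'
#' @param path path to the matrix text file.
#' @param name label stored on the returned matrix (defaults to the file
#'   name).
#' @return a `substitution_matrix` (see [substitution_matrix()]).
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a matrix file: ", path, call. = FALSE)
  cols <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- character(0)
  vals <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != length(cols) + 1L) {
      stop("malformed matrix row: ", ln, call. = FALSE)
    }
    rows <- c(rows, parts[[1]])
    vals[[parts[[1]]]] <- as.numeric(parts[-1])
  }
  raw <- do.call(rbind, vals)
  dimnames(raw) <- list(rows, cols)
  as_substitution_matrix(raw, name)
}

# Standard genetic code over the package nucleotide order TACG, exposed as a
# named character vector codon -> single-letter residue ("*" = stop).
codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      g <- Biostrings::GENETIC_CODE
      names(g) <- chartr("U", "T", names(g))
      gc <<- g
    }
    gc
  }
})

#' Translate one codon
#'
#' @param triplet a 3-character nucleotide string over T/A/C/G/N.
#' @return the single-letter amino acid, `"*"` for a stop codon, or `"X"`
#'   when the triplet contains an N.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(triplet) {
  triplet <- toupper(triplet)
  if (nchar(triplet) != 3L) stop("triplet must have length 3", call. = FALSE)
  if (grepl("N", triplet, fixed = TRUE)) {
    if (!grepl("^[TACGN]{3}$", triplet)) {
      stop("non-nucleotide character in triplet: ", triplet, call. = FALSE)
    }
    return("X")
  }
  aa <- codon_table()[triplet]
  if (is.na(aa)) stop("non-nucleotide character in triplet: ", triplet,
                      call. = FALSE)
  unname(aa)
}

#' Codon-vs-amino-acid match score
#'
#' The width-3 match function: the substitution score of `aa` against the
#' translation of `triplet`.  Stop-translating triplets score the fixed
#' [STOP_SCORE] regardless of `aa`.
#'
#' @param aa single-letter amino acid.
#' @param triplet 3-nucleotide string.
#' @param matrix a [substitution_matrix()].
#' @return numeric score.
#' @examples
#' m3_score("M", "ATG", substitution_matrix())  # 5
#' @export
m3_score <- function(aa, triplet, matrix = substitution_matrix()) {
  res <- translate_codon(triplet)
  if (res == "*") return(STOP_SCORE)
  aa <- toupper(aa)
  if (!aa %in% rownames(matrix)) aa <- "X"
  unname(matrix[aa, res])
}

aa_encode <- function(s) {
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  ch[!ch %in% AA_ALPHABET] <- "X"
  match(ch, AA_ALPHABET) - 1L
}
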