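#' Read sequences from a FASTA file
#'
#' Reads a FASTA file and normalizes every sequence to the internal RNA
#' alphabet: characters are uppercased and `T` becomes `U`, so DNA- and
#' RNA-style files are interchangeable. Characters outside `ACGUN` are
#' rejected with a parse error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `name` (first whitespace-delimited token of
#'   the header), `seq` (normalized RNA sequence) and `length`, in input
#'   order.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">m", "tgaggt"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Cannot read FASTA: no such file '%s'.", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("Malformed FASTA '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (length(set) == 0L) {
    abort(sprintf("Malformed FASTA '%s': no records.", path))
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    # Locate the first offending line for the error message.
    lines <- toupper(readLines(path, warn = FALSE))
    lines <- chartr("T", "U", lines)
    is_seq <- !startsWith(lines, ">")
    bad_line <- which(is_seq & grepl("[^ACGUN[:space:]]", lines))[1]
    abort(sprintf(
      "Illegal sequence character in FASTA '%s' at line %s (alphabet is ACGT/U/N).",
      path, if (is.na(bad_line)) "?" else bad_line))
  }
  names <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  tibble(name = names, seq = unname(seqs), length = nchar(unname(seqs)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `name` and `seq` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    nm <- seqs$name
    sq <- seqs$seq
  } else {
    nm <- names(seqs)
    sq <- unname(seqs)
  }
  writeLines(paste0(">", nm, "\n", sq), path)
  invisible(path)
}

#' Reverse complement of an RNA sequence
#'
#' Complements in the RNA alphabet (`A<->U`, `C<->G`, `N` self) and reverses.
#' `T` on input is treated as `U`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements (RNA alphabet).
#' @export
revcomp_rna <- function(x) {
  x <- chartr("T", "U", toupper(x))
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Complement (no reversal), used when building aligned duplex rows.
comp_rna <- function(x) chartr("ACGU", "UGCA", chartr("T", "U", toupper(x)))
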