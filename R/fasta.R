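# Sequence records are represented throughout the package as a named
# character vector: names are FASTA header tokens, values are uppercase
# DNA strings over {A,C,G,T,N}.

.DNA_OK <- c("A", "C", "G", "T", "N")

# Validate a DNA string; returns the uppercased string or stops.
validate_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  if (grepl("[^ACGTN]", x)) {
    bad <- regmatches(x, regexpr("[^ACGTN]", x))
    stop("illegal character '", bad, "' in ", what,
         " (alphabet is A,C,G,T,N)")
  }
  x
}

#' Parse FASTA text into named DNA sequences
#'
#' Accepts a file path or raw FASTA text (a character vector of lines, or a
#' single string containing newlines).  Sequences are uppercased on ingest;
#' soft-masked lowercase regions are not treated specially.  Characters
#' outside `{A,C,G,T,N}` (either case) are rejected with the offending line
#' number, as is sequence data appearing before the first header.
#'
#' @param x Path to a FASTA file, or FASTA text.
#' @return Named character vector of uppercase sequences, one element per
#'   record in file order; names are the first whitespace-delimited header
#'   token.
#' @examples
#' read_fasta(c(">a", "AC", "GT", ">b", "NN"))
#' @export
read_fasta <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[\n>]", substr(x, 1, 1)) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  ids <- character(0)
  seqs <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      header <- sub("^>\\s*", "", ln)
      id <- strsplit(header, "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id)) {
        stop("FASTA parse error at line ", i, ": empty header")
      }
      ids <- c(ids, id)
      cur <- length(ids)
      seqs[[cur]] <- character(0)
    } else {
      if (is.null(cur)) {
        stop("FASTA parse error at line ", i,
             ": sequence data before first header")
      }
      up <- toupper(gsub("[ \t\r]", "", ln))
      if (grepl("[^ACGTN]", up)) {
        stop("FASTA parse error at line ", i, ": illegal character '",
             regmatches(up, regexpr("[^ACGTN]", up)), "'")
      }
      seqs[[cur]] <- c(seqs[[cur]], up)
    }
  }
  out <- vapply(seqs, paste, character(1), collapse = "")
  names(out) <- ids
  out
}

#' Write named DNA sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq.int(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Vectorised over its input.  `N` is self-complementary; the operation is
#' an involution (applying it twice returns the input).
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("GATTACA")  # "TGTAATC"
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    s <- validate_dna(s)
    if (nchar(s) == 0L) return("")
    intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", s))))
  }, character(1), USE.NAMES = FALSE)
}
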