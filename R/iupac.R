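# Standard IUPAC nucleotide degeneracy table. Each code maps to the subset
# of {A,C,G,T} it stands for; a genomic 'N' is deliberately absent from every
# set, so an ambiguous assembly base never satisfies a pattern position (an
# 'N' in the genome is not a designable target, even opposite pattern 'N').
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Construct a degenerate IUPAC nucleotide pattern
#'
#' Builds a validated pattern object from an IUPAC string such as
#' `"NNGRRT"`.  Each position carries the subset of `{A,C,G,T}` it allows
#' (`N` = any base, `R` = purine A/G, `Y` = pyrimidine C/T, plus the other
#' standard two- and three-base codes).  Pattern objects drive the PAM
#' scanner, the closed-form density model, and the synthetic site planter.
#'
#' @param pattern IUPAC string, length >= 1, case-insensitive.
#' @param name Optional display name; defaults to the uppercased pattern.
#' @return An object of class `iupac_pattern` with elements `name`,
#'   `symbols` (character vector of codes) and `sets` (list of allowed-base
#'   character vectors, one per position).
#' @examples
#' p <- iupac_pattern("NNGRRT")
#' lengths(p$sets)  # 4 4 1 2 2 1
#' @export
iupac_pattern <- function(pattern, name = NULL) {
  if (inherits(pattern, "iupac_pattern")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  symbols <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(symbols, names(IUPAC_SETS))
  if (length(bad) > 0L) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  }
  structure(
    list(
      name = if (is.null(name)) paste(symbols, collapse = "") else name,
      symbols = symbols,
      sets = IUPAC_SETS[symbols]
    ),
    class = "iupac_pattern"
  )
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat("IUPAC pattern ", x$name, " (", length(x$symbols), " nt): ",
      paste(vapply(x$sets, function(s) paste0("[", paste(s, collapse = ""), "]"),
                   character(1)), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
length.iupac_pattern <- function(x) length(x$symbols)

#' Test whether a window matches a degenerate pattern
#'
#' A window matches when every position's base lies in that position's
#' allowed set.  A genomic `N` matches no pattern position, including
#' pattern `N`: ambiguous assembly bases are never counted as target sites.
#'
#' @param window DNA string over `{A,C,G,T,N}`, same length as `pattern`.
#' @param pattern An [iupac_pattern()] (or IUPAC string).
#' @return Logical scalar.
#' @examples
#' matches_pattern("AAGAGT", "NNGRRT")  # TRUE
#' matches_pattern("ANGAGT", "NNGRRT")  # FALSE: genomic N excluded
#' @export
matches_pattern <- function(window, pattern) {
  pattern <- iupac_pattern(pattern)
  window <- toupper(window)
  if (nchar(window) != length(pattern$symbols)) {
    stop("window length (", nchar(window), ") != pattern length (",
         length(pattern$symbols), ")")
  }
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  all(mapply(function(b, set) b %in% set, chars, pattern$sets))
}

# Per-strand match probability of `pattern` under an i.i.d. composition
# (named probability vector over A,C,G,T): product over positions of the
# summed probabilities of the allowed bases.
pattern_match_prob <- function(pattern, comp) {
  pattern <- iupac_pattern(pattern)
  prod(vapply(pattern$sets, function(set) sum(comp[set]), numeric(1)))
}

# Reverse complement of a pattern: reverse position order and complement
# each allowed set (used by the strand-aware scanner oracle and planter).
complement_pattern <- function(pattern) {
  pattern <- iupac_pattern(pattern)
  comp_tab <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")
  iupac_pattern(paste(rev(comp_tab[pattern$symbols]), collapse = ""),
                name = paste0("revcomp(", pattern$name, ")"))
}
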