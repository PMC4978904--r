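#' Define a PAM class to scan for
#'
#' Couples a degenerate PAM pattern with the protospacer length expected
#' 5' of it.  The six classes from the SpCas9/SaCas9 repertoire analysis
#' (`NGG`, `NGA`, `NNGRRN`, `NNGRRT`, `NNNRRN`, `NNNRRT`) can be named
#' directly; any other IUPAC string defines a custom class.
#'
#' @param class_name PAM class name; used verbatim as the pattern unless
#'   `pattern` is supplied.
#' @param pattern Optional [iupac_pattern()] or IUPAC string overriding the
#'   class name.
#' @param spacer_length Protospacer length in bp 5' of the PAM (default 20,
#'   the canonical SpCas9 spacer; 21-23 are common for SaCas9).
#' @return An object of class `pam_spec`.
#' @examples
#' pam_spec("NNGRRT")
#' pam_spec("SaCas9-21nt", pattern = "NNGRRT", spacer_length = 21)
#' @export
pam_spec <- function(class_name, pattern = NULL, spacer_length = 20L) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  spacer_length <- as.integer(spacer_length)
  if (is.na(spacer_length) || spacer_length < 1L) {
    stop("spacer_length must be a positive integer")
  }
  pat <- iupac_pattern(if (is.null(pattern)) class_name else pattern)
  if (length(pat$symbols) < 2L) stop("PAM pattern must be at least 2 nt")
  structure(
    list(class_name = class_name, pattern = pat,
         spacer_length = spacer_length),
    class = "pam_spec"
  )
}

#' @export
print.pam_spec <- function(x, ...) {
  cat("PAM class ", x$class_name, ": pattern ",
      paste(x$pattern$symbols, collapse = ""),
      ", spacer ", x$spacer_length, " bp\n", sep = "")
  invisible(x)
}

#' The six PAM classes of the repertoire analysis
#'
#' Convenience constructor for the PAM classes scanned genome-wide:
#' SpCas9 `NGG`, VQR-SpCas9 `NGA`, and the SaCas9 family `NNGRRN`,
#' `NNGRRT`, `NNNRRN`, `NNNRRT` (native SaCas9 prefers `NNGRRT`; the KKH
#' variant relaxes it to `NNNRRT`).
#'
#' @param spacer_length Protospacer length applied to all six (default 20).
#' @return Named list of six [pam_spec()] objects.
#' @export
pam_six_classes <- function(spacer_length = 20L) {
  classes <- c("NGG", "NGA", "NNGRRN", "NNGRRT", "NNNRRN", "NNNRRT")
  specs <- lapply(classes, pam_spec, spacer_length = spacer_length)
  names(specs) <- classes
  specs
}

# --- internal vectorized matcher ------------------------------------------

# 1-based start positions of all pattern matches in the integer-coded
# sequence `si` (utf8 codes).  Lookup tables over char codes make each
# pattern position one vectorized subset-test; genomic N (code 78) is in no
# table, implementing the ambiguous-base exclusion.
match_starts <- function(si, pattern) {
  k <- length(pattern$symbols)
  L <- length(si)
  if (L < k) return(integer(0))
  n <- L - k + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    lut <- logical(128L)
    lut[utf8ToInt(paste(pattern$sets[[j]], collapse = ""))] <- TRUE
    ok <- ok & lut[si[j:(n + j - 1L)]]
  }
  which(ok)
}

empty_site_frame <- function() {
  data.frame(
    record_id = character(0), strand = character(0),
    protospacer_start = integer(0), protospacer_end = integer(0),
    pam_start = integer(0), pam_end = integer(0),
    protospacer_seq = character(0), pam_seq = character(0),
    pam_class = character(0), stringsAsFactors = FALSE
  )
}

new_site_table <- function(df, scanned_bp) {
  rownames(df) <- NULL
  structure(df, scanned_bp = as.double(scanned_bp),
            class = c("site_table", "data.frame"))
}

#' Enumerate all target sites for one PAM class in one sequence record
#'
#' Slides the PAM pattern over both strands.  A forward match at 0-based
#' `[i, i+k)` with full spacer room yields a `+` site with protospacer
#' `[i - spacer, i)`; matches on the reverse complement are mapped back to
#' forward coordinates as `-` sites.  Overlapping sites are all reported.
#' Sites whose protospacer or PAM contains an ambiguous `N` are suppressed,
#' as are sites lacking full spacer room at a record edge (a guide cannot
#' be designed there).
#'
#' @param sequence DNA string over `{A,C,G,T,N}` (uppercased on ingest).
#' @param spec A [pam_spec()].
#' @param record_id Record name used in output coordinates.
#' @return A `site_table`: a data frame with one row per site and columns
#'   `record_id`, `strand`, `protospacer_start`, `protospacer_end`,
#'   `pam_start`, `pam_end` (0-based half-open, forward coordinate system),
#'   `protospacer_seq`, `pam_seq` (as read on the targeted strand), and
#'   `pam_class`; attribute `scanned_bp` holds the record length.  Sorted
#'   by (record_id, union start, strand).
#' @examples
#' scan_record("ATACGG", pam_spec("NGG", spacer_length = 2), "t")
#' @export
scan_record <- function(sequence, spec, record_id = "seq") {
  stopifnot(inherits(spec, "pam_spec"))
  sequence <- validate_dna(sequence, what = paste0("record '", record_id, "'"))
  L <- nchar(sequence)
  if (L == 0L) return(new_site_table(empty_site_frame(), 0))
  k <- length(spec$pattern$symbols)
  sp <- spec$spacer_length
  si <- utf8ToInt(sequence)
  cumN <- c(0L, cumsum(si == 78L))  # N count in 1-based [a,b] = cumN[b+1]-cumN[a]

  rows <- list()

  # forward strand: PAM starts (1-based)
  fwd <- match_starts(si, spec$pattern)
  fwd <- fwd[fwd > sp]
  if (length(fwd) > 0L) {
    fwd <- fwd[cumN[fwd] - cumN[fwd - sp] == 0L]  # N-free spacer
  }
  if (length(fwd) > 0L) {
    ps0 <- fwd - 1L - sp  # 0-based protospacer start
    rows$fwd <- data.frame(
      record_id = record_id, strand = "+",
      protospacer_start = ps0, protospacer_end = ps0 + sp,
      pam_start = ps0 + sp, pam_end = ps0 + sp + k,
      protospacer_seq = substring(sequence, ps0 + 1L, ps0 + sp),
      pam_seq = substring(sequence, ps0 + sp + 1L, ps0 + sp + k),
      pam_class = spec$class_name, stringsAsFactors = FALSE
    )
  }

  # reverse strand: scan the reverse complement, remap to forward coords
  rc <- reverse_complement(sequence)
  ri <- utf8ToInt(rc)
  rcumN <- c(0L, cumsum(ri == 78L))
  rev_hits <- match_starts(ri, spec$pattern)
  rev_hits <- rev_hits[rev_hits > sp]
  if (length(rev_hits) > 0L) {
    rev_hits <- rev_hits[rcumN[rev_hits] - rcumN[rev_hits - sp] == 0L]
  }
  if (length(rev_hits) > 0L) {
    j <- rev_hits  # 1-based PAM start within rc
    pam0 <- L - j - k + 1L         # forward 0-based PAM start
    rows$rev <- data.frame(
      record_id = record_id, strand = "-",
      protospacer_start = L - j + 1L, protospacer_end = L - j + 1L + sp,
      pam_start = pam0, pam_end = pam0 + k,
      protospacer_seq = substring(rc, j - sp, j - 1L),
      pam_seq = substring(rc, j, j + k - 1L),
      pam_class = spec$class_name, stringsAsFactors = FALSE
    )
  }

  df <- if (length(rows) == 0L) empty_site_frame() else do.call(rbind, rows)
  start <- pmin(df$protospacer_start, df$pam_start)
  df <- df[order(df$record_id, start, df$strand), , drop = FALSE]
  new_site_table(df, L)
}

#' Scan a multi-record genome for several PAM classes
#'
#' @param records Named character vector of sequences (see [read_fasta()]).
#' @param specs A [pam_spec()], or a list of them with unique class names
#'   (e.g. [pam_six_classes()]).
#' @return Named list mapping class name to a `site_table` covering all
#'   records; each table's `scanned_bp` attribute equals the total genome
#'   length.  Rows sorted by (record_id, union start, strand).
#' @export
scan_genome <- function(records, specs) {
  if (inherits(specs, "pam_spec")) specs <- list(specs)
  cls <- vapply(specs, function(s) s$class_name, character(1))
  if (anyDuplicated(cls)) {
    stop("duplicate PAM class names: ",
         paste(unique(cls[duplicated(cls)]), collapse = ", "))
  }
  names(specs) <- cls
  total_bp <- if (length(records) == 0L) 0 else sum(nchar(records))
  ids <- names(records)
  out <- lapply(specs, function(spec) {
    parts <- lapply(seq_along(records), function(i) {
      scan_record(records[[i]], spec, record_id = ids[i])
    })
    df <- if (length(parts) == 0L) empty_site_frame()
          else do.call(rbind, lapply(parts, as.data.frame))
    start <- pmin(df$protospacer_start, df$pam_start)
    df <- df[order(df$record_id, start, df$strand), , drop = FALSE]
    new_site_table(df, total_bp)
  })
  out
}

#' Combine per-class site tables into one table
#'
#' Row-binds tables that were produced from the same scan (equal
#' `scanned_bp`), re-sorting by (record_id, union start, strand,
#' pam_class).
#'
#' @param tables List of `site_table` objects over the same genome.
#' @return A single `site_table`.
#' @export
combine_sites <- function(tables) {
  stopifnot(length(tables) > 0L)
  bp <- unique(vapply(tables, function(t) attr(t, "scanned_bp"), numeric(1)))
  if (length(bp) != 1L) {
    stop("site tables were not scanned over the same genome (scanned_bp differs)")
  }
  df <- do.call(rbind, lapply(tables, as.data.frame))
  start <- pmin(df$protospacer_start, df$pam_start)
  df <- df[order(df$record_id, start, df$strand, df$pam_class), , drop = FALSE]
  new_site_table(df, bp)
}

#' @export
print.site_table <- function(x, ...) {
  cat("site_table: ", nrow(x), " site(s) over ",
      format(attr(x, "scanned_bp"), big.mark = ","), " bp scanned\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more)\n", sep = "")
  invisible(x)
}

#' Write a site table as BED6
#'
#' Emits tab-separated BED6: `chrom` is the record id; the interval spans
#' either the union of protospacer and PAM (default: the whole editable
#' locus, the natural unit for exon intersection) or the PAM alone;
#' `name` is `"<pam_class>|<protospacer_seq>|<pam_seq>"`; `score` is 0.
#' Coordinates are 0-based half-open per the BED standard.
#'
#' @param table A `site_table`.
#' @param path Output path or connection.
#' @param span `"union"` (protospacer+PAM, default) or `"pam"`.
#' @return Invisibly, the number of lines written.
#' @export
write_bed <- function(table, path, span = c("union", "pam")) {
  span <- match.arg(span)
  lines <- bed_lines(table, span)
  writeLines(lines, path)
  invisible(length(lines))
}

bed_lines <- function(table, span = "union") {
  if (nrow(table) == 0L) return(character(0))
  if (span == "union") {
    s <- pmin(table$protospacer_start, table$pam_start)
    e <- pmax(table$protospacer_end, table$pam_end)
  } else {
    s <- table$pam_start
    e <- table$pam_end
  }
  paste(table$record_id, s, e,
        paste(table$pam_class, table$protospacer_seq, table$pam_seq, sep = "|"),
        0L, table$strand, sep = "\t")
}
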