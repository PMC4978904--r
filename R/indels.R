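# Allele classification against a reference amplicon: global affine-gap
# alignment, gap runs become insertion/deletion events, events are
# left-aligned (VCF convention) so homopolymer-ambiguous placements are
# canonical.

empty_events <- function() {
  data.frame(kind = character(0), ref_position = integer(0),
             length = integer(0), inserted_seq = character(0),
             stringsAsFactors = FALSE)
}

#' Left-align indel events against a reference
#'
#' Shifts each event to its leftmost equivalent placement: a deletion of
#' `ref[p, p+len)` moves to `p-1` while `ref[p-1] == ref[p+len-1]`; an
#' insertion before `ref[p]` moves to `p-1` while its last inserted base
#' equals `ref[p-1]` (the inserted sequence is rotated accordingly).
#' Events never shift past the end of the preceding event.
#'
#' @param reference DNA string.
#' @param events Event data frame (`kind`, `ref_position`, `length`,
#'   `inserted_seq`) sorted by position.
#' @return The event data frame with canonical leftmost positions.
#' @export
left_align_events <- function(reference, events) {
  if (nrow(events) == 0L) return(events)
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  events <- events[order(events$ref_position), , drop = FALSE]
  floor_pos <- 0L
  for (i in seq_len(nrow(events))) {
    p <- events$ref_position[i]
    if (events$kind[i] == "deletion") {
      len <- events$length[i]
      # shift left while the base preceding the run equals its last base
      while (p > floor_pos && ref[p] == ref[p + len]) {
        p <- p - 1L
      }
      events$ref_position[i] <- p
      floor_pos <- p + len
    } else {
      ins <- strsplit(events$inserted_seq[i], "", fixed = TRUE)[[1]]
      while (p > floor_pos && ref[p] == ins[length(ins)]) {
        ins <- c(ref[p], ins[-length(ins)])
        p <- p - 1L
      }
      events$ref_position[i] <- p
      events$inserted_seq[i] <- paste(ins, collapse = "")
      floor_pos <- p
    }
  }
  rownames(events) <- NULL
  events
}

#' Call indels in one allele against a reference amplicon
#'
#' Globally aligns the allele to the reference (end-to-end
#' Needleman-Wunsch with affine gaps; defaults match +1, mismatch -1, gap
#' open -5, gap extend -1) and converts maximal gap runs into events: a
#' gap in the allele row is a deletion, a gap in the reference row an
#' insertion carrying the inserted bases.  Events are left-aligned
#' post hoc (VCF convention).  Substitutions are not events; their count
#' is reported separately, so a substitution-only allele is a zero-indel
#' call.
#'
#' @param reference,allele Non-empty DNA strings over `{A,C,G,T}`
#'   (ambiguous `N` bases are rejected: Sanger-derived alleles should be
#'   base-called before classification).
#' @param allele_id Identifier stored in the call.
#' @param match,mismatch,gap_open,gap_extend Alignment scores; a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @return An object of class `allele_call`: `allele_id`, `events` (data
#'   frame `kind`, `ref_position` 0-based, `length`, `inserted_seq`),
#'   `net_change` (signed bp), `n_substitutions`, `multiplicity` (1).
#' @examples
#' call_indels("ACGTACGT", "ACGACGT")$events  # 1-bp deletion at position 3
#' @export
call_indels <- function(reference, allele, allele_id = "allele",
                        match = 1, mismatch = -1,
                        gap_open = 5, gap_extend = 1) {
  reference <- validate_dna(reference, "reference")
  allele <- validate_dna(allele, "allele")
  if (nchar(reference) == 0L || nchar(allele) == 0L) {
    stop("reference and allele must be non-empty")
  }
  if (grepl("N", reference) || grepl("N", allele)) {
    stop("call_indels requires unambiguous {A,C,G,T} sequences")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = allele, subject = reference, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  arow <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  rrow <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  events <- empty_events()
  refpos <- 0L
  n_sub <- 0L
  i <- 1L
  n <- length(arow)
  while (i <= n) {
    if (arow[i] == "-") {                       # deletion run
      j <- i
      while (j <= n && arow[j] == "-") j <- j + 1L
      events <- rbind(events, data.frame(
        kind = "deletion", ref_position = refpos, length = j - i,
        inserted_seq = "", stringsAsFactors = FALSE))
      refpos <- refpos + (j - i)
      i <- j
    } else if (rrow[i] == "-") {                # insertion run
      j <- i
      while (j <= n && rrow[j] == "-") j <- j + 1L
      events <- rbind(events, data.frame(
        kind = "insertion", ref_position = refpos, length = j - i,
        inserted_seq = paste(arow[i:(j - 1L)], collapse = ""),
        stringsAsFactors = FALSE))
      i <- j
    } else {
      if (arow[i] != rrow[i]) n_sub <- n_sub + 1L
      refpos <- refpos + 1L
      i <- i + 1L
    }
  }
  events <- left_align_events(reference, events)
  net <- sum(ifelse(events$kind == "insertion", events$length, -events$length))
  structure(
    list(allele_id = allele_id, events = events,
         net_change = as.integer(net), n_substitutions = n_sub,
         multiplicity = 1L),
    class = "allele_call"
  )
}

#' @export
print.allele_call <- function(x, ...) {
  cat("allele_call ", x$allele_id, ": net ", sprintf("%+d", x$net_change),
      " bp, ", nrow(x$events), " event(s), ", x$n_substitutions,
      " substitution(s)\n", sep = "")
  if (nrow(x$events) > 0L) print.data.frame(x$events)
  invisible(x)
}

# Render one allele diagram line: reference with deleted bases as dashes
# and inserted bases in lower case (figure-style allele display).
render_allele <- function(reference, events) {
  ref <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(events))) {
    if (events$kind[i] == "deletion") {
      idx <- events$ref_position[i] + seq_len(events$length[i])
      ref[idx] <- "-"
    }
  }
  ins <- events[events$kind == "insertion", , drop = FALSE]
  if (nrow(ins) > 0L) {
    for (i in order(ins$ref_position, decreasing = TRUE)) {
      p <- ins$ref_position[i]
      ref <- append(ref, strsplit(tolower(ins$inserted_seq[i]), "")[[1]],
                    after = p)
    }
  }
  paste(ref, collapse = "")
}

#' Summarize allele calls as a figure-style diagram
#'
#' Groups identical event lists, renders each group as the reference with
#' deletions shown as dashes and insertions as lower-case letters, and
#' appends the observed multiplicity in `[x N]` brackets.  Groups are
#' ordered by ascending net change, then by first event position.
#'
#' @param calls List of `allele_call` objects against the same reference.
#' @param reference The reference amplicon sequence (needed to render
#'   diagrams; omit for a table-only summary).
#' @return An object of class `allele_summary`: data frame `groups`
#'   (`net_change`, `n_events`, `multiplicity`, `signature`) and, when a
#'   reference is given, a character vector `lines` of rendered diagrams.
#' @export
summarize_alleles <- function(calls, reference = NULL) {
  sig <- vapply(calls, function(cl) {
    if (nrow(cl$events) == 0L) return("wild-type")
    paste(sprintf("%s@%d:%d%s", cl$events$kind, cl$events$ref_position,
                  cl$events$length,
                  ifelse(nzchar(cl$events$inserted_seq),
                         paste0(":", cl$events$inserted_seq), "")),
          collapse = ";")
  }, character(1))
  groups <- split(seq_along(calls), sig)
  rows <- lapply(groups, function(idx) {
    cl <- calls[[idx[1]]]
    data.frame(
      net_change = cl$net_change,
      n_events = nrow(cl$events),
      first_position = if (nrow(cl$events)) min(cl$events$ref_position) else NA_integer_,
      multiplicity = sum(vapply(calls[idx], function(c) c$multiplicity, integer(1))),
      signature = sig[idx[1]],
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows) == 0L) {
    data.frame(net_change = integer(0), n_events = integer(0),
               first_position = integer(0), multiplicity = integer(0),
               signature = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  df <- df[order(df$net_change, df$first_position), , drop = FALSE]
  rownames(df) <- NULL

  lines <- NULL
  if (!is.null(reference) && nrow(df) > 0L) {
    rep_call <- function(s) calls[[which(sig == s)[1]]]
    lines <- vapply(df$signature, function(s) {
      paste0(render_allele(reference, rep_call(s)$events),
             "  [x", df$multiplicity[df$signature == s], "]")
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(groups = df, lines = lines, reference = reference),
            class = "allele_summary")
}

#' @export
print.allele_summary <- function(x, ...) {
  cat("allele_summary: ", nrow(x$groups), " distinct allele(s)\n", sep = "")
  if (!is.null(x$reference)) cat("ref  ", toupper(x$reference), "\n", sep = "")
  if (!is.null(x$lines)) cat(paste0("     ", x$lines, collapse = "\n"), "\n", sep = "")
  invisible(x)
}

#' Indel fraction from T7E1 band intensities
#'
#' The T7 endonuclease I assay reanneals amplicons from a mutagenized
#' pool; heteroduplexes (mutant/wild-type hybrids) are cleaved.  Under
#' the standard assumption that every duplex with at least one mutant
#' strand is cleaved, a mutant fraction f yields a cleaved fraction of
#' `1 - (1 - f)^2`, so the indel fraction is recovered as
#' `indel = 1 - sqrt(1 - cleaved)`.  Both the raw cleaved fraction and
#' the corrected indel fraction are reported, since published
#' band-intensity numbers are sometimes left uncorrected.
#'
#' @param uncut_intensity Intensity of the undigested band (>= 0).
#' @param cleaved_intensities Numeric vector of cleavage-product band
#'   intensities (>= 0); total intensity must be positive.
#' @return An object of class `t7e1_estimate` with `cleaved_fraction` and
#'   `indel_fraction`, both in `[0, 1]`.
#' @examples
#' t7e1_indel_fraction(25, c(50, 25))  # cleaved 0.75, indel 0.5
#' @export
t7e1_indel_fraction <- function(uncut_intensity, cleaved_intensities) {
  if (uncut_intensity < 0 || any(cleaved_intensities < 0)) {
    stop("band intensities must be non-negative")
  }
  total <- uncut_intensity + sum(cleaved_intensities)
  if (total <= 0) stop("total band intensity must be positive")
  cf <- sum(cleaved_intensities) / total
  structure(
    list(cleaved_fraction = cf,
         indel_fraction = 1 - sqrt(max(0, 1 - cf))),
    class = "t7e1_estimate"
  )
}

#' @export
print.t7e1_estimate <- function(x, ...) {
  cat(sprintf("T7E1: cleaved fraction %.3f -> indel fraction %.3f\n",
              x$cleaved_fraction, x$indel_fraction))
  invisible(x)
}
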