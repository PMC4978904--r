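# Oligo design for the cloning-free gRNA template method: a forward oligo
# (T7 promoter + spacer + 5' end of the scaffold) is annealed/extended
# against a scaffold oligo by overlap PCR, and the product transcribed in
# vitro from the T7 promoter.

.DEFAULT_T7 <- "TAATACGACTCACTATAG"

.KNOWN_PROFILES <- c("SpCas9" = "NGG", "VQR-SpCas9" = "NGA",
                     "SaCas9" = "NNGRRT", "KKH-SaCas9" = "NNNRRT")

#' Describe a Cas system for guide-template design
#'
#' Scaffold sequences differ between Cas systems (Sp vs Sa tracrRNA-fused
#' scaffolds) and are deliberately a required input rather than being
#' hard-coded: a silently wrong scaffold is worse than an explicit one.
#'
#' @param name One of `"SpCas9"`, `"VQR-SpCas9"`, `"SaCas9"`,
#'   `"KKH-SaCas9"` (which imply a PAM class), or any other label with
#'   `pam_class` given explicitly.
#' @param scaffold DNA string of the gRNA scaffold template (DNA sense of
#'   the transcribed scaffold), non-empty.
#' @param pam_class PAM class the profile targets; required for custom
#'   names.
#' @param spacer_length Protospacer length in bp (default 20).
#' @param t7_promoter T7 promoter sequence prefixed to the forward oligo.
#' @param require_5prime_g Number of leading `G`s the transcribed region
#'   must start with for efficient T7 initiation (default 2).
#' @param g_mode How to satisfy the 5'-G requirement: `"prepend"` extra
#'   `G`s (default, as in the cloning-free protocol), `"substitute"` the
#'   spacer's first bases, or `"reject"` unsuitable spacers.
#' @return An object of class `cas_profile`.
#' @export
cas_profile <- function(name, scaffold, pam_class = NULL,
                        spacer_length = 20L,
                        t7_promoter = .DEFAULT_T7,
                        require_5prime_g = 2L,
                        g_mode = c("prepend", "substitute", "reject")) {
  g_mode <- match.arg(g_mode)
  if (is.null(pam_class)) {
    if (!name %in% names(.KNOWN_PROFILES)) {
      stop("unknown Cas system '", name, "': give pam_class explicitly")
    }
    pam_class <- .KNOWN_PROFILES[[name]]
  }
  scaffold <- validate_dna(scaffold, "scaffold")
  if (nchar(scaffold) == 0L) stop("scaffold must be non-empty")
  t7_promoter <- validate_dna(t7_promoter, "t7_promoter")
  structure(
    list(name = name, pam_class = pam_class,
         spec = pam_spec(pam_class, spacer_length = spacer_length),
         scaffold = scaffold, t7_promoter = t7_promoter,
         require_5prime_g = as.integer(require_5prime_g),
         g_mode = g_mode),
    class = "cas_profile"
  )
}

#' @export
print.cas_profile <- function(x, ...) {
  cat("cas_profile ", x$name, ": PAM ", x$pam_class, ", spacer ",
      x$spec$spacer_length, " bp, scaffold ", nchar(x$scaffold),
      " nt, 5'-G rule: ", x$require_5prime_g, "x G (", x$g_mode, ")\n",
      sep = "")
  invisible(x)
}

gc_fraction <- function(x) {
  si <- utf8ToInt(x)
  sum(si == 71L | si == 67L) / length(si)
}

longest_homopolymer <- function(x) {
  r <- rle(strsplit(x, "", fixed = TRUE)[[1]])
  max(r$lengths)
}

#' Design the oligo pair for one target site
#'
#' Assembles the forward oligo (T7 promoter + spacer + the first
#' `overlap_fwd` bases of the scaffold) and the reverse oligo (reverse
#' complement of the scaffold's last `rev_len` bases) for the cloning-free
#' overlap-PCR gRNA template.  If the protospacer does not start with the
#' required number of `G`s for T7 initiation, the profile's `g_mode`
#' decides whether `G`s are prepended (default; lengthens the spacer),
#' substituted in place, or the design rejected.
#'
#' @param site One row of a `site_table` (data frame row or list with at
#'   least `protospacer_seq` and `pam_class`).
#' @param profile A [cas_profile()]; its `pam_class` must equal the
#'   site's.
#' @param overlap_fwd Bases of scaffold appended to the forward oligo
#'   (default 20, minimum 15 for reliable annealing).
#' @param rev_len Length of the reverse scaffold oligo (default 20,
#'   minimum 15).
#' @return An object of class `guide_oligo_set`: `spacer_used`,
#'   `forward_oligo`, `reverse_oligo`, `gc_fraction` (of `spacer_used`),
#'   `prepended_g`, `warnings`, and the originating site fields.
#' @export
design_guide <- function(site, profile, overlap_fwd = 20L, rev_len = 20L) {
  stopifnot(inherits(profile, "cas_profile"))
  site <- as.list(site)
  if (!identical(site$pam_class, profile$pam_class)) {
    stop("PAM class mismatch: site is '", site$pam_class,
         "', profile expects '", profile$pam_class, "'")
  }
  overlap_fwd <- as.integer(overlap_fwd)
  rev_len <- as.integer(rev_len)
  if (overlap_fwd < 15L || rev_len < 15L) {
    stop("overlap_fwd and rev_len must be >= 15 bp for reliable annealing")
  }
  scaf <- profile$scaffold
  if (nchar(scaf) < overlap_fwd || nchar(scaf) < rev_len) {
    stop("scaffold (", nchar(scaf), " nt) shorter than requested overlaps")
  }

  spacer <- validate_dna(site$protospacer_seq, "protospacer")
  warnings <- character(0)
  n_lead_g <- nchar(sub("[^G].*$", "", paste0(spacer, "x")))  # leading-G run
  n_lead_g <- min(n_lead_g, nchar(spacer))
  need <- profile$require_5prime_g
  prepended <- 0L
  if (n_lead_g < need) {
    if (profile$g_mode == "prepend") {
      prepended <- need - n_lead_g
      spacer_used <- paste0(strrep("G", prepended), spacer)
      warnings <- c(warnings, sprintf(
        "prepended %d G for T7 initiation (+%d nt spacer)", prepended, prepended))
    } else if (profile$g_mode == "substitute") {
      spacer_used <- paste0(strrep("G", need),
                            substr(spacer, need + 1L, nchar(spacer)))
      warnings <- c(warnings, sprintf(
        "substituted first %d nt with G for T7 initiation", need))
    } else {
      stop("spacer does not start with ", need,
           " G and profile g_mode is 'reject'")
    }
  } else {
    spacer_used <- spacer
  }

  gc <- gc_fraction(spacer_used)
  if (gc < 0.3 || gc > 0.8) {
    warnings <- c(warnings, sprintf("spacer GC fraction %.2f outside [0.30, 0.80]", gc))
  }
  hp <- longest_homopolymer(spacer_used)
  if (hp >= 5L) {
    warnings <- c(warnings, sprintf("homopolymer run of %d nt in spacer", hp))
  }

  structure(
    list(
      record_id = site$record_id %||% NA_character_,
      strand = site$strand %||% NA_character_,
      protospacer_start = site$protospacer_start %||% NA_integer_,
      pam_class = profile$pam_class,
      protospacer_seq = spacer,
      spacer_used = spacer_used,
      prepended_g = prepended,
      forward_oligo = paste0(profile$t7_promoter, spacer_used,
                             substr(scaf, 1L, overlap_fwd)),
      reverse_oligo = reverse_complement(
        substr(scaf, nchar(scaf) - rev_len + 1L, nchar(scaf))),
      gc_fraction = gc,
      warnings = warnings
    ),
    class = "guide_oligo_set"
  )
}

#' @export
print.guide_oligo_set <- function(x, ...) {
  cat("guide_oligo_set [", x$pam_class, "] spacer ", x$spacer_used,
      if (x$prepended_g > 0) sprintf(" (+%dG)", x$prepended_g), "\n",
      "  fwd: 5'-", x$forward_oligo, "-3'\n",
      "  rev: 5'-", x$reverse_oligo, "-3'\n", sep = "")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Enumerate guide designs across a locus
#'
#' Scans a region (at most 100 kb; this is a locus-level tool, not a
#' genome scanner) with each profile's PAM spec and designs oligos for
#' every site found.  Duplicated profiles yield duplicated outputs; no
#' deduplication is performed.
#'
#' @param region DNA string (the locus) or a single named element of
#'   [read_fasta()] output.
#' @param profiles A [cas_profile()] or list of them.
#' @param record_id Region name for coordinates.
#' @return List of `guide_oligo_set` objects in deterministic
#'   (profile, site) order.
#' @export
enumerate_guides <- function(region, profiles, record_id = "region") {
  if (inherits(profiles, "cas_profile")) profiles <- list(profiles)
  if (!is.null(names(region)) && length(region) == 1L) {
    record_id <- names(region)
    region <- region[[1]]
  }
  if (nchar(region) > 1e5) stop("region exceeds 100 kb; locus-level tool only")
  out <- list()
  for (pr in profiles) {
    sites <- scan_record(region, pr$spec, record_id = record_id)
    if (nrow(sites) == 0L) next
    for (i in seq_len(nrow(sites))) {
      out[[length(out) + 1L]] <- design_guide(sites[i, , drop = FALSE], pr)
    }
  }
  out
}

#' Write guide oligo sets as TSV
#'
#' @param guides List of `guide_oligo_set` objects.
#' @param path Output path or connection.
#' @return Invisibly, the data frame written.
#' @export
write_guides_tsv <- function(guides, path) {
  df <- do.call(rbind, lapply(guides, function(g) {
    data.frame(record_id = g$record_id, strand = g$strand,
               protospacer_start = g$protospacer_start,
               pam_class = g$pam_class,
               protospacer_seq = g$protospacer_seq,
               spacer_used = g$spacer_used,
               forward_oligo = g$forward_oligo,
               reverse_oligo = g$reverse_oligo,
               gc_fraction = g$gc_fraction,
               warnings = paste(g$warnings, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(record_id = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
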