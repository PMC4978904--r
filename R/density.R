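#' Base composition for the i.i.d. sequence model
#'
#' @param pA,pC,pG,pT Base probabilities; must be non-negative and sum to 1
#'   (within 1e-9).  Defaults give the uniform composition.
#' @return Named numeric vector of class `base_composition`.
#' @export
base_composition <- function(pA = 0.25, pC = 0.25, pG = 0.25, pT = 0.25) {
  p <- c(A = pA, C = pC, G = pG, T = pT)
  if (any(p < 0)) stop("base probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("base probabilities must sum to 1")
  structure(p, class = c("base_composition", "numeric"))
}

#' Estimate base composition from sequences
#'
#' Counts A/C/G/T frequencies across all records; `N` bases are excluded
#' from the denominator.
#'
#' @param records Named character vector of sequences.
#' @return A [base_composition()].
#' @export
estimate_composition <- function(records) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (s in records) {
    si <- utf8ToInt(s)
    counts["A"] <- counts["A"] + sum(si == 65L)
    counts["C"] <- counts["C"] + sum(si == 67L)
    counts["G"] <- counts["G"] + sum(si == 71L)
    counts["T"] <- counts["T"] + sum(si == 84L)
  }
  if (sum(counts) == 0) stop("no unambiguous bases to estimate composition from")
  p <- counts / sum(counts)
  base_composition(p["A"], p["C"], p["G"], p["T"])
}

new_density_report <- function(pam_class,
                               p_match_per_strand = NA_real_,
                               expected_rate_both_strands = NA_real_,
                               expected_spacing = NA_real_,
                               observed_count = NA_integer_,
                               scanned_bp = NA_real_,
                               observed_spacing = NA_real_) {
  structure(
    list(pam_class = pam_class,
         p_match_per_strand = p_match_per_strand,
         expected_rate_both_strands = expected_rate_both_strands,
         expected_spacing = expected_spacing,
         observed_count = observed_count,
         scanned_bp = scanned_bp,
         observed_spacing = observed_spacing),
    class = "density_report"
  )
}

#' @export
print.density_report <- function(x, ...) {
  cat("density_report [", x$pam_class, "]\n", sep = "")
  if (!is.na(x$p_match_per_strand)) {
    cat(sprintf("  expected: p = %.6g per strand, rate = %.6g /bp, mean spacing = %s bp\n",
                x$p_match_per_strand, x$expected_rate_both_strands,
                format(x$expected_spacing)))
  }
  if (!is.na(x$observed_count)) {
    cat(sprintf("  observed: %d sites in %s bp, spacing = %s bp\n",
                x$observed_count, format(x$scanned_bp, big.mark = ","),
                format(x$observed_spacing)))
  }
  invisible(x)
}

#' Closed-form expected site density for a PAM pattern
#'
#' Under an i.i.d. base model, the per-strand probability that a window
#' matches is the product over pattern positions of the summed allowed-base
#' probabilities.  Counting both strands, the expected rate is twice that,
#' and the mean spacing between sites is its reciprocal.  For the SaCas9
#' PAM `NNGRRT` under uniform composition this gives
#' p = (1/4)(1/2)^2(1/4) = 1/64 per strand, i.e. one site per 32 bp of
#' random DNA.  Record-edge effects (L - k + 1 windows vs L positions) are
#' ignored: the statement is an asymptotic rate with bias O(k/L).
#'
#' @param pattern An [iupac_pattern()], IUPAC string, or [pam_spec()].
#' @param comp A [base_composition()] (default uniform).
#' @return A `density_report` with the expected fields filled in; a
#'   zero-rate motif reports infinite spacing.
#' @examples
#' expected_density("NNGRRT")$expected_spacing  # 32
#' expected_density("NGG")$expected_spacing     # 8
#' @export
expected_density <- function(pattern, comp = base_composition()) {
  if (inherits(pattern, "pam_spec")) {
    cls <- pattern$class_name
    pattern <- pattern$pattern
  } else {
    pattern <- iupac_pattern(pattern)
    cls <- pattern$name
  }
  comp <- base_composition(comp[["A"]], comp[["C"]], comp[["G"]], comp[["T"]])
  p <- pattern_match_prob(pattern, comp)
  rate <- 2 * p
  new_density_report(cls,
                     p_match_per_strand = p,
                     expected_rate_both_strands = rate,
                     expected_spacing = if (rate > 0) 1 / rate else Inf)
}

#' Empirical site density from a scan
#'
#' @param table A `site_table` from [scan_record()] or [scan_genome()]
#'   (both-strand totals); its `scanned_bp` attribute must be positive.
#' @param pam_class Class name to report; defaults to the table's single
#'   class.
#' @return A `density_report` with the observed fields filled in; zero
#'   sites report infinite spacing.
#' @export
empirical_density <- function(table, pam_class = NULL) {
  bp <- attr(table, "scanned_bp")
  if (is.null(bp) || bp == 0) stop("scanned_bp must be positive")
  if (is.null(pam_class)) {
    cls <- unique(table$pam_class)
    if (length(cls) > 1L) {
      stop("table holds multiple PAM classes; give pam_class explicitly")
    }
    pam_class <- if (length(cls) == 1L) cls else NA_character_
  }
  n <- if (nrow(table) == 0L) 0L else sum(table$pam_class == pam_class)
  new_density_report(pam_class,
                     observed_count = n,
                     scanned_bp = bp,
                     observed_spacing = if (n > 0L) bp / n else Inf)
}

#' Compare expected and observed site densities
#'
#' Poisson z-diagnostic: with E = expected rate x scanned bp,
#' z = (observed - E) / sqrt(E).  Overlapping-occurrence correlations are
#' ignored; the Poisson approximation is adequate for this diagnostic.
#'
#' @param expected A `density_report` from [expected_density()].
#' @param observed A `density_report` from [empirical_density()], same
#'   PAM class.
#' @param threshold Absolute z above which the verdict is `FALSE`
#'   (default 3).
#' @return List with `pam_class`, `expected_count`, `observed_count`,
#'   `z`, and logical `consistent`.
#' @export
compare_densities <- function(expected, observed, threshold = 3) {
  if (!identical(expected$pam_class, observed$pam_class)) {
    stop("PAM class mismatch: '", expected$pam_class, "' vs '",
         observed$pam_class, "'")
  }
  E <- expected$expected_rate_both_strands * observed$scanned_bp
  z <- if (E > 0) (observed$observed_count - E) / sqrt(E)
       else if (observed$observed_count == 0) 0 else Inf
  list(pam_class = expected$pam_class,
       expected_count = E,
       observed_count = observed$observed_count,
       z = z,
       consistent = is.finite(z) && abs(z) <= threshold)
}

#' Density report table for several PAM classes
#'
#' Convenience wrapper combining [expected_density()],
#' [empirical_density()] and [compare_densities()] over the result of
#' [scan_genome()].
#'
#' @param tables Named list of `site_table`s (one per class).
#' @param comp A [base_composition()].
#' @param specs Optional named list of [pam_spec()]s giving each class's
#'   pattern; by default the class name itself is parsed as the pattern
#'   (true for the six standard classes).
#' @return Data frame with one row per class: probabilities, expected and
#'   observed rates/spacings, and the Poisson z.
#' @export
density_table <- function(tables, comp = base_composition(), specs = NULL) {
  rows <- lapply(names(tables), function(cl) {
    pat <- if (!is.null(specs) && !is.null(specs[[cl]])) specs[[cl]]$pattern
           else iupac_pattern(cl)
    e <- expected_density(pat, comp)
    e$pam_class <- cl
    o <- empirical_density(tables[[cl]], pam_class = cl)
    cmp <- compare_densities(e, o)
    data.frame(pam_class = cl,
               p_match_per_strand = e$p_match_per_strand,
               expected_rate_both_strands = e$expected_rate_both_strands,
               expected_spacing_bp = e$expected_spacing,
               observed_count = o$observed_count,
               scanned_bp = o$scanned_bp,
               observed_spacing_bp = o$observed_spacing,
               z = cmp$z,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
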