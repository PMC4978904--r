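#' Parse exon intervals from BED or GFF3
#'
#' BED (3 or 6+ columns) is read as-is (0-based half-open).  GFF3 keeps
#' only lines whose feature type is `exon` and converts their 1-based
#' closed coordinates to 0-based half-open.  Malformed coordinates are
#' reported with their line number.
#'
#' @param x Path to a file, or text (vector of lines / single string).
#' @param format `"auto"` (default; GFF3 if the first data line has 9
#'   tab-separated fields or a `##gff` pragma is present), `"bed"`, or
#'   `"gff3"`.
#' @return Data frame with columns `record_id`, `start`, `end` (0-based
#'   half-open), `name`, `strand` (`+`, `-` or `.`).
#' @export
parse_intervals <- function(x, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else if (length(x) == 1L && grepl("\n", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    x
  }
  is_data <- nzchar(lines) & !startsWith(lines, "#")
  if (format == "auto") {
    first <- lines[is_data][1]
    n_fields <- if (is.na(first)) 0L else length(strsplit(first, "\t", fixed = TRUE)[[1]])
    format <- if (any(startsWith(lines, "##gff")) || n_fields == 9L) "gff3" else "bed"
  }

  out <- list()
  for (i in seq_along(lines)) {
    if (!is_data[i]) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (format == "bed") {
      if (length(f) < 3L) {
        stop("BED parse error at line ", i, ": fewer than 3 fields")
      }
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      if (is.na(s) || is.na(e)) {
        stop("BED parse error at line ", i, ": non-integer coordinates")
      }
      if (s < 0L || e <= s) {
        stop("BED parse error at line ", i, ": require 0 <= start < end")
      }
      out[[length(out) + 1L]] <- data.frame(
        record_id = f[1], start = s, end = e,
        name = if (length(f) >= 4L) f[4] else ".",
        strand = if (length(f) >= 6L && f[6] %in% c("+", "-")) f[6] else ".",
        stringsAsFactors = FALSE
      )
    } else {
      if (length(f) < 9L) {
        stop("GFF3 parse error at line ", i, ": fewer than 9 fields")
      }
      if (tolower(f[3]) != "exon") next
      s <- suppressWarnings(as.integer(f[4]))
      e <- suppressWarnings(as.integer(f[5]))
      if (is.na(s) || is.na(e)) {
        stop("GFF3 parse error at line ", i, ": non-integer coordinates")
      }
      if (s < 1L || e < s) {
        stop("GFF3 parse error at line ", i, ": require 1 <= start <= end")
      }
      attr_str <- f[9]
      nm <- NA_character_
      for (key in c("ID=", "Name=", "Parent=")) {
        m <- regmatches(attr_str, regexpr(paste0(key, "[^;]+"), attr_str))
        if (length(m) == 1L) { nm <- sub(key, "", m, fixed = TRUE); break }
      }
      out[[length(out) + 1L]] <- data.frame(
        record_id = f[1], start = s - 1L, end = e,
        name = if (is.na(nm)) "." else nm,
        strand = if (f[7] %in% c("+", "-")) f[7] else ".",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Intersect target sites with exon intervals
#'
#' A site's interval is the union of its protospacer and PAM (the whole
#' editable locus).  Under `any_overlap` a site is exonic when at least one
#' bp of that interval overlaps at least one exon; under `full_containment`
#' it must lie entirely within a single exon.  Half-open adjacency is not
#' overlap.  Exon strand is ignored (a Cas9 site on either strand disrupts
#' an exon); overlapping exon annotations are not merged, and a site lists
#' each overlapping exon once.
#'
#' @param table A `site_table` (possibly multi-class, see
#'   [combine_sites()]).
#' @param exons Exon data frame from [parse_intervals()] or
#'   [generate_exons()].
#' @param mode `"any_overlap"` (default) or `"full_containment"`.
#' @return An `annotated_site_table`: the site data frame plus columns
#'   `exons` (comma-separated overlapping exon names, `""` if none) and
#'   `exonic` (logical); attributes `per_class_counts` (data frame with
#'   `pam_class`, `total_sites`, `exonic_sites`), `scanned_bp`, and
#'   `exon_bp` (merged exon footprint).
#' @export
intersect_sites <- function(table, exons, mode = c("any_overlap", "full_containment")) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  us <- pmin(df$protospacer_start, df$pam_start)
  ue <- pmax(df$protospacer_end, df$pam_end)

  exon_names <- rep("", nrow(df))
  if (nrow(df) > 0L && nrow(exons) > 0L) {
    ov_type <- if (mode == "any_overlap") "any" else "within"
    for (rid in unique(df$record_id)) {
      si <- which(df$record_id == rid)
      ei <- which(exons$record_id == rid)
      if (length(ei) == 0L) next
      # half-open [s,e) -> 1-based closed [s+1, e]
      q <- IRanges::IRanges(start = us[si] + 1L, end = ue[si])
      s <- IRanges::IRanges(start = exons$start[ei] + 1L, end = exons$end[ei])
      hits <- IRanges::findOverlaps(q, s, type = ov_type)
      if (length(hits) == 0L) next
      qh <- S4Vectors::queryHits(hits)
      nm <- exons$name[ei][S4Vectors::subjectHits(hits)]
      agg <- tapply(nm, qh, function(v) paste(sort(unique(v)), collapse = ","))
      exon_names[si[as.integer(names(agg))]] <- as.character(agg)
    }
  }
  df$exons <- exon_names
  df$exonic <- nzchar(exon_names)

  classes <- sort(unique(df$pam_class))
  per_class <- data.frame(
    pam_class = classes,
    total_sites = vapply(classes, function(cl) sum(df$pam_class == cl), integer(1)),
    exonic_sites = vapply(classes, function(cl) sum(df$exonic[df$pam_class == cl]), integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_class) <- NULL

  exon_bp <- 0
  if (nrow(exons) > 0L) {
    exon_bp <- sum(vapply(split(exons, exons$record_id), function(e) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = e$start + 1L, end = e$end))))
    }, numeric(1)))
  }

  rownames(df) <- NULL
  structure(df,
            per_class_counts = per_class,
            scanned_bp = attr(table, "scanned_bp"),
            exon_bp = exon_bp,
            mode = mode,
            class = c("annotated_site_table", "data.frame"))
}

#' @export
print.annotated_site_table <- function(x, ...) {
  pc <- attr(x, "per_class_counts")
  cat("annotated_site_table: ", nrow(x), " site(s), ",
      sum(x$exonic), " exonic (mode ", attr(x, "mode"), ")\n", sep = "")
  print.data.frame(pc)
  invisible(x)
}

#' Summarize per-class exonic availability
#'
#' @param annotated An `annotated_site_table` from [intersect_sites()].
#' @return Data frame with one row per PAM class: `pam_class`,
#'   `total_sites`, `exonic_sites`, `sites_per_kb_scanned`, and
#'   `sites_per_kb_exon` (exonic sites per kb of merged exon footprint;
#'   `NA` when no exons were provided).
#' @export
summarize_availability <- function(annotated) {
  pc <- attr(annotated, "per_class_counts")
  bp <- attr(annotated, "scanned_bp")
  ebp <- attr(annotated, "exon_bp")
  pc$sites_per_kb_scanned <- if (bp > 0) pc$total_sites / (bp / 1000)
                             else rep(0, nrow(pc))
  pc$sites_per_kb_exon <- if (ebp > 0) pc$exonic_sites / (ebp / 1000)
                          else rep(NA_real_, nrow(pc))
  pc
}

#' Write an annotated site table as BED6 with exon annotations
#'
#' BED6 as in [write_bed()], with the name field extended to
#' `"<class>|<protospacer>|<pam>|exonic:<e1,e2>"` for exonic sites.
#'
#' @param annotated An `annotated_site_table`.
#' @param path Output path or connection.
#' @param span `"union"` or `"pam"`.
#' @return Invisibly, the number of lines written.
#' @export
write_annotated_bed <- function(annotated, path, span = c("union", "pam")) {
  span <- match.arg(span)
  lines <- annotated_bed_lines(annotated, span)
  writeLines(lines, path)
  invisible(length(lines))
}

annotated_bed_lines <- function(annotated, span = "union") {
  df <- as.data.frame(annotated)
  if (nrow(df) == 0L) return(character(0))
  if (span == "union") {
    s <- pmin(df$protospacer_start, df$pam_start)
    e <- pmax(df$protospacer_end, df$pam_end)
  } else {
    s <- df$pam_start
    e <- df$pam_end
  }
  name <- paste(df$pam_class, df$protospacer_seq, df$pam_seq, sep = "|")
  name <- ifelse(df$exonic, paste0(name, "|exonic:", df$exons), name)
  paste(df$record_id, s, e, name, 0L, df$strand, sep = "\t")
}
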