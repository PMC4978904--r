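# End-to-end orchestration: scan -> annotate -> density -> report.
# Classed error conditions give the command-line wrapper a stable
# exit-code contract (missing input = 2, parse failure = 3, internal
# invariant violation = 4).

pam_abort <- function(class, msg) {
  stop(structure(class = c(class, "pamscape_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Read a pipeline configuration file
#'
#' Plain `key = value` lines; `#` starts a comment.  Recognised keys:
#' `genome` (FASTA path, or the token `synthetic`), `exons` (BED/GFF3
#' path, `synthetic`, or absent), `pam_classes` (comma-separated; default
#' the six standard classes), `spacer_length`, `bed_span` (`union`/`pam`),
#' `composition` (`uniform`/`empirical`), `outdir`, `seed`, and for
#' synthetic inputs `record_length`, `n_records`, `n_exons`,
#' `exon_length_min`, `exon_length_max`.
#'
#' @param path Config file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    pam_abort("pamscape_missing_input", paste0("config file not found: ", path))
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    pam_abort("pamscape_parse", paste0("config parse error at: ",
                                       lines[which(bad)[1]]))
  }
  cfg <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, character(1), 1L))
  defaults <- list(pam_classes = "NGG,NGA,NNGRRN,NNGRRT,NNNRRN,NNNRRT",
                   spacer_length = "20", bed_span = "union",
                   composition = "uniform", outdir = "pamscape_out",
                   seed = "1", record_length = "100000", n_records = "1",
                   n_exons = "20", exon_length_min = "100",
                   exon_length_max = "300")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$genome)) {
    pam_abort("pamscape_parse", "config is missing required key 'genome'")
  }
  structure(cfg, class = "pipeline_config")
}

write_atomic <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    pam_abort("pamscape_invariant", paste0("atomic rename failed for ", path))
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    pam_abort("pamscape_invariant", paste0("atomic rename failed for ", path))
  }
  invisible(path)
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[pamscape:%s] %s", stage, paste0(...)))
}

#' Run the full scan / annotate / density pipeline
#'
#' Loads (or synthesises) the genome, scans every configured PAM class on
#' both strands, writes one BED file per class, intersects sites with
#' exons when provided (annotated BED + availability summary TSV), writes
#' the density report TSV (closed-form expectation vs observation with a
#' Poisson z per class), and finally a manifest TSV listing every output
#' with its MD5 checksum.  All files are written atomically (temp file +
#' rename), so a failed stage never leaves truncated outputs, and reruns
#' with an unchanged config are byte-identical.
#'
#' @param config A `pipeline_config` from [read_pipeline_config()], a path
#'   to a config file, or a named list of the same keys.
#' @param outdir Optional output-directory override.
#' @return Invisibly, a list with `status` (0), `outdir`, and `manifest`
#'   (data frame `file`, `md5`, `bytes`).  Failures signal classed
#'   conditions: `pamscape_missing_input`, `pamscape_parse`,
#'   `pamscape_invariant`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  cfg <- as.list(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  seed <- as.integer(cfg$seed)

  # --- load inputs (validate everything before writing anything) ----------
  if (identical(cfg$genome, "synthetic")) {
    pipeline_log("load", "generating synthetic genome (", cfg$n_records,
                 " x ", cfg$record_length, " bp, seed ", seed, ")")
    genome <- generate_genome(as.integer(cfg$n_records),
                              as.integer(cfg$record_length),
                              seed = seed)
  } else {
    if (!file.exists(cfg$genome)) {
      pam_abort("pamscape_missing_input",
                paste0("genome file not found: ", cfg$genome))
    }
    genome <- tryCatch(read_fasta(cfg$genome), error = function(e) {
      pam_abort("pamscape_parse", conditionMessage(e))
    })
  }

  exons <- NULL
  if (!is.null(cfg$exons)) {
    if (identical(cfg$exons, "synthetic")) {
      exons <- generate_exons(genome, as.integer(cfg$n_exons),
                              c(as.integer(cfg$exon_length_min),
                                as.integer(cfg$exon_length_max)),
                              seed = seed + 1L)
    } else {
      if (!file.exists(cfg$exons)) {
        pam_abort("pamscape_missing_input",
                  paste0("exon file not found: ", cfg$exons))
      }
      exons <- tryCatch(parse_intervals(cfg$exons), error = function(e) {
        pam_abort("pamscape_parse", conditionMessage(e))
      })
    }
  }

  classes <- trimws(strsplit(cfg$pam_classes, ",", fixed = TRUE)[[1]])
  if (length(classes) == 0L) {
    pam_abort("pamscape_parse", "pam_classes is empty")
  }
  specs <- lapply(classes, pam_spec,
                  spacer_length = as.integer(cfg$spacer_length))
  names(specs) <- classes
  span <- match.arg(cfg$bed_span, c("union", "pam"))

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  # --- scan ---------------------------------------------------------------
  t0 <- Sys.time()
  tables <- scan_genome(genome, specs)
  pipeline_log("scan", sum(vapply(tables, nrow, integer(1))), " sites in ",
               sum(nchar(genome)), " bp across ", length(classes),
               " classes (", sprintf("%.1fs", as.numeric(Sys.time() - t0, "secs")), ")")
  for (cl in classes) {
    f <- file.path(cfg$outdir, paste0("sites_", cl, ".bed"))
    write_atomic(bed_lines(tables[[cl]], span), f)
    written <- c(written, f)
  }

  # --- annotate -----------------------------------------------------------
  if (!is.null(exons)) {
    combined <- combine_sites(tables)
    annotated <- intersect_sites(combined, exons)
    pipeline_log("annotate", sum(annotated$exonic), " of ", nrow(annotated),
                 " sites exonic over ", nrow(exons), " exon intervals")
    f <- file.path(cfg$outdir, "sites_annotated.bed")
    write_atomic(annotated_bed_lines(annotated, span), f)
    written <- c(written, f)
    f <- file.path(cfg$outdir, "availability.tsv")
    write_tsv_atomic(summarize_availability(annotated), f)
    written <- c(written, f)
  }

  # --- density ------------------------------------------------------------
  comp <- if (identical(cfg$composition, "empirical")) {
    estimate_composition(genome)
  } else {
    base_composition()
  }
  dens <- density_table(tables, comp, specs)
  pipeline_log("density", "max |z| = ",
               sprintf("%.2f", max(abs(dens$z[is.finite(dens$z)]))))
  f <- file.path(cfg$outdir, "density.tsv")
  write_tsv_atomic(dens, f)
  written <- c(written, f)

  # --- manifest -----------------------------------------------------------
  manifest <- data.frame(
    file = basename(written),
    md5 = unname(tools::md5sum(written)),
    bytes = unname(file.size(written)),
    stringsAsFactors = FALSE
  )
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write_tsv_atomic(manifest, file.path(cfg$outdir, "manifest.tsv"))
  pipeline_log("done", length(written), " artifact(s) in ", cfg$outdir)
  invisible(list(status = 0L, outdir = cfg$outdir, manifest = manifest))
}
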