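# Seeded generators for every input the pipeline consumes: i.i.d. random
# genomes, exon intervals, planted PAM-bearing sites at known coordinates,
# and mutant alleles with known indels.  All are deterministic for a fixed
# seed and leave the caller's RNG state untouched.

local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a random genome of i.i.d. bases
#'
#' Emulates the "random DNA" model underlying closed-form site-density
#' expectations: each base drawn independently from the given composition.
#'
#' @param n_records Number of records.
#' @param record_length Length of each record in bp (recycled to
#'   `n_records`).
#' @param composition A [base_composition()] (default uniform).
#' @param seed Integer seed; identical inputs give identical output.
#' @return Named character vector of sequences with ids `syn1..synN`.
#' @export
generate_genome <- function(n_records = 1L, record_length = 1000L,
                            composition = base_composition(), seed = 1L) {
  record_length <- rep_len(as.integer(record_length), n_records)
  local_seed(seed, {
    seqs <- vapply(seq_len(n_records), function(i) {
      paste(sample(c("A", "C", "G", "T"), record_length[i], replace = TRUE,
                   prob = as.numeric(composition)), collapse = "")
    }, character(1))
    names(seqs) <- paste0("syn", seq_len(n_records))
    seqs
  })
}

#' Plant concrete PAM-bearing target sites at known coordinates
#'
#' Overwrites each requested window with a concrete realisation of the PAM
#' pattern (degenerate positions sampled uniformly from their allowed
#' sets), leaving every other base untouched.  `offset` is the 0-based
#' forward-strand start of the PAM window; on the `-` strand the pattern
#' is realised on the reverse strand and its reverse complement written at
#' the forward coordinates.  Each position must leave full spacer room so
#' the scanner is guaranteed to recover the planted site.
#'
#' @param records Named character vector of sequences.
#' @param pattern [iupac_pattern()] or IUPAC string to plant.
#' @param at Data frame with columns `record` (index or id), `offset`
#'   (0-based PAM start, forward coordinates) and `strand` (`+`/`-`).
#' @param spacer_length Spacer room to enforce (default 20).
#' @param seed Integer seed for sampling degenerate positions.
#' @return The modified records; attribute `planted` holds a truth table
#'   (`record_id`, `offset`, `strand`, `pam_seq` as read on the targeted
#'   strand).
#' @export
plant_sites <- function(records, pattern, at, spacer_length = 20L, seed = 1L) {
  pattern <- iupac_pattern(pattern)
  k <- length(pattern$symbols)
  if (nrow(at) == 0L) {
    attr(records, "planted") <- data.frame(record_id = character(0),
                                           offset = integer(0),
                                           strand = character(0),
                                           pam_seq = character(0),
                                           stringsAsFactors = FALSE)
    return(records)
  }
  idx <- if (is.character(at$record)) match(at$record, names(records)) else as.integer(at$record)
  if (anyNA(idx) || any(idx < 1L | idx > length(records))) {
    stop("plant position references an unknown record")
  }
  # overlap / range / spacer-room checks
  for (i in seq_len(nrow(at))) {
    L <- nchar(records[[idx[i]]])
    off <- at$offset[i]
    if (off < 0L || off + k > L) stop("planted window out of range")
    room <- if (at$strand[i] == "+") off else L - (off + k)
    if (room < spacer_length) stop("planted site lacks spacer room")
  }
  windows <- data.frame(rec = idx, s = at$offset, e = at$offset + k)
  windows <- windows[order(windows$rec, windows$s), ]
  if (nrow(windows) > 1L) {
    same <- windows$rec[-1] == windows$rec[-nrow(windows)]
    if (any(same & windows$s[-1] < windows$e[-nrow(windows)])) {
      stop("planted windows overlap")
    }
  }
  local_seed(seed, {
    truth <- vector("list", nrow(at))
    for (i in seq_len(nrow(at))) {
      concrete <- paste(vapply(pattern$sets,
                               function(set) sample(set, 1L)[[1]],
                               character(1)), collapse = "")
      fwd_text <- if (at$strand[i] == "+") concrete else reverse_complement(concrete)
      s <- records[[idx[i]]]
      substr(s, at$offset[i] + 1L, at$offset[i] + k) <- fwd_text
      records[[idx[i]]] <- s
      truth[[i]] <- data.frame(record_id = names(records)[idx[i]],
                               offset = at$offset[i], strand = at$strand[i],
                               pam_seq = concrete, stringsAsFactors = FALSE)
    }
    attr(records, "planted") <- do.call(rbind, truth)
    records
  })
}

#' Generate random exon intervals over a genome
#'
#' Uniformly placed, possibly overlapping intervals; deterministic for a
#' fixed seed.
#'
#' @param records Named character vector of sequences.
#' @param n_exons Number of intervals.
#' @param length_range Two-element integer vector `c(min, max)` of exon
#'   lengths in bp.
#' @param seed Integer seed.
#' @return Exon data frame as from [parse_intervals()] (`record_id`,
#'   `start`, `end`, `name`, `strand`).
#' @export
generate_exons <- function(records, n_exons, length_range = c(100L, 300L),
                           seed = 1L) {
  if (n_exons == 0L) {
    return(data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  lens <- nchar(records)
  if (min(lens) < length_range[2]) {
    stop("length_range exceeds the shortest record")
  }
  local_seed(seed, {
    rec <- sample(seq_along(records), n_exons, replace = TRUE)
    w <- sample(seq.int(length_range[1], length_range[2]), n_exons, replace = TRUE)
    start <- vapply(seq_len(n_exons), function(i) {
      sample.int(lens[rec[i]] - w[i] + 1L, 1L) - 1L
    }, integer(1))
    data.frame(record_id = names(records)[rec],
               start = start, end = start + w,
               name = paste0("exon", seq_len(n_exons)),
               strand = sample(c("+", "-"), n_exons, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

#' Generate mutant alleles with known indels
#'
#' Applies specified insertion/deletion events to a reference amplicon and
#' returns the mutated alleles together with a truth table for recovery
#' tests.  Event positions are 0-based reference coordinates: a deletion
#' at `position` removes `length` reference bases starting there; an
#' insertion places `seq` (or `length` random bases) immediately before
#' the base at `position`.  Events within one allele must not overlap.
#'
#' @param reference DNA string (the amplicon).
#' @param events_per_allele List (one element per distinct allele) of data
#'   frames with columns `kind` (`insertion`/`deletion`), `position`,
#'   `length`, and optionally `seq` for insertions.
#' @param n_copies Copies of each allele to emit (recycled).
#' @param seed Integer seed for sampling unspecified insertion bases.
#' @return List with `alleles` (named character vector,
#'   `allele<i>_copy<j>`) and `truth` (data frame of planted events with
#'   `allele`, `kind`, `position`, `length`, `inserted_seq`).
#' @export
generate_mutant_alleles <- function(reference, events_per_allele,
                                    n_copies = 1L, seed = 1L) {
  reference <- validate_dna(reference)
  n_copies <- rep_len(as.integer(n_copies), length(events_per_allele))
  local_seed(seed, {
    alleles <- character(0)
    truth <- list()
    for (a in seq_along(events_per_allele)) {
      ev <- events_per_allele[[a]]
      if (is.null(ev) || nrow(ev) == 0L) {
        ev <- data.frame(kind = character(0), position = integer(0),
                         length = integer(0), stringsAsFactors = FALSE)
      }
      if (!"seq" %in% names(ev)) ev$seq <- rep(NA_character_, nrow(ev))
      ev <- ev[order(ev$position), , drop = FALSE]
      # overlap check on reference footprints (insertions are points)
      if (nrow(ev) > 1L) {
        foot_end <- ev$position + ifelse(ev$kind == "deletion", ev$length, 0L)
        if (any(ev$position[-1] < foot_end[-nrow(ev)])) {
          stop("events overlap on the reference")
        }
      }
      s <- reference
      for (i in rev(seq_len(nrow(ev)))) {   # apply right-to-left
        p <- ev$position[i]
        if (ev$kind[i] == "deletion") {
          if (p + ev$length[i] > nchar(reference)) stop("deletion out of range")
          s <- paste0(substr(s, 1L, p), substr(s, p + ev$length[i] + 1L, nchar(s)))
        } else {
          ins <- ev$seq[i]
          if (is.na(ins)) {
            ins <- paste(sample(c("A", "C", "G", "T"), ev$length[i],
                                replace = TRUE), collapse = "")
            ev$seq[i] <- ins
          }
          s <- paste0(substr(s, 1L, p), ins, substr(s, p + 1L, nchar(s)))
        }
      }
      for (j in seq_len(n_copies[a])) {
        alleles[[paste0("allele", a, "_copy", j)]] <- s
      }
      if (nrow(ev) > 0L) {
        truth[[a]] <- data.frame(allele = a, kind = ev$kind,
                                 position = ev$position, length = ev$length,
                                 inserted_seq = ifelse(ev$kind == "insertion",
                                                       ev$seq, ""),
                                 stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth) == 0L) {
      data.frame(allele = integer(0), kind = character(0),
                 position = integer(0), length = integer(0),
                 inserted_seq = character(0), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, c(truth, list(make.row.names = FALSE)))
    }
    list(alleles = alleles, truth = truth)
  })
}
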