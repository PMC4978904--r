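# Independent oracles used to cross-check the package implementation.
# They deliberately take different routes: the scanner oracle uses perl
# lookahead regexes on the forward sequence only (reverse-strand sites are
# found by matching the reverse-complemented *pattern*, never by
# reverse-complementing the sequence); reverse complement is delegated to
# Biostrings; interval overlap is a literal O(n*m) double loop.

.ORACLE_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                     R = "AG", Y = "CT", S = "CG", W = "AT",
                     K = "GT", M = "AC", B = "CGT", D = "AGT",
                     H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(pattern_str) {
  syms <- strsplit(pattern_str, "", fixed = TRUE)[[1]]
  paste0(vapply(syms, function(s) paste0("[", .ORACLE_SETS[[s]], "]"),
                character(1)), collapse = "")
}

revcomp_pattern_str <- function(p) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(p, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_revcomp <- function(x) {
  unname(as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x))))
}

regex_starts <- function(seq, re) {
  m <- gregexpr(paste0("(?=", re, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

# Independent site enumeration for one record and one PAM class.
oracle_scan <- function(seq, pattern_str, spacer, record_id = "seq") {
  L <- nchar(seq)
  k <- nchar(pattern_str)
  empty <- data.frame(
    record_id = character(0), strand = character(0),
    protospacer_start = integer(0), protospacer_end = integer(0),
    pam_start = integer(0), pam_end = integer(0),
    protospacer_seq = character(0), pam_seq = character(0),
    pam_class = character(0), stringsAsFactors = FALSE)
  if (L < k + spacer) return(empty)

  parts <- list()
  # forward strand
  i <- regex_starts(seq, iupac_regex(pattern_str))
  i <- i[i > spacer]
  if (length(i) > 0L) {
    proto <- substring(seq, i - spacer, i - 1L)
    keep <- !grepl("N", proto, fixed = TRUE)
    i <- i[keep]; proto <- proto[keep]
    if (length(i) > 0L) {
      parts$fwd <- data.frame(
        record_id = record_id, strand = "+",
        protospacer_start = as.integer(i - 1L - spacer),
        protospacer_end = as.integer(i - 1L),
        pam_start = as.integer(i - 1L),
        pam_end = as.integer(i - 1L + k),
        protospacer_seq = proto,
        pam_seq = substring(seq, i, i + k - 1L),
        pam_class = pattern_str, stringsAsFactors = FALSE)
    }
  }
  # reverse strand: match the reverse-complemented pattern on the forward
  # sequence; spacer lies 3' of the matched window in forward coordinates
  a <- regex_starts(seq, iupac_regex(revcomp_pattern_str(pattern_str)))
  a <- a[a - 1L + k + spacer <= L]
  if (length(a) > 0L) {
    proto_f <- substring(seq, a + k, a + k + spacer - 1L)
    keep <- !grepl("N", proto_f, fixed = TRUE)
    a <- a[keep]; proto_f <- proto_f[keep]
    if (length(a) > 0L) {
      parts$rev <- data.frame(
        record_id = record_id, strand = "-",
        protospacer_start = as.integer(a - 1L + k),
        protospacer_end = as.integer(a - 1L + k + spacer),
        pam_start = as.integer(a - 1L),
        pam_end = as.integer(a - 1L + k),
        protospacer_seq = oracle_revcomp(proto_f),
        pam_seq = oracle_revcomp(substring(seq, a, a + k - 1L)),
        pam_class = pattern_str, stringsAsFactors = FALSE)
    }
  }
  if (length(parts) == 0L) return(empty)
  df <- do.call(rbind, parts)
  start <- pmin(df$protospacer_start, df$pam_start)
  df <- df[order(df$record_id, start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Literal O(sites x exons) overlap check.
brute_intersect <- function(us, ue, rec, exons, mode) {
  n <- length(us)
  exonic <- logical(n)
  names_list <- character(n)
  for (i in seq_len(n)) {
    hits <- character(0)
    for (j in seq_len(nrow(exons))) {
      if (exons$record_id[j] != rec[i]) next
      ok <- if (mode == "any_overlap") {
        us[i] < exons$end[j] && exons$start[j] < ue[i]
      } else {
        exons$start[j] <= us[i] && ue[i] <= exons$end[j]
      }
      if (ok) hits <- c(hits, exons$name[j])
    }
    exonic[i] <- length(hits) > 0L
    names_list[i] <- paste(sort(unique(hits)), collapse = ",")
  }
  list(exonic = exonic, names = names_list)
}

random_dna <- function(n, probs = rep(0.25, 4), n_rate = 0) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs)
  if (n_rate > 0) {
    idx <- which(stats::runif(n) < n_rate)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

# site_table -> bare data frame comparable with oracle output
as_plain_df <- function(x) {
  x <- as.data.frame(x)
  attr(x, "scanned_bp") <- NULL
  rownames(x) <- NULL
  x
}

site_key <- function(df) {
  paste(df$record_id, df$pam_start, df$pam_end, df$strand, sep = ":")
}
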