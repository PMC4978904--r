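spec_ngg2 <- pam_spec("NGG", spacer_length = 2)

test_that("forward-strand site is reported with adjacent protospacer and PAM", {
  st <- scan_record("ATACGG", spec_ngg2, "t")
  expect_equal(nrow(st), 1L)
  expect_equal(st$strand, "+")
  expect_equal(st$protospacer_start, 1L)
  expect_equal(st$protospacer_end, 3L)
  expect_equal(st$pam_start, 3L)
  expect_equal(st$pam_end, 6L)
  expect_equal(st$protospacer_seq, "TA")
  expect_equal(st$pam_seq, "CGG")
})

test_that("reverse-strand site is mapped back to forward coordinates", {
  # reverse complement of the forward example; strand-symmetry oracle
  st <- scan_record("CCGTAT", spec_ngg2, "t")
  expect_equal(nrow(st), 1L)
  expect_equal(st$strand, "-")
  expect_equal(st$pam_start, 0L)
  expect_equal(st$pam_end, 3L)
  expect_equal(st$protospacer_start, 3L)
  expect_equal(st$protospacer_end, 5L)
  expect_equal(st$protospacer_seq, "TA")
  expect_equal(st$pam_seq, "CGG")
})

test_that("empty records, spacer-room edges and ambiguous bases suppress sites", {
  expect_equal(nrow(scan_record("", spec_ngg2)), 0L)
  # PAM at the very start: no spacer room on '+'
  expect_equal(nrow(scan_record("AGG", spec_ngg2)), 0L)
  # N in the spacer suppresses the site
  expect_equal(nrow(scan_record("ANACGG", spec_ngg2)), 0L)
  # N opposite pattern N suppresses the match itself
  expect_equal(nrow(scan_record("ATANGG", spec_ngg2)), 0L)
})

test_that("scanner equals the regex oracle on random sequences with N and edge cases", {
  set.seed(101)
  classes <- names(pam_six_classes())
  seqs <- c(
    replicate(25, random_dna(sample(50:2000, 1),
                             probs = as.numeric(base_composition()),
                             n_rate = sample(c(0, 0.02), 1))),
    # AT-rich and GC-rich compositions
    replicate(5, random_dna(500, probs = c(0.4, 0.1, 0.1, 0.4))),
    replicate(5, random_dna(500, probs = c(0.1, 0.4, 0.4, 0.1))),
    # shorter than spacer+PAM, exactly spacer+PAM
    "ACGT", paste0(strrep("A", 20), "TGGAGT")
  )
  for (s in seqs) {
    for (cl in classes) {
      spec <- pam_spec(cl, spacer_length = 20)
      got <- as_plain_df(scan_record(s, spec, "r"))
      want <- oracle_scan(s, cl, 20, "r")
      expect_identical(got, want)
    }
  }
})

test_that("scanning a reverse-complemented record swaps strand labels and counts", {
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(800)
    a <- scan_record(s, pam_spec("NNGRRT", spacer_length = 20))
    b <- scan_record(reverse_complement(s), pam_spec("NNGRRT", spacer_length = 20))
    expect_equal(nrow(a), nrow(b))
    expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
    expect_equal(sum(a$strand == "-"), sum(b$strand == "+"))
  }
})

test_that("pattern containment forces site-set subset relations", {
  set.seed(23)
  g <- generate_genome(2, 3000, seed = 23)
  tabs <- scan_genome(g, pam_six_classes())
  expect_true(all(site_key(tabs$NNGRRT) %in% site_key(tabs$NNGRRN)))
  expect_true(all(site_key(tabs$NNGRRN) %in% site_key(tabs$NNNRRN)))
  expect_true(all(site_key(tabs$NNGRRT) %in% site_key(tabs$NNNRRT)))
  expect_true(all(site_key(tabs$NNNRRT) %in% site_key(tabs$NNNRRN)))
})

test_that("genome scans count repeated-motif records like the oracle and share scanned_bp", {
  rep_seq <- strrep("AGGT", 250)  # 1 kb
  tabs <- scan_genome(c(chr = rep_seq), pam_spec("NGG", spacer_length = 20))
  expect_equal(nrow(tabs$NGG), nrow(oracle_scan(rep_seq, "NGG", 20, "chr")))
  expect_equal(attr(tabs$NGG, "scanned_bp"), 1000)

  empty <- scan_genome(character(0), pam_six_classes())
  expect_equal(vapply(empty, nrow, integer(1)),
               c(NGG = 0L, NGA = 0L, NNGRRN = 0L, NNGRRT = 0L,
                 NNNRRN = 0L, NNNRRT = 0L))
  expect_equal(unique(vapply(empty, attr, numeric(1), "scanned_bp")), 0)

  expect_error(
    scan_genome(c(chr = "ACGT"), list(pam_spec("NGG"), pam_spec("NGG"))),
    "duplicate")
})

test_that("BED output is bit-exact BED6 and round-trips through parsing", {
  st1 <- scan_record("ATACGG", spec_ngg2, "t")
  st2 <- scan_record("CCGTAT", spec_ngg2, "t")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(st1, f)
  expect_identical(readLines(f), "t\t1\t6\tNGG|TA|CGG\t0\t+")
  write_bed(st2, f)
  expect_identical(readLines(f), "t\t0\t5\tNGG|TA|CGG\t0\t-")
  # PAM-only span preserves the narrow reading
  write_bed(st2, f, span = "pam")
  expect_identical(readLines(f), "t\t0\t3\tNGG|TA|CGG\t0\t-")
  # empty table -> empty file
  write_bed(scan_record("", spec_ngg2), f)
  expect_identical(readLines(f), character(0))

  # round-trip: every interval, name and strand recovered exactly
  set.seed(5)
  g <- generate_genome(1, 4000, seed = 77)
  st <- scan_genome(g, pam_spec("NNGRRT", spacer_length = 20))$NNGRRT
  write_bed(st, f)
  bed <- parse_intervals(f, format = "bed")
  expect_equal(bed$record_id, st$record_id)
  expect_equal(bed$start, pmin(st$protospacer_start, st$pam_start))
  expect_equal(bed$end, pmax(st$protospacer_end, st$pam_end))
  expect_equal(bed$strand, st$strand)
  expect_equal(bed$name,
               paste(st$pam_class, st$protospacer_seq, st$pam_seq, sep = "|"))
})
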