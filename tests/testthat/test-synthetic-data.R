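test_that("genome generation is seeded, composition-faithful and leaves RNG alone", {
  g <- generate_genome(3, c(100, 200, 300), seed = 7)
  expect_equal(names(g), c("syn1", "syn2", "syn3"))
  expect_equal(nchar(g), c(syn1 = 100L, syn2 = 200L, syn3 = 300L))
  expect_false(any(grepl("[^ACGT]", g)))
  expect_identical(generate_genome(3, c(100, 200, 300), seed = 7), g)
  expect_false(identical(generate_genome(3, c(100, 200, 300), seed = 8), g))

  # caller's RNG stream is untouched
  set.seed(1); a <- stats::runif(1)
  set.seed(1); invisible(generate_genome(1, 100, seed = 99)); b <- stats::runif(1)
  expect_identical(a, b)

  # binomial 3-sigma bound on base frequencies at 100 kb
  big <- generate_genome(1, 1e5, seed = 12)
  freq <- table(strsplit(big[[1]], "")[[1]]) / 1e5
  tol <- 3 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < tol))

  skewed <- generate_genome(1, 1e5, base_composition(0.4, 0.1, 0.1, 0.4), seed = 12)
  f2 <- table(strsplit(skewed[[1]], "")[[1]]) / 1e5
  expect_lt(abs(f2[["A"]] - 0.4), 3 * sqrt(0.4 * 0.6 / 1e5))
  expect_lt(abs(f2[["C"]] - 0.1), 3 * sqrt(0.1 * 0.9 / 1e5))
})

test_that("planted PAM sites are recovered by the scanner at their coordinates", {
  g <- generate_genome(2, 2000, seed = 5)
  at <- data.frame(record = c(1L, 1L, 2L, 2L, 2L),
                   offset = c(50L, 500L, 100L, 900L, 1500L),
                   strand = c("+", "-", "+", "+", "-"))
  planted <- plant_sites(g, "NNGRRT", at, spacer_length = 20, seed = 9)
  truth <- attr(planted, "planted")
  expect_equal(nrow(truth), 5L)
  tabs <- scan_genome(planted, pam_spec("NNGRRT", spacer_length = 20))
  key <- paste(tabs$NNGRRT$record_id, tabs$NNGRRT$pam_start, tabs$NNGRRT$strand)
  want <- paste(truth$record_id, truth$offset, truth$strand)
  expect_true(all(want %in% key))
  # planted windows hold a concrete realisation of the pattern
  for (i in seq_len(nrow(truth))) {
    expect_true(matches_pattern(truth$pam_seq[i], "NNGRRT"))
  }
  # all other bases untouched
  n_diff <- sum(mapply(function(a, b) {
    sum(utf8ToInt(a) != utf8ToInt(b))
  }, g, planted))
  expect_lte(n_diff, 5L * 6L)
})

test_that("planting validates spacer room, range and overlap; zero plants are identity", {
  g <- generate_genome(1, 100, seed = 1)
  expect_error(plant_sites(g, "NNGRRT",
                           data.frame(record = 1L, offset = 5L, strand = "+"),
                           spacer_length = 20), "spacer room")
  expect_error(plant_sites(g, "NNGRRT",
                           data.frame(record = 1L, offset = 98L, strand = "+"),
                           spacer_length = 20), "out of range")
  expect_error(plant_sites(g, "NNGRRT",
                           data.frame(record = c(1L, 1L), offset = c(30L, 33L),
                                      strand = c("+", "+")),
                           spacer_length = 20), "overlap")
  same <- plant_sites(g, "NNGRRT",
                      data.frame(record = integer(0), offset = integer(0),
                                 strand = character(0)))
  expect_identical(unname(same[1]), unname(g[1]))
})

test_that("exon generation is seeded, in-bounds and sized to the request", {
  g <- generate_genome(2, 1000, seed = 2)
  expect_equal(nrow(generate_exons(g, 0)), 0L)
  e1 <- generate_exons(g, 15, c(50L, 120L), seed = 3)
  expect_identical(generate_exons(g, 15, c(50L, 120L), seed = 3), e1)
  expect_equal(nrow(e1), 15L)
  expect_true(all(e1$start >= 0L))
  expect_true(all(e1$end <= 1000L))
  w <- e1$end - e1$start
  expect_true(all(w >= 50L & w <= 120L))
  expect_error(generate_exons(g, 3, c(900L, 1200L)), "shortest record")
})

test_that("mutant-allele generation applies exact events and copies", {
  set.seed(8)
  ref <- random_dna(120)
  # delete 4 bp at position 10 -> allele length ref - 4
  made <- generate_mutant_alleles(ref, list(data.frame(
    kind = "deletion", position = 10, length = 4)), seed = 1)
  expect_equal(nchar(made$alleles[[1]]), nchar(ref) - 4L)
  expect_identical(substr(made$alleles[[1]], 1, 10), substr(ref, 1, 10))
  expect_identical(substr(made$alleles[[1]], 11, nchar(ref) - 4),
                   substr(ref, 15, nchar(ref)))

  # no events, 3 copies -> identical to reference
  wt <- generate_mutant_alleles(ref, list(NULL), n_copies = 3, seed = 1)
  expect_length(wt$alleles, 3L)
  expect_true(all(wt$alleles == ref))
  expect_equal(nrow(wt$truth), 0L)

  # planted {-7, +6, -3} net changes recovered through the caller
  evs <- list(data.frame(kind = "deletion", position = 30, length = 7),
              data.frame(kind = "insertion", position = 60, length = 6),
              data.frame(kind = "deletion", position = 90, length = 3))
  made3 <- generate_mutant_alleles(ref, evs, seed = 4)
  nets <- vapply(seq_along(made3$alleles), function(i) {
    call_indels(ref, made3$alleles[[i]])$net_change
  }, integer(1))
  expect_equal(nets, c(-7L, 6L, -3L))

  expect_error(generate_mutant_alleles(ref, list(data.frame(
    kind = c("deletion", "deletion"), position = c(10, 12),
    length = c(5, 2))), seed = 1), "overlap")
})
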