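make_table <- function(rows, scanned_bp = 1000) {
  if (length(rows) == 0L) {
    df <- data.frame(record_id = character(0), strand = character(0),
                     protospacer_start = integer(0), protospacer_end = integer(0),
                     pam_start = integer(0), pam_end = integer(0),
                     protospacer_seq = character(0), pam_seq = character(0),
                     pam_class = character(0), stringsAsFactors = FALSE)
    return(structure(df, scanned_bp = scanned_bp,
                     class = c("site_table", "data.frame")))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r$rec, strand = r$strand %||% "+",
               protospacer_start = r$ps, protospacer_end = r$pe,
               pam_start = r$pe, pam_end = r$pe + 3L,
               protospacer_seq = "AA", pam_seq = "AGG",
               pam_class = r$cl %||% "NGG", stringsAsFactors = FALSE)
  }))
  structure(df, scanned_bp = scanned_bp,
            class = c("site_table", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("BED and GFF3 intervals parse with coordinate-convention conversion", {
  bed <- parse_intervals("chr1\t10\t50\te1\t0\t+\n", format = "bed")
  expect_equal(bed, data.frame(record_id = "chr1", start = 10L, end = 50L,
                               name = "e1", strand = "+",
                               stringsAsFactors = FALSE))
  gff <- parse_intervals(
    "chr1\tuc\texon\t11\t50\t.\t+\t.\tID=e1;Parent=tx1\n", format = "gff3")
  expect_equal(gff$start, 10L)
  expect_equal(gff$end, 50L)
  expect_equal(gff$name, "e1")
  # non-exon features are ignored; format auto-detected from 9 fields
  mixed <- parse_intervals(paste0(
    "chr1\tuc\tgene\t1\t100\t.\t+\t.\tID=g1\n",
    "chr1\tuc\texon\t11\t50\t.\t+\t.\tID=e1\n"))
  expect_equal(nrow(mixed), 1L)
})

test_that("malformed intervals are rejected with their line number", {
  expect_error(parse_intervals("chr1\t50\t10\te\t0\t+", format = "bed"), "line 1")
  expect_error(parse_intervals(c("chr1\t0\t5\te\t0\t+", "chr1\tx\t9\te\t0\t+"),
                               format = "bed"), "line 2")
  expect_error(parse_intervals("chr1\tuc\texon\t50\t10\t.\t+\t.\tID=e",
                               format = "gff3"), "line 1")
})

test_that("overlap semantics are half-open: adjacency is not overlap", {
  # site union interval [1,6) on record "t"
  tab <- make_table(list(list(rec = "t", ps = 1L, pe = 3L)))
  exon <- function(s, e) data.frame(record_id = "t", start = s, end = e,
                                    name = "e", strand = ".",
                                    stringsAsFactors = FALSE)
  a <- intersect_sites(tab, exon(0L, 3L), mode = "any_overlap")
  expect_true(a$exonic)
  expect_equal(a$exons, "e")
  expect_false(intersect_sites(tab, exon(6L, 9L), mode = "any_overlap")$exonic)
  expect_false(intersect_sites(tab, exon(0L, 3L), mode = "full_containment")$exonic)
  expect_true(intersect_sites(tab, exon(0L, 6L), mode = "full_containment")$exonic)
  expect_error(intersect_sites(tab, exon(0L, 3L), mode = "nonsense"))
})

test_that("intersection equals brute force and is order-invariant, both modes", {
  set.seed(31)
  for (rep in 1:30) {
    g <- generate_genome(2, 600, seed = rep)
    tab <- combine_sites(scan_genome(g, list(pam_spec("NGG", spacer_length = 5),
                                             pam_spec("NNGRRT", spacer_length = 5))))
    exons <- generate_exons(g, sample(0:12, 1), c(10L, 80L), seed = rep + 100)
    us <- pmin(tab$protospacer_start, tab$pam_start)
    ue <- pmax(tab$protospacer_end, tab$pam_end)
    for (mode in c("any_overlap", "full_containment")) {
      got <- intersect_sites(tab, exons, mode = mode)
      want <- brute_intersect(us, ue, tab$record_id, exons, mode)
      expect_identical(got$exonic, want$exonic)
      expect_identical(got$exons, want$names)
      # permuting exon input order never changes the result (per-site
      # exon lists are emitted name-sorted)
      if (nrow(exons) > 1L) {
        perm <- intersect_sites(tab, exons[sample(nrow(exons)), ], mode = mode)
        expect_identical(perm$exonic, got$exonic)
        expect_identical(perm$exons, got$exons)
      }
    }
    any_n <- sum(intersect_sites(tab, exons, mode = "any_overlap")$exonic)
    full_n <- sum(intersect_sites(tab, exons, mode = "full_containment")$exonic)
    expect_gte(any_n, full_n)
  }
})

test_that("availability summary reports counts and per-kb densities", {
  empty <- intersect_sites(make_table(list(), scanned_bp = 0),
                           parse_intervals(character(0), format = "bed"))
  s0 <- summarize_availability(empty)
  expect_equal(nrow(s0), 0L)

  # 64 sites, 16 exonic, 32 kb scanned -> 2.0 sites/kb
  rows <- lapply(seq_len(64), function(i)
    list(rec = "t", ps = (i - 1L) * 40L, pe = (i - 1L) * 40L + 2L))
  tab <- make_table(rows, scanned_bp = 32000)
  # one exon covering the first 16 site unions: sites 1..16 end at 15*40+5=605
  exons <- data.frame(record_id = "t", start = 0L, end = 606L, name = "e1",
                      strand = ".", stringsAsFactors = FALSE)
  s <- summarize_availability(intersect_sites(tab, exons))
  expect_equal(s$total_sites, 64L)
  expect_equal(s$exonic_sites, 16L)
  expect_equal(s$sites_per_kb_scanned, 2.0)
  expect_equal(s$sites_per_kb_exon, 16 / 0.606)
})

test_that("annotated BED extends names with exon lists", {
  tab <- make_table(list(list(rec = "t", ps = 1L, pe = 3L),
                         list(rec = "t", ps = 100L, pe = 102L)))
  exons <- data.frame(record_id = "t", start = 0L, end = 4L, name = "e1",
                      strand = ".", stringsAsFactors = FALSE)
  ann <- intersect_sites(tab, exons)
  f <- withr::local_tempfile(fileext = ".bed")
  write_annotated_bed(ann, f)
  lines <- readLines(f)
  expect_match(lines[1], "\\|exonic:e1\t0\t\\+$")
  expect_no_match(lines[2], "exonic")
})
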