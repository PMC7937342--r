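test_that("srl_target validates the motif and marks the adenine", {
  t <- srl_target()
  expect_equal(t$motif, "TACGAGAGGAACC")
  expect_equal(t$target_offset, 4L)
  expect_equal(substr(t$motif, 5, 5), "A")
  expect_error(srl_target("TACGC", target_offset = 4), "adenine")
  expect_error(srl_target("ACG"), "at least 5")
})

test_that("locate_srl finds a unique motif and errors otherwise", {
  ref <- tibble::tibble(id = "r", sequence = paste0("GG", "TACGAGAGGAACC", "CC"))
  span <- locate_srl(ref)
  expect_equal(span$start, 2L)
  expect_equal(span$end, 15L)
  expect_equal(span$target_pos, 6L)

  expect_error(locate_srl(tibble::tibble(id = "r", sequence = "AAAA")), "absent")
  twice <- tibble::tibble(id = "r", sequence = strrep("TACGAGAGGAACC", 2))
  expect_error(locate_srl(twice), "occurs 2 times")
})

test_that("aligned reads are retained only with full motif coverage", {
  ref <- fixture_reference()
  span <- locate_srl(ref)
  # motif occupies 0-based [30, 43); target at 34
  recs <- list(
    list(qname = "full", pos = 21L, cigar = "40M",
         seq = substr(ref$sequence, 21, 60)),
    list(qname = "partial", pos = 32L, cigar = "40M", # covers 12 of 13 motif bases
         seq = substr(ref$sequence, 32, 71))
  )
  sam <- withr::local_tempfile(fileext = ".sam")
  write_fixture_sam(recs, sam, ref = ref)
  aln <- read_alignments(sam, "ref28S")
  calls <- assign_reads(aln, reference = ref, span = span)
  expect_equal(calls$reason[calls$read_id == "full"], "retained")
  expect_equal(calls$base[calls$read_id == "full"], "A")
  expect_equal(calls$reason[calls$read_id == "partial"], "partial_coverage")
  drops <- attr(calls, "drops")
  expect_equal(sum(drops), nrow(calls))
})

test_that("a mismatch at the target site is exempt from the mismatch cap", {
  ref <- fixture_reference()
  span <- locate_srl(ref)
  base_seq <- substr(ref$sequence, 21, 60) # 40 bp, covers motif fully
  t_at_target <- base_seq
  substr(t_at_target, 35 - 21 + 1, 35 - 21 + 1) <- "T" # 1-based target is 35
  # two extra mismatches elsewhere: 2/40 = 5% > 2% cap
  many_mm <- t_at_target
  substr(many_mm, 1, 1) <- "C"
  substr(many_mm, 2, 2) <- "C"
  recs <- list(
    list(qname = "target_only", pos = 21L, cigar = "40M", seq = t_at_target),
    list(qname = "excess", pos = 21L, cigar = "40M", seq = many_mm)
  )
  sam <- withr::local_tempfile(fileext = ".sam")
  write_fixture_sam(recs, sam, ref = ref)
  calls <- assign_reads(read_alignments(sam, "ref28S"), reference = ref, span = span)
  expect_equal(calls$base[calls$read_id == "target_only"], "T")
  expect_equal(calls$reason[calls$read_id == "excess"], "mismatch_excess")

  # brute-force check of the retained call against a pure string comparison
  expect_equal(substr(t_at_target, 15, 15), "T")
})

test_that("a deletion spanning the target is called as a gap", {
  ref <- fixture_reference()
  span <- locate_srl(ref)
  # read aligned from 0-based 20, 14M 1D 25M deletes reference position 34
  seq_del <- paste0(substr(ref$sequence, 21, 34), substr(ref$sequence, 36, 60))
  recs <- list(list(qname = "gapdel", pos = 21L, cigar = "14M1D25M", seq = seq_del))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_fixture_sam(recs, sam, ref = ref)
  calls <- assign_reads(read_alignments(sam, "ref28S"), reference = ref, span = span)
  expect_equal(calls$base, "-")
  cb <- count_bases(calls, "s")
  expect_equal(cb$gapped, 1L)
  expect_equal(cb$total_ungapped, 0L)
})

test_that("count_bases tallies exhaustively and exclusively", {
  calls <- tibble::tibble(read_id = as.character(1:5), retained = TRUE,
                          reason = "retained",
                          base = c("A", "A", "A", "T", "-"))
  cb <- count_bases(calls, "s1")
  expect_equal(cb$a, 3L)
  expect_equal(cb$t, 1L)
  expect_equal(cb$gapped, 1L)
  expect_equal(cb$total_ungapped, 4L)

  empty <- count_bases(calls[0, ], "s0")
  expect_equal(empty$total_ungapped, 0L)

  # N at the target counts as other, not adenine
  withN <- count_bases(tibble::tibble(read_id = "x", retained = TRUE,
                                      reason = "retained", base = "N"), "sN")
  expect_equal(withN$other, 1L)
})

test_that("estimates follow the arithmetic, Wilson interval and QC rule", {
  cb <- tibble::tibble(sample_id = "s", a = 90L, c = 0L, g = 0L, t = 10L,
                       other = 0L, gapped = 0L, total_ungapped = 100L)
  est <- estimate_depurination(cb)
  expect_equal(est$adenine_fraction, 0.90)
  expect_equal(est$depurination_fraction, 0.10)
  expect_true(est$passed_qc)

  low <- tibble::tibble(sample_id = "s", a = 5L, c = 0L, g = 0L, t = 0L,
                        other = 0L, gapped = 0L, total_ungapped = 5L)
  expect_false(estimate_depurination(low)$passed_qc)

  # Wilson 95% interval at 50/100 against the prop.test implementation
  half <- tibble::tibble(sample_id = "s", a = 50L, c = 0L, g = 0L, t = 50L,
                         other = 0L, gapped = 0L, total_ungapped = 100L)
  esth <- estimate_depurination(half)
  oracle <- stats::prop.test(50, 100, correct = FALSE)$conf.int
  expect_equal(esth$ci_low, oracle[1], tolerance = 1e-10)
  expect_equal(esth$ci_high, oracle[2], tolerance = 1e-10)
  expect_equal(round(esth$ci_low, 3), 0.404)
  expect_equal(round(esth$ci_high, 3), 0.596)

  zero <- tibble::tibble(sample_id = "s", a = 0L, c = 0L, g = 0L, t = 0L,
                         other = 0L, gapped = 0L, total_ungapped = 0L)
  estz <- estimate_depurination(zero)
  expect_true(is.na(estz$adenine_fraction))
  expect_false(estz$passed_qc)
})

test_that("raw-read base counts equal the brute-force string-scan oracle", {
  for (seed in c(2, 9, 23)) {
    rd <- simulate_reads(n_reads = 50, depurination_rate = 0.3,
                         error_rate = 0.01, seed = seed)
    calls <- assign_reads(rd)
    cb <- count_bases(calls, "s")
    orc <- oracle_count_bases(rd$sequence)
    expect_equal(c(a = cb$a, c = cb$c, g = cb$g, t = cb$t, other = cb$other),
                 orc, ignore_attr = TRUE)
  }
})

test_that("base counts are invariant to reverse-complementing the input reads", {
  rd <- simulate_reads(n_reads = 200, depurination_rate = 0.2,
                       error_rate = 0.005, seed = 31)
  flipped <- rd
  flipped$sequence <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(rd$sequence)))
  cb1 <- count_bases(assign_reads(rd), "s")
  cb2 <- count_bases(assign_reads(flipped), "s")
  expect_equal(cb1, cb2)
})

test_that("retained plus dropped reads account for every input read", {
  rd <- simulate_reads(n_reads = 300, depurination_rate = 0.1,
                       error_rate = 0.01, seed = 12)
  calls <- assign_reads(rd)
  cb <- count_bases(calls, "s")
  expect_equal(nrow(calls), 300L)
  expect_equal(sum(calls$retained), cb$total_ungapped + cb$gapped)
  expect_equal(sum(attr(calls, "drops")), 300L)
})
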