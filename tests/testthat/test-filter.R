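# matched-normal subtraction, read-end re-evaluation and the QC cascade

test_that("subtraction removes shared keys and keys match on the exact allele", {
  tum <- dplyr::bind_rows(
    make_candidate(500, 250, rep(0.5, 250), pos0 = 10L, alt_allele = "C"),
    make_candidate(500, 40, rep(0.5, 40), pos0 = 20L, alt_allele = "T"),
    make_candidate(500, 30, rep(0.5, 30), pos0 = 30L, alt_allele = "C"))
  nor <- dplyr::bind_rows(
    make_candidate(480, 240, rep(0.5, 240), pos0 = 10L, alt_allele = "C"),
    make_candidate(470, 220, rep(0.5, 220), pos0 = 30L, alt_allele = "G"))
  out <- subtract_normal(tum, nor)
  # germline het removed; somatic retained; same position different alt retained
  expect_equal(out$pos0, c(20L, 30L))
  expect_equal(out$alt_allele, c("T", "C"))
})

test_that("read-end re-evaluation flags terminal offsets and recomputes AF", {
  # read length 200, variant at index 10 -> offset 0.05 < 0.15: flagged
  cand <- make_candidate(500, 3, c(10 / 200, 0.5, 0.6))
  re <- end_read_reeval(cand, 0.15)
  expect_equal(re$ao_core, 2L)
  expect_equal(nrow(re$end_flagged_supports), 1L)
  expect_equal(re$af_core, 2 / 499)

  # boundary: offset exactly 0.15 is NOT flagged; exactly 0.85 is
  cand <- make_candidate(100, 2, c(15 / 100, 85 / 100))
  re <- end_read_reeval(cand, 0.15)
  expect_equal(re$ao_core, 1L)
  expect_equal(re$end_flagged_supports$offset_frac, 0.85)

  # total removal: 0/0 on the alt side defined as 0
  cand <- make_candidate(500, 40, rep(0.05, 40))
  re <- end_read_reeval(cand, 0.15)
  expect_equal(re$ao_core, 0L)
  expect_equal(re$af_core, 0)
})

test_that("the published threshold cases gate exactly as printed", {
  # AF 4%, 12 interior alt reads at depth 300: low tier satisfied (>= 10)
  v <- apply_qc(make_candidate(300, 12, rep(0.5, 12)))
  expect_true(v$passed)
  expect_equal(v$trail[[1]], character())

  # AF 10%, 24 alt reads: high tier needs >= 25
  v <- apply_qc(make_candidate(240, 24, rep(0.5, 24)))
  expect_false(v$passed)
  expect_equal(v$trail[[1]], "tier_support")

  # depth 99 fails the 100-read floor even at high support
  v <- apply_qc(make_candidate(99, 50, rep(0.5, 50)))
  expect_false(v$passed)
  expect_equal(v$trail[[1]], "min_depth")

  # more than 2 distinct alt alleles at the site
  v <- apply_qc(make_candidate(300, 30, rep(0.5, 30), n_alleles = 3L))
  expect_false(v$passed)
  expect_true("multiallelic" %in% v$trail[[1]])
})

test_that("the AF tier boundary at 5% belongs to the low tier; below 2% is rejected", {
  # af_core exactly 0.05 with 10 reads passes (low tier inclusive)
  v <- apply_qc(make_candidate(200, 10, rep(0.5, 10)))
  expect_equal(v$af_core, 0.05)
  expect_true(v$passed)
  # just above 5% with 10 reads needs 25
  v <- apply_qc(make_candidate(190, 10, rep(0.5, 10)))
  expect_gt(v$af_core, 0.05)
  expect_equal(v$trail[[1]], "tier_support")
  # below the 2% floor
  v <- apply_qc(make_candidate(1000, 15, rep(0.5, 15)))
  expect_equal(v$trail[[1]], "low_af")
})

test_that("a fully end-flagged candidate fails with the end_read label alone", {
  v <- apply_qc(make_candidate(500, 40, rep(0.05, 40)))
  expect_equal(v$trail[[1]], "end_read")
  expect_false(v$passed)
})

test_that("a milder end-read cut can push a candidate across the 5% tier boundary", {
  # 21 alt reads at depth 400; 11 supports sit at offset 0.10
  cand <- make_candidate(400, 21, c(rep(0.10, 11), rep(0.5, 10)))
  # terminal 15%: the 11 near-end supports are removed; AF 10/389 = 2.6%
  # falls in the 2-5% tier, 10 supports suffice
  strict <- apply_qc(cand, filter_params(end_frac = 0.15))
  expect_true(strict$passed)
  # terminal 5%: those supports are retained; AF 21/400 = 5.25% now exceeds
  # the 5% tier boundary, where 25 supports are required
  relaxed <- apply_qc(cand, filter_params(end_frac = 0.05))
  expect_false(relaxed$passed)
  expect_equal(relaxed$trail[[1]], "tier_support")
})

test_that("apply_qc agrees with an independent predicate oracle on fuzzed candidates", {
  cands <- fuzz_candidates(300, seed = 17)
  verdicts <- apply_qc(cands)
  oracle <- vapply(seq_len(nrow(cands)),
                   function(i) oracle_qc_pass(cands[i, ]), logical(1))
  expect_equal(verdicts$passed, oracle)
})

test_that("apply_qc is idempotent on passing records", {
  cands <- fuzz_candidates(200, seed = 23)
  v1 <- apply_qc(cands)
  pass1 <- v1[v1$passed, names(cands)]
  v2 <- apply_qc(pass1)
  expect_true(all(v2$passed))
  expect_equal(v2$trail, rep(list(character()), nrow(v2)))
  expect_equal(v2$af_core, v1$af_core[v1$passed])
})

test_that("re-evaluation bounds hold on fuzzed candidates", {
  cands <- fuzz_candidates(200, seed = 29)
  v <- apply_qc(cands)
  expect_true(all(v$ao_core <= v$alt_reads))
  expect_true(all(v$af_core >= 0 & v$af_core <= 1))
})

test_that("the pipeline passes exactly the clean somatic variant on constructed truth", {
  ref <- tiny_reference(paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 200L, depth = 1000L)
  pick_alt <- function(p) setdiff(c("A", "C", "G", "T"),
                                  substr(ref$seq, p + 1, p + 1))[1]
  planted <- tibble::tibble(
    ref_name = "chrT",
    pos0 = c(60L, 100L, 190L),
    ref_allele = vapply(c(60L, 100L, 190L),
                        function(p) substr(ref$seq, p + 1, p + 1), ""),
    alt_allele = vapply(c(60L, 100L, 190L), pick_alt, ""),
    af = c(0.5, 0.10, 0.08),
    scope = c("germline", "somatic", "somatic"))  # 190/200 = 0.95: end artifact
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 77)
  screen <- run_somatic_pipeline(sim$tumor, sim$normal, ref)
  pass <- screen$verdicts[screen$verdicts$passed, ]
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$pos0, 100L)
  art <- screen$verdicts[screen$verdicts$pos0 == 190L, ]
  expect_equal(art$trail[[1]], "end_read")
  germ <- screen$verdicts[screen$verdicts$pos0 == 60L, ]
  expect_equal(germ$trail[[1]], "in_normal")
})

test_that("self-subtraction leaves nothing and relaxing min_depth only grows the PASS set", {
  ref <- tiny_reference(paste(rep(c("A", "C", "G", "T"), 100), collapse = ""))
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 200L, depth = 150L)
  refb <- substr(ref$seq, 81, 81)
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 80L, ref_allele = refb,
                            alt_allele = setdiff(c("A", "C", "G", "T"), refb)[1],
                            af = 0.3, scope = "somatic")
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 99)

  self <- run_somatic_pipeline(sim$tumor, sim$tumor, ref)
  expect_equal(sum(self$verdicts$passed), 0L)
  expect_true(all(vapply(self$verdicts$trail, function(t) "in_normal" %in% t, TRUE)))

  strict <- run_somatic_pipeline(sim$tumor, sim$normal, ref,
                                 params = filter_params(min_depth = 200L))
  relaxed <- run_somatic_pipeline(sim$tumor, sim$normal, ref,
                                  params = filter_params(min_depth = 1L))
  strict_pass <- strict$verdicts[strict$verdicts$passed, c("pos0", "alt_allele")]
  relaxed_pass <- relaxed$verdicts[relaxed$verdicts$passed, c("pos0", "alt_allele")]
  expect_equal(nrow(dplyr::anti_join(strict_pass, relaxed_pass,
                                     by = c("pos0", "alt_allele"))), 0L)
})

test_that("tidy, glance and autoplot summarise a screen", {
  cands <- fuzz_candidates(50, seed = 31)
  screen <- structure(list(verdicts = apply_qc(cands), params = filter_params(),
                           n_tumor_candidates = 50L, n_normal_candidates = 0L,
                           n_pass = sum(apply_qc(cands)$passed)),
                      class = "somatic_screen")
  td <- tidy(screen)
  expect_equal(nrow(td), 50L)
  expect_true(all(c("filter", "af_core", "passed") %in% names(td)))
  g <- glance(screen)
  expect_equal(g$n_verdicts, 50L)
  expect_s3_class(autoplot(screen), "ggplot")
  expect_s3_class(plot_af_reeval(screen), "ggplot")
})
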