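# matched-pair amplicon simulator

ref200 <- function(seed = 5) {
  set.seed(seed)
  tibble::tibble(name = "chrT",
                 seq = paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                             collapse = ""))
}

test_that("an AF 1.0 germline SNV with zero error appears on every read of both samples", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 100L, depth = 50L)
  refb <- substr(ref$seq, 41, 41)
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 40L, ref_allele = refb,
                            alt_allele = alt, af = 1.0, scope = "germline")
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 3)
  for (s in c("tumor", "normal")) {
    cand <- call_candidates(build_pileup(sim[[s]], ref))
    hit <- cand[cand$pos0 == 40L, ]
    expect_equal(hit$alt_reads, 50L)
    expect_equal(hit$depth, 50L)
  }
})

test_that("identical seeds give identical output; read count equals the sum of amplicon depths", {
  ref <- ref200()
  amps <- tibble::tibble(ref_name = "chrT", start = c(0L, 150L),
                         end = c(200L, 350L), depth = c(30L, 70L))
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 60L, ref_allele = substr(ref$seq, 61, 61),
                            alt_allele = "A", af = 0.5, scope = "somatic")
  planted$alt_allele <- setdiff(c("A", "C", "G", "T"), planted$ref_allele)[1]
  a <- simulate_pair(ref, amps, planted, error_model(), seed = 11)
  b <- simulate_pair(ref, amps, planted, error_model(), seed = 11)
  expect_identical(a, b)
  expect_equal(nrow(a$tumor), 100L)
  expect_equal(nrow(a$normal), 100L)

  # and SAM bytes round the loop too
  f1 <- tempfile(); f2 <- tempfile()
  write_sam(a$tumor, ref, f1); write_sam(b$tumor, ref, f2)
  expect_identical(readLines(f1), readLines(f2))

  c_ <- simulate_pair(ref, amps, planted, error_model(), seed = 12)
  expect_false(identical(a$tumor$seq, c_$tumor$seq))
})

test_that("a 10% somatic SNV at depth 1000 lands in the central 99.9% binomial band, tumor only", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 200L, depth = 1000L)
  refb <- substr(ref$seq, 101, 101)
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 100L, ref_allele = refb,
                            alt_allele = setdiff(c("A", "C", "G", "T"), refb)[1],
                            af = 0.10, scope = "somatic")
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 21)
  tcand <- call_candidates(build_pileup(sim$tumor, ref))
  alt <- tcand$alt_reads[tcand$pos0 == 100L]
  expect_gte(alt, qbinom(0.0005, 1000, 0.10))
  expect_lte(alt, qbinom(0.9995, 1000, 0.10))
  ncand <- call_candidates(build_pileup(sim$normal, ref), min_alt_reads = 1,
                           min_af = 1e-6)
  expect_equal(sum(ncand$pos0 == 100L), 0L)
})

test_that("empirical AF converges to the planted AF at depth 10,000", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 120L, depth = 10000L)
  refb <- substr(ref$seq, 61, 61)
  af <- 0.07
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 60L, ref_allele = refb,
                            alt_allele = setdiff(c("A", "C", "G", "T"), refb)[1],
                            af = af, scope = "somatic")
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 31,
                       samples = "tumor")
  cand <- call_candidates(build_pileup(sim$tumor, ref))
  af_hat <- cand$af[cand$pos0 == 60L]
  expect_lt(abs(af_hat - af), 3 * sqrt(af * (1 - af) / 10000))
})

test_that("plant_end_artifact fixes the variant offset by amplicon geometry", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 100L, end = 300L, depth = 500L)

  reads <- plant_end_artifact(ref, amp, pos0 = 110L, af = 0.08, seed = 9)
  expect_equal(nrow(reads), 500L)
  cand <- call_candidates(build_pileup(reads, ref))
  hit <- cand[cand$pos0 == 110L, ]
  offs <- hit$supports[[1]]$offset_frac
  expect_true(all(offs == 10 / 200))     # 0.05 for every supporting read
  # support count is a Binomial(500, 0.08) draw
  expect_gte(hit$alt_reads, qbinom(0.0005, 500, 0.08))
  expect_lte(hit$alt_reads, qbinom(0.9995, 500, 0.08))

  expect_error(plant_end_artifact(ref, amp, pos0 = 200L, af = 0.08),
               class = "somaticsieve_config_error")
})

test_that("every planted variant with af*depth >= 30 is recovered by the caller at zero error", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 300L, depth = 1000L)
  pick_alt <- function(p) setdiff(c("A", "C", "G", "T"), substr(ref$seq, p + 1, p + 1))[1]
  planted <- tibble::tibble(
    ref_name = "chrT",
    pos0 = c(40L, 90L, 150L, 210L),
    ref_allele = c(substr(ref$seq, 41, 41), substr(ref$seq, 91, 91),
                   substr(ref$seq, 151, 152), substr(ref$seq, 211, 211)),
    alt_allele = c(pick_alt(40L), pick_alt(90L),
                   substr(ref$seq, 151, 151), pick_alt(210L)),
    af = c(0.5, 0.05, 0.20, 0.03),
    scope = c("germline", "somatic", "somatic", "somatic"))
  sim <- simulate_pair(ref, amp, planted, error_model(0, 0), seed = 41,
                       samples = "tumor")
  cand <- call_candidates(build_pileup(sim$tumor, ref))
  key <- paste(cand$pos0, cand$ref_allele, cand$alt_allele)
  truth_key <- paste(planted$pos0, planted$ref_allele, planted$alt_allele)
  expect_true(all(truth_key %in% key))
})

test_that("error rates are elevated only in the terminal read fraction", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 200L, depth = 2000L)
  sim <- simulate_pair(ref, amp, NULL, error_model(0, 0.05, 0.15), seed = 51,
                       samples = "tumor")
  pu <- build_pileup(sim$tumor, ref)
  mm_pos <- unique(pu$events$pos0)
  # zero interior rate: every mismatch sits in the terminal 15% of the amplicon
  expect_true(all(mm_pos < 30 | mm_pos >= 170))
  expect_gt(nrow(pu$events), 0)
})

test_that("shotgun mode draws read starts uniformly and stays reproducible", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 200L, depth = 300L)
  a <- simulate_pair(ref, amp, NULL, error_model(0, 0), seed = 5,
                     samples = "tumor", mode = "shotgun", read_len = 80L)
  b <- simulate_pair(ref, amp, NULL, error_model(0, 0), seed = 5,
                     samples = "tumor", mode = "shotgun", read_len = 80L)
  expect_identical(a, b)
  expect_true(all(nchar(a$tumor$seq) == 80L))
  expect_gt(dplyr::n_distinct(a$tumor$ref_start), 20L)
})

test_that("configuration errors are raised for invalid panels", {
  ref <- ref200()
  amp <- tibble::tibble(ref_name = "chrT", start = 0L, end = 100L, depth = 10L)
  planted <- tibble::tibble(ref_name = "chrT", pos0 = 250L, ref_allele = "A",
                            alt_allele = "G", af = 0.5, scope = "somatic")
  expect_error(simulate_pair(ref, amp, planted, seed = 1),
               class = "somaticsieve_config_error")
  expect_error(error_model(0.1, 0.01), class = "somaticsieve_config_error")
  expect_error(error_model(0, 0.01, 0.7), class = "somaticsieve_config_error")
})
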