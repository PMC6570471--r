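# Independent brute-force oracles, deliberately written from the rule
# statements rather than from the package internals.

# PASS/FAIL oracle for the QC cascade, as five independent predicates
oracle_qc_pass <- function(cand, end_frac = 0.15, max_alt_alleles = 2,
                           min_depth = 100, af_lo = 0.02, af_hi = 0.05,
                           low_support = 10, high_support = 25) {
  off <- cand$supports[[1]]$offset_frac
  n_end <- sum(off < end_frac | off >= 1 - end_frac)
  ao <- cand$alt_reads - n_end
  denom <- cand$depth - n_end
  afc <- if (denom <= 0) 0 else ao / denom
  if (ao == 0) return(FALSE)                                   # end-read event
  if (cand$n_alt_alleles_at_site > max_alt_alleles) return(FALSE)
  if (cand$depth < min_depth) return(FALSE)
  if (afc < af_lo) return(FALSE)
  if (afc <= af_hi && ao < low_support) return(FALSE)
  if (afc > af_hi && ao < high_support) return(FALSE)
  TRUE
}

# two-sided Fisher p by explicit hypergeometric enumeration (stats::dhyper)
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  x <- max(0, k - n2):min(k, m)
  if (length(x) == 1L) return(1)
  p <- stats::dhyper(x, m, n2, k)
  p0 <- stats::dhyper(a, m, n2, k)
  min(1, sum(p[p <= p0 * (1 + 1e-7)]))
}
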