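# Shared fixture builders: everything is generated in code at test time.

# a small fixed reference contig (60 bp, no stop-codon constraints needed)
tiny_reference <- function(seq = NULL) {
  seq <- seq %||% paste0(
    "ACGTACGTTGCAACGGATCCTTAGGCATCGAT",
    "GGCCATTGCAATCGGATGCATGCAATTGGCCA")
  tibble::tibble(name = "chrT", seq = seq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-build an aligned-read tibble
make_reads <- function(seqs, ref_start = 0L, cigar = NULL, ref_name = "chrT",
                       sample = "tumor", prefix = "r") {
  n <- length(seqs)
  tibble::tibble(
    read_id = sprintf("%s%03d", prefix, seq_len(n)),
    ref_name = ref_name,
    ref_start = rep_len(ref_start, n),
    cigar = if (is.null(cigar)) paste0(nchar(seqs), "M") else rep_len(cigar, n),
    seq = seqs,
    sample = sample
  )
}

# write a SAM text file from raw field vectors (to exercise the parser)
write_sam_lines <- function(lines, path = tempfile(fileext = ".sam"),
                            sq = c("chrT" = 64L)) {
  hdr <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  writeLines(c(hdr, lines), path)
  path
}

sam_line <- function(qname, pos, cigar, seq, flag = 0L, rname = "chrT") {
  sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
          qname, flag, rname, pos, cigar, seq)
}

# hand-build a candidate row with explicit support offsets
make_candidate <- function(depth, alt_reads, offsets, n_alleles = 1L,
                           pos0 = 10L, ref_allele = "A", alt_allele = "G",
                           ref_name = "chrT") {
  stopifnot(length(offsets) == alt_reads)
  tibble::tibble(
    ref_name = ref_name, pos0 = as.integer(pos0),
    ref_allele = ref_allele, alt_allele = alt_allele,
    depth = as.integer(depth), alt_reads = as.integer(alt_reads),
    af = alt_reads / depth,
    n_alt_alleles_at_site = as.integer(n_alleles),
    supports = list(tibble::tibble(
      read_id = sprintf("s%04d", seq_len(alt_reads)),
      offset_frac = offsets))
  )
}

# random candidates for fuzz tests (depths, AFs, offsets, allele counts)
fuzz_candidates <- function(n, seed) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    depth <- sample(20:2000, 1)
    alt <- sample(0:min(depth, 200), 1)
    alt <- max(alt, 1L)
    offsets <- round(runif(alt), 4)   # includes terminal offsets
    make_candidate(depth, alt, offsets,
                   n_alleles = sample(1:4, 1),
                   pos0 = 10L + i)
  }) |> purrr::list_rbind()
}
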