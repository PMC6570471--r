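# FASTA and SAM text I/O.
#
# All coordinates are 0-based half-open internally; SAM stores 1-based POS on
# disk and the conversion happens only at the file boundary.

#' Read a FASTA file into a reference tibble
#'
#' Sequences are upper-cased on read and restricted to the `A/C/G/T/N`
#' alphabet, the representation every downstream step assumes.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `name` (first whitespace-separated
#'   token of the header) and `seq` (upper-case DNA string).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">chrT", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file '%s' does not exist", path)
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) stop_format("malformed FASTA '%s': %s", path, conditionMessage(e))
    ),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop_format("FASTA '%s': %s", path, conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(set) == 0L) stop_format("FASTA '%s' contains no records", path)
  name <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seq <- str_to_upper(as.character(set))
  if (any(!nzchar(seq))) {
    stop_format("FASTA '%s': empty sequence for record '%s'",
                path, name[!nzchar(seq)][1])
  }
  bad <- str_detect(seq, "[^ACGTN]")
  if (any(bad)) {
    stop_format("FASTA '%s': record '%s' contains non-ACGTN characters",
                path, name[bad][1])
  }
  tibble(name = name, seq = seq)
}

#' Write a reference tibble to FASTA
#'
#' @param reference A tibble with columns `name`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  check_reference(reference)
  set <- Biostrings::DNAStringSet(setNames(reference$seq, reference$name))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# CIGAR helpers ---------------------------------------------------------------

# parse "2S4M1D3M" -> data.frame(len, op); ops restricted to M/I/D/S
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([A-Z=])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(cigar)) {
    stop_format("unparseable CIGAR '%s'", cigar)
  }
  toks <- regmatches(cigar, gregexpr("\\d+|[A-Z=]", cigar))[[1]]
  len <- as.integer(toks[c(TRUE, FALSE)])
  op <- toks[c(FALSE, TRUE)]
  bad <- setdiff(op, c("M", "I", "D", "S"))
  if (length(bad)) stop_format("unsupported CIGAR op '%s' in '%s'", bad[1], cigar)
  if (any(len < 1L)) stop_format("zero-length CIGAR op in '%s'", cigar)
  data.frame(len = len, op = op)
}

cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S")])
cigar_aligned_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I")])
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D")])

#' Read a SAM text file into an aligned-read tibble
#'
#' Supports the single-end dialect the simulator emits: CIGAR ops `M/I/D/S`
#' only, no mate fields. Unmapped reads (FLAG bit 0x4) are skipped. Soft-clipped
#' bases are trimmed from the stored sequence so that every retained base is
#' aligned evidence; the read-end positional filter and all offset fractions
#' are computed over aligned bases only.
#'
#' @param path Path to a SAM text file.
#' @param sample Sample tag attached to every read, e.g. `"tumor"` or
#'   `"normal"` (one file per sample).
#' @return A tibble with columns `read_id`, `ref_name`, `ref_start` (0-based
#'   leftmost aligned position), `cigar` (soft clips removed), `seq` (aligned
#'   bases only) and `sample`.
#' @export
read_sam <- function(path, sample = "tumor") {
  if (!file.exists(path)) stop_format("SAM file '%s' does not exist", path)
  lines <- readLines(path)
  aln <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(aln) == 0L) {
    return(tibble(read_id = character(), ref_name = character(),
                  ref_start = integer(), cigar = character(),
                  seq = character(), sample = character()))
  }
  fields <- str_split(aln, "\t")
  short <- lengths(fields) < 11L
  if (any(short)) {
    stop_format("SAM '%s': alignment line with fewer than 11 fields: '%s'",
                path, substr(aln[short][1], 1, 60))
  }
  rows <- map(fields, function(f) {
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop_format("SAM '%s': non-integer FLAG for read '%s'", path, f[1])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)   # unmapped
    ops <- parse_cigar(f[6])
    seq <- str_to_upper(f[10])
    if (cigar_query_len(ops) != nchar(seq)) {
      stop_format("SAM '%s': CIGAR/sequence length mismatch for read '%s'", path, f[1])
    }
    # trim soft clips (ends only) from the stored sequence
    if (ops$op[1] == "S") {
      seq <- str_sub(seq, ops$len[1] + 1L)
      ops <- ops[-1, , drop = FALSE]
    }
    k <- nrow(ops)
    if (k > 0L && ops$op[k] == "S") {
      seq <- str_sub(seq, 1L, nchar(seq) - ops$len[k])
      ops <- ops[-k, , drop = FALSE]
    }
    if (any(ops$op == "S")) stop_format("SAM '%s': internal soft clip for read '%s'", path, f[1])
    if (nrow(ops) == 0L) return(NULL)
    tibble(read_id = f[1], ref_name = f[3],
           ref_start = as.integer(f[4]) - 1L,
           cigar = paste0(ops$len, ops$op, collapse = ""),
           seq = seq)
  })
  out <- list_rbind(keep(rows, ~ !is.null(.x)))
  if (nrow(out) == 0L) {
    return(tibble(read_id = character(), ref_name = character(),
                  ref_start = integer(), cigar = character(),
                  seq = character(), sample = character()))
  }
  if (any(out$ref_start < 0L)) stop_format("SAM '%s': POS < 1", path)
  out$sample <- sample
  out
}

#' Write an aligned-read tibble to SAM text
#'
#' @param reads Read tibble as produced by [read_sam()] or [simulate_pair()].
#' @param reference Reference tibble (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  check_reference(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", reference$name, nchar(reference$seq)))
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                  reads$read_id, reads$ref_name, reads$ref_start + 1L,
                  reads$cigar, reads$seq)
  writeLines(c(hdr, body), path)
  invisible(path)
}
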