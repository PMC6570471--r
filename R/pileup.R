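# Pileup construction and low-stringency candidate calling.

utils::globalVariables(c("read_id", "offset_frac"))
#
# This stand-in caller is deliberately permissive (1% AF, 4 supporting reads
# by default): the downstream QC cascade owns the real thresholds, so the
# caller's job is to surface every plausible event together with the per-read
# positional metadata the read-end filter needs.

# Extract non-reference observations and consumed-reference intervals from
# aligned reads. Reads whose CIGAR is a single M run (the vast majority of
# amplicon data) go through a vectorised matrix path; indel-bearing reads are
# walked per CIGAR op.
alignment_events <- function(reads, reference) {
  check_reference(reference)
  contig_len <- setNames(nchar(reference$seq), reference$name)
  if (nrow(reads)) {
    ends <- reads$ref_start + map_int(reads$cigar, function(c) cigar_ref_len(parse_cigar(c)))
    over <- ends > contig_len[reads$ref_name]
    if (any(is.na(over)) || any(over)) {
      bad <- reads$read_id[which(is.na(over) | over)[1]]
      abort(sprintf("read '%s' aligns past the end of its contig (or to an unknown contig)", bad),
            class = "somaticsieve_alignment_error")
    }
  }
  simple <- str_detect(reads$cigar, "^\\d+M$")

  events <- list()
  cov <- list()    # per segment: ref_name, start, end, m (consumes base?)

  # fast path: group pure-M reads by (contig, start, length)
  sreads <- reads[simple, , drop = FALSE]
  if (nrow(sreads)) {
    key <- paste(sreads$ref_name, sreads$ref_start, nchar(sreads$seq), sep = "\r")
    for (grp in split(seq_len(nrow(sreads)), key)) {
      g <- sreads[grp, , drop = FALSE]
      L <- nchar(g$seq[1])
      start <- g$ref_start[1]
      refw <- strsplit(str_sub(ref_seq(reference, g$ref_name[1]),
                               start + 1L, start + L), "")[[1]]
      mat <- matrix(unlist(strsplit(g$seq, ""), use.names = FALSE),
                    nrow = nrow(g), byrow = TRUE)
      mm <- which(mat != matrix(refw, nrow(g), L, byrow = TRUE), arr.ind = TRUE)
      if (nrow(mm)) {
        events[[length(events) + 1L]] <- tibble(
          ref_name = g$ref_name[1],
          pos0 = start + mm[, 2] - 1L,
          ref_allele = refw[mm[, 2]],
          alt_allele = mat[mm],
          read_id = g$read_id[mm[, 1]],
          offset_frac = (mm[, 2] - 1) / L
        )
      }
      cov[[length(cov) + 1L]] <- tibble(ref_name = g$ref_name[1],
                                        start = g$ref_start, end = g$ref_start + L,
                                        m = TRUE)
    }
  }

  # general path: walk CIGAR per read
  for (i in which(!simple)) {
    rd <- reads[i, ]
    ops <- parse_cigar(rd$cigar)
    refseq <- ref_seq(reference, rd$ref_name)
    alen <- nchar(rd$seq)
    qpos <- 0L            # 0-based within aligned bases
    rpos <- rd$ref_start  # 0-based reference
    for (k in seq_len(nrow(ops))) {
      len <- ops$len[k]
      op <- ops$op[k]
      if (op == "M") {
        rw <- strsplit(str_sub(refseq, rpos + 1L, rpos + len), "")[[1]]
        qw <- strsplit(str_sub(rd$seq, qpos + 1L, qpos + len), "")[[1]]
        d <- which(rw != qw)
        if (length(d)) {
          events[[length(events) + 1L]] <- tibble(
            ref_name = rd$ref_name, pos0 = rpos + d - 1L,
            ref_allele = rw[d], alt_allele = qw[d],
            read_id = rd$read_id, offset_frac = (qpos + d - 1) / alen)
        }
        cov[[length(cov) + 1L]] <- tibble(ref_name = rd$ref_name,
                                          start = rpos, end = rpos + len, m = TRUE)
        rpos <- rpos + len
        qpos <- qpos + len
      } else if (op == "D") {
        if (k == 1L || ops$op[k - 1L] != "M") {
          abort(sprintf("read '%s': deletion without a preceding aligned base", rd$read_id),
                class = "somaticsieve_alignment_error")
        }
        anchor <- rpos - 1L
        events[[length(events) + 1L]] <- tibble(
          ref_name = rd$ref_name, pos0 = anchor,
          ref_allele = str_sub(refseq, anchor + 1L, anchor + 1L + len),
          alt_allele = str_sub(refseq, anchor + 1L, anchor + 1L),
          read_id = rd$read_id, offset_frac = (qpos - 1) / alen)
        cov[[length(cov) + 1L]] <- tibble(ref_name = rd$ref_name,
                                          start = rpos, end = rpos + len, m = FALSE)
        rpos <- rpos + len
      } else if (op == "I") {
        if (k == 1L || ops$op[k - 1L] != "M") {
          abort(sprintf("read '%s': insertion without a preceding aligned base", rd$read_id),
                class = "somaticsieve_alignment_error")
        }
        anchor <- rpos - 1L
        events[[length(events) + 1L]] <- tibble(
          ref_name = rd$ref_name, pos0 = anchor,
          ref_allele = str_sub(refseq, anchor + 1L, anchor + 1L),
          alt_allele = paste0(str_sub(refseq, anchor + 1L, anchor + 1L),
                              str_sub(rd$seq, qpos + 1L, qpos + len)),
          read_id = rd$read_id, offset_frac = (qpos - 1) / alen)
        qpos <- qpos + len
      } else {
        stop_format("read '%s': unexpected CIGAR op '%s' after parsing", rd$read_id, op)
      }
    }
  }

  events <- if (length(events)) list_rbind(events) else {
    tibble(ref_name = character(), pos0 = integer(), ref_allele = character(),
           alt_allele = character(), read_id = character(), offset_frac = double())
  }
  cov <- if (length(cov)) list_rbind(cov) else {
    tibble(ref_name = character(), start = integer(), end = integer(), m = logical())
  }
  list(events = events, segments = cov)
}

# per-position depth from consumed-reference segments
coverage_table <- function(segments) {
  if (nrow(segments) == 0L) {
    return(tibble(ref_name = character(), pos0 = integer(),
                  depth = integer(), m_depth = integer()))
  }
  out <- list()
  for (ct in unique(segments$ref_name)) {
    s <- segments[segments$ref_name == ct, , drop = FALSE]
    ir_all <- IRanges::IRanges(start = s$start + 1L, end = s$end)
    ir_m <- IRanges::IRanges(start = s$start[s$m] + 1L, end = s$end[s$m])
    cov_all <- IRanges::coverage(ir_all)
    cov_m <- IRanges::coverage(ir_m, width = length(cov_all))
    v_all <- as.integer(cov_all)
    v_m <- as.integer(cov_m)
    pos <- which(v_all > 0L)
    out[[ct]] <- tibble(ref_name = ct, pos0 = pos - 1L,
                        depth = v_all[pos], m_depth = v_m[pos])
  }
  list_rbind(out)
}

#' Build per-position pileups from aligned reads
#'
#' Every reference position consumed by at least one alignment gets a pileup
#' column. Deletions consume reference positions without contributing a base
#' call; deletion and insertion alleles are recorded as left-anchored alleles
#' at the preceding aligned position (VCF convention).
#'
#' @param reads Aligned-read tibble ([read_sam()] / [simulate_pair()]).
#' @param reference Reference tibble.
#' @return An object of class `amp_pileup` carrying the per-allele columns,
#'   the per-read non-reference events (with read-offset fractions), and
#'   per-position depth. Access the column table with `$columns`.
#' @export
build_pileup <- function(reads, reference) {
  ev <- alignment_events(reads, reference)
  coverage <- coverage_table(ev$segments)
  snv <- ev$events[nchar(ev$events$ref_allele) == 1L &
                     nchar(ev$events$alt_allele) == 1L, , drop = FALSE]
  alt_counts <- ev$events |>
    group_by(.data$ref_name, .data$pos0, .data$ref_allele, .data$alt_allele) |>
    summarise(count = n(), .groups = "drop")
  snv_per_pos <- snv |>
    count(.data$ref_name, .data$pos0, name = "n_snv")
  ref_rows <- coverage |>
    filter(.data$m_depth > 0L) |>
    left_join(snv_per_pos, by = c("ref_name", "pos0")) |>
    mutate(n_snv = dplyr::coalesce(.data$n_snv, 0L))
  ref_base <- map2_chr_ref(ref_rows, reference)
  ref_rows <- ref_rows |>
    mutate(ref_allele = ref_base, alt_allele = ref_base,
           count = .data$m_depth - .data$n_snv) |>
    select("ref_name", "pos0", "ref_allele", "alt_allele", "count")
  columns <- bind_rows(ref_rows, alt_counts) |>
    left_join(select(coverage, "ref_name", "pos0", "depth"),
              by = c("ref_name", "pos0")) |>
    arrange(.data$ref_name, .data$pos0, .data$alt_allele != .data$ref_allele,
            .data$alt_allele)
  structure(list(columns = columns, events = ev$events, coverage = coverage,
                 reference = reference, n_reads = nrow(reads)),
            class = "amp_pileup")
}

# reference base lookup for a (ref_name, pos0) table
map2_chr_ref <- function(rows, reference) {
  if (nrow(rows) == 0L) return(character())
  out <- character(nrow(rows))
  for (ct in unique(rows$ref_name)) {
    idx <- rows$ref_name == ct
    chars <- strsplit(ref_seq(reference, ct), "")[[1]]
    out[idx] <- chars[rows$pos0[idx] + 1L]
  }
  out
}

#' @export
print.amp_pileup <- function(x, ...) {
  cat(sprintf("<amp_pileup> %d reads, %d covered positions, %d non-reference events\n",
              x$n_reads, nrow(x$coverage), nrow(x$events)))
  invisible(x)
}

#' Call low-stringency variant candidates from a pileup
#'
#' Emits one candidate per (site, alternate allele) whose support meets the
#' permissive caller floor. Each candidate carries the exact per-supporting-
#' read offset fractions (`supports` list-column) consumed by the read-end
#' filter, and the count of distinct non-reference alleles seen at the site
#' in the raw pileup (`n_alt_alleles_at_site`), consumed by the multi-allele
#' filter.
#'
#' @param pileup An `amp_pileup` from [build_pileup()].
#' @param min_alt_reads Minimum alt-supporting reads (default 4).
#' @param min_af Minimum allele frequency (default 0.01).
#' @return A tibble of candidates sorted by position (alt alleles at one site
#'   in lexicographic order): `ref_name`, `pos0`, `ref_allele`, `alt_allele`,
#'   `depth`, `alt_reads`, `af`, `n_alt_alleles_at_site`, `supports`
#'   (list-column of tibbles with `read_id`, `offset_frac`).
#' @export
call_candidates <- function(pileup, min_alt_reads = 4L, min_af = 0.01) {
  if (!inherits(pileup, "amp_pileup")) stop_format("`pileup` must come from build_pileup()")
  if (min_alt_reads < 1L) stop_config("min_alt_reads must be >= 1")
  if (!(min_af > 0 && min_af < 1)) stop_config("min_af must be in (0, 1)")
  ev <- pileup$events
  empty <- tibble(ref_name = character(), pos0 = integer(),
                  ref_allele = character(), alt_allele = character(),
                  depth = integer(), alt_reads = integer(), af = double(),
                  n_alt_alleles_at_site = integer(), supports = list())
  if (nrow(ev) == 0L) return(empty)
  site_alleles <- ev |>
    distinct(.data$ref_name, .data$pos0, .data$ref_allele, .data$alt_allele) |>
    count(.data$ref_name, .data$pos0, name = "n_alt_alleles_at_site")
  cand <- ev |>
    group_by(.data$ref_name, .data$pos0, .data$ref_allele, .data$alt_allele) |>
    summarise(alt_reads = n(),
              supports = list(tibble(read_id = read_id,
                                     offset_frac = offset_frac)),
              .groups = "drop") |>
    left_join(select(pileup$coverage, "ref_name", "pos0", "depth"),
              by = c("ref_name", "pos0")) |>
    left_join(site_alleles, by = c("ref_name", "pos0")) |>
    mutate(af = .data$alt_reads / .data$depth) |>
    filter(.data$alt_reads >= min_alt_reads, .data$af >= min_af) |>
    arrange(.data$ref_name, .data$pos0, .data$alt_allele) |>
    select("ref_name", "pos0", "ref_allele", "alt_allele", "depth",
           "alt_reads", "af", "n_alt_alleles_at_site", "supports")
  cand
}
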