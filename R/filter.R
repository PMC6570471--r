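# Somatic QC cascade for matched tumor-normal amplicon candidates:
#   1. matched-normal subtraction (exact pos/ref/alt key);
#   2. read-end exclusion: drop supporting reads whose variant base lies in
#      the terminal 15% of aligned bases, re-evaluate AF on what remains;
#   3. multi-allele gate (> 2 distinct alt alleles at the site);
#   4. depth floor (>= 100 reads);
#   5. AF-tiered support: AF 2-5% needs >= 10 alt reads, AF > 5% needs >= 25.
#
# All filters are evaluated for every candidate (no short-circuit), so the
# verdict trail is a complete diagnostic; PASS/FAIL is unaffected.

FILTER_ORDER <- c("end_read", "multiallelic", "min_depth", "low_af", "tier_support")

#' Somatic filter parameters
#'
#' Defaults are the published screening thresholds: terminal 15% read-end
#' exclusion, at most 2 distinct variant alleles per site, a 100-read depth
#' floor, and tiered minimum support (10 alt reads when the re-evaluated AF
#' is 2-5% inclusive, 25 alt reads when it exceeds 5%). Re-evaluated AF below
#' 2% is rejected outright.
#'
#' @param end_frac Terminal fraction of aligned read length flagged at each end.
#' @param max_alt_alleles Maximum distinct alt alleles tolerated at a site.
#' @param min_depth Minimum total read depth.
#' @param tier_low List with `af_lo`, `af_hi`, `min_support` for the low tier.
#' @param tier_high List with `af_gt`, `min_support` for the high tier.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(end_frac = 0.15,
                          max_alt_alleles = 2L,
                          min_depth = 100L,
                          tier_low = list(af_lo = 0.02, af_hi = 0.05, min_support = 10L),
                          tier_high = list(af_gt = 0.05, min_support = 25L)) {
  if (!(end_frac > 0 && end_frac < 0.5)) stop_config("need 0 < end_frac < 0.5")
  if (min_depth < 1L) stop_config("min_depth must be >= 1")
  if (max_alt_alleles < 1L) stop_config("max_alt_alleles must be >= 1")
  if (tier_low$min_support < 1L || tier_high$min_support < 1L) {
    stop_config("tier min_support values must be >= 1")
  }
  if (!(tier_low$af_lo <= tier_low$af_hi && tier_low$af_hi <= tier_high$af_gt)) {
    stop_config("AF tier bounds must be ordered: af_lo <= af_hi <= af_gt")
  }
  structure(list(end_frac = end_frac,
                 max_alt_alleles = as.integer(max_alt_alleles),
                 min_depth = as.integer(min_depth),
                 tier_low = tier_low, tier_high = tier_high),
            class = "filter_params")
}

candidate_key <- function(x) {
  paste(x$ref_name, x$pos0, x$ref_allele, x$alt_allele, sep = "\r")
}

#' Subtract matched-normal candidates from tumor candidates
#'
#' Removes every tumor candidate whose exact (contig, position, ref allele,
#' alt allele) key also appears among the normal sample's candidates, leaving
#' the somatic candidate list. Matching is allele-exact: a tumor allele at a
#' germline-variant position survives if the normal carries a different
#' alternate allele there.
#'
#' @param tumor,normal Candidate tibbles from [call_candidates()], both
#'   against the same reference.
#' @return The retained tumor candidates, order preserved.
#' @export
subtract_normal <- function(tumor, normal) {
  tumor[!(candidate_key(tumor) %in% candidate_key(normal)), , drop = FALSE]
}

#' Re-evaluate a candidate after read-end removal
#'
#' A supporting read is end-flagged when the variant base lies within the
#' terminal `end_frac` of its aligned bases (offset fraction < `end_frac` or
#' >= 1 - `end_frac`). Flagged supports are removed from both the alt count
#' and the AF denominator; reference-supporting reads are retained in the
#' denominator. 0/0 is defined as 0.
#'
#' @param candidate One-row candidate tibble (with `supports`).
#' @param end_frac Terminal fraction (default 0.15).
#' @return A list: `ao_core`, `af_core`, `end_flagged_supports` (tibble of
#'   the removed supports).
#' @export
end_read_reeval <- function(candidate, end_frac = 0.15) {
  sup <- candidate$supports[[1]]
  flagged <- sup$offset_frac < end_frac | sup$offset_frac >= 1 - end_frac
  ao_core <- candidate$alt_reads - sum(flagged)
  denom <- candidate$depth - sum(flagged)
  af_core <- if (denom <= 0) 0 else ao_core / denom
  list(ao_core = as.integer(ao_core), af_core = af_core,
       end_flagged_supports = sup[flagged, , drop = FALSE])
}

#' Apply the somatic QC cascade to normal-subtracted candidates
#'
#' Evaluates, for every candidate, the ordered filter set
#' `end_read` (no supporting read remains after read-end removal),
#' `multiallelic` (more than `max_alt_alleles` distinct alt alleles at the
#' site in the raw tumor pileup), `min_depth` (raw depth below the floor),
#' `low_af` (interior support remains but re-evaluated AF is below the 2%
#' reporting floor) and `tier_support` (too few alt reads for the AF tier).
#' Every failing filter is recorded in the verdict trail; a candidate passes
#' iff its trail is empty.
#'
#' @param candidates Candidate tibble (already normal-subtracted).
#' @param params A [filter_params()] object.
#' @return A verdict tibble: the candidate columns plus `n_end_flagged`,
#'   `ao_core`, `af_core`, `trail` (list-column of failed filter labels, in
#'   fixed order) and `passed`.
#' @export
apply_qc <- function(candidates, params = filter_params()) {
  if (!inherits(params, "filter_params")) stop_config("`params` must come from filter_params()")
  n <- nrow(candidates)
  ao_core <- integer(n); af_core <- double(n); n_flag <- integer(n)
  trail <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- candidates[i, ]
    re <- end_read_reeval(cand, params$end_frac)
    ao_core[i] <- re$ao_core
    af_core[i] <- re$af_core
    n_flag[i] <- nrow(re$end_flagged_supports)
    fails <- c(
      end_read     = re$ao_core == 0L,
      multiallelic = cand$n_alt_alleles_at_site > params$max_alt_alleles,
      min_depth    = cand$depth < params$min_depth,
      low_af       = re$ao_core > 0L && re$af_core < params$tier_low$af_lo,
      tier_support =
        (re$af_core >= params$tier_low$af_lo && re$af_core <= params$tier_low$af_hi &&
           re$ao_core < params$tier_low$min_support) ||
        (re$af_core > params$tier_high$af_gt && re$ao_core < params$tier_high$min_support)
    )
    trail[[i]] <- FILTER_ORDER[fails[FILTER_ORDER]]
  }
  out <- candidates
  out$n_end_flagged <- n_flag
  out$ao_core <- ao_core
  out$af_core <- af_core
  out$trail <- trail
  out$passed <- lengths(trail) == 0L
  out
}

# verdict rows for candidates removed at subtraction
in_normal_verdicts <- function(candidates) {
  n <- nrow(candidates)
  out <- candidates
  out$n_end_flagged <- rep.int(0L, n)
  out$ao_core <- as.integer(candidates$alt_reads)
  out$af_core <- candidates$af
  out$trail <- rep(list("in_normal"), n)
  out$passed <- rep.int(FALSE, n)
  out
}

#' Run the full somatic screening pipeline on a matched pair
#'
#' Pileup and candidate calling on tumor and normal, matched-normal
#' subtraction, then the QC cascade. Candidates removed at subtraction are
#' reported with trail `in_normal` so the output is a complete account of
#' every tumor candidate.
#'
#' @param tumor,normal Aligned-read tibbles or paths to SAM files.
#' @param reference Reference tibble or path to a FASTA file.
#' @param params [filter_params()].
#' @param min_alt_reads,min_af Caller floors passed to [call_candidates()].
#' @param vcf Optional path; when given, verdicts are written as VCF 4.2.
#' @return An object of class `somatic_screen`: a list with `verdicts`
#'   (tibble sorted by position), `params`, and candidate counts. Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
run_somatic_pipeline <- function(tumor, normal, reference,
                                 params = filter_params(),
                                 min_alt_reads = 4L, min_af = 0.01,
                                 vcf = NULL) {
  if (is.character(reference)) reference <- read_fasta(reference)
  if (is.character(tumor)) tumor <- read_sam(tumor, sample = "tumor")
  if (is.character(normal)) normal <- read_sam(normal, sample = "normal")
  tcand <- call_candidates(build_pileup(tumor, reference), min_alt_reads, min_af)
  ncand <- call_candidates(build_pileup(normal, reference), min_alt_reads, min_af)
  somatic <- subtract_normal(tcand, ncand)
  removed <- tcand[candidate_key(tcand) %in% candidate_key(ncand), , drop = FALSE]
  verdicts <- bind_rows(apply_qc(somatic, params), in_normal_verdicts(removed)) |>
    arrange(.data$ref_name, .data$pos0, .data$alt_allele)
  res <- structure(
    list(verdicts = verdicts, params = params,
         n_tumor_candidates = nrow(tcand), n_normal_candidates = nrow(ncand),
         n_pass = sum(verdicts$passed)),
    class = "somatic_screen")
  if (!is.null(vcf)) write_vcf(verdicts, vcf)
  res
}

#' @export
print.somatic_screen <- function(x, ...) {
  cat(sprintf("<somatic_screen> %d tumor candidates, %d normal candidates\n",
              x$n_tumor_candidates, x$n_normal_candidates))
  cat(sprintf("  %d PASS / %d total verdicts\n", x$n_pass, nrow(x$verdicts)))
  labs <- table(unlist(x$verdicts$trail))
  if (length(labs)) {
    cat("  failed-filter labels:",
        paste(sprintf("%s=%d", names(labs), labs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a somatic screen result
#'
#' @param x A `somatic_screen`.
#' @param ... Unused.
#' @return One row per verdict, with the trail flattened to a `filter`
#'   string (`"PASS"` or semicolon-joined labels) and `supports` dropped.
#' @export
tidy.somatic_screen <- function(x, ...) {
  x$verdicts |>
    mutate(filter = map_chr(.data$trail,
                            ~ if (length(.x) == 0L) "PASS" else paste(.x, collapse = ";"))) |>
    select("ref_name", "pos0", "ref_allele", "alt_allele", "depth",
           "alt_reads", "af", "n_end_flagged", "ao_core", "af_core",
           "filter", "passed")
}

#' One-row summary of a somatic screen
#'
#' @param x A `somatic_screen`.
#' @param ... Unused.
#' @return A tibble with candidate counts and per-filter failure counts.
#' @export
glance.somatic_screen <- function(x, ...) {
  labs <- unlist(x$verdicts$trail)
  counts <- setNames(
    as.integer(table(factor(labs, levels = c("in_normal", FILTER_ORDER)))),
    paste0("n_", c("in_normal", FILTER_ORDER)))
  bind_cols(
    tibble(n_tumor_candidates = x$n_tumor_candidates,
           n_normal_candidates = x$n_normal_candidates,
           n_verdicts = nrow(x$verdicts),
           n_pass = x$n_pass),
    as_tibble(as.list(counts)))
}

#' Plot the filter outcome of a somatic screen
#'
#' Bar panel of verdict counts per outcome label, and raw vs re-evaluated AF
#' for every candidate, coloured by outcome.
#'
#' @param object A `somatic_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.somatic_screen <- function(object, ...) {
  d <- tidy(object) |>
    mutate(outcome = if_else(.data$passed, "PASS",
                             map_chr(str_split(.data$filter, ";"), 1L)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "first filter outcome", y = "candidates",
                  title = "Somatic screen verdicts") +
    ggplot2::theme_minimal()
}

#' Scatter of raw versus re-evaluated allele frequency
#'
#' Shows how read-end removal moves each candidate's AF; end artifacts drop
#' to zero, clean variants stay on the diagonal.
#'
#' @param screen A `somatic_screen`.
#' @return A ggplot object.
#' @export
plot_af_reeval <- function(screen) {
  d <- tidy(screen)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$af, y = .data$af_core,
                                  colour = .data$passed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "raw AF", y = "AF after read-end removal",
                  colour = "passed") +
    ggplot2::theme_minimal()
}
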