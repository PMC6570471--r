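# Bundled end-to-end demonstration: a fixed synthetic panel (the "study
# conditions") run through simulator -> caller -> QC cascade -> annotation.
#
# The panel design -- reference sequence, amplicon tiling, planted variant
# positions and allele fractions -- is a fixture generated from a fixed
# design seed, so protein-effect labels and expected outcomes are stable;
# only the sequencing randomness (carrier and error draws) follows the
# user-supplied seed.

#' Default demonstration configuration
#'
#' Five overlapping 200-bp amplicons at 1,000x over a synthetic 900-bp
#' single-ORF gene, with 2 germline heterozygous SNVs, 3 clean somatic SNVs
#' at AF 3/8/20%, 1 somatic 1-bp deletion at AF 15% (a frameshift), and one
#' somatic SNV planted in the terminal 15% of its amplicon so that every
#' supporting read is a read-end artifact. The error model is zero so that
#' every verdict is exactly attributable to a planted variant.
#'
#' @return A list describing the panel, planted variants, error model and
#'   filter/caller parameters.
#' @export
demo_config <- function() {
  list(
    gene = "GENE1",
    ref_name = "chrS",
    n_codons = 300L,
    design_seed = 42L,
    # codons fixed so the planted somatic SNVs are E->K and the deletion a
    # frameshift at a glycine
    fixed_codons = c("34" = "GAG", "84" = "GAG", "184" = "GAG", "141" = "GGA"),
    amplicons = tibble(ref_name = "chrS",
                       start = c(0L, 150L, 300L, 450L, 600L),
                       end   = c(200L, 350L, 500L, 650L, 800L),
                       depth = 1000L),
    variants = tibble(
      name  = c("germ1", "germ2", "som_af03", "som_af08", "som_af20",
                "som_del15", "end_artifact"),
      pos0  = c(80L, 380L, 99L, 249L, 549L, 420L, 775L),
      type  = c("snv", "snv", "snv", "snv", "snv", "del1", "snv"),
      af    = c(0.5, 0.5, 0.03, 0.08, 0.20, 0.15, 0.08),
      scope = c("germline", "germline", "somatic", "somatic", "somatic",
                "somatic", "somatic"),
      artifact = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    model = error_model(e_interior = 0, e_end = 0, end_frac = 0.15),
    caller = list(min_alt_reads = 4L, min_af = 0.01),
    params = filter_params()
  )
}

#' Build the demo reference from a configuration
#'
#' @param config A [demo_config()] list.
#' @return A reference tibble (`name`, `seq`).
#' @export
demo_reference <- function(config = demo_config()) {
  tx <- make_synthetic_transcript(config$n_codons, config$fixed_codons,
                                  seed = config$design_seed)
  tibble(name = config$ref_name, seq = tx$seq)
}

#' Materialise the demo planted-variant table against the reference
#'
#' Alleles are derived from the reference at run time: SNV alternates are the
#' transition partner of the reference base; `del1` rows become left-anchored
#' 1-bp deletions.
#'
#' @param config A [demo_config()] list.
#' @param reference Reference tibble from [demo_reference()].
#' @return A planted-variant tibble for [simulate_pair()] (plus `name` and
#'   `artifact` bookkeeping columns).
#' @export
demo_planted <- function(config = demo_config(), reference = demo_reference(config)) {
  seq <- ref_seq(reference, config$ref_name)
  v <- config$variants
  ref_allele <- character(nrow(v)); alt_allele <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    if (v$type[i] == "snv") {
      ref_allele[i] <- str_sub(seq, v$pos0[i] + 1L, v$pos0[i] + 1L)
      alt_allele[i] <- transition_base(ref_allele[i])
    } else if (v$type[i] == "del1") {
      ref_allele[i] <- str_sub(seq, v$pos0[i] + 1L, v$pos0[i] + 2L)
      alt_allele[i] <- str_sub(seq, v$pos0[i] + 1L, v$pos0[i] + 1L)
    } else {
      stop_config("unknown planted variant type '%s'", v$type[i])
    }
  }
  mutate(v, ref_name = config$ref_name,
         ref_allele = ref_allele, alt_allele = alt_allele)
}

#' Transcript model for the demo gene
#'
#' @param config A [demo_config()] list.
#' @return A [transcript_model()] covering the single-exon ORF.
#' @export
demo_transcript_model <- function(config = demo_config()) {
  transcript_model(config$gene, config$ref_name, "+",
                   list(c(0L, 3L * config$n_codons)))
}

#' Run the bundled end-to-end demonstration
#'
#' Simulates the matched pair, runs the full somatic screen, annotates
#' passing variants, compares the PASS set against the planted truth, and
#' (optionally) writes `reference.fasta`, `tumor.sam`, `normal.sam`,
#' `truth.tsv`, `somatic.vcf`, `annotated.tsv` and `report.json` to
#' `out_dir`. The report is a deterministic function of the seed: identical
#' seeds give byte-identical JSON.
#'
#' @param out_dir Output directory, created if needed; `NULL` to skip file
#'   output.
#' @param seed Integer seed for the sequencing randomness.
#' @param config A [demo_config()]-shaped list.
#' @return Invisibly, a list: `screen` (the [run_somatic_pipeline()] result),
#'   `annotated` (effect tibble for PASS records), `truth`, and `report`
#'   (named list of counts also written as JSON).
#' @export
run_demo <- function(out_dir = NULL, seed = 1L, config = demo_config()) {
  reference <- demo_reference(config)
  planted <- demo_planted(config, reference)
  sim <- simulate_pair(reference, config$amplicons,
                       planted[, c("ref_name", "pos0", "ref_allele",
                                   "alt_allele", "af", "scope")],
                       model = config$model, seed = seed)
  screen <- run_somatic_pipeline(sim$tumor, sim$normal, reference,
                                 params = config$params,
                                 min_alt_reads = config$caller$min_alt_reads,
                                 min_af = config$caller$min_af)
  pass <- screen$verdicts[screen$verdicts$passed, , drop = FALSE]
  annotated <- if (nrow(pass)) {
    annotate_variants(
      pass[, c("ref_name", "pos0", "ref_allele", "alt_allele",
               "depth", "alt_reads", "af", "af_core")],
      demo_transcript_model(config), reference)
  } else tibble()

  clean <- planted[planted$scope == "somatic" & !planted$artifact, , drop = FALSE]
  pass_keys <- candidate_key(pass)
  truth_keys <- candidate_key(clean)
  g <- glance(screen)
  report <- c(
    list(seed = as.integer(seed),
         params = list(end_frac = config$params$end_frac,
                       max_alt_alleles = config$params$max_alt_alleles,
                       min_depth = config$params$min_depth,
                       tier_low_min_support = config$params$tier_low$min_support,
                       tier_high_min_support = config$params$tier_high$min_support),
         n_planted_somatic_clean = nrow(clean),
         n_truth_recovered = sum(truth_keys %in% pass_keys),
         n_false_pass = sum(!(pass_keys %in% truth_keys)),
         pass_count = nrow(pass)),
    as.list(g[, grep("^n_", names(g), value = TRUE)])
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(reference, file.path(out_dir, "reference.fasta"))
    write_sam(sim$tumor, reference, file.path(out_dir, "tumor.sam"))
    write_sam(sim$normal, reference, file.path(out_dir, "normal.sam"))
    write.table(planted, file.path(out_dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_vcf(screen$verdicts, file.path(out_dir, "somatic.vcf"))
    ann_out <- if (nrow(annotated)) {
      annotated[, c("ref_name", "pos0", "ref_allele", "alt_allele",
                    "af_core", "gene", "kind", "label")]
    } else annotated
    write.table(ann_out, file.path(out_dir, "annotated.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(screen = screen, annotated = annotated, truth = planted,
                 report = report))
}
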