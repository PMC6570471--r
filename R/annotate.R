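# Codon-level protein-effect annotation against a transcript model.
#
# Labels follow the compact clinical style: "E20K" (missense), "E20*"
# (nonsense), "E20E" (synonymous), "Frameshift at G488" (frameshift, named
# for the reference amino acid of the first codon whose composition changes).
# No downstream-consequence tail is predicted.

#' Construct a transcript model
#'
#' @param gene Gene symbol.
#' @param ref_name Contig the CDS lives on.
#' @param strand `"+"` or `"-"`.
#' @param cds_intervals List of 0-based half-open `c(start, end)` genomic
#'   intervals, sorted 5'->3' in transcript orientation (descending genomic
#'   coordinates on the minus strand). Total length must be divisible by 3.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene, ref_name, strand, cds_intervals) {
  if (!strand %in% c("+", "-")) stop_config("strand must be '+' or '-'")
  iv <- map(cds_intervals, as.integer)
  if (!length(iv) || any(map_int(iv, length) != 2L)) {
    stop_config("cds_intervals must be a list of c(start, end) pairs")
  }
  if (any(map_int(iv, ~ .x[2] - .x[1]) < 1L)) stop_config("empty CDS interval")
  total <- sum(map_int(iv, ~ .x[2] - .x[1]))
  if (total %% 3L != 0L) stop_config("total CDS length %d is not divisible by 3", total)
  starts <- map_int(iv, 1L)
  ord <- if (strand == "+") !is.unsorted(starts, strictly = TRUE)
         else !is.unsorted(rev(starts), strictly = TRUE)
  if (!ord) stop_config("cds_intervals must be sorted 5'->3' in transcript orientation")
  structure(list(gene = gene, ref_name = ref_name, strand = strand,
                 cds_intervals = iv, cds_len = total),
            class = "transcript_model")
}

#' Read a transcript model from JSON
#'
#' Expected keys: `gene`, `ref_name`, `strand`, `cds_intervals` (array of
#' `[start, end]` pairs, 0-based half-open).
#'
#' @param path Path to a JSON file.
#' @return A [transcript_model()].
#' @export
read_transcript_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  transcript_model(j$gene, j$ref_name, j$strand,
                   map(j$cds_intervals, ~ as.integer(unlist(.x))))
}

#' Write a transcript model to JSON
#'
#' @param model A [transcript_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_model <- function(model, path) {
  jsonlite::write_json(
    list(gene = model$gene, ref_name = model$ref_name, strand = model$strand,
         cds_intervals = model$cds_intervals),
    path, auto_unbox = TRUE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# genomic 0-based positions of CDS bases, in transcript (5'->3') order
cds_genomic_positions <- function(model) {
  unlist(map(model$cds_intervals, function(iv) {
    p <- seq.int(iv[1], iv[2] - 1L)
    if (model$strand == "-") rev(p) else p
  }), use.names = FALSE)
}

# CDS nucleotide string in transcript orientation
cds_sequence <- function(model, reference) {
  chars <- strsplit(ref_seq(reference, model$ref_name), "")[[1]]
  b <- chars[cds_genomic_positions(model) + 1L]
  if (model$strand == "-") b <- COMPLEMENT[b]
  paste(b, collapse = "")
}

translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop_config("CDS length not divisible by 3")
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Validate a transcript model against the reference
#'
#' Checks that the CDS translates to an open reading frame with no internal
#' stop codon.
#'
#' @param model A [transcript_model()].
#' @param reference Reference tibble.
#' @return The model, invisibly; errors on inconsistency.
#' @export
validate_transcript_model <- function(model, reference) {
  aa <- translate_cds(cds_sequence(model, reference))
  body <- str_sub(aa, 1L, nchar(aa) - 1L)
  if (str_detect(body, "\\*")) {
    stop_config("CDS of '%s' contains an internal stop codon", model$gene)
  }
  invisible(model)
}

effect_row <- function(gene, kind, aa_pos = NA_integer_, ref_aa = NA_character_,
                       alt_aa = NA_character_, label = NA_character_) {
  tibble(gene = gene, kind = kind, aa_pos = as.integer(aa_pos),
         ref_aa = ref_aa, alt_aa = alt_aa, label = label)
}

#' Annotate one variant with its protein-level effect
#'
#' SNVs inside the CDS are translated before and after; indels are classified
#' frameshift (length not divisible by 3) or in-frame, labelled by the
#' reference amino acid of the first affected codon. Variants outside the CDS
#' (or spanning a CDS boundary) are returned as `non_coding`.
#'
#' @param variant One-row tibble with `ref_name`, `pos0`, `ref_allele`,
#'   `alt_allele` (left-anchored indels).
#' @param model A [transcript_model()].
#' @param reference Reference tibble.
#' @return A one-row tibble: `gene`, `kind` (`missense`, `synonymous`,
#'   `nonsense`, `frameshift`, `inframe_indel` or `non_coding`), `aa_pos`,
#'   `ref_aa`, `alt_aa`, `label`.
#' @export
annotate_variant <- function(variant, model, reference) {
  if (!inherits(model, "transcript_model")) stop_config("`model` must be a transcript_model")
  v <- as_tibble(variant)[1, ]
  obs <- str_sub(ref_seq(reference, v$ref_name), v$pos0 + 1L,
                 v$pos0 + nchar(v$ref_allele))
  if (obs != v$ref_allele) {
    abort(sprintf("variant ref_allele '%s' at %s:%d disagrees with reference '%s'",
                  v$ref_allele, v$ref_name, v$pos0, obs),
          class = "somaticsieve_consistency_error")
  }
  if (v$ref_name != model$ref_name) return(effect_row(model$gene, "non_coding"))

  gpos <- cds_genomic_positions(model)
  cds_index <- match(seq.int(0L, max(gpos)), gpos) # genomic pos -> 1-based CDS idx
  lookup <- function(p) if (p >= 0L && p <= max(gpos)) cds_index[p + 1L] else NA_integer_
  cds <- cds_sequence(model, reference)
  rlen <- nchar(v$ref_allele); alen <- nchar(v$alt_allele)

  if (rlen == 1L && alen == 1L) {                         # SNV
    ci <- lookup(v$pos0)
    if (is.na(ci)) return(effect_row(model$gene, "non_coding"))
    codon_i <- (ci - 1L) %/% 3L + 1L
    within <- (ci - 1L) %% 3L
    codon <- str_sub(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
    alt_base <- if (model$strand == "-") unname(COMPLEMENT[v$alt_allele]) else v$alt_allele
    new_codon <- codon
    str_sub(new_codon, within + 1L, within + 1L) <- alt_base
    ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[new_codon])
    kind <- if (ref_aa == alt_aa) "synonymous"
            else if (alt_aa == "*") "nonsense"
            else "missense"
    return(effect_row(model$gene, kind, codon_i, ref_aa, alt_aa,
                      paste0(ref_aa, codon_i, alt_aa)))
  }

  # left-anchored indel
  if (str_sub(v$ref_allele, 1L, 1L) != str_sub(v$alt_allele, 1L, 1L)) {
    stop_config("indel at %s:%d is not left-anchored", v$ref_name, v$pos0)
  }
  if (rlen > 1L && alen == 1L) {                          # deletion
    del_pos <- seq.int(v$pos0 + 1L, v$pos0 + rlen - 1L)
    idx <- map_int(del_pos, lookup)
    if (all(is.na(idx))) return(effect_row(model$gene, "non_coding"))
    if (any(is.na(idx))) {
      warn(sprintf("deletion at %s:%d spans a CDS boundary; annotated as non_coding",
                   v$ref_name, v$pos0))
      return(effect_row(model$gene, "non_coding"))
    }
    first_ci <- min(idx)
    indel_len <- rlen - 1L
  } else if (rlen == 1L && alen > 1L) {                   # insertion
    anchor_ci <- lookup(v$pos0)
    shift_ci <- if (model$strand == "+") {
      if (is.na(anchor_ci)) lookup(v$pos0 + 1L) else anchor_ci + 1L
    } else {
      if (is.na(anchor_ci)) NA_integer_ else anchor_ci   # 5' neighbour on -
    }
    if (is.na(shift_ci) || shift_ci > model$cds_len) {
      return(effect_row(model$gene, "non_coding"))
    }
    first_ci <- shift_ci
    indel_len <- alen - 1L
  } else {
    stop_config("unsupported allele pair '%s'>'%s' (SNVs and simple indels only)",
                v$ref_allele, v$alt_allele)
  }
  codon_i <- (first_ci - 1L) %/% 3L + 1L
  codon <- str_sub(cds, (codon_i - 1L) * 3L + 1L, codon_i * 3L)
  ref_aa <- unname(Biostrings::GENETIC_CODE[codon])
  if (indel_len %% 3L != 0L) {
    effect_row(model$gene, "frameshift", codon_i, ref_aa, "",
               sprintf("Frameshift at %s%d", ref_aa, codon_i))
  } else {
    effect_row(model$gene, "inframe_indel", codon_i, ref_aa, "",
               sprintf("Inframe indel at %s%d", ref_aa, codon_i))
  }
}

#' Annotate a table of variants
#'
#' @param variants Tibble of variants (one row each, columns as in
#'   [annotate_variant()]).
#' @param model A [transcript_model()].
#' @param reference Reference tibble.
#' @return `variants` with the effect columns bound on.
#' @export
annotate_variants <- function(variants, model, reference) {
  eff <- map(seq_len(nrow(variants)),
             ~ annotate_variant(variants[.x, ], model, reference)) |>
    list_rbind()
  bind_cols(variants, eff)
}

#' Parse a protein-effect label back to its components
#'
#' Inverse of the labelling scheme: `"E20K"`-style substitutions and
#' `"Frameshift at G488"`-style frameshifts.
#'
#' @param label Character vector of labels.
#' @return A tibble with `kind`, `aa_pos`, `ref_aa`, `alt_aa`.
#' @export
parse_effect_label <- function(label) {
  sub <- str_match(label, "^([A-Z])(\\d+)([A-Z*])$")
  fs <- str_match(label, "^Frameshift at ([A-Z])(\\d+)$")
  tibble(
    kind = dplyr::case_when(
      !is.na(fs[, 1]) ~ "frameshift",
      !is.na(sub[, 1]) & sub[, 4] == "*" ~ "nonsense",
      !is.na(sub[, 1]) & sub[, 2] == sub[, 4] ~ "synonymous",
      !is.na(sub[, 1]) ~ "missense",
      TRUE ~ NA_character_),
    aa_pos = as.integer(dplyr::coalesce(sub[, 3], fs[, 3])),
    ref_aa = dplyr::coalesce(sub[, 2], fs[, 2]),
    alt_aa = if_else(!is.na(fs[, 1]), "", sub[, 4])
  )
}

#' Is a missense effect a glutamate-to-lysine substitution?
#'
#' @param effect Effect tibble (rows from [annotate_variant()]); all rows
#'   must be missense.
#' @return Logical vector: TRUE where the substitution is E -> K.
#' @export
is_e_to_k <- function(effect) {
  if (any(effect$kind != "missense")) {
    abort("is_e_to_k() is defined for missense effects only",
          class = "somaticsieve_contract_error")
  }
  effect$ref_aa == "E" & effect$alt_aa == "K"
}
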