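# Matched tumor/normal amplicon-sequencing simulator.
#
# Reads span their amplicon exactly (amplicon sequencing semantics), so a
# variant's offset within every read equals its offset within the amplicon:
# variants planted near an amplicon boundary land near read ends, which is the
# artifact class the positional filter targets. A uniform-random-start
# "shotgun" mode is available for property tests.
#
# Reproducibility contract: one seeded RNG; draws happen in a documented
# order -- samples (tumor then normal), amplicons in table order, then per
# amplicon (1) one carrier uniform per read for each planted variant in table
# order, (2) one uniform per read base (reads in index order, bases 5'->3')
# for error positions, (3) one uniform per error for the substituted base.
# The same seed therefore yields byte-identical output.

#' Per-base substitution error model with elevated read ends
#'
#' Amplicon platforms accumulate substitution noise toward read ends; the
#' model applies `e_end` to every base whose 0-based offset fraction within
#' the aligned read falls in the terminal `end_frac` at either end
#' (offset/length < `end_frac` or >= 1 - `end_frac`) and `e_interior`
#' elsewhere. The 0.15 default mirrors the positional filter's definition of
#' the terminal region.
#'
#' @param e_interior Interior per-base substitution rate.
#' @param e_end Per-base substitution rate within the terminal fraction.
#' @param end_frac Terminal fraction of the read length at each end.
#' @return An object of class `error_model`.
#' @export
error_model <- function(e_interior = 0.001, e_end = 0.01, end_frac = 0.15) {
  if (!(e_interior >= 0 && e_interior <= e_end && e_end < 0.5)) {
    stop_config("need 0 <= e_interior <= e_end < 0.5")
  }
  if (!(end_frac > 0 && end_frac < 0.5)) stop_config("need 0 < end_frac < 0.5")
  structure(list(e_interior = e_interior, e_end = e_end, end_frac = end_frac),
            class = "error_model")
}

transition_base <- function(base) {
  unname(c(A = "G", G = "A", C = "T", T = "C")[base])
}

# substitution targets for error draws, indexed by current base
OTHER_BASES <- matrix(
  c("C", "G", "T",
    "A", "G", "T",
    "A", "C", "T",
    "A", "C", "G"),
  nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, NULL)
)

check_amplicons <- function(amplicons, reference) {
  req <- c("ref_name", "start", "end", "depth")
  if (!all(req %in% names(amplicons))) {
    stop_config("amplicons need columns %s", paste(req, collapse = ", "))
  }
  if (any(amplicons$end - amplicons$start < 50L)) {
    stop_config("amplicons must be at least 50 bp")
  }
  if (any(amplicons$depth < 1L)) stop_config("amplicon depth must be >= 1")
  for (i in seq_len(nrow(amplicons))) {
    len <- nchar(ref_seq(reference, amplicons$ref_name[i]))
    if (amplicons$start[i] < 0L || amplicons$end[i] > len) {
      stop_config("amplicon %d outside contig '%s'", i, amplicons$ref_name[i])
    }
  }
  invisible(amplicons)
}

check_planted <- function(planted, amplicons, reference) {
  if (nrow(planted) == 0L) return(invisible(planted))
  req <- c("ref_name", "pos0", "ref_allele", "alt_allele", "af", "scope")
  if (!all(req %in% names(planted))) {
    stop_config("planted variants need columns %s", paste(req, collapse = ", "))
  }
  if (!all(planted$scope %in% c("germline", "somatic"))) {
    stop_config("planted scope must be 'germline' or 'somatic'")
  }
  if (any(planted$af <= 0 | planted$af > 1)) stop_config("planted af must be in (0, 1]")
  for (i in seq_len(nrow(planted))) {
    v <- planted[i, ]
    obs <- str_sub(ref_seq(reference, v$ref_name), v$pos0 + 1L,
                   v$pos0 + nchar(v$ref_allele))
    if (obs != v$ref_allele) {
      stop_config("planted variant at %s:%d has ref_allele '%s' but reference reads '%s'",
                  v$ref_name, v$pos0, v$ref_allele, obs)
    }
    if (nchar(v$ref_allele) > 1L || nchar(v$alt_allele) > 1L) {
      if (str_sub(v$ref_allele, 1L, 1L) != str_sub(v$alt_allele, 1L, 1L)) {
        stop_config("indel at %s:%d must be left-anchored (shared first base)",
                    v$ref_name, v$pos0)
      }
    }
    inside <- amplicons$ref_name == v$ref_name &
      amplicons$start <= v$pos0 &
      amplicons$end >= v$pos0 + nchar(v$ref_allele)
    if (!any(inside)) {
      stop_config("planted variant at %s:%d falls inside no amplicon",
                  v$ref_name, v$pos0)
    }
  }
  invisible(planted)
}

# per-base error rate profile along a read of length L
end_rate_profile <- function(L, model) {
  frac <- (seq_len(L) - 1L) / L
  ifelse(frac < model$end_frac | frac >= 1 - model$end_frac,
         model$e_end, model$e_interior)
}

# apply substitution errors to a depth x L character matrix, in place
apply_errors <- function(mat, model) {
  L <- ncol(mat)
  depth <- nrow(mat)
  rate <- end_rate_profile(L, model)
  if (all(rate == 0)) return(mat)
  # row-major fill: reads in index order, bases 5'->3'
  u <- matrix(runif(depth * L), nrow = depth, byrow = TRUE)
  err <- u < matrix(rate, nrow = depth, ncol = L, byrow = TRUE)
  idx <- which(t(err))
  if (length(idx) == 0L) return(mat)
  rows <- (idx - 1L) %/% L + 1L
  cols <- (idx - 1L) %% L + 1L
  cur <- mat[cbind(rows, cols)]
  pick <- floor(runif(length(idx)) * 3) + 1L
  known <- cur %in% DNA_BASES
  mat[cbind(rows, cols)[known, , drop = FALSE]] <-
    OTHER_BASES[cbind(match(cur[known], DNA_BASES), pick[known])]
  mat
}

# rebuild seq + CIGAR for one read carrying the given indel events
# events: tibble(rel_anchor (1-based col of anchor base), ref_len, alt_allele)
apply_indels_to_read <- function(seq_chars, events) {
  events <- events[order(events$rel_anchor), , drop = FALSE]
  L <- length(seq_chars)
  pieces <- character(0)
  cig <- character(0)
  prev <- 0L
  for (i in seq_len(nrow(events))) {
    a <- events$rel_anchor[i]
    mlen <- a - prev
    if (mlen < 1L) stop_config("overlapping planted indels on one read")
    pieces <- c(pieces, paste(seq_chars[(prev + 1L):a], collapse = ""))
    cig <- c(cig, paste0(mlen, "M"))
    d <- events$ref_len[i] - 1L
    ins <- str_sub(events$alt_allele[i], 2L)
    if (d > 0L) {                       # deletion
      cig <- c(cig, paste0(d, "D"))
      prev <- a + d
    } else {                            # insertion
      pieces <- c(pieces, ins)
      cig <- c(cig, paste0(nchar(ins), "I"))
      prev <- a
    }
  }
  if (prev < L) {
    pieces <- c(pieces, paste(seq_chars[(prev + 1L):L], collapse = ""))
    cig <- c(cig, paste0(L - prev, "M"))
  }
  # merge adjacent M runs (insertion case leaves aM bI cM already correct)
  list(seq = paste(pieces, collapse = ""), cigar = paste(cig, collapse = ""))
}

simulate_sample <- function(reference, amplicons, planted, model, sample_tag,
                            mode = "amplicon", read_len = NULL) {
  out <- vector("list", nrow(amplicons))
  for (ai in seq_len(nrow(amplicons))) {
    amp <- amplicons[ai, ]
    L <- amp$end - amp$start
    depth <- amp$depth
    refc <- strsplit(str_sub(ref_seq(reference, amp$ref_name),
                             amp$start + 1L, amp$end), "")[[1]]
    if (mode == "shotgun") {
      rl <- read_len %||% min(100L, L)
      starts <- amp$start + floor(runif(depth) * (L - rl + 1L))
      mat <- matrix("", nrow = depth, ncol = rl)
      for (j in seq_len(rl)) mat[, j] <- refc[starts - amp$start + j]
      read_starts <- as.integer(starts)
      Lr <- rl
    } else {
      mat <- matrix(refc, nrow = depth, ncol = L, byrow = TRUE)
      read_starts <- rep.int(amp$start, depth)
      Lr <- L
    }
    # planted variants, table order: one carrier uniform per read each
    indel_events <- list()
    applicable <- planted[planted$ref_name == amp$ref_name &
                            planted$pos0 >= amp$start &
                            planted$pos0 + nchar(planted$ref_allele) <= amp$end &
                            (planted$scope == "germline" | sample_tag == "tumor"), ,
                          drop = FALSE]
    for (vi in seq_len(nrow(applicable))) {
      v <- applicable[vi, ]
      carrier <- runif(depth) < v$af
      is_indel <- nchar(v$ref_allele) != nchar(v$alt_allele)
      if (is_indel && mode == "shotgun") {
        stop_config("shotgun mode supports planted SNVs only")
      }
      if (is_indel) {
        rel <- v$pos0 - amp$start + 1L
        for (r in which(carrier)) {
          key <- as.character(r)
          indel_events[[key]] <- bind_rows(
            indel_events[[key]],
            tibble(rel_anchor = rel, ref_len = nchar(v$ref_allele),
                   alt_allele = v$alt_allele))
        }
      } else {
        col <- v$pos0 - read_starts + 1L
        hit <- carrier & col >= 1L & col <= Lr
        if (any(hit)) mat[cbind(which(hit), col[hit])] <- v$alt_allele
      }
    }
    mat <- apply_errors(mat, model)
    seqs <- do.call(paste0, asplit(mat, 2L))
    cigars <- rep.int(paste0(Lr, "M"), depth)
    for (key in names(indel_events)) {
      r <- as.integer(key)
      res <- apply_indels_to_read(mat[r, ], indel_events[[key]])
      seqs[r] <- res$seq
      cigars[r] <- res$cigar
    }
    out[[ai]] <- tibble(
      read_id = sprintf("%s_a%02d_%05d", sample_tag, ai, seq_len(depth)),
      ref_name = amp$ref_name,
      ref_start = read_starts,
      cigar = cigars,
      seq = seqs,
      sample = sample_tag
    )
  }
  list_rbind(out)
}

#' Simulate a matched tumor/normal amplicon sequencing pair
#'
#' Each amplicon yields `depth` reads spanning exactly its interval. Every
#' planted variant overlapping a read is written into it with independent
#' probability `af`; germline variants are planted in both samples, somatic
#' variants in the tumor only. Substitution errors are then drawn per base
#' from `model`. Identical seeds give byte-identical output.
#'
#' @param reference Reference tibble (`name`, `seq`), e.g. from [read_fasta()].
#' @param amplicons Tibble with columns `ref_name`, `start`, `end` (0-based
#'   half-open) and `depth` (reads to generate per sample).
#' @param planted Tibble of planted variants: `ref_name`, `pos0` (0-based),
#'   `ref_allele`, `alt_allele` (indels left-anchored), `af` in (0, 1], and
#'   `scope` (`"germline"` or `"somatic"`).
#' @param model An [error_model()].
#' @param seed Integer seed.
#' @param samples Which samples to generate (default both).
#' @param mode `"amplicon"` (reads span the amplicon) or `"shotgun"`
#'   (uniform random read starts; SNVs only), the latter for property tests.
#' @param read_len Read length in shotgun mode.
#' @return A list with elements `tumor` and `normal` (aligned-read tibbles;
#'   absent samples are NULL) and `truth` (the planted-variant manifest).
#' @export
simulate_pair <- function(reference, amplicons, planted = NULL,
                          model = error_model(), seed = 1L,
                          samples = c("tumor", "normal"),
                          mode = c("amplicon", "shotgun"), read_len = NULL) {
  mode <- match.arg(mode)
  check_reference(reference)
  amplicons <- as_tibble(amplicons)
  check_amplicons(amplicons, reference)
  planted <- if (is.null(planted)) {
    tibble(ref_name = character(), pos0 = integer(), ref_allele = character(),
           alt_allele = character(), af = double(), scope = character())
  } else as_tibble(planted)
  check_planted(planted, amplicons, reference)
  samples <- match.arg(samples, several.ok = TRUE)
  set.seed(as.integer(seed))
  res <- list(tumor = NULL, normal = NULL, truth = planted)
  for (s in c("tumor", "normal")) {
    if (s %in% samples) {
      res[[s]] <- simulate_sample(reference, amplicons, planted, model, s,
                                  mode = mode, read_len = read_len)
    }
  }
  res
}

#' Plant a read-end artifact variant
#'
#' Generates error-free tumor reads over one amplicon carrying a single
#' somatic SNV whose position lies within the terminal 15% of the amplicon,
#' so every alt-supporting read places the variant within the terminal 15%
#' of its aligned bases -- the artifact class the positional filter removes.
#'
#' @param reference Reference tibble.
#' @param amplicon One-row amplicon tibble (`ref_name`, `start`, `end`, `depth`).
#' @param pos0 0-based variant position; must fall in the first or last 15%
#'   of the amplicon interval.
#' @param af Planted allele fraction.
#' @param seed Integer seed.
#' @param alt_allele Alternate base; defaults to the transition partner of the
#'   reference base.
#' @return An aligned-read tibble (tumor reads).
#' @export
plant_end_artifact <- function(reference, amplicon, pos0, af, seed = 1L,
                               alt_allele = NULL) {
  amplicon <- as_tibble(amplicon)[1, ]
  frac <- (pos0 - amplicon$start) / (amplicon$end - amplicon$start)
  if (!(frac < 0.15 || frac >= 0.85)) {
    stop_config("pos0 %d lies in the amplicon interior (offset fraction %.3f); an end artifact needs offset < 0.15 or >= 0.85",
                pos0, frac)
  }
  ref_base <- str_sub(ref_seq(reference, amplicon$ref_name), pos0 + 1L, pos0 + 1L)
  alt <- alt_allele %||% transition_base(ref_base)
  planted <- tibble(ref_name = amplicon$ref_name, pos0 = pos0,
                    ref_allele = ref_base, alt_allele = alt,
                    af = af, scope = "somatic")
  sim <- simulate_pair(reference, amplicon, planted,
                       model = error_model(0, 0, 0.15),
                       seed = seed, samples = "tumor")
  sim$tumor
}

#' Build a synthetic single-ORF coding sequence
#'
#' Draws random non-stop codons, overwrites the requested codon positions
#' with fixed codons, and terminates with a TAA stop. Used to construct
#' reference contigs whose protein-level annotations are known by design.
#'
#' @param n_codons Total codon count including the stop.
#' @param fixed_codons Named character vector: names are 1-based codon
#'   indices, values 3-letter codons (e.g. `c("20" = "GAG")`).
#' @param seed Integer seed.
#' @return A list: `seq` (CDS string, length `3 * n_codons`), `n_codons`.
#' @export
make_synthetic_transcript <- function(n_codons, fixed_codons = character(),
                                      seed = 1L) {
  if (n_codons < 2L) stop_config("n_codons must be >= 2")
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  set.seed(as.integer(seed))
  draw <- sense[floor(runif(n_codons - 1L) * length(sense)) + 1L]
  draw <- c(draw, "TAA")
  if (length(fixed_codons)) {
    idx <- as.integer(names(fixed_codons))
    if (any(is.na(idx) | idx < 1L | idx >= n_codons)) {
      stop_config("fixed codon indices must lie in [1, n_codons - 1]")
    }
    draw[idx] <- toupper(unname(fixed_codons))
  }
  list(seq = paste(draw, collapse = ""), n_codons = n_codons)
}
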