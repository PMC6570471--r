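# Auxiliary statistics: per-gene E->K missense enrichment, a two-sided
# Fisher's exact test, and delta-delta-Ct relative expression.

#' Percentage of E->K substitutions among a gene's missense mutations
#'
#' Glutamate-to-lysine (E->K) recurrence is a recognisable signature in some
#' genes; this computes 100 x (#E->K missense) / (#missense) for one gene
#' from a MAF-like mutation table. Missense labels that do not parse as
#' `<AA><pos><AA>` stay in the denominator (they are missense calls, just
#' unlabelled) and are reported via a message rather than dropped silently.
#'
#' @param records Tibble with columns `gene`, `label` (protein-change string)
#'   and `kind` (`"missense"` or anything else).
#' @param gene Gene symbol to evaluate.
#' @return Percentage in `[0, 100]`.
#' @export
ek_fraction <- function(records, gene) {
  mis <- records[records$gene == gene & records$kind == "missense", , drop = FALSE]
  if (nrow(mis) == 0L) {
    abort(sprintf("no missense records for gene '%s'; the E->K fraction is undefined", gene),
          class = "somaticsieve_undefined_ratio_error")
  }
  m <- str_match(mis$label, "^([A-Z])(\\d+)([A-Z])$")
  unparsed <- is.na(m[, 1])
  if (any(unparsed)) {
    inform(sprintf("%d missense label(s) for '%s' could not be parsed and count only in the denominator",
                   sum(unparsed), gene))
  }
  ek <- !unparsed & m[, 2] == "E" & m[, 4] == "K"
  100 * sum(ek) / nrow(mis)
}

#' E->K fraction for every gene in a mutation table
#'
#' @param records MAF-like tibble (`gene`, `label`, `kind`).
#' @return A tibble with `gene`, `n_missense`, `n_e_to_k`, `ek_percent`,
#'   genes with no missense records omitted.
#' @export
ek_fraction_by_gene <- function(records) {
  genes <- unique(records$gene[records$kind == "missense"])
  list_rbind(map(genes, function(g) {
    mis <- records[records$gene == g & records$kind == "missense", , drop = FALSE]
    m <- str_match(mis$label, "^([A-Z])(\\d+)([A-Z])$")
    ek <- !is.na(m[, 1]) & m[, 2] == "E" & m[, 4] == "K"
    tibble(gene = g, n_missense = nrow(mis), n_e_to_k = sum(ek),
           ek_percent = 100 * sum(ek) / nrow(mis))
  })) |>
    arrange(dplyr::desc(.data$ek_percent), .data$gene)
}

#' Bar plot of per-gene E->K missense enrichment
#'
#' @param records MAF-like tibble (`gene`, `label`, `kind`).
#' @param highlight Optional gene symbol drawn in a highlight colour.
#' @return A ggplot object.
#' @export
plot_ek_fraction <- function(records, highlight = NULL) {
  d <- ek_fraction_by_gene(records) |>
    mutate(gene = factor(.data$gene, levels = rev(.data$gene)),
           hl = !is.null(highlight) & .data$gene == (highlight %||% ""))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gene, y = .data$ek_percent,
                                  fill = .data$hl)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "E->K mutations / total missense (%)") +
    ggplot2::theme_minimal()
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test of association. The two-sided p-value is the
#' sum, over all tables with the observed margins, of the point
#' probabilities not exceeding that of the observed table (the classic
#' "sum of smaller probabilities" convention, with a 1e-7 relative tolerance
#' on the inclusion comparison to guard against floating-point ties; mid-p
#' is not used). Point probabilities are computed in log space from
#' log-binomial coefficients.
#'
#' @param a,b,c,d Non-negative integer counts, rows = condition, columns =
#'   outcome: `matrix(c(a, b, c, d), 2, 2, byrow = TRUE)`. Alternatively `a`
#'   may be a 2x2 matrix.
#' @return The p-value, in (0, 1].
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)    # 34/70
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2L, 2L))) stop_config("need a 2x2 table")
    cnt <- c(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
  } else {
    cnt <- base::c(a, b, c, d)
  }
  if (length(cnt) != 4L || any(is.na(cnt)) || any(cnt < 0) || any(cnt != floor(cnt))) {
    stop_config("counts must be four non-negative integers")
  }
  n <- sum(cnt)
  if (n < 1) stop_config("table total must be >= 1")
  r1 <- cnt[1] + cnt[2]; c1 <- cnt[1] + cnt[3]
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)  # degenerate margins
  k <- seq.int(max(0, r1 + c1 - n), min(r1, c1))
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  log_obs <- logp[match(cnt[1], k)]
  p <- sum(exp(logp[logp <= log_obs + 1e-7]))
  min(p, 1)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Each measurement pairs a target-gene Ct with a reference-gene Ct from the
#' same reaction (e.g. normalising against 18S rRNA). Per group,
#' `dCt = mean(target_ct - reference_ct)`; the fold change of the test group
#' over the control group is `2^-(dCt_test - dCt_control)`.
#'
#' @param test,control Tibbles with columns `target_ct` and `reference_ct`
#'   (cycle-threshold values).
#' @return Fold change (1 = no change).
#' @export
relative_expression <- function(test, control) {
  for (g in list(test, control)) {
    if (!all(c("target_ct", "reference_ct") %in% names(g)) || nrow(g) == 0L) {
      stop_config("both groups need non-empty `target_ct` and `reference_ct` columns")
    }
    if (any(g$target_ct <= 0 | g$reference_ct <= 0)) {
      stop_config("Ct values must be positive")
    }
  }
  dct_test <- mean(test$target_ct - test$reference_ct)
  dct_control <- mean(control$target_ct - control$reference_ct)
  2^-(dct_test - dct_control)
}
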