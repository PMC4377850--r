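#' Counts-per-million normalization
#'
#' @param raw raw count(s).
#' @param library_total total (clean) reads in the library; must be > 0.
#' @return `raw / library_total * 1e6`.
#' @export
normalize_cpm <- function(raw, library_total) {
  if (any(library_total <= 0)) abort("library_total must be positive")
  raw / library_total * 1e6
}

#' Two-by-two count tests for a feature across two libraries
#'
#' `test_2x2_chisq()` is the Pearson chi-square test with 1 df and no
#' continuity correction on the table (feature count, remaining reads) x
#' (CT, NT); `test_2x2_fisher()` is the two-sided Fisher exact test
#' (point-probability method). Both delegate to the stats package; the test
#' suite checks them against the textbook formula and full hypergeometric
#' enumeration.
#'
#' @param a,b,c,d table cells: `a`,`b` = feature/rest counts in the first
#'   library, `c`,`d` in the second.
#' @return the p-value.
#' @export
test_2x2_chisq <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("chi-square test requires all margins > 0")
  }
  suppressWarnings(chisq.test(tab, correct = FALSE))$p.value
}

#' @rdname test_2x2_chisq
#' @export
test_2x2_fisher <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("counts must be non-negative")
  # the enumeration can overshoot 1 by an ulp; the p-value is capped at 1
  min(fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value, 1)
}

#' Pseudocounted log2 expression ratio
#'
#' @param norm_ct,norm_nt normalized (per-million) counts.
#' @param pseudocount added to both terms so library-specific features stay
#'   finite (default 0.5 per-million units).
#' @return `log2((norm_ct + pseudocount) / (norm_nt + pseudocount))`.
#' @export
log2_fold <- function(norm_ct, norm_nt, pseudocount = 0.5) {
  if (any(pseudocount <= 0)) abort("pseudocount must be positive")
  log2((norm_ct + pseudocount) / (norm_nt + pseudocount))
}

#' Dual-threshold significance call
#'
#' A feature is significantly regulated when both the chi-square and the
#' Fisher exact p-values are below `alpha` and |log2(CT/NT)| is at least
#' `lfc`; direction follows the sign of the log2 ratio.
#'
#' @param p_chisq,p_fisher,log2_ratio per-feature statistics.
#' @param alpha significance level (default 0.05).
#' @param lfc minimum absolute log2 ratio (default 1).
#' @return tibble `significant` (logical), `direction`
#'   ("increased"/"decreased"/"constant").
#' @export
call_significant <- function(p_chisq, p_fisher, log2_ratio, alpha = 0.05,
                             lfc = 1) {
  tibble(
    significant = p_chisq < alpha & p_fisher < alpha &
      abs(log2_ratio) >= lfc,
    direction = dplyr::case_when(
      log2_ratio > 0 ~ "increased",
      log2_ratio < 0 ~ "decreased",
      TRUE ~ "constant"
    )
  )
}

#' Two-library differential expression on raw feature counts
#'
#' For every feature, tests the 2x2 table (feature count, remaining reads)
#' x (CT, NT) with the chi-square and Fisher exact tests, computes
#' per-million normalized counts and the pseudocounted log2(CT/NT) ratio,
#' and applies the dual p-value / fold-change significance rule. No
#' multiple-testing correction is applied by default (raw p < alpha);
#' Benjamini-Hochberg adjusted p-values can be requested.
#'
#' @param counts tibble with columns `id`, `count_CT`, `count_NT`.
#' @param total_ct,total_nt library totals (clean reads); default: column
#'   sums of `counts`.
#' @param alpha,lfc,pseudocount thresholds, see [call_significant()] and
#'   [log2_fold()].
#' @param adjust if TRUE, adds BH-adjusted p-value columns (`padj_chisq`,
#'   `padj_fisher`); the significance call still uses raw p-values.
#' @return tibble of class `chillmir_de`: `id`, raw and normalized counts,
#'   `log2_ratio`, `p_chisq`, `p_fisher`, `direction`, `significant`, plus
#'   presence flags `in_CT`, `in_NT`.
#' @export
diff_expression <- function(counts, total_ct = NULL, total_nt = NULL,
                            alpha = 0.05, lfc = 1, pseudocount = 0.5,
                            adjust = FALSE) {
  total_ct <- total_ct %||% sum(counts$count_CT)
  total_nt <- total_nt %||% sum(counts$count_NT)
  if (nrow(counts) == 0) {
    out <- tibble(id = character(0), raw_CT = integer(0), raw_NT = integer(0),
                  norm_CT = double(0), norm_NT = double(0),
                  log2_ratio = double(0), p_chisq = double(0),
                  p_fisher = double(0), direction = character(0),
                  significant = logical(0), in_CT = logical(0),
                  in_NT = logical(0))
    return(new_chillmir_tbl(out, "chillmir_de",
                            alpha = alpha, lfc = lfc,
                            total_ct = total_ct, total_nt = total_nt))
  }
  res <- counts |>
    mutate(raw_CT = .data$count_CT, raw_NT = .data$count_NT,
           norm_CT = normalize_cpm(.data$count_CT, total_ct),
           norm_NT = normalize_cpm(.data$count_NT, total_nt),
           log2_ratio = log2_fold(.data$norm_CT, .data$norm_NT, pseudocount),
           p_chisq = purrr::map2_dbl(.data$count_CT, .data$count_NT,
             ~ test_2x2_chisq(.x, total_ct - .x, .y, total_nt - .y)),
           p_fisher = purrr::map2_dbl(.data$count_CT, .data$count_NT,
             ~ test_2x2_fisher(.x, total_ct - .x, .y, total_nt - .y)),
           in_CT = .data$count_CT > 0, in_NT = .data$count_NT > 0)
  res <- bind_cols(res, call_significant(res$p_chisq, res$p_fisher,
                                         res$log2_ratio,
                                         alpha = alpha, lfc = lfc))
  if (adjust) {
    res <- mutate(res, padj_chisq = stats::p.adjust(.data$p_chisq, "BH"),
                  padj_fisher = stats::p.adjust(.data$p_fisher, "BH"))
  }
  keep <- c("id", "raw_CT", "raw_NT", "norm_CT", "norm_NT", "log2_ratio",
            "p_chisq", "p_fisher", "direction", "significant",
            "in_CT", "in_NT",
            if (adjust) c("padj_chisq", "padj_fisher"))
  new_chillmir_tbl(res[, keep], "chillmir_de", alpha = alpha, lfc = lfc,
                   total_ct = total_ct, total_nt = total_nt)
}

#' Partition features by library membership
#'
#' @param presence tibble with columns `id`, `in_CT`, `in_NT` (logical).
#' @return list with character vectors `shared`, `CT_only`, `NT_only`;
#'   the three are disjoint and cover every feature present in at least
#'   one library.
#' @export
venn_partition <- function(presence) {
  list(
    shared = sort(presence$id[presence$in_CT & presence$in_NT]),
    CT_only = sort(presence$id[presence$in_CT & !presence$in_NT]),
    NT_only = sort(presence$id[!presence$in_CT & presence$in_NT])
  )
}
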