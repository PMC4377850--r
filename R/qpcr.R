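#' Relative quantification of qPCR Ct tables by 2^-ddCt
#'
#' Technical replicates are aggregated as mean Ct before the delta-delta-Ct
#' computation. For every sample and assayed gene: dCt = Ct(target) -
#' Ct(reference); ddCt = dCt(sample) - dCt(calibrator); fold change =
#' 2^-ddCt. The calibrator's fold change is exactly 1 by construction.
#'
#' @param ct_table long tibble with columns `sample`, `condition`,
#'   `time_h`, `gene`, `replicate`, `ct` including reference-gene rows.
#' @param reference_gene reference gene name (e.g. "5S_rRNA" or "Actin").
#' @param calibrator_sample sample id whose expression is set to 1.
#' @return tibble of class `chillmir_qpcr`: `sample`, `condition`,
#'   `time_h`, `gene`, `mean_ct`, `sd_ct`, `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(ct_table, reference_gene, calibrator_sample) {
  if (!reference_gene %in% ct_table$gene) {
    abort(sprintf("reference gene '%s' missing from Ct table",
                  reference_gene))
  }
  if (!calibrator_sample %in% ct_table$sample) {
    abort(sprintf("calibrator sample '%s' missing from Ct table",
                  calibrator_sample))
  }
  agg <- ct_table |>
    group_by(.data$sample, .data$condition, .data$time_h, .data$gene) |>
    summarise(mean_ct = mean(.data$ct), sd_ct = stats::sd(.data$ct),
              .groups = "drop")
  refs <- agg |>
    filter(.data$gene == reference_gene) |>
    select("sample", ref_ct = "mean_ct")
  targets <- agg |>
    filter(.data$gene != reference_gene) |>
    left_join(refs, by = "sample")
  if (any(is.na(targets$ref_ct))) {
    abort("some samples are missing a reference-gene Ct")
  }
  targets <- mutate(targets, dct = .data$mean_ct - .data$ref_ct)
  out <- targets |>
    group_by(.data$gene) |>
    mutate(ddct = .data$dct -
             .data$dct[.data$sample == calibrator_sample][1],
           fold_change = 2^(-.data$ddct)) |>
    ungroup() |>
    select("sample", "condition", "time_h", "gene", "mean_ct", "sd_ct",
           "dct", "ddct", "fold_change") |>
    arrange(.data$gene, .data$condition, .data$time_h)
  new_chillmir_tbl(out, "chillmir_qpcr",
                   reference_gene = reference_gene,
                   calibrator_sample = calibrator_sample)
}

#' Per-replicate fold changes (for condition comparisons)
#'
#' Computes 2^-ddCt per technical replicate (replicate Ct paired with the
#' same-numbered reference replicate; calibrator dCt from replicate means),
#' providing the replicate-level values the CT-versus-NT t-test runs on.
#'
#' @inheritParams ddct_fold_change
#' @return tibble `sample`, `condition`, `time_h`, `gene`, `replicate`,
#'   `fold_change`.
#' @export
replicate_fold_changes <- function(ct_table, reference_gene,
                                   calibrator_sample) {
  refs <- ct_table |>
    filter(.data$gene == reference_gene) |>
    select("sample", "replicate", ref_ct = "ct")
  targets <- ct_table |>
    filter(.data$gene != reference_gene) |>
    inner_join(refs, by = c("sample", "replicate")) |>
    mutate(dct = .data$ct - .data$ref_ct)
  cal <- targets |>
    filter(.data$sample == calibrator_sample) |>
    group_by(.data$gene) |>
    summarise(cal_dct = mean(.data$dct), .groups = "drop")
  targets |>
    left_join(cal, by = "gene") |>
    mutate(fold_change = 2^(-(.data$dct - .data$cal_dct))) |>
    select("sample", "condition", "time_h", "gene", "replicate",
           "fold_change")
}

#' Compare CT and NT fold changes per time point
#'
#' A two-sample t-test (Welch by default, pooled-variance optionally) on
#' replicate fold changes at each time point, flagged significant at
#' `alpha`. Degenerate zero-variance identical groups return p = 1.
#'
#' @param fold_changes tibble with columns `condition` ("CT"/"NT"),
#'   `time_h`, `gene`, `replicate`, `fold_change` (see
#'   [replicate_fold_changes()]).
#' @param alpha significance level (default 0.05).
#' @param var_equal FALSE for Welch (default), TRUE for pooled variance.
#' @return tibble `gene`, `time_h`, `mean_CT`, `mean_NT`, `p_value`,
#'   `significant`.
#' @export
compare_conditions <- function(fold_changes, alpha = 0.05,
                               var_equal = FALSE) {
  fold_changes |>
    group_by(.data$gene, .data$time_h) |>
    summarise(p_value = {
      ct <- .data$fold_change[.data$condition == "CT"]
      nt <- .data$fold_change[.data$condition == "NT"]
      if (length(ct) < 2 || length(nt) < 2) {
        abort("compare_conditions needs >= 2 replicates per group")
      }
      if (stats::sd(ct) == 0 && stats::sd(nt) == 0) {
        # degenerate zero-variance groups: identical means are a sure null,
        # differing means a sure difference
        if (isTRUE(all.equal(mean(ct), mean(nt)))) 1 else 0
      } else {
        t.test(ct, nt, var.equal = var_equal)$p.value
      }
    },
    mean_CT = mean(.data$fold_change[.data$condition == "CT"]),
    mean_NT = mean(.data$fold_change[.data$condition == "NT"]),
    .groups = "drop") |>
    mutate(significant = .data$p_value < alpha) |>
    select("gene", "time_h", "mean_CT", "mean_NT", "p_value", "significant")
}
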