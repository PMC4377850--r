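new_chillmir_tbl <- function(x, subclass, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(subclass, class(x))
  x
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarize differential-expression results
#'
#' `tidy()` returns the per-feature table in broom column conventions;
#' `glance()` returns a one-row summary (feature counts, significant
#' features by direction, thresholds used).
#'
#' @param x a `chillmir_de` object from [diff_expression()].
#' @param ... unused.
#' @export
tidy.chillmir_de <- function(x, ...) {
  as_tibble(x) |>
    select(term = "id", estimate = "log2_ratio", p.value = "p_chisq",
           p.value.fisher = "p_fisher", "direction", "significant")
}

#' @rdname tidy.chillmir_de
#' @export
glance.chillmir_de <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_increased = sum(x$significant & x$direction == "increased"),
    n_decreased = sum(x$significant & x$direction == "decreased"),
    n_shared = sum(x$in_CT & x$in_NT),
    n_CT_only = sum(x$in_CT & !x$in_NT),
    n_NT_only = sum(!x$in_CT & x$in_NT),
    alpha = attr(x, "alpha"),
    lfc = attr(x, "lfc")
  )
}

#' Tidy and summarize degradome target calls
#'
#' @param x a `chillmir_targets` object from [call_targets()].
#' @param ... unused.
#' @export
tidy.chillmir_targets <- function(x, ...) as_tibble(x)

#' @rdname tidy.chillmir_targets
#' @export
glance.chillmir_targets <- function(x, ...) {
  cats <- table(factor(x$category, levels = 0:4))
  tibble(
    n_targets = nrow(x),
    n_mirnas = dplyr::n_distinct(x$mirna_id),
    n_transcripts = dplyr::n_distinct(x$transcript_id),
    n_category_0 = as.integer(cats["0"]), n_category_1 = as.integer(cats["1"]),
    n_category_2 = as.integer(cats["2"]), n_category_3 = as.integer(cats["3"]),
    n_category_4 = as.integer(cats["4"]),
    min_tpb = if (nrow(x)) min(x$tpb) else NA_real_,
    max_tpb = if (nrow(x)) max(x$tpb) else NA_real_
  )
}

#' Tidy and summarize qPCR quantification results
#'
#' @param x a `chillmir_qpcr` object from [ddct_fold_change()].
#' @param ... unused.
#' @export
tidy.chillmir_qpcr <- function(x, ...) {
  as_tibble(x) |>
    select(term = "sample", "condition", "time_h", "gene",
           estimate = "fold_change", "ddct")
}

#' @rdname tidy.chillmir_qpcr
#' @export
glance.chillmir_qpcr <- function(x, ...) {
  tibble(
    n_samples = dplyr::n_distinct(x$sample),
    n_genes = dplyr::n_distinct(x$gene),
    reference_gene = attr(x, "reference_gene"),
    calibrator_sample = attr(x, "calibrator_sample"),
    max_fold_change = max(x$fold_change),
    min_fold_change = min(x$fold_change)
  )
}
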