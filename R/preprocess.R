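#' Trim sequencing adapters from small RNA reads
#'
#' The insert is everything 5' of the first occurrence of the 3' adapter;
#' reads in which no 3' adapter can be detected (neither a full internal
#' match nor a read-suffix overlap of at least `min_overlap` adapter bases)
#' are flagged into the "3ADT&length" class rather than dropped. A 5'
#' adapter prefix, when given, is removed first.
#'
#' @param reads tibble with columns `id`, `sequence`.
#' @param adapter3 3' adapter sequence (required, non-empty).
#' @param adapter5 optional 5' adapter; removed when the read starts with it.
#' @param min_overlap minimum adapter prefix length accepted at the read end.
#' @return tibble `id`, `sequence` (the trimmed insert), `adapter_found`;
#'   untrimmable reads keep their full sequence and carry
#'   `adapter_found = FALSE`.
#' @export
trim_adapters <- function(reads, adapter3, adapter5 = NULL, min_overlap = 8L) {
  if (is.null(adapter3) || !nzchar(adapter3)) abort("adapter3 must be non-empty")
  adapter3 <- as_rna(adapter3)
  seqs <- as_rna(reads$sequence)
  if (!is.null(adapter5) && nzchar(adapter5)) {
    adapter5 <- as_rna(adapter5)
    has5 <- startsWith(seqs, adapter5)
    seqs[has5] <- substring(seqs[has5], nchar(adapter5) + 1L)
  }
  hit <- stringr::str_locate(seqs, stringr::fixed(adapter3))[, "start"]
  insert <- ifelse(is.na(hit), seqs, substr(seqs, 1L, hit - 1L))
  found <- !is.na(hit)
  # fall back to a partial adapter at the very end of the read
  ovs <- if (nchar(adapter3) - 1L >= min_overlap)
    seq(nchar(adapter3) - 1L, min_overlap) else integer(0)
  for (ov in ovs) {
    idx <- !found & endsWith(seqs, substr(adapter3, 1L, ov))
    insert[idx] <- substr(seqs[idx], 1L, nchar(seqs[idx]) - ov)
    found <- found | idx
  }
  tibble(id = reads$id, sequence = insert, adapter_found = found)
}

is_junk <- function(seqs, homopolymer_frac = 0.8) {
  vapply(seqs, function(s) {
    if (!nzchar(s)) return(TRUE)
    if (grepl("[^ACGUN]", s)) return(TRUE)
    b <- strsplit(s, "")[[1]]
    max(table(factor(b, levels = c("A", "C", "G", "U", "N")))) / length(b) >=
      homopolymer_frac
  }, NA, USE.NAMES = FALSE)
}

#' Length- and junk-filter trimmed reads
#'
#' Every input read lands exactly once in the output, either kept or
#' removed with a recorded reason: reads without a detected 3' adapter or
#' with lengths outside `[min_len, max_len]` go to class "3ADT&length";
#' junk reads (homopolymer fraction at least `homopolymer_frac`, or any
#' character outside the nucleotide alphabet) go to class "junk". The
#' default retention window is 15--29 nt; the narrower 19--24 nt candidacy
#' window is applied separately at the miRNA-discovery stage.
#'
#' @param trimmed output of [trim_adapters()].
#' @param min_len,max_len retained insert length bounds (nt).
#' @param homopolymer_frac junk threshold on the most frequent base.
#' @return tibble `id`, `sequence`, `kept`, `reason` (`NA` for kept reads,
#'   else "3ADT&length" or "junk").
#' @export
filter_reads <- function(trimmed, min_len = 15L, max_len = 29L,
                         homopolymer_frac = 0.8) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  len <- nchar(trimmed$sequence)
  no_adapter <- if ("adapter_found" %in% names(trimmed))
    !trimmed$adapter_found else rep(FALSE, nrow(trimmed))
  bad_len <- len < min_len | len > max_len
  junk <- is_junk(trimmed$sequence, homopolymer_frac)
  reason <- dplyr::case_when(
    no_adapter | bad_len ~ "3ADT&length",
    junk ~ "junk",
    TRUE ~ NA_character_
  )
  tibble(id = trimmed$id, sequence = as_rna(trimmed$sequence),
         kept = is.na(reason), reason = reason)
}

#' Collapse reads to unique tags with per-library counts
#'
#' @param reads named list of per-library read tibbles (columns `id`,
#'   `sequence`), e.g. `list(CT = ..., NT = ...)`; only kept reads should be
#'   passed in.
#' @return tibble with one row per distinct sequence: `sequence` plus one
#'   `count_<library>` column per library. Counts sum to the numbers of
#'   input reads.
#' @export
collapse_tags <- function(reads) {
  stopifnot(is.list(reads), !is.null(names(reads)))
  per_lib <- purrr::imap(reads, function(df, lib) {
    if (nrow(df) == 0) {
      return(tibble(sequence = character(0), !!paste0("count_", lib) := integer(0)))
    }
    dplyr::count(df, .data$sequence, name = paste0("count_", lib))
  })
  out <- purrr::reduce(per_lib, dplyr::full_join, by = "sequence")
  out <- dplyr::mutate(out, across(dplyr::starts_with("count_"),
                                   ~ tidyr::replace_na(as.integer(.x), 0L)))
  arrange(out, .data$sequence)
}

match_any_ref <- function(tags, ref_seqs) {
  if (!length(ref_seqs) || !length(tags)) return(rep(FALSE, length(tags)))
  haystack <- paste(ref_seqs, collapse = "#")
  vapply(tags, function(t) grepl(t, haystack, fixed = TRUE), NA,
         USE.NAMES = FALSE)
}

#' Classify unique tags against contaminant sets and the genome
#'
#' Each tag is searched (exact substring, sense strand) against the
#' contaminant sets in the fixed precedence order rRNA, tRNA, snoRNA,
#' snRNA, otherRfam, mRNA, repeat; the first hit wins. Tags matching none
#' of the sets are searched against the genome on both strands and labelled
#' "clean" on a hit; tags matching nothing are labelled "unmapped".
#'
#' @param tags output of [collapse_tags()].
#' @param ref a `chillmir_reference` bundle (needs `contaminant_sets` and
#'   `genome`).
#' @return the input tibble with a `class` column added.
#' @export
classify_tags <- function(tags, ref) {
  if (is.null(ref$genome) || nrow(ref$genome) == 0) {
    abort("reference bundle has an empty genome")
  }
  cls <- rep(NA_character_, nrow(tags))
  seqs <- as_rna(tags$sequence)
  for (label in TAG_CLASSES) {
    set <- ref$contaminant_sets[[label]]
    if (is.null(set) || nrow(set) == 0) next
    todo <- is.na(cls)
    if (!any(todo)) break
    hit <- match_any_ref(seqs[todo], as_rna(set$sequence))
    cls[todo][hit] <- label
  }
  todo <- is.na(cls)
  if (any(todo)) {
    gseq <- as_rna(ref$genome$sequence)
    fwd <- match_any_ref(seqs[todo], gseq)
    rev <- match_any_ref(seqs[todo], rev_comp(gseq))
    cls[todo][fwd | rev] <- "clean"
  }
  cls[is.na(cls)] <- "unmapped"
  mutate(tags, class = cls)
}

#' Library composition report
#'
#' Per-class, per-library totals and percentages in the style of a
#' two-library sRNA sequencing summary: one row per class (adapter/length
#' failures, junk, each contaminant class, clean reads, and unmapped if
#' any), with total and unique counts and percentages of the raw totals.
#' Percentages are count/raw x 100, rounded half-up to 2 decimals.
#'
#' @param classified output of [classify_tags()] (unique tags with `class`
#'   and `count_<library>` columns).
#' @param removed optional tibble of removed reads per library:
#'   columns `library`, `reason` ("3ADT&length"/"junk"), `n_total`,
#'   `n_unique`.
#' @param raw_totals named list/vector of raw read counts per library; must
#'   be at least the per-class sums.
#' @return tibble `class`, `library`, `total_count`, `total_percent`,
#'   `unique_count`, `unique_percent`, including a "Raw reads" row at 100%.
#' @export
composition_table <- function(classified, raw_totals, removed = NULL) {
  libs <- sub("^count_", "", grep("^count_", names(classified), value = TRUE))
  if (any(unlist(raw_totals) <= 0)) abort("raw totals must be positive")
  rows <- purrr::map_dfr(libs, function(lib) {
    col <- paste0("count_", lib)
    per_class <- classified |>
      group_by(.data$class) |>
      summarise(total_count = sum(.data[[col]]),
                unique_count = sum(.data[[col]] > 0), .groups = "drop") |>
      filter(.data$total_count > 0)
    if (!is.null(removed)) {
      rem <- removed |>
        filter(.data$library == lib) |>
        dplyr::transmute(class = .data$reason,
                         total_count = .data$n_total,
                         unique_count = .data$n_unique)
      per_class <- bind_rows(rem, per_class)
    }
    raw <- as.numeric(raw_totals[[lib]])
    raw_unique <- sum(per_class$unique_count)
    bind_rows(
      tibble(class = "Raw reads", total_count = raw,
             unique_count = raw_unique),
      per_class
    ) |>
      mutate(library = lib,
             total_percent = round_half_up(.data$total_count / raw * 100),
             unique_percent = round_half_up(
               .data$unique_count / max(raw_unique, 1) * 100))
  })
  class_order <- c("Raw reads", "3ADT&length", "junk", TAG_CLASSES,
                   "clean", "unmapped")
  rows |>
    mutate(class = factor(.data$class, levels = class_order)) |>
    arrange(.data$library, .data$class) |>
    mutate(class = as.character(.data$class)) |>
    select("class", "library", "total_count", "total_percent",
           "unique_count", "unique_percent")
}

#' Percentage of a raw total, rounded half-up to two decimals
#'
#' The rounding rule used throughout composition and degradome summary
#' tables.
#'
#' @param count,total non-negative counts, `total > 0`.
#' @return `count / total * 100` rounded half-up to 2 decimals.
#' @export
percent_of <- function(count, total) {
  if (any(total <= 0)) abort("total must be positive")
  round_half_up(count / total * 100)
}
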