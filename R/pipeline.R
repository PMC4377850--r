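#' Build a pipeline run configuration
#'
#' Collects the input paths and every tunable threshold of the pipeline,
#' with defaults mirroring the analysis this package implements: a 15--29
#' nt read-retention window with a separate 19--24 nt miRNA candidacy
#' window, at most 1 mismatch in the first 16 nt and 3 total for conserved
#' matching, MFEI > 0.80 for novel hairpins, dual significance thresholds
#' p < 0.05 (chi-square and Fisher) with |log2(CT/NT)| >= 1, and a maximum
#' duplex penalty of 7 for degradome site scanning.
#'
#' @param inputs named list of input paths: `srna_CT`, `srna_NT` (FASTQ),
#'   `genome`, `transcriptome`, `known_mature`, `known_hairpin` (FASTA),
#'   `contaminant_dir` (directory of `<class>.fa`), `degradome_CT`,
#'   `degradome_NT` (FASTA), `qpcr` (TSV), optional `truth` (manifest).
#' @param out_dir directory for reports.
#' @param seed integer seed recorded for provenance.
#' @param ... threshold overrides (see the defaults in the returned list).
#' @return list of class `chillmir_config`.
#' @export
run_config <- function(inputs, out_dir, seed = 1L, ...) {
  cfg <- list(
    inputs = inputs, out_dir = out_dir, seed = as.integer(seed),
    adapter3 = "AGAUCGGAAGAGC", adapter5 = NULL,
    min_len = 15L, max_len = 29L,
    candidacy_min = 19L, candidacy_max = 24L,
    max_mm_first16 = 1L, max_mm_total = 3L,
    mfei_threshold = 0.80,
    alpha = 0.05, lfc = 1, pseudocount = 0.5,
    max_score = 7, degradome_tag_length = 20L,
    qpcr_reference_gene = "5S_rRNA", qpcr_calibrator = NULL
  )
  cfg <- modifyList(cfg, list(...))
  validate_config(cfg)
  structure(cfg, class = "chillmir_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (min_len > max_len || candidacy_min > candidacy_max) {
      abort("length windows must be non-empty")
    }
    if (mfei_threshold <= 0) abort("mfei_threshold must be positive")
    if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
    if (lfc < 0) abort("lfc must be non-negative")
    if (max_score < 0) abort("max_score must be non-negative")
  })
  invisible(cfg)
}

#' Write and read a run configuration (YAML or JSON by extension)
#'
#' @param cfg a `chillmir_config`.
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @export
write_run_config <- function(cfg, path) {
  x <- unclass(cfg)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- run_config(inputs = x$inputs, out_dir = x$out_dir, seed = x$seed)
  defaults <- names(cfg)
  keep <- setdiff(names(x), c("inputs", "out_dir", "seed"))
  cfg <- modifyList(cfg, x[keep])
  # modifyList drops keys serialized as null; restore them explicitly
  for (nm in setdiff(defaults, names(cfg))) cfg[nm] <- list(NULL)
  cfg <- cfg[defaults]
  validate_config(cfg)
  structure(cfg, class = "chillmir_config")
}

#' Write a reference bundle to FASTA files
#'
#' @param ref a `chillmir_reference`.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(file.path(dir, "contaminants"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    transcriptome = file.path(dir, "transcriptome.fa"),
    known_mature = file.path(dir, "known_mature.fa"),
    known_hairpin = file.path(dir, "known_hairpin.fa"),
    contaminant_dir = file.path(dir, "contaminants")
  )
  write_seq_fasta(ref$genome, paths$genome)
  write_seq_fasta(ref$transcriptome, paths$transcriptome)
  write_seq_fasta(ref$known_mature, paths$known_mature)
  write_seq_fasta(ref$known_hairpin, paths$known_hairpin)
  for (cl in names(ref$contaminant_sets)) {
    write_seq_fasta(ref$contaminant_sets[[cl]],
                    file.path(paths$contaminant_dir, paste0(cl, ".fa")))
  }
  paths
}

#' @rdname write_reference
#' @param paths named list as returned by `write_reference()`.
#' @param adapter3 3' adapter associated with the bundle.
#' @export
read_reference <- function(paths, adapter3 = "AGAUCGGAAGAGC") {
  sets <- list()
  for (f in list.files(paths$contaminant_dir, pattern = "\\.fa$",
                       full.names = TRUE)) {
    sets[[sub("\\.fa$", "", basename(f))]] <- read_seq_fasta(f)
  }
  structure(list(
    genome = read_seq_fasta(paths$genome),
    transcriptome = read_seq_fasta(paths$transcriptome),
    known_mature = read_seq_fasta(paths$known_mature),
    known_hairpin = read_seq_fasta(paths$known_hairpin),
    contaminant_sets = sets,
    adapter3 = as_rna(adapter3)
  ), class = "chillmir_reference")
}

#' Simulate a complete input set on disk
#'
#' Generates the reference bundle and truth manifest, writes every
#' pipeline input (reference FASTAs, CT/NT small RNA FASTQs, CT/NT
#' degradome FASTAs, qPCR Ct TSV, truth manifest JSON) under `dir`, and
#' returns a ready [run_config()].
#'
#' @param params [reference_params()].
#' @param dir output directory.
#' @param seed integer seed driving every stage of the simulation.
#' @param noise noise spec for [gen_srna_library()] (NULL = noise-free).
#' @param background degradome background rate.
#' @return a `chillmir_config` whose inputs point at the written files.
#' @export
simulate_inputs <- function(params = reference_params(), dir,
                            seed = 1L, noise = NULL, background = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- gen_reference(params, seed = seed)
  ref <- bundle$reference
  truth <- bundle$truth
  paths <- write_reference(ref, dir)
  paths$srna_CT <- file.path(dir, "srna_CT.fastq")
  paths$srna_NT <- file.path(dir, "srna_NT.fastq")
  write_seq_fastq(gen_srna_library(ref, truth, "CT", noise, seed = seed + 1L),
                  paths$srna_CT)
  write_seq_fastq(gen_srna_library(ref, truth, "NT", noise, seed = seed + 2L),
                  paths$srna_NT)
  paths$degradome_CT <- file.path(dir, "degradome_CT.fa")
  paths$degradome_NT <- file.path(dir, "degradome_NT.fa")
  write_seq_fasta(gen_degradome_library(ref, truth, "CT", background,
                                        seed = seed + 3L),
                  paths$degradome_CT)
  write_seq_fasta(gen_degradome_library(ref, truth, "NT", background,
                                        seed = seed + 4L),
                  paths$degradome_NT)
  paths$qpcr <- file.path(dir, "qpcr_ct.tsv")
  write_tsv_quiet(gen_qpcr_table(truth$qpcr, seed = seed + 5L), paths$qpcr)
  paths$truth <- file.path(dir, "truth_manifest.json")
  write_truth_manifest(truth, paths$truth)
  run_config(inputs = paths, out_dir = file.path(dir, "run"),
             seed = seed, adapter3 = as_rna(params$adapter3))
}

preprocess_library <- function(fastq_path, cfg, ref, lib) {
  reads <- read_seq_fastq(fastq_path)
  trimmed <- trim_adapters(reads, cfg$adapter3, cfg$adapter5)
  filtered <- filter_reads(trimmed, cfg$min_len, cfg$max_len)
  removed <- filtered |>
    filter(!.data$kept) |>
    group_by(reason = .data$reason) |>
    summarise(n_total = dplyr::n(),
              n_unique = dplyr::n_distinct(.data$sequence),
              .groups = "drop") |>
    mutate(library = lib)
  list(raw_total = nrow(reads),
       kept = filter(filtered, .data$kept)[, c("id", "sequence")],
       removed = removed,
       log = filtered)
}

#' Run the full pipeline from a configuration
#'
#' Executes preprocessing, miRNA discovery, differential expression,
#' degradome target calling and qPCR quantification, writing all reports
#' (TSV tables, a filter log with per-read reasons, and a machine-readable
#' JSON summary) into `cfg$out_dir`. Missing inputs abort before any stage
#' runs; a failing stage leaves earlier outputs in place and flags the
#' failure in the summary.
#'
#' @param cfg a `chillmir_config` (see [run_config()],
#'   [simulate_inputs()]).
#' @return invisibly, a list with every stage result (`composition`,
#'   `mirna_calls`, `diff_expr`, `targets_CT`, `targets_NT`,
#'   `target_comparison`, `qpcr`, `qpcr_tests`, `summary`).
#' @export
run_pipeline <- function(cfg) {
  validate_config(cfg)
  required <- c("srna_CT", "srna_NT", "genome", "transcriptome",
                "known_mature", "known_hairpin", "contaminant_dir",
                "degradome_CT", "degradome_NT", "qpcr")
  missing <- required[!vapply(cfg$inputs[required], function(p)
    !is.null(p) && file.exists(p), NA)]
  if (length(missing)) {
    abort(paste("missing inputs:", paste(missing, collapse = ", ")))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  ref <- read_reference(cfg$inputs, adapter3 = cfg$adapter3)

  pp <- list(CT = preprocess_library(cfg$inputs$srna_CT, cfg, ref, "CT"),
             NT = preprocess_library(cfg$inputs$srna_NT, cfg, ref, "NT"))
  tags <- collapse_tags(list(CT = pp$CT$kept, NT = pp$NT$kept))
  classified <- classify_tags(tags, ref)
  raw_totals <- list(CT = pp$CT$raw_total, NT = pp$NT$raw_total)
  composition <- if (all(unlist(raw_totals) > 0)) {
    composition_table(classified, raw_totals,
                      removed = bind_rows(pp$CT$removed, pp$NT$removed))
  } else {
    tibble(class = character(0), library = character(0),
           total_count = double(0), total_percent = double(0),
           unique_count = integer(0), unique_percent = double(0))
  }
  write_tsv_quiet(composition, file.path(cfg$out_dir, "composition.tsv"))
  filter_log <- bind_rows(mutate(pp$CT$log, library = "CT"),
                          mutate(pp$NT$log, library = "NT"))
  write_tsv_quiet(filter_log, file.path(cfg$out_dir, "filter_log.tsv"))

  calls <- discover_mirnas(classified, ref,
                           candidacy_min = cfg$candidacy_min,
                           candidacy_max = cfg$candidacy_max,
                           mfei_threshold = cfg$mfei_threshold)
  clean_totals <- classified |>
    filter(.data$class == "clean") |>
    summarise(CT = sum(.data$count_CT), NT = sum(.data$count_NT))
  norm <- calls |>
    mutate(norm_CT = normalize_cpm(.data$count_CT, max(clean_totals$CT, 1)),
           norm_NT = normalize_cpm(.data$count_NT, max(clean_totals$NT, 1)))
  write_tsv_quiet(norm, file.path(cfg$out_dir, "mirna_calls.tsv"))

  de <- diff_expression(
    tibble(id = calls$id, count_CT = calls$count_CT,
           count_NT = calls$count_NT),
    total_ct = max(clean_totals$CT, 1), total_nt = max(clean_totals$NT, 1),
    alpha = cfg$alpha, lfc = cfg$lfc, pseudocount = cfg$pseudocount)
  write_tsv_quiet(as_tibble(de), file.path(cfg$out_dir,
                                           "diff_expression.tsv"))
  venn <- venn_partition(de)

  mir_seqs <- calls[, c("id", "sequence")]
  tx <- ref$transcriptome
  deg <- lapply(c(CT = "degradome_CT", NT = "degradome_NT"), function(k) {
    call_targets(mir_seqs, tx, read_seq_fasta(cfg$inputs[[k]]),
                 max_score = cfg$max_score)
  })
  write_tsv_quiet(as_tibble(deg$CT),
                  file.path(cfg$out_dir, "target_calls_CT.tsv"))
  write_tsv_quiet(as_tibble(deg$NT),
                  file.path(cfg$out_dir, "target_calls_NT.tsv"))
  tcomp <- compare_targets(deg$CT, deg$NT, alpha = cfg$alpha, lfc = cfg$lfc,
                           pseudocount = cfg$pseudocount)
  write_tsv_quiet(tcomp, file.path(cfg$out_dir, "target_comparison.tsv"))

  ct_table <- readr::read_tsv(cfg$inputs$qpcr, show_col_types = FALSE)
  calibrator <- cfg$qpcr_calibrator %||%
    ct_table$sample[ct_table$condition == "NT"][1]
  qp <- ddct_fold_change(ct_table, cfg$qpcr_reference_gene, calibrator)
  qp_tests <- compare_conditions(
    replicate_fold_changes(ct_table, cfg$qpcr_reference_gene, calibrator),
    alpha = cfg$alpha)
  write_tsv_quiet(as_tibble(qp), file.path(cfg$out_dir, "qpcr.tsv"))
  write_tsv_quiet(qp_tests, file.path(cfg$out_dir, "qpcr_tests.tsv"))

  summary <- list(
    seed = cfg$seed,
    raw_reads = raw_totals,
    clean_reads = as.list(clean_totals),
    n_tags = nrow(tags),
    class_counts = as.list(table(classified$class)),
    n_mirnas = nrow(calls),
    n_conserved = sum(calls$status == "conserved"),
    n_novel = sum(calls$status == "novel"),
    n_families = dplyr::n_distinct(calls$family),
    venn = lapply(venn, length),
    n_significant = sum(de$significant),
    n_targets_CT = nrow(deg$CT), n_targets_NT = nrow(deg$NT),
    target_categories_CT = as.list(table(deg$CT$category)),
    target_categories_NT = as.list(table(deg$NT$category)),
    n_qpcr_samples = dplyr::n_distinct(qp$sample)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(composition = composition, tags = classified,
                 mirna_calls = calls, diff_expr = de, venn = venn,
                 targets_CT = deg$CT, targets_NT = deg$NT,
                 target_comparison = tcomp, qpcr = qp,
                 qpcr_tests = qp_tests, summary = summary))
}

#' Summary tables for sRNA composition and degradome mapping
#'
#' `emit_summary()` packages the two standard report tables: the per-class
#' sRNA composition table (class x total/unique counts and percentages per
#' library) and the degradome mapping summary (raw reads, unique reads,
#' mapped reads with percentage, input and covered cDNAs with percentage),
#' all percentages rounded half-up to 2 decimals.
#'
#' @param composition a [composition_table()] result.
#' @param degradome_stats tibble with columns `library`, `raw_reads`,
#'   `unique_raw_reads`, `mapped_reads`, `input_cdnas`, `covered_cdnas`.
#' @return list with `srna_composition` and `degradome_summary` tibbles.
#' @export
emit_summary <- function(composition = NULL, degradome_stats = NULL) {
  out <- list()
  if (!is.null(composition)) out$srna_composition <- composition
  if (!is.null(degradome_stats)) {
    out$degradome_summary <- degradome_stats |>
      mutate(mapped_percent = percent_of(.data$mapped_reads,
                                         .data$raw_reads),
             covered_percent = percent_of(.data$covered_cdnas,
                                          .data$input_cdnas))
  }
  out
}
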