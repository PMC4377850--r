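#' Parameters for the synthetic reference generator
#'
#' Defines the simulated study: a small genome carrying planted miRNA
#' hairpin precursors, a transcriptome carrying complementary target sites,
#' miRBase-style known mature/hairpin sets, and contaminant reference sets
#' (rRNA, tRNA, snoRNA, snRNA, other Rfam, mRNA, repeat). The defaults
#' emulate a two-library chilling experiment: two condition libraries (CT =
#' chilling-treated, NT = untreated) pooled over six sampling time points,
#' with a subset of planted miRNAs carrying 4-fold expression changes.
#'
#' @param n_precursors number of planted miRNA precursors.
#' @param mature_length mature miRNA length in nt; must lie in 19--24.
#' @param n_conserved how many planted matures are present in the known
#'   (miRBase-style) mature set; the rest are novel.
#' @param gc target GC fraction of random background sequence, in (0, 1).
#' @param flank_stem extra perfectly paired stem (nt) flanking the
#'   mature/star duplex in each planted precursor.
#' @param loop_length terminal loop length (nt) of planted precursors.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_transcripts,transcript_length transcriptome shape.
#' @param n_cleavages number of planted miRNA target sites (at most one per
#'   transcript); cleavage position is the transcript base paired to miRNA
#'   position 10.
#' @param base_abundance per-miRNA pooled read abundance in the NT library.
#' @param fold_changes recycled vector of planted CT/NT expression ratios.
#' @param cleavage_abundance degradome tag abundance at each planted site
#'   (NT library).
#' @param cleavage_fold_changes recycled CT/NT ratios for degradome peaks.
#' @param contaminant_abundance per planted contaminant read count, each
#'   library.
#' @param n_contaminant_refs,contaminant_length contaminant reference sets.
#' @param adapter3 3' sequencing adapter appended to simulated reads.
#' @param time_points sampling times (h); per-time-point abundances are
#'   summed ("pooled") before read generation.
#' @return a list of class `chillmir_params`.
#' @export
reference_params <- function(n_precursors = 8,
                             mature_length = 21,
                             n_conserved = 4,
                             gc = 0.5,
                             flank_stem = 15,
                             loop_length = 8,
                             n_chromosomes = 2,
                             chrom_length = 4000,
                             n_transcripts = 6,
                             transcript_length = 500,
                             n_cleavages = 4,
                             base_abundance = 200,
                             fold_changes = c(1, 4, 0.25, 1),
                             cleavage_abundance = 50,
                             cleavage_fold_changes = c(1, 4, 0.25, 1),
                             contaminant_abundance = 40,
                             n_contaminant_refs = 2,
                             contaminant_length = 120,
                             adapter3 = "AGAUCGGAAGAGC",
                             time_points = c(1, 4, 8, 12, 24, 48)) {
  if (mature_length < 19 || mature_length > 24) {
    abort("mature_length must lie within the 19-24 nt candidacy window")
  }
  if (gc <= 0 || gc >= 1) abort("gc must lie strictly within (0, 1)")
  if (n_conserved > n_precursors) abort("n_conserved exceeds n_precursors")
  structure(as.list(environment()), class = "chillmir_params")
}

random_seq <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, "")
}

# integer split of `total` across k time points (remainder on the first)
split_timepoints <- function(total, k) {
  base <- total %/% k
  out <- rep(base, k)
  out[1] <- out[1] + total - base * k
  out
}

mirna_family_pool <- c(156, 159, 160, 166, 167, 169, 171, 319, 396, 398, 408)

#' Generate a synthetic reference bundle with planted truth
#'
#' Builds the genome, transcriptome, known-miRNA and contaminant references
#' together with a truth manifest recording every planted miRNA (with its
#' precursor locus and per-library pooled abundance), contaminant,
#' degradome cleavage site, and qPCR fold change. Deterministic for a fixed
#' seed. Every planted mature occurs verbatim inside its precursor, every
#' planted precursor is a perfect inverted repeat (so it folds into a
#' hairpin under the built-in folder), and every planted cleavage position
#' is the transcript base paired to position 10 of the planted miRNA.
#'
#' @param params a [reference_params()] list.
#' @param seed integer RNG seed.
#' @return list with elements `reference` (class `chillmir_reference`) and
#'   `truth` (class `chillmir_truth`).
#' @export
gen_reference <- function(params = reference_params(), seed = 1L) {
  stopifnot(inherits(params, "chillmir_params"))
  withr::with_seed(seed, gen_reference_impl(params, seed))
}

gen_reference_impl <- function(p, seed) {
  L <- p$mature_length
  n <- p$n_precursors

  if (n > 0) {
    matures <- random_seq(n, L, p$gc)
    arms <- rep(c("5p", "3p"), length.out = n)
    flank5 <- random_seq(max(n, 1), p$flank_stem, p$gc)
    loops <- random_seq(max(n, 1), p$loop_length, 0.2) # A/U-rich loop
    precursor <- character(n)
    mature_off <- integer(n) # 0-based offset of mature within precursor
    for (i in seq_len(n)) {
      stem5 <- if (arms[i] == "5p") paste0(flank5[i], matures[i]) else
        paste0(flank5[i], rev_comp(matures[i]))
      precursor[i] <- paste0(stem5, loops[i], rev_comp(stem5))
      mature_off[i] <- if (arms[i] == "5p") p$flank_stem else
        p$flank_stem + L + p$loop_length
    }
  } else {
    matures <- character(0); arms <- character(0)
    precursor <- character(0); mature_off <- integer(0)
  }

  # genome: random chromosomes with precursors embedded at spaced slots
  genome_seq <- random_seq(p$n_chromosomes, p$chrom_length, p$gc)
  chrom_of <- if (n > 0) rep(seq_len(p$n_chromosomes), length.out = n) else integer(0)
  pre_start <- integer(n)
  for (ci in seq_len(p$n_chromosomes)) {
    idx <- which(chrom_of == ci)
    if (!length(idx)) next
    slot <- floor(p$chrom_length / (length(idx) + 1))
    for (k in seq_along(idx)) {
      i <- idx[k]
      start <- (k - 1) * slot + 50
      if (start + nchar(precursor[i]) - 1 > p$chrom_length) {
        abort("chrom_length too small for the requested precursors")
      }
      substr(genome_seq[ci], start, start + nchar(precursor[i]) - 1) <- precursor[i]
      pre_start[i] <- start
    }
  }
  genome <- tibble(id = paste0("chr", seq_len(p$n_chromosomes)),
                   sequence = genome_seq)

  conserved <- seq_len(n) <= p$n_conserved
  fams <- rep(mirna_family_pool, length.out = max(n, 1))
  known_id <- ifelse(conserved,
                     paste0("miR", fams[seq_len(max(n, 0))],
                            letters[seq_len(max(n, 0))]),
                     NA_character_)
  mir_id <- ifelse(conserved, known_id,
                   paste0("planted-novel-", seq_len(max(n, 0))))

  fc <- rep(p$fold_changes, length.out = max(n, 0))
  ab_nt <- rep(as.integer(p$base_abundance), max(n, 0))
  ab_ct <- as.integer(round(ab_nt * fc))

  mirnas <- tibble(
    id = as.character(mir_id[seq_len(n)]),
    mature = matures,
    arm = arms,
    conserved = conserved,
    known_id = as.character(known_id[seq_len(n)]),
    chrom = if (n) paste0("chr", chrom_of) else character(0),
    precursor_start = pre_start,
    precursor_end = pre_start + nchar(precursor) - 1L,
    mature_start = pre_start + mature_off,
    mature_end = pre_start + mature_off + L - 1L,
    strand = rep("+", n),
    precursor = precursor,
    abundance_CT = ab_ct[seq_len(n)],
    abundance_NT = ab_nt[seq_len(n)]
  )

  known_mature <- dplyr::filter(mirnas, .data$conserved) |>
    dplyr::transmute(id = .data$known_id, sequence = .data$mature)
  known_hairpin <- dplyr::filter(mirnas, .data$conserved) |>
    dplyr::transmute(id = paste0(.data$known_id, "-precursor"),
                     sequence = .data$precursor)
  # decoy known matures never planted in the genome
  if (nrow(known_mature) > 0) {
    decoys <- tibble(id = paste0("miR", 9990 + seq_len(2)),
                     sequence = random_seq(2, L, p$gc))
    known_mature <- bind_rows(known_mature, decoys) |> arrange(.data$id)
  }

  contaminant_sets <- lapply(setNames(TAG_CLASSES, TAG_CLASSES), function(cl) {
    tibble(id = paste0(cl, "-ref-", seq_len(p$n_contaminant_refs)),
           sequence = random_seq(p$n_contaminant_refs, p$contaminant_length, p$gc))
  })
  contaminants <- purrr::map_dfr(TAG_CLASSES, function(cl) {
    tibble(class = cl,
           sequence = substr(contaminant_sets[[cl]]$sequence[1], 11, 10 + L),
           abundance_CT = as.integer(p$contaminant_abundance),
           abundance_NT = as.integer(p$contaminant_abundance))
  })

  # transcriptome with planted target sites (reverse complement of a mature)
  tx_seq <- random_seq(p$n_transcripts, p$transcript_length, p$gc)
  n_cleave <- min(p$n_cleavages, n, p$n_transcripts)
  cfc <- rep(p$cleavage_fold_changes, length.out = max(n_cleave, 0))
  cleavages <- tibble(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      position = integer(0),
                      abundance_CT = integer(0), abundance_NT = integer(0))
  for (k in seq_len(n_cleave)) {
    site <- rev_comp(matures[k])
    start <- 100L + 7L * k
    substr(tx_seq[k], start, start + L - 1L) <- site
    cleavages <- bind_rows(cleavages, tibble(
      mirna_id = mirnas$id[k],
      transcript_id = paste0("tx", k),
      site_start = start,
      site_end = start + L - 1L,
      position = start + L - 10L,
      abundance_CT = as.integer(round(p$cleavage_abundance * cfc[k])),
      abundance_NT = as.integer(p$cleavage_abundance)
    ))
  }
  transcriptome <- tibble(id = paste0("tx", seq_len(p$n_transcripts)),
                          sequence = tx_seq)

  # qPCR truth: one assayed gene, CT/NT at each time point, NT at the first
  # time point is the calibrator (fold change 1)
  qpcr <- tidyr::expand_grid(condition = c("NT", "CT"),
                             time_h = p$time_points) |>
    mutate(sample = paste0(.data$condition, "_", .data$time_h, "h"),
           gene = "target1",
           fold_change = ifelse(.data$condition == "NT", 1,
                                rep(c(2, 4, 0.5, 1, 8, 0.25),
                                    length.out = length(p$time_points))))

  reference <- structure(list(
    genome = genome,
    transcriptome = transcriptome,
    known_mature = known_mature,
    known_hairpin = known_hairpin,
    contaminant_sets = contaminant_sets,
    adapter3 = as_rna(p$adapter3)
  ), class = "chillmir_reference")

  truth <- structure(list(
    mirnas = mirnas,
    contaminants = contaminants,
    cleavages = cleavages,
    qpcr = qpcr[, c("sample", "condition", "time_h", "gene", "fold_change")],
    time_points = p$time_points,
    seed = as.integer(seed)
  ), class = "chillmir_truth")

  list(reference = reference, truth = truth)
}

truth_abundance <- function(truth, condition) {
  col <- paste0("abundance_", condition)
  if (!col %in% names(truth$mirnas)) {
    abort(sprintf("unknown condition label '%s'", condition))
  }
  col
}

#' Simulate a small RNA sequencing library
#'
#' Emits adapter-flanked reads for every planted miRNA and contaminant at
#' its per-library truth abundance. Per-time-point abundances are generated
#' by integer-splitting the pooled abundance over the configured time points
#' and summing again, mirroring the pooled-library design, so with noise
#' disabled per-sequence copy numbers equal the truth abundances exactly.
#'
#' @param ref,truth from [gen_reference()].
#' @param condition library label, "CT" or "NT".
#' @param noise `NULL` for exact copy numbers, or a list with optional
#'   elements `count_model = "poisson"` (Poisson-resampled copy numbers) and
#'   `junk_n` (number of homopolymer junk reads to add).
#' @param seed integer RNG seed.
#' @return tibble of reads with columns `id`, `sequence` (insert + 3'
#'   adapter, RNA alphabet); write with [write_seq_fastq()].
#' @export
gen_srna_library <- function(ref, truth, condition, noise = NULL, seed = 1L) {
  col <- truth_abundance(truth, condition)
  withr::with_seed(seed, {
    pool <- bind_rows(
      dplyr::select(truth$mirnas, source_id = "id", sequence = "mature",
                    abundance = dplyr::all_of(col)),
      dplyr::select(truth$contaminants, source_id = "class",
                    sequence = "sequence", abundance = dplyr::all_of(col))
    )
    counts <- purrr::map_int(pool$abundance, function(a) {
      pooled <- split_timepoints(a, length(truth$time_points))
      if (!is.null(noise$count_model) &&
          identical(noise$count_model, "poisson")) {
        pooled <- rpois(length(pooled), pooled)
      }
      as.integer(sum(pooled))
    })
    reads <- tibble(
      sequence = rep(paste0(pool$sequence, ref$adapter3), counts)
    )
    if (!is.null(noise$junk_n) && noise$junk_n > 0) {
      junk <- strrep(sample(c("A", "U", "C", "G"), noise$junk_n, replace = TRUE),
                     sample(18:25, noise$junk_n, replace = TRUE))
      reads <- bind_rows(reads, tibble(sequence = paste0(junk, ref$adapter3)))
    }
    if (nrow(reads) > 0) {
      reads$id <- sprintf("%s_read_%06d", condition, seq_len(nrow(reads)))
    } else {
      reads$id <- character(0)
    }
    reads[, c("id", "sequence")]
  })
}

#' Simulate a degradome (PARE) tag library
#'
#' For each planted cleavage, emits `tag_length`-nt tags whose 5' end sits
#' exactly at the cleavage position, at the planted abundance for the
#' requested library. Optionally adds uniform Poisson background tags at
#' every other eligible transcript position.
#'
#' @inheritParams gen_srna_library
#' @param background expected background tag count per transcript position
#'   (Poisson rate); 0 disables background.
#' @param tag_length degradome tag length in nt (default 20).
#' @return tibble of tags with columns `id`, `sequence`.
#' @export
gen_degradome_library <- function(ref, truth, condition, background = 0,
                                  seed = 1L, tag_length = 20L) {
  col <- truth_abundance(truth, condition)
  withr::with_seed(seed, {
    tx <- setNames(ref$transcriptome$sequence, ref$transcriptome$id)
    tags <- character(0)
    for (k in seq_len(nrow(truth$cleavages))) {
      cl <- truth$cleavages[k, ]
      seq_tx <- tx[[cl$transcript_id]]
      if (cl$position + tag_length - 1L > nchar(seq_tx)) {
        abort("cleavage position + tag length exceeds transcript end")
      }
      tag <- substr(seq_tx, cl$position, cl$position + tag_length - 1L)
      tags <- c(tags, rep(tag, cl[[col]]))
    }
    if (background > 0) {
      planted <- split(truth$cleavages$position, truth$cleavages$transcript_id)
      for (tid in names(tx)) {
        npos <- nchar(tx[[tid]]) - tag_length + 1L
        bg <- rpois(npos, background)
        skip <- planted[[tid]] %||% integer(0)
        bg[skip] <- 0L
        hit <- which(bg > 0)
        for (pos in hit) {
          tags <- c(tags, rep(substr(tx[[tid]], pos, pos + tag_length - 1L),
                              bg[pos]))
        }
      }
    }
    tibble(id = if (length(tags)) sprintf("%s_tag_%06d", condition,
                                          seq_along(tags)) else character(0),
           sequence = tags)
  })
}

#' Simulate a qPCR Ct table
#'
#' Constructs cycle-threshold values such that the 2^-ddCt method recovers
#' the planted fold changes exactly when noise is off. The reference gene is
#' held at a constant Ct; each sample's target Ct is offset by
#' `-log2(fold_change)` relative to the calibrator's delta-Ct. Three
#' replicates per reaction by default.
#'
#' @param qpcr_truth tibble with columns `sample`, `condition`, `time_h`,
#'   `gene`, `fold_change` (all > 0); the calibrator is the sample whose
#'   fold change is defined as 1 (see `calibrator_sample`).
#' @param reference_gene reference gene name (e.g. "5S_rRNA" for miRNA
#'   assays, "Actin" for target-gene assays).
#' @param calibrator_sample sample id used as calibrator; defaults to the
#'   first NT sample.
#' @param seed integer RNG seed.
#' @param noise_sd Gaussian Ct noise standard deviation (cycles); 0 = exact.
#' @param n_replicates technical replicates per reaction.
#' @param ct_reference constant Ct of the reference gene.
#' @param ct_calibrator_delta calibrator delta-Ct (target minus reference).
#' @return long tibble with columns `sample`, `condition`, `time_h`, `gene`,
#'   `replicate`, `ct`, including reference-gene rows.
#' @export
gen_qpcr_table <- function(qpcr_truth, reference_gene = "5S_rRNA",
                           calibrator_sample = NULL, seed = 1L,
                           noise_sd = 0, n_replicates = 3L,
                           ct_reference = 20, ct_calibrator_delta = 5) {
  if (any(qpcr_truth$fold_change <= 0)) {
    abort("planted fold changes must be strictly positive")
  }
  calibrator_sample <- calibrator_sample %||%
    qpcr_truth$sample[qpcr_truth$condition == "NT"][1]
  if (!calibrator_sample %in% qpcr_truth$sample) {
    abort("calibrator sample not present in truth table")
  }
  withr::with_seed(seed, {
    fc_cal <- qpcr_truth$fold_change[qpcr_truth$sample == calibrator_sample][1]
    rows <- purrr::map_dfr(seq_len(nrow(qpcr_truth)), function(i) {
      r <- qpcr_truth[i, ]
      dct <- ct_calibrator_delta - log2(r$fold_change / fc_cal)
      tibble(
        sample = r$sample, condition = r$condition, time_h = r$time_h,
        gene = c(rep(r$gene, n_replicates),
                 rep(reference_gene, n_replicates)),
        replicate = rep(seq_len(n_replicates), 2),
        ct = c(rep(ct_reference + dct, n_replicates),
               rep(ct_reference, n_replicates))
      )
    })
    if (noise_sd > 0) rows$ct <- rows$ct + rnorm(nrow(rows), 0, noise_sd)
    rows
  })
}

#' Write and read the planted-truth manifest
#'
#' The manifest (planted miRNAs with loci and abundances, contaminants,
#' cleavage sites, qPCR fold changes, seed) round-trips losslessly through
#' JSON. Identifiers containing whitespace are rejected.
#'
#' @param truth a `chillmir_truth` object.
#' @param path output path.
#' @export
write_truth_manifest <- function(truth, path) {
  stopifnot(inherits(truth, "chillmir_truth"))
  ids <- c(truth$mirnas$id, truth$cleavages$mirna_id,
           truth$cleavages$transcript_id, truth$qpcr$sample)
  if (any(grepl("\\s", ids))) {
    abort("manifest identifiers must not contain whitespace")
  }
  out <- list(
    mirnas = truth$mirnas, contaminants = truth$contaminants,
    cleavages = truth$cleavages, qpcr = truth$qpcr,
    time_points = truth$time_points, seed = truth$seed
  )
  jsonlite::write_json(out, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_truth_manifest
#' @export
read_truth_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(x, template) {
    if (is.null(x) || length(x) == 0) return(template)
    out <- as_tibble(lapply(x, function(col) if (is.list(col) && !length(col))
      character(0) else col))
    out[names(template)]
  }
  empty <- gen_reference(reference_params(n_precursors = 0, n_conserved = 0,
                                          n_cleavages = 0), seed = 1L)$truth
  structure(list(
    mirnas = as_tbl(raw$mirnas, empty$mirnas),
    contaminants = as_tbl(raw$contaminants, empty$contaminants),
    cleavages = as_tbl(raw$cleavages, empty$cleavages),
    qpcr = as_tbl(raw$qpcr, empty$qpcr),
    time_points = raw$time_points,
    seed = as.integer(raw$seed)
  ), class = "chillmir_truth")
}
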