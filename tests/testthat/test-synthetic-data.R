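small_params <- function(...) {
  reference_params(n_precursors = 4, n_conserved = 2, n_transcripts = 3,
                   n_cleavages = 2, chrom_length = 2500, ...)
}

test_that("generation is deterministic and validates its parameters", {
  a <- gen_reference(small_params(), seed = 11)
  b <- gen_reference(small_params(), seed = 11)
  expect_identical(a, b)
  c <- gen_reference(small_params(), seed = 12)
  expect_false(identical(a$reference$genome, c$reference$genome))

  expect_error(reference_params(mature_length = 18), "19-24")
  expect_error(reference_params(mature_length = 25), "19-24")
  expect_error(reference_params(gc = 0), "gc")
  expect_error(reference_params(gc = 1), "gc")
})

test_that("planted matures sit verbatim in their precursors and genome loci", {
  b <- gen_reference(reference_params(n_precursors = 5, n_conserved = 2),
                     seed = 3)
  m <- b$truth$mirnas
  expect_equal(nrow(m), 5)
  for (i in seq_len(nrow(m))) {
    expect_true(grepl(m$mature[i], m$precursor[i], fixed = TRUE))
    chrom <- b$reference$genome$sequence[b$reference$genome$id == m$chrom[i]]
    expect_equal(substr(chrom, m$mature_start[i], m$mature_end[i]),
                 m$mature[i])
    expect_equal(substr(chrom, m$precursor_start[i], m$precursor_end[i]),
                 m$precursor[i])
  }
  # planted precursors fold into hairpins that pass the structural criteria
  for (i in seq_len(nrow(m))) {
    fold <- fold_rna(m$precursor[i])
    off <- m$mature_start[i] - m$precursor_start[i] + 1
    hp <- evaluate_hairpin(fold$structure, off, off + nchar(m$mature[i]) - 1)
    expect_true(hp$pass, info = m$id[i])
  }
})

test_that("zero-precursor request yields an empty truth and genome without planted loci", {
  b <- gen_reference(reference_params(n_precursors = 0, n_conserved = 0,
                                      n_cleavages = 0), seed = 5)
  expect_equal(nrow(b$truth$mirnas), 0)
  expect_equal(nrow(b$truth$cleavages), 0)
  expect_equal(nrow(b$reference$known_mature), 0)
})

test_that("noise-free sRNA libraries conserve planted abundances exactly", {
  b <- gen_reference(small_params(), seed = 21)
  reads <- gen_srna_library(b$reference, b$truth, "CT", seed = 2)
  expected <- sum(b$truth$mirnas$abundance_CT) +
    sum(b$truth$contaminants$abundance_CT)
  expect_equal(nrow(reads), expected)
  # each read is insert + 3' adapter
  expect_true(all(grepl(paste0(b$reference$adapter3, "$"), reads$sequence)))
  # per-sequence copy numbers match the truth
  one <- b$truth$mirnas[1, ]
  expect_equal(sum(reads$sequence ==
                     paste0(one$mature, b$reference$adapter3)),
               one$abundance_CT)
  expect_error(gen_srna_library(b$reference, b$truth, "XX"), "condition")
})

test_that("Poisson-noise read totals match an independent replay of the sampler", {
  b <- gen_reference(small_params(), seed = 31)
  noise <- list(count_model = "poisson")
  reads <- gen_srna_library(b$reference, b$truth, "NT", noise, seed = 9)
  # replay: same RNG stream, same per-sequence split across time points
  replay <- withr::with_seed(9, {
    ab <- c(b$truth$mirnas$abundance_NT, b$truth$contaminants$abundance_NT)
    sum(vapply(ab, function(a) {
      k <- length(b$truth$time_points)
      per <- rep(a %/% k, k)
      per[1] <- per[1] + a - sum(per)
      sum(rpois(k, per))
    }, 0))
  })
  expect_equal(nrow(reads), replay)
})

test_that("degradome tags start exactly at planted cleavage positions", {
  b <- gen_reference(small_params(), seed = 41)
  tags <- gen_degradome_library(b$reference, b$truth, "NT", background = 0,
                                seed = 3)
  expect_equal(nrow(tags), sum(b$truth$cleavages$abundance_NT))
  tx <- setNames(b$reference$transcriptome$sequence,
                 b$reference$transcriptome$id)
  for (k in seq_len(nrow(b$truth$cleavages))) {
    cl <- b$truth$cleavages[k, ]
    expected_tag <- substr(tx[[cl$transcript_id]], cl$position,
                           cl$position + 19)
    expect_equal(sum(tags$sequence == expected_tag), cl$abundance_NT)
  }
  # no cleavages -> empty tag set
  b0 <- gen_reference(reference_params(n_cleavages = 0), seed = 41)
  t0 <- gen_degradome_library(b0$reference, b0$truth, "NT", seed = 3)
  expect_equal(nrow(t0), 0)
})

test_that("degradome background counts match an independent RNG replay", {
  b <- gen_reference(small_params(), seed = 51)
  bg <- 0.01
  tags <- gen_degradome_library(b$reference, b$truth, "CT", background = bg,
                                seed = 13)
  replay_n <- withr::with_seed(13, {
    total <- sum(b$truth$cleavages$abundance_CT)
    planted <- split(b$truth$cleavages$position,
                     b$truth$cleavages$transcript_id)
    for (i in seq_len(nrow(b$reference$transcriptome))) {
      tid <- b$reference$transcriptome$id[i]
      npos <- nchar(b$reference$transcriptome$sequence[i]) - 20 + 1
      draws <- rpois(npos, bg)
      skip <- planted[[tid]]
      if (!is.null(skip)) draws[skip] <- 0
      total <- total + sum(draws)
    }
    total
  })
  expect_equal(nrow(tags), replay_n)
})

test_that("qPCR tables round-trip planted fold changes through 2^-ddCt", {
  truth <- tibble::tibble(
    sample = c("NT_1h", "CT_1h", "CT_4h"),
    condition = c("NT", "CT", "CT"),
    time_h = c(1, 1, 4),
    gene = "g",
    fold_change = c(1, 2, 0.5)
  )
  ct <- gen_qpcr_table(truth, seed = 1)
  expect_equal(sum(ct$gene == "g"), 9) # three replicates per sample
  res <- ddct_fold_change(ct, "5S_rRNA", "NT_1h")
  expect_equal(res$fold_change[match(truth$sample, res$sample)],
               truth$fold_change)
  # fold change 1 means target/reference dCt equal across samples
  flat <- gen_qpcr_table(dplyr::mutate(truth, fold_change = 1), seed = 1)
  dct <- tidyr::pivot_wider(flat, names_from = "gene", values_from = "ct")
  expect_true(all(abs((dct$g - dct$`5S_rRNA`) -
                        (dct$g[1] - dct$`5S_rRNA`[1])) < 1e-12))
  expect_error(gen_qpcr_table(dplyr::mutate(truth, fold_change = 0)),
               "positive")
})

test_that("the truth manifest round-trips losslessly and validates ids", {
  b <- gen_reference(small_params(), seed = 61)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(b$truth, path)
  back <- read_truth_manifest(path)
  expect_equal(back$mirnas, b$truth$mirnas)
  expect_equal(back$cleavages, b$truth$cleavages)
  expect_equal(back$contaminants, b$truth$contaminants)
  expect_equal(back$qpcr, b$truth$qpcr)
  expect_equal(back$seed, b$truth$seed)

  # empty manifest round-trips too
  e <- gen_reference(reference_params(n_precursors = 0, n_conserved = 0,
                                      n_cleavages = 0), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".json")
  write_truth_manifest(e$truth, p2)
  expect_equal(nrow(read_truth_manifest(p2)$mirnas), 0)

  bad <- b$truth
  bad$mirnas$id[1] <- "has space"
  expect_error(write_truth_manifest(bad, path), "whitespace")
})
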