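mutate_at_pos <- function(seq, pos) {
  b <- strsplit(seq, "")[[1]]
  b[pos] <- setdiff(c("A", "C", "G", "U"), b[pos])[1]
  paste(b, collapse = "")
}

test_that("conserved matching applies the two mismatch tolerances", {
  known <- tibble::tibble(id = "miR1", sequence = "ACGUACGUACGUACGUACGUA")
  tag <- known$sequence

  expect_equal(match_conserved(tag, known)$mismatches_total, 0)

  two_in_16 <- mutate_at_pos(mutate_at_pos(tag, 3), 9)
  expect_equal(nrow(match_conserved(two_in_16, known)), 0)

  three_spread <- mutate_at_pos(mutate_at_pos(mutate_at_pos(tag, 5), 18), 20)
  m <- match_conserved(three_spread, known)
  expect_equal(nrow(m), 1)
  expect_equal(m$mismatches_first16, 1)
  expect_equal(m$mismatches_total, 3)

  four_total <- mutate_at_pos(three_spread, 21)
  expect_equal(nrow(match_conserved(four_total, known)), 0)

  expect_error(match_conserved(tag, known[0, ]), "empty")
})

test_that("matching ranks by total mismatches with lexicographic ties", {
  tag <- "ACGUACGUACGUACGUACGUA"
  known <- tibble::tibble(
    id = c("miR9b", "miR9a", "miR5"),
    sequence = c(tag, tag, mutate_at_pos(tag, 20))
  )
  m <- match_conserved(tag, known)
  expect_equal(m$known_id, c("miR9a", "miR9b", "miR5"))
})

test_that("matching agrees with brute force on 1000 random pairs", {
  set.seed(99)
  tags <- random_rna(1000, 21)
  knowns <- random_rna(1000, 21)
  # random sequences rarely match; seed some near-duplicates so both
  # branches are exercised
  idx <- seq(1, 1000, by = 4)
  knowns[idx] <- vapply(tags[idx], function(t) {
    k <- sample(0:4, 1)
    for (p in sample(21, k)) t <- mutate_at_pos(t, p)
    t
  }, "")
  for (i in seq_along(tags)) {
    known <- tibble::tibble(id = "k", sequence = knowns[i])
    got <- nrow(match_conserved(tags[i], known)) == 1
    expect_equal(got, oracle_match(tags[i], knowns[i])$ok,
                 info = paste(tags[i], knowns[i]))
  }
})

test_that("precursor windows extend, clip and deduplicate correctly", {
  genome <- tibble::tibble(id = "chr1", sequence = strrep("ACGU", 300))
  w <- excise_precursors(genome, "chr1", 500, 520, flanks = c(20L, 200L))
  expect_true(all(c("window_start", "window_end") %in% names(w)))
  expect_true(any(w$window_start == 480 & w$window_end == 720))
  expect_equal(nrow(w), 4) # 2x2 flank combinations, all distinct

  clipped <- excise_precursors(genome, "chr1", 5, 25, flanks = c(20L))
  expect_equal(clipped$window_start, 1)
  expect_equal(clipped$mature_offset, 5)

  expect_error(excise_precursors(genome, "chr1", 1190, 1210, flanks = c(20L)),
               "bounds")
})

test_that("hairpin evaluation enforces arm placement and duplex quality", {
  stem <- "GCAUGCAUGCAUGCAUGCAUGCAUGCAUGC" # 30 nt
  hp <- paste0(stem, "AAAAAA", rc(stem))
  fold <- fold_rna(hp)

  ok <- evaluate_hairpin(fold$structure, 3, 23)
  expect_true(ok$pass)
  expect_equal(ok$arm, "5p")
  # star of a perfect stem: partner span shifted by the 2-nt 3' overhang
  pt <- chillmir:::pair_table(fold$structure)
  expect_equal(ok$star_start, pt[23] + 2)
  expect_equal(ok$star_end, pt[3] + 2)

  loop_span <- evaluate_hairpin(fold$structure, 25, 45)
  expect_false(loop_span$pass)
  expect_true("loop-overlap" %in% loop_span$reasons)

  on3p <- evaluate_hairpin(fold$structure, 40, 60)
  expect_true(on3p$pass)
  expect_equal(on3p$arm, "3p")

  expect_error(evaluate_hairpin(fold$structure, 0, 10), "span")
})

test_that("unpaired mature positions beyond the tolerance fail evaluation", {
  # five unpaired positions in the mature: structure built by hand
  structure <- paste0("((((((.....((((", strrep(".", 6), "))))",
                      strrep(".", 0), "))))))")
  # mature spans the 5-nt internal gap plus paired flanks
  res <- evaluate_hairpin(structure, 2, 15, max_unpaired = 4)
  expect_false(res$pass)
  expect_true("too-many-unpaired" %in% res$reasons)
  res_ok <- evaluate_hairpin(structure, 2, 15, max_unpaired = 5)
  expect_true(res_ok$pass || "asymmetric-bulge" %in% res_ok$reasons)
})

test_that("identity assignment names canonical, flanking and novel tags", {
  set.seed(606)
  stem5 <- random_rna(1, 40) # non-repetitive 5' arm
  mature <- substr(stem5, 16, 36)
  hairpin <- paste0(stem5, "AAAAAA", rc(stem5))
  known_mature <- tibble::tibble(id = "miR156a", sequence = mature)
  known_hairpin <- tibble::tibble(id = "miR156a-precursor",
                                  sequence = hairpin)

  canonical <- assign_identity(mature, known_mature, known_hairpin)
  expect_equal(canonical$id, "miR156a")
  expect_equal(canonical$designation, "canonical")

  upstream <- substr(hairpin, 1, 14) # 5' of the mature, inside the hairpin
  p5 <- assign_identity(upstream, known_mature, known_hairpin)
  expect_equal(p5$designation, "p5")
  expect_equal(p5$id, "miR156a-p5")

  downstream <- substr(hairpin, 60, 80)
  p3 <- assign_identity(downstream, known_mature, known_hairpin)
  expect_equal(p3$designation, "p3")

  novel <- assign_identity("ACGUACGUACGUACGUACGUA", known_mature,
                           known_hairpin, pc_number = 7, arm = "5p")
  expect_equal(novel$id, "PC-7-5p")
  expect_equal(novel$designation, "novel")
})

test_that("family grouping extracts numeric stems and keeps novels singleton", {
  calls <- tibble::tibble(
    id = c("miR156a", "miR156j", "miR169", "PC-1-5p", "weird"),
    status = c("conserved", "conserved", "conserved", "novel", "conserved"),
    known_id = c("miR156a", "miR156j", "miR169", NA, "oddname")
  )
  fam <- group_families(calls)
  expect_equal(fam$family, c("156", "156", "169", "PC-1-5p", "unknown"))
  expect_equal(sum(fam$family == "156"), 2)
  expect_equal(nrow(group_families(calls[0, ])), 0)
})

test_that("planted miRNAs are recovered with correct status and no false calls", {
  b <- gen_reference(reference_params(n_precursors = 6, n_conserved = 3),
                     seed = 77)
  reads <- list(
    CT = gen_srna_library(b$reference, b$truth, "CT", seed = 1),
    NT = gen_srna_library(b$reference, b$truth, "NT", seed = 2)
  )
  processed <- lapply(reads, function(r) {
    f <- filter_reads(trim_adapters(r, b$reference$adapter3))
    f[f$kept, c("id", "sequence")]
  })
  tags <- classify_tags(collapse_tags(processed), b$reference)
  calls <- discover_mirnas(tags, b$reference)

  truth <- b$truth$mirnas
  expect_equal(nrow(calls), nrow(truth))
  for (i in seq_len(nrow(truth))) {
    hit <- calls[calls$sequence == truth$mature[i], ]
    expect_equal(nrow(hit), 1, info = truth$id[i])
    expect_equal(hit$status, ifelse(truth$conserved[i], "conserved",
                                    "novel"))
    if (truth$conserved[i]) expect_equal(hit$known_id, truth$known_id[i])
    if (!truth$conserved[i]) expect_gt(hit$mfei, 0.80)
  }

  # a pure-contaminant library yields zero calls
  cont_only <- b$truth
  cont_only$mirnas <- cont_only$mirnas[0, ]
  creads <- gen_srna_library(b$reference, cont_only, "CT", seed = 3)
  cf <- filter_reads(trim_adapters(creads, b$reference$adapter3))
  ctags <- classify_tags(collapse_tags(list(CT = cf[cf$kept, c("id", "sequence")])),
                         b$reference)
  expect_equal(nrow(discover_mirnas(ctags, b$reference)), 0)
})
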