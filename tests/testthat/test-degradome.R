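mk_mirna <- function(len = 21) {
  set.seed(555)
  random_rna(1, len)
}

# a target site whose duplex with `mirna` is perfect except as edited
perfect_site <- function(mirna) rc(mirna)

# introduce a defect opposite miRNA position `pos` (site is 5'->3')
site_with <- function(mirna, pos, kind = c("mismatch", "wobble")) {
  kind <- match.arg(kind)
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(rc(mirna), "")[[1]]
  j <- length(s) - pos + 1 # site index facing miRNA position pos
  s[j] <- if (kind == "mismatch") {
    # the same base as the miRNA position never pairs and never wobbles
    m[pos]
  } else {
    # G:U wobble: put U opposite G, or G opposite U
    if (m[pos] == "G") "U" else if (m[pos] == "U") "G" else
      stop("wobble needs G or U at that miRNA position")
  }
  paste(s, collapse = "")
}

test_that("duplex penalties follow the published scoring rules", {
  mir <- "ACGUACGUACGUACGGACGUA" # position 16 is G
  expect_equal(score_duplex(mir, perfect_site(mir))$score, 0)

  # single non-core G:U at position 16 scores 0.5
  expect_equal(score_duplex(mir, site_with(mir, 16, "wobble"))$score, 0.5)

  # single non-core mismatch at position 18 scores 1
  expect_equal(score_duplex(mir, site_with(mir, 18, "mismatch"))$score, 1)

  # core mismatch at 5 doubles; plus non-core wobble at 16: 2 + 0.5
  s2 <- local({
    a <- strsplit(site_with(mir, 16, "wobble"), "")[[1]]
    b <- strsplit(site_with(mir, 5, "mismatch"), "")[[1]]
    j <- 21 - 5 + 1
    a[j] <- b[j]
    paste(a, collapse = "")
  })
  expect_equal(score_duplex(mir, s2)$score, 2.5)

  expect_error(score_duplex(mir, "ACGT!"), "alphabet|\\+/- 1")
})

test_that("duplex scores agree with the rule-trace oracle on random duplexes", {
  set.seed(321)
  for (i in 1:1000) {
    mir <- random_rna(1, 21)
    site <- if (i %% 3 == 0) rc(mir) else random_rna(1, 21)
    expect_equal(score_duplex(mir, site)$score,
                 oracle_duplex_score(mir, site),
                 info = paste(mir, site))
  }
})

test_that("adding a defect never decreases the score; core costs at least non-core", {
  set.seed(11)
  for (i in 1:50) {
    mir <- random_rna(1, 21)
    base <- score_duplex(mir, perfect_site(mir))$score
    pos <- sample(21, 1)
    worse <- tryCatch(
      score_duplex(mir, site_with(mir, pos, "mismatch"))$score,
      error = function(e) NA)
    if (!is.na(worse)) expect_gte(worse, base)
  }
  mir <- "ACGUACGUACGUACGUACGUA"
  core_pen <- score_duplex(mir, site_with(mir, 5, "mismatch"))$score
  edge_pen <- score_duplex(mir, site_with(mir, 18, "mismatch"))$score
  expect_gte(core_pen, edge_pen)
})

test_that("site scanning finds planted sites with correct cleavage coordinates", {
  set.seed(777)
  mir <- random_rna(1, 21)
  left <- random_rna(1, 100)
  right <- random_rna(1, 80)
  tx <- paste0(left, rc(mir), right)
  hits <- scan_target_sites(mir, tx, max_score = 0, max_bulges = 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$site_start, 101)
  expect_equal(hits$score, 0)
  expect_equal(hits$cleavage_pos, 101 + 21 - 10) # paired to miRNA position 10

  # max_score 0 returns exactly the exact-reverse-complement matches
  set.seed(778)
  for (i in 1:10) {
    m2 <- random_rna(1, 20)
    t2 <- random_rna(1, 400)
    expected <- gregexpr(rc(m2), t2, fixed = TRUE)[[1]]
    expected <- expected[expected > 0]
    got <- scan_target_sites(m2, t2, max_score = 0, max_bulges = 1)
    expect_equal(got$site_start, as.integer(expected))
  }

  none <- scan_target_sites(mir, random_rna(1, 60), max_score = 0)
  expect_equal(nrow(none), 0)
  expect_error(scan_target_sites(mir, tx, max_score = -1), "max_score")
})

test_that("vectorized scanning equals direct duplex scoring at every site", {
  set.seed(999)
  mir <- random_rna(1, 21)
  tx <- random_rna(1, 120)
  hits <- scan_target_sites(mir, tx, max_score = 100, max_bulges = 0)
  for (k in seq_len(nrow(hits))) {
    site <- substr(tx, hits$site_start[k], hits$site_end[k])
    expect_equal(hits$score[k], score_duplex(mir, site)$score)
  }
})

test_that("tags-per-billion normalization matches the printed-scale arithmetic", {
  expect_equal(tpb_normalize(1, 1e9), 1)
  expect_equal(tpb_normalize(0, 1e9), 0)
  expect_equal(tpb_normalize(75, 9382112), 75 / 9382112 * 1e9)
  expect_equal(round(tpb_normalize(75, 9382112), 1), 7993.9)
  expect_error(tpb_normalize(1, 0), "positive")
})

test_that("tag mapping accumulates 5'-end counts, multi-maps at every hit", {
  tx <- tibble::tibble(
    id = c("t1", "t2"),
    sequence = c(paste0(strrep("A", 119), "CCGGUUCCAAGGCCGGUUAA", strrep("A", 60)),
                 paste0(strrep("G", 49), "CCGGUUCCAAGGCCGGUUAA", strrep("G", 30)))
  )
  tags <- tibble::tibble(sequence = "CCGGUUCCAAGGCCGGUUAA", count = 50L)
  m <- map_degradome_tags(tags, tx)
  expect_equal(m$positions$count[m$positions$transcript_id == "t1"], 50)
  expect_equal(m$positions$position[m$positions$transcript_id == "t1"], 120)
  expect_equal(m$positions$position[m$positions$transcript_id == "t2"], 50)
  expect_equal(m$total_mapped, 100)

  m2 <- map_degradome_tags(tibble::tibble(sequence = "UUUUUCCCCCGGGGGAAAAA"), tx)
  expect_equal(nrow(m2$positions), 0)
  expect_equal(nrow(m2$unmapped), 1)
})

test_that("t-plots record max, nonzero median and site abundance", {
  pos <- tibble::tibble(position = c(10L, 20L, 30L), count = c(10L, 2L, 2L))
  tp <- build_tplot(pos, 50, expected_site = 10, total_mapped = 1000)
  expect_equal(tp$max_abundance, 10)
  expect_equal(tp$median_abundance, 2)
  expect_equal(tp$site_count, 10)
  expect_equal(tp$abundance$tpb[10], 10 / 1000 * 1e9)

  single <- build_tplot(tibble::tibble(position = 5L, count = 7L), 20)
  expect_equal(single$max_abundance, 7)
  expect_equal(single$median_abundance, 7)

  zero <- build_tplot(pos[0, ], 20)
  expect_true(zero$no_signal)
  expect_true(is.na(zero$median_abundance))
  expect_error(build_tplot(pos, 0), "empty")
})

test_that("category assignment implements the five published tiers", {
  mk <- function(counts, site) {
    pos <- tibble::tibble(position = seq_along(counts)[counts > 0],
                          count = counts[counts > 0])
    categorize_site(build_tplot(pos, length(counts)), site)
  }
  # unique maximum (count > 1) -> category 0
  expect_equal(mk(c(0, 5, 0, 0), 2), 0L)
  # tied maximum -> category 1
  expect_equal(mk(c(8, 0, 8, 0, 2), 3), 1L)
  # strictly between median and maximum -> 2; at/below median -> 3
  expect_equal(mk(c(10, 4, 2, 2, 2), 2), 2L)
  expect_equal(mk(c(10, 4, 2, 2, 2), 3), 3L)
  # single raw read -> category 4 regardless of profile
  expect_equal(mk(c(10, 1, 0), 2), 4L)
  # no signal at the site -> no call
  expect_true(is.na(mk(c(10, 0, 0), 2)))
})

test_that("categories match the rule-trace oracle over random profiles", {
  set.seed(31415)
  for (i in 1:500) {
    n <- sample(5:40, 1)
    vec <- integer(n)
    k <- sample(seq_len(min(6, n)), 1)
    idx <- sample(n, k)
    vec[idx] <- sample(1:12, k, replace = TRUE)
    site <- sample(n, 1)
    pos <- tibble::tibble(position = which(vec > 0), count = vec[vec > 0])
    got <- categorize_site(build_tplot(pos, n), site)
    expect_identical(got, oracle_category(vec, site),
                     info = paste(paste(vec, collapse = ","), site))
  }
})

test_that("planted cleavage sites come out category 0; background keeps them in {0,1}", {
  b <- gen_reference(reference_params(n_precursors = 4, n_conserved = 2,
                                      n_cleavages = 3), seed = 88)
  mirnas <- b$truth$mirnas[, c("id", "mature")]
  names(mirnas) <- c("id", "sequence")

  tags0 <- gen_degradome_library(b$reference, b$truth, "CT", background = 0,
                                 seed = 4)
  calls0 <- call_targets(mirnas, b$reference$transcriptome, tags0)
  tr <- b$truth$cleavages
  for (k in seq_len(nrow(tr))) {
    hit <- calls0[calls0$mirna_id == tr$mirna_id[k] &
                    calls0$transcript_id == tr$transcript_id[k] &
                    calls0$cleavage_pos == tr$position[k], ]
    expect_equal(nrow(hit), 1, info = tr$mirna_id[k])
    expect_equal(hit$category, 0L)
    expect_equal(hit$raw_count, tr$abundance_CT[k])
  }

  # low uniform background below peak height: planted sites stay in {0, 1}
  tagsbg <- gen_degradome_library(b$reference, b$truth, "CT",
                                  background = 0.05, seed = 5)
  callsbg <- call_targets(mirnas, b$reference$transcriptome, tagsbg)
  for (k in seq_len(nrow(tr))) {
    hit <- callsbg[callsbg$mirna_id == tr$mirna_id[k] &
                     callsbg$transcript_id == tr$transcript_id[k] &
                     callsbg$cleavage_pos == tr$position[k], ]
    expect_true(hit$category %in% c(0L, 1L), info = tr$mirna_id[k])
  }
})

test_that("library comparison labels membership and flags planted excess", {
  b <- gen_reference(reference_params(n_precursors = 4, n_conserved = 2,
                                      n_cleavages = 4,
                                      cleavage_abundance = 200),
                     seed = 99)
  mirnas <- b$truth$mirnas[, c("id", "mature")]
  names(mirnas) <- c("id", "sequence")
  ct <- call_targets(mirnas, b$reference$transcriptome,
                     gen_degradome_library(b$reference, b$truth, "CT",
                                           seed = 6))
  nt <- call_targets(mirnas, b$reference$transcriptome,
                     gen_degradome_library(b$reference, b$truth, "NT",
                                           seed = 7))
  cmp <- compare_targets(ct, nt)
  expect_true(all(cmp$library == "both"))
  planted4x <- b$truth$cleavages[
    b$truth$cleavages$abundance_CT == 4 * b$truth$cleavages$abundance_NT, ]
  for (k in seq_len(nrow(planted4x))) {
    row <- cmp[cmp$mirna_id == planted4x$mirna_id[k] &
                 cmp$cleavage_pos == planted4x$position[k], ]
    expect_true(row$significant)
    expect_equal(row$direction, "increased")
  }
  flat <- b$truth$cleavages[b$truth$cleavages$abundance_CT ==
                              b$truth$cleavages$abundance_NT, ]
  for (k in seq_len(nrow(flat))) {
    row <- cmp[cmp$mirna_id == flat$mirna_id[k] &
                 cmp$cleavage_pos == flat$position[k], ]
    expect_lt(abs(row$log2_ratio), 1)
  }
})
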