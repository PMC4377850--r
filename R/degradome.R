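#' Map degradome tags onto the transcriptome
#'
#' Each tag contributes its count at the transcript position of its 5' end
#' for every exact sense-strand match; multi-mapping tags count at every
#' match. Tags with no match are reported separately.
#'
#' @param tags tibble of degradome tags (`sequence`, optional `count`
#'   column; identical sequences are collapsed first).
#' @param transcriptome tibble `id`, `sequence`.
#' @return list with `positions` (tibble `transcript_id`, `position`,
#'   `count`), `total_mapped` (sum of mapped tag counts, multi-maps counted
#'   at every site), and `unmapped` (tibble `sequence`, `count`).
#' @export
map_degradome_tags <- function(tags, transcriptome) {
  tg <- tags
  if (!"count" %in% names(tg)) tg$count <- 1L
  tg <- tg |>
    mutate(sequence = as_rna(.data$sequence)) |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop")
  pos <- tibble(transcript_id = character(0), position = integer(0),
                count = integer(0))
  mapped <- rep(FALSE, nrow(tg))
  for (i in seq_len(nrow(transcriptome))) {
    tx <- as_rna(transcriptome$sequence[i])
    for (k in seq_len(nrow(tg))) {
      loc <- stringr::str_locate_all(tx, stringr::fixed(tg$sequence[k]))[[1]]
      if (nrow(loc)) {
        mapped[k] <- TRUE
        pos <- bind_rows(pos, tibble(transcript_id = transcriptome$id[i],
                                     position = as.integer(loc[, "start"]),
                                     count = tg$count[k]))
      }
    }
  }
  pos <- pos |>
    group_by(.data$transcript_id, .data$position) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$transcript_id, .data$position)
  list(positions = pos,
       total_mapped = sum(pos$count),
       unmapped = tg[!mapped, c("sequence", "count")])
}

#' Tags-per-billion normalization
#'
#' @param count tag count(s) at a position.
#' @param total_mapped total mapped tags in the library; must be > 0.
#' @return `count / total_mapped * 1e9`.
#' @export
tpb_normalize <- function(count, total_mapped) {
  if (any(total_mapped <= 0)) abort("total_mapped must be positive")
  count / total_mapped * 1e9
}

pair_penalty_class <- function(x, y) {
  wc <- (x == "A" & y == "U") | (x == "U" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G")
  gu <- (x == "G" & y == "U") | (x == "U" & y == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "mismatch"))
}

duplex_penalty <- function(state, position, core = c(2L, 13L)) {
  base <- dplyr::case_when(
    state == "WC" ~ 0,
    state == "GU" ~ 0.5,
    TRUE ~ 1 # mismatch or single-nt bulge
  )
  ifelse(position >= core[1] & position <= core[2] & base > 0, 2 * base, base)
}

#' Score a miRNA:target duplex by base-pairing penalties
#'
#' Penalties per miRNA position (1-based from the miRNA 5' end):
#' Watson-Crick pair 0; G:U wobble 0.5; mismatched pair or single
#' nucleotide bulge 1; any penalty is doubled when the position lies in the
#' core region 2--13. The target site is given 5'->3'; the duplex is
#' antiparallel, so miRNA position i faces site position
#' `site_length - i + 1`. A site one nucleotide longer or shorter than the
#' miRNA is aligned with a single bulge placed to minimize the score (ties:
#' the 5'-most miRNA position).
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param site target site, transcript orientation 5'->3'; length within
#'   miRNA length +/- 1.
#' @param core core-region bounds (miRNA positions, inclusive).
#' @return list with `score`, `pairing` (per-miRNA-position states,
#'   including "bulge"), and `bulge_at` (miRNA position of the bulge or
#'   NA).
#' @export
score_duplex <- function(mirna, site, core = c(2L, 13L)) {
  mirna <- assert_rna(mirna, "mirna")
  site <- assert_rna(site, "site")
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]]) # antiparallel: align to miRNA 5'->3'
  L <- length(mb)
  S <- length(sb)
  if (abs(L - S) > 1) abort("site length must be within miRNA length +/- 1")

  score_ungapped <- function(m, s) {
    state <- pair_penalty_class(m, s)
    sum(duplex_penalty(state, seq_along(m), core))
  }

  if (L == S) {
    state <- pair_penalty_class(mb, sb)
    return(list(score = sum(duplex_penalty(state, seq_len(L), core)),
                pairing = state, bulge_at = NA_integer_))
  }

  # one single-nucleotide bulge: skip one base of the longer strand
  longer_site <- S > L
  best <- NULL
  for (g in seq_len(max(L, S))) {
    if (longer_site) {
      s_used <- sb[-g]
      state <- pair_penalty_class(mb, s_used)
      # the bulged target base sits between miRNA positions g-1 and g
      bpos <- min(g, L)
    } else {
      m_used <- mb[-g]
      s_state <- pair_penalty_class(m_used, sb)
      state <- append(s_state, "bulge", after = g - 1L)[seq_len(L)]
      bpos <- g
    }
    if (longer_site) {
      pen <- sum(duplex_penalty(state, seq_len(L), core)) +
        duplex_penalty("mismatch", bpos, core)
      pairing <- state
    } else {
      pen <- sum(duplex_penalty(ifelse(state == "bulge", "mismatch", state),
                                seq_len(L), core))
      pairing <- state
    }
    if (is.null(best) || pen < best$score) {
      best <- list(score = pen, pairing = pairing, bulge_at = bpos)
    }
  }
  best
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Slides over every site of miRNA length (and length +/- 1 when
#' `max_bulges = 1`) and keeps reverse-complement alignments with duplex
#' penalty score at most `max_score`. Each site is annotated with the
#' expected cleavage position: the transcript base paired to miRNA
#' position 10, i.e. `site_start + site_length - 10`.
#'
#' @param mirna miRNA sequence, 5'->3'.
#' @param transcript transcript sequence, 5'->3'.
#' @param max_score maximum duplex penalty (default 7).
#' @param max_bulges 0 for strictly ungapped scanning, 1 (default) to also
#'   try sites with one single-nucleotide bulge.
#' @param core core-region bounds passed to [score_duplex()].
#' @return tibble `site_start`, `site_end`, `score`, `cleavage_pos`,
#'   ordered by position, at most one site per start (the best-scoring site
#'   length).
#' @export
scan_target_sites <- function(mirna, transcript, max_score = 7,
                              max_bulges = 1L, core = c(2L, 13L)) {
  if (max_score < 0) abort("max_score must be >= 0")
  mirna <- assert_rna(mirna, "mirna")
  tx <- strsplit(assert_rna(transcript, "transcript"), "")[[1]]
  mb <- strsplit(mirna, "")[[1]]
  L <- length(mb)
  n <- length(tx)
  lens <- unique(pmax(1L, c(L, if (max_bulges >= 1) c(L - 1L, L + 1L))))

  hits <- list()
  for (sl in lens) {
    n_starts <- n - sl + 1L
    if (n_starts < 1) next
    scores <- site_scores_vec(mb, tx, sl, core)
    keep <- which(scores <= max_score)
    if (length(keep)) {
      hits[[length(hits) + 1L]] <- tibble(
        site_start = keep, site_end = keep + sl - 1L,
        score = scores[keep],
        cleavage_pos = keep + sl - 10L
      )
    }
  }
  if (!length(hits)) {
    return(tibble(site_start = integer(0), site_end = integer(0),
                  score = double(0), cleavage_pos = integer(0)))
  }
  bind_rows(hits) |>
    group_by(.data$site_start) |>
    slice_min(.data$score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$site_start)
}

# vectorized duplex scores for every site of length `sl` along a transcript
site_scores_vec <- function(mb, tx, sl, core) {
  L <- length(mb)
  n <- length(tx)
  starts <- seq_len(n - sl + 1L)
  if (sl == L) {
    total <- rep(0, length(starts))
    for (i in seq_len(L)) {
      y <- tx[starts + sl - i] # site base facing miRNA position i
      total <- total + duplex_penalty(pair_penalty_class(mb[i], y), i, core)
    }
    return(total)
  }
  # bulged alignments: minimum over every placement of the single bulge
  best <- rep(Inf, length(starts))
  if (sl == L + 1L) {
    for (g in seq_len(sl)) { # skipped site base (counting from site 3' end)
      total <- rep(duplex_penalty("mismatch", min(g, L), core), length(starts))
      for (i in seq_len(L)) {
        off <- if (i < g) i else i + 1L # site offset from its 3' end
        y <- tx[starts + sl - off]
        total <- total + duplex_penalty(pair_penalty_class(mb[i], y), i, core)
      }
      best <- pmin(best, total)
    }
  } else if (sl == L - 1L) {
    for (g in seq_len(L)) { # skipped miRNA position
      total <- rep(duplex_penalty("mismatch", g, core), length(starts))
      for (i in setdiff(seq_len(L), g)) {
        off <- if (i < g) i else i - 1L
        y <- tx[starts + sl - off]
        total <- total + duplex_penalty(pair_penalty_class(mb[i], y), i, core)
      }
      best <- pmin(best, total)
    }
  }
  best
}

#' Build a per-transcript degradome t-plot
#'
#' Records per-position raw and tags-per-billion abundances, the maximum,
#' and the median over positions with nonzero abundance, plus the abundance
#' at the expected cleavage site. An all-zero transcript is flagged
#' no-signal (median NA).
#'
#' @param positions tibble `position`, `count` for one transcript (from
#'   [map_degradome_tags()]).
#' @param transcript_length transcript length (nt), > 0.
#' @param expected_site expected cleavage position (1-based) or NA.
#' @param total_mapped library total mapped tags, for TPB scaling.
#' @return list of class `chillmir_tplot`: `abundance` (tibble `position`,
#'   `count`, `tpb`), `max_abundance`, `median_abundance` (nonzero
#'   positions), `expected_site`, `site_count`, `no_signal`.
#' @export
build_tplot <- function(positions, transcript_length, expected_site = NA,
                        total_mapped = NULL, transcript_id = NA_character_) {
  if (transcript_length < 1) abort("empty transcript")
  vec <- rep(0L, transcript_length)
  if (nrow(positions)) {
    if (any(positions$position < 1 | positions$position > transcript_length)) {
      abort("tag position outside transcript")
    }
    vec[positions$position] <- positions$count
  }
  total_mapped <- total_mapped %||% max(sum(vec), 1L)
  nz <- vec[vec > 0]
  structure(list(
    transcript_id = transcript_id,
    abundance = tibble(position = seq_len(transcript_length), count = vec,
                       tpb = tpb_normalize(vec, total_mapped)),
    max_abundance = if (length(nz)) max(nz) else 0L,
    median_abundance = if (length(nz)) median(nz) else NA_real_,
    expected_site = expected_site,
    site_count = if (is.na(expected_site)) NA_integer_ else vec[expected_site],
    no_signal = !length(nz)
  ), class = "chillmir_tplot")
}

#' Classify a cleavage site into degradome categories 0-4
#'
#' Given the transcript's tag-abundance profile and the raw count at the
#' expected site: category 4 when the site carries exactly one raw read;
#' otherwise (count > 1) category 0 when the site is the unique maximum on
#' the transcript, category 1 when it equals a maximum attained at more
#' than one position, category 2 when it lies strictly between the median
#' (over nonzero positions) and the maximum, and category 3 when it is at
#' or below the median. A site with zero abundance yields no call (NA).
#'
#' @param tplot a `chillmir_tplot` (see [build_tplot()]).
#' @param site 1-based transcript position of the expected cleavage site.
#' @param median_rule "inclusive" (default; category 3 is <= median) or
#'   "strict" (< median, values equal to the median fall in category 2).
#' @return integer category 0, 1, 2, 3, 4, or NA.
#' @export
categorize_site <- function(tplot, site, median_rule = c("inclusive",
                                                         "strict")) {
  median_rule <- match.arg(median_rule)
  vec <- tplot$abundance$count
  if (site < 1 || site > length(vec)) abort("site outside transcript")
  x <- vec[site]
  if (x == 0) return(NA_integer_)
  if (x == 1) return(4L)
  mx <- max(vec)
  med <- median(vec[vec > 0])
  if (x == mx) {
    if (sum(vec == mx) == 1L) return(0L) else return(1L)
  }
  at_or_below <- if (median_rule == "inclusive") x <= med else x < med
  if (at_or_below) 3L else 2L
}

#' Call miRNA cleavage targets from a degradome library
#'
#' End-to-end target calling for one library: maps tags to the
#' transcriptome, scans every miRNA against every transcript for duplex
#' sites with penalty at most `max_score`, and keeps sites whose expected
#' cleavage position (opposite miRNA position 10) carries degradome
#' signal, classified into categories 0-4 and quantified in tags per
#' billion.
#'
#' @param mirnas tibble `id`, `sequence`.
#' @param transcriptome tibble `id`, `sequence`.
#' @param tags degradome tag tibble (`sequence`, optional `count`).
#' @param max_score,max_bulges,core see [scan_target_sites()].
#' @param median_rule see [categorize_site()].
#' @return tibble of class `chillmir_targets`: `mirna_id`,
#'   `transcript_id`, `site_start`, `site_end`, `score`, `cleavage_pos`,
#'   `raw_count`, `tpb`, `category`.
#' @export
call_targets <- function(mirnas, transcriptome, tags, max_score = 7,
                         max_bulges = 1L, core = c(2L, 13L),
                         median_rule = "inclusive") {
  mapping <- map_degradome_tags(tags, transcriptome)
  out <- list()
  for (t in seq_len(nrow(transcriptome))) {
    tx_id <- transcriptome$id[t]
    tx_seq <- as_rna(transcriptome$sequence[t])
    pos <- filter(mapping$positions, .data$transcript_id == tx_id)
    if (nrow(pos) == 0) next
    tp <- build_tplot(pos[, c("position", "count")], nchar(tx_seq),
                      total_mapped = mapping$total_mapped,
                      transcript_id = tx_id)
    for (m in seq_len(nrow(mirnas))) {
      sites <- scan_target_sites(mirnas$sequence[m], tx_seq,
                                 max_score = max_score,
                                 max_bulges = max_bulges, core = core)
      for (s in seq_len(nrow(sites))) {
        cp <- sites$cleavage_pos[s]
        if (cp < 1 || cp > nchar(tx_seq)) next
        cat <- categorize_site(tp, cp, median_rule = median_rule)
        if (is.na(cat)) next
        out[[length(out) + 1L]] <- tibble(
          mirna_id = mirnas$id[m], transcript_id = tx_id,
          site_start = sites$site_start[s], site_end = sites$site_end[s],
          score = sites$score[s], cleavage_pos = cp,
          raw_count = tp$abundance$count[cp],
          tpb = tp$abundance$tpb[cp], category = cat)
      }
    }
  }
  res <- if (length(out)) bind_rows(out) else
    tibble(mirna_id = character(0), transcript_id = character(0),
           site_start = integer(0), site_end = integer(0), score = double(0),
           cleavage_pos = integer(0), raw_count = integer(0), tpb = double(0),
           category = integer(0))
  # one call per cleavage site: keep the best-scoring duplex
  res <- res |>
    group_by(.data$mirna_id, .data$transcript_id, .data$cleavage_pos) |>
    slice_min(.data$score, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$mirna_id, .data$transcript_id, .data$cleavage_pos)
  new_chillmir_tbl(res, "chillmir_targets",
                   total_mapped = mapping$total_mapped)
}

#' Compare target calls between the CT and NT libraries
#'
#' Labels each (miRNA, transcript, cleavage position) target CT-only,
#' NT-only or both; for shared targets the raw tag counts at the cleavage
#' site are compared with the two-library chi-square/Fisher machinery.
#'
#' @param calls_ct,calls_nt `chillmir_targets` tibbles from
#'   [call_targets()].
#' @param total_ct,total_nt total mapped degradome tags per library
#'   (defaults to the totals recorded on the calls).
#' @param ... passed to [diff_expression()] (alpha, lfc, pseudocount).
#' @return tibble: target key columns, `library`
#'   ("CT-only"/"NT-only"/"both"), per-library raw counts and TPB, and for
#'   shared targets `log2_ratio`, `p_chisq`, `p_fisher`, `significant`,
#'   `direction`.
#' @export
compare_targets <- function(calls_ct, calls_nt, total_ct = NULL,
                            total_nt = NULL, ...) {
  total_ct <- total_ct %||% attr(calls_ct, "total_mapped") %||%
    sum(calls_ct$raw_count)
  total_nt <- total_nt %||% attr(calls_nt, "total_mapped") %||%
    sum(calls_nt$raw_count)
  key <- c("mirna_id", "transcript_id", "cleavage_pos")
  ct <- calls_ct |>
    select(dplyr::all_of(key), raw_CT = "raw_count", tpb_CT = "tpb",
           category_CT = "category", score = "score")
  nt <- calls_nt |>
    select(dplyr::all_of(key), raw_NT = "raw_count", tpb_NT = "tpb",
           category_NT = "category", score_nt = "score")
  joined <- dplyr::full_join(ct, nt, by = key) |>
    mutate(score = dplyr::coalesce(.data$score, .data$score_nt),
           raw_CT = tidyr::replace_na(.data$raw_CT, 0L),
           raw_NT = tidyr::replace_na(.data$raw_NT, 0L),
           tpb_CT = tidyr::replace_na(.data$tpb_CT, 0),
           tpb_NT = tidyr::replace_na(.data$tpb_NT, 0),
           library = dplyr::case_when(
             .data$raw_CT > 0 & .data$raw_NT > 0 ~ "both",
             .data$raw_CT > 0 ~ "CT-only",
             TRUE ~ "NT-only")) |>
    select(-"score_nt")
  if (nrow(joined) == 0) return(joined)
  de <- diff_expression(
    tibble(id = paste(joined$mirna_id, joined$transcript_id,
                      joined$cleavage_pos, sep = "|"),
           count_CT = joined$raw_CT, count_NT = joined$raw_NT),
    total_ct = total_ct, total_nt = total_nt, ...)
  bind_cols(joined,
            de[match(paste(joined$mirna_id, joined$transcript_id,
                           joined$cleavage_pos, sep = "|"), de$id),
               c("log2_ratio", "p_chisq", "p_fisher", "direction",
                 "significant")])
}
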