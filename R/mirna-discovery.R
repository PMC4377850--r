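#' Match a candidate tag against known mature miRNAs
#'
#' An ungapped comparison anchored at the 5' ends, over the shorter of the
#' two lengths (5'-end identity is the conserved feature; overhanging bases
#' are not counted as mismatches). A known mature is a match when there is
#' at most `max_mm_first16` mismatch within positions 1--16 and at most
#' `max_mm_total` mismatches in total. Matches are ordered best-first:
#' fewest total mismatches, ties broken lexicographically by known id.
#'
#' @param tag candidate sequence (19--24 nt).
#' @param known tibble of known matures with columns `id`, `sequence`.
#' @param max_mm_first16,max_mm_total mismatch tolerances.
#' @return tibble `known_id`, `mismatches_first16`, `mismatches_total`
#'   (zero rows when nothing matches).
#' @export
match_conserved <- function(tag, known, max_mm_first16 = 1L,
                            max_mm_total = 3L) {
  if (is.null(known) || nrow(known) == 0) abort("known mature set is empty")
  tag <- as_rna(tag)
  tb <- strsplit(tag, "")[[1]]
  res <- purrr::map_dfr(seq_len(nrow(known)), function(i) {
    kb <- strsplit(as_rna(known$sequence[i]), "")[[1]]
    m <- min(length(tb), length(kb))
    mm <- which(tb[seq_len(m)] != kb[seq_len(m)])
    tibble(known_id = known$id[i],
           mismatches_first16 = sum(mm <= min(16L, m)),
           mismatches_total = length(mm))
  })
  res |>
    filter(.data$mismatches_first16 <= max_mm_first16,
           .data$mismatches_total <= max_mm_total) |>
    arrange(.data$mismatches_total, .data$known_id)
}

#' Excise candidate precursor windows around a genome-mapped tag
#'
#' Extends the mapped tag by each flank size on each side (all asymmetric
#' combinations of the configured flank set), clips to chromosome bounds,
#' and deduplicates identical windows.
#'
#' @param genome tibble `id`, `sequence`.
#' @param chrom chromosome id the tag maps to.
#' @param start,end 1-based inclusive tag locus.
#' @param flanks candidate flank lengths (nt) tried on each side.
#' @return tibble `window_start`, `window_end`, `sequence`,
#'   `mature_offset` (1-based position of the tag inside the window).
#' @export
excise_precursors <- function(genome, chrom, start, end,
                              flanks = c(20L, 60L, 120L, 200L)) {
  row <- genome[genome$id == chrom, ]
  if (nrow(row) != 1) abort(sprintf("chromosome '%s' not in genome", chrom))
  n <- nchar(row$sequence)
  if (start < 1 || end > n || start > end) {
    abort("tag locus outside genome bounds")
  }
  grid <- tidyr::expand_grid(f5 = flanks, f3 = flanks)
  out <- grid |>
    mutate(window_start = pmax(1L, start - .data$f5),
           window_end = pmin(n, end + .data$f3)) |>
    distinct(.data$window_start, .data$window_end) |>
    mutate(sequence = substr(rep(row$sequence, dplyr::n()),
                             .data$window_start, .data$window_end),
           mature_offset = start - .data$window_start + 1L) |>
    arrange(.data$window_start, .data$window_end)
  out[, c("window_start", "window_end", "sequence", "mature_offset")]
}

#' Evaluate a folded precursor as a miRNA hairpin
#'
#' Community-style structural criteria: the mature must lie entirely on one
#' arm of the hairpin (no overlap with a terminal loop), have at most
#' `max_unpaired` unpaired positions against its star region, no
#' asymmetric bulge larger than `max_bulge` nt within the duplex, and a
#' star span derivable with a `overhang`-nt 3' overhang.
#'
#' @param structure dot-bracket string of the folded precursor.
#' @param mature_start,mature_end 1-based mature span within the precursor.
#' @param max_unpaired maximum unpaired mature positions (default 4).
#' @param max_bulge maximum asymmetric bulge size in nt (default 2).
#' @param overhang star 3' overhang in nt (default 2).
#' @return list with `pass` (logical), `reasons` (character), `arm`
#'   ("5p"/"3p" or NA), `star_start`, `star_end`.
#' @export
evaluate_hairpin <- function(structure, mature_start, mature_end,
                             max_unpaired = 4L, max_bulge = 2L,
                             overhang = 2L) {
  n <- nchar(structure)
  if (mature_start < 1 || mature_end > n || mature_start > mature_end) {
    abort("mature span outside precursor")
  }
  pt <- pair_table(structure)
  span <- mature_start:mature_end
  partners <- pt[span]
  paired <- span[partners != 0]
  reasons <- character(0)
  arm <- NA_character_
  star <- c(NA_integer_, NA_integer_)

  if (!length(paired)) {
    reasons <- c(reasons, "unpaired-mature")
  } else {
    pp <- pt[paired]
    if (any(pp >= mature_start & pp <= mature_end) ||
        (any(pp > mature_end) && any(pp < mature_start))) {
      reasons <- c(reasons, "loop-overlap")
    } else {
      arm <- if (all(pp > mature_end)) "5p" else "3p"
      unpaired <- sum(partners == 0)
      if (unpaired > max_unpaired) {
        reasons <- c(reasons, "too-many-unpaired")
      }
      if (length(paired) > 1) {
        gm <- diff(paired) - 1L
        gs <- abs(diff(pt[paired])) - 1L
        if (any(abs(gm - gs) > max_bulge)) {
          reasons <- c(reasons, "asymmetric-bulge")
        }
      }
      star <- sort(c(pt[paired[length(paired)]], pt[paired[1]])) + overhang
      if (star[2] > n || star[1] < 1) {
        reasons <- c(reasons, "no-star")
        star <- c(NA_integer_, NA_integer_)
      }
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons, arm = arm,
       star_start = star[1], star_end = star[2])
}

#' Name a tag relative to the known miRNA annotation
#'
#' A tag overlapping a known mature inside a known hairpin keeps the
#' canonical mature name; a tag inside a known hairpin but not overlapping
#' the mature (or its star) is a new flanking product and gets the `-p5` or
#' `-p3` suffix according to which side of the hairpin it sits on; a tag
#' from an unannotated hairpin receives a predicted-candidate id
#' `PC-<n>-<arm>`.
#'
#' @param sequence the tag.
#' @param known_mature,known_hairpin reference tibbles (`id`, `sequence`).
#' @param pc_number candidate number to use for a novel id.
#' @param arm "5p"/"3p" arm of the (novel) precursor, used for PC naming.
#' @return tibble `id`, `designation` ("canonical", "p5", "p3" or "novel"),
#'   `source_hairpin` (NA for novel calls).
#' @export
assign_identity <- function(sequence, known_mature, known_hairpin,
                            pc_number = 1L, arm = NA_character_) {
  sequence <- as_rna(sequence)
  if (!is.null(known_hairpin) && nrow(known_hairpin) > 0) {
    for (h in seq_len(nrow(known_hairpin))) {
      hp <- as_rna(known_hairpin$sequence[h])
      pos <- stringr::str_locate(hp, stringr::fixed(sequence))[1, "start"]
      if (is.na(pos)) next
      tag_span <- c(pos, pos + nchar(sequence) - 1L)
      # locate any known mature within this hairpin
      stem_id <- sub("-precursor$", "", known_hairpin$id[h])
      for (m in seq_len(nrow(known_mature))) {
        mp <- stringr::str_locate(hp, stringr::fixed(
          as_rna(known_mature$sequence[m])))[1, "start"]
        if (is.na(mp)) next
        mspan <- c(mp, mp + nchar(known_mature$sequence[m]) - 1L)
        if (tag_span[1] <= mspan[2] && tag_span[2] >= mspan[1]) {
          return(tibble(id = known_mature$id[m], designation = "canonical",
                        source_hairpin = known_hairpin$id[h]))
        }
      }
      # inside the hairpin but away from any mature: flanking p5/p3 product
      fold <- fold_rna(hp)
      pt <- pair_table(fold$structure)
      paired <- which(pt != 0)
      mid <- if (length(paired)) {
        arms <- which(pt > seq_along(pt))       # opening side
        max(arms)                               # last 5'-arm position
      } else nchar(hp) / 2
      side <- if (tag_span[2] <= mid) "p5" else "p3"
      return(tibble(id = paste0(stem_id, "-", side), designation = side,
                    source_hairpin = known_hairpin$id[h]))
    }
  }
  arm_sfx <- if (is.na(arm)) "5p" else arm
  tibble(id = sprintf("PC-%d-%s", pc_number, arm_sfx),
         designation = "novel", source_hairpin = NA_character_)
}

#' Group miRNA calls into families
#'
#' Conserved calls are grouped by the numeric stem of the matched known
#' miRNA name (miR156a and miR156j both belong to family "156"); novel
#' calls form singleton families; unparseable known names fall into family
#' "unknown".
#'
#' @param calls tibble of miRNA calls with columns `id`, `status`, and
#'   `known_id` for conserved calls.
#' @return the input with a `family` column added.
#' @export
group_families <- function(calls) {
  if (nrow(calls) == 0) return(mutate(calls, family = character(0)))
  stem <- stringr::str_match(calls$known_id, stringr::regex(
    "miR-?([0-9]+)", ignore_case = TRUE))[, 2]
  mutate(calls, family = dplyr::case_when(
    .data$status == "novel" ~ .data$id,
    !is.na(stem) ~ stem,
    TRUE ~ "unknown"
  ))
}

locate_in_genome <- function(sequence, genome) {
  hits <- tibble(chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0))
  for (i in seq_len(nrow(genome))) {
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") as_rna(genome$sequence[i]) else
        rev_comp(genome$sequence[i])
      loc <- stringr::str_locate_all(subject, stringr::fixed(sequence))[[1]]
      if (nrow(loc)) {
        st <- loc[, "start"]; en <- loc[, "end"]
        if (strand == "-") {
          n <- nchar(subject)
          tmp <- n - en + 1L
          en <- n - st + 1L
          st <- tmp
        }
        hits <- bind_rows(hits, tibble(chrom = genome$id[i],
                                       start = as.integer(st),
                                       end = as.integer(en),
                                       strand = strand))
      }
    }
  }
  arrange(hits, .data$chrom, .data$start, .data$strand)
}

#' Identify conserved and novel miRNAs among clean unique tags
#'
#' Tags within the 19--24 nt candidacy window are first matched against the
#' known mature set (at most one mismatch in the first 16 nt, at most three
#' in total); unmatched tags located inside a known hairpin become p5/p3
#' flanking calls; the remainder are mapped to the genome, candidate
#' precursor windows are excised and folded, and a tag whose best window
#' passes the hairpin criteria with MFEI strictly above `mfei_threshold`
#' is called novel (`PC-<n>-<arm>`).
#'
#' @param tags classified unique tags (needs `sequence`, `class`, count
#'   columns); only "clean" tags are considered.
#' @param ref a `chillmir_reference` bundle.
#' @param candidacy_min,candidacy_max miRNA length window (nt).
#' @param mfei_threshold novel-candidate MFEI cutoff (strict).
#' @param flanks precursor excision flank set.
#' @param backend folding backend passed to [fold_rna()].
#' @return tibble of miRNA calls: `id`, `sequence`, `status`
#'   ("conserved"/"novel"), `designation`, `family`, `arm`, `known_id`,
#'   `mismatches_first16`, `mismatches_total`, `precursor_id`, `mfei`, and
#'   the per-library count columns carried over from `tags`.
#' @export
discover_mirnas <- function(tags, ref, candidacy_min = 19L,
                            candidacy_max = 24L, mfei_threshold = 0.80,
                            flanks = c(20L, 60L, 120L, 200L),
                            backend = "builtin") {
  count_cols <- grep("^count_", names(tags), value = TRUE)
  empty <- tibble(id = character(0), sequence = character(0),
                  status = character(0), designation = character(0),
                  arm = character(0), known_id = character(0),
                  mismatches_first16 = integer(0),
                  mismatches_total = integer(0),
                  precursor_id = character(0), mfei = double(0))
  for (cc in count_cols) empty[[cc]] <- integer(0)
  cand <- tags |>
    filter(.data$class == "clean",
           nchar(.data$sequence) >= candidacy_min,
           nchar(.data$sequence) <= candidacy_max) |>
    arrange(.data$sequence)
  if (nrow(cand) == 0) return(group_families(empty))

  have_known <- !is.null(ref$known_mature) && nrow(ref$known_mature) > 0
  calls <- list()
  pc_n <- 0L
  for (i in seq_len(nrow(cand))) {
    sq <- as_rna(cand$sequence[i])
    counts <- cand[i, count_cols]

    if (have_known) {
      m <- match_conserved(sq, ref$known_mature)
      if (nrow(m) > 0) {
        best <- m[1, ]
        calls[[length(calls) + 1L]] <- bind_cols(tibble(
          id = best$known_id, sequence = sq, status = "conserved",
          designation = "canonical",
          arm = stringr::str_match(best$known_id, "-([35]p)$")[, 2],
          known_id = best$known_id,
          mismatches_first16 = best$mismatches_first16,
          mismatches_total = best$mismatches_total,
          precursor_id = NA_character_, mfei = NA_real_), counts)
        next
      }
      ident <- assign_identity(sq, ref$known_mature, ref$known_hairpin)
      if (ident$designation %in% c("p5", "p3", "canonical")) {
        calls[[length(calls) + 1L]] <- bind_cols(tibble(
          id = ident$id, sequence = sq, status = "conserved",
          designation = ident$designation,
          arm = NA_character_, known_id = ident$id,
          mismatches_first16 = if (ident$designation == "canonical") 0L else NA_integer_,
          mismatches_total = if (ident$designation == "canonical") 0L else NA_integer_,
          precursor_id = ident$source_hairpin, mfei = NA_real_), counts)
        next
      }
    }

    # novel route: genome mapping, precursor excision, folding, MFEI
    loci <- locate_in_genome(sq, ref$genome)
    best_call <- NULL
    for (l in seq_len(nrow(loci))) {
      locus <- loci[l, ]
      wins <- excise_precursors(ref$genome, locus$chrom, locus$start,
                                locus$end, flanks = flanks)
      for (w in seq_len(nrow(wins))) {
        win <- wins[w, ]
        wseq <- if (locus$strand == "+") win$sequence else
          rev_comp(win$sequence)
        moff <- if (locus$strand == "+") win$mature_offset else
          nchar(wseq) - (win$mature_offset + nchar(sq) - 1L) + 1L
        fold <- fold_rna(wseq, backend = backend)
        hp <- evaluate_hairpin(fold$structure, moff, moff + nchar(sq) - 1L)
        if (!hp$pass) next
        mf <- compute_mfei(fold$mfe, nchar(wseq), gc_fraction(wseq) * 100,
                           threshold = mfei_threshold)
        if (!mf$candidate) next
        cand_call <- list(mfei = mf$mfei, arm = hp$arm,
                          precursor_id = sprintf("%s:%d-%d:%s", locus$chrom,
                                                 win$window_start,
                                                 win$window_end,
                                                 locus$strand))
        if (is.null(best_call) || cand_call$mfei > best_call$mfei ||
            (cand_call$mfei == best_call$mfei &&
             cand_call$precursor_id < best_call$precursor_id)) {
          best_call <- cand_call
        }
      }
    }
    if (!is.null(best_call)) {
      pc_n <- pc_n + 1L
      calls[[length(calls) + 1L]] <- bind_cols(tibble(
        id = sprintf("PC-%d-%s", pc_n, best_call$arm), sequence = sq,
        status = "novel", designation = "novel", arm = best_call$arm,
        known_id = NA_character_, mismatches_first16 = NA_integer_,
        mismatches_total = NA_integer_,
        precursor_id = best_call$precursor_id,
        mfei = best_call$mfei), counts)
    }
  }
  if (!length(calls)) return(group_families(empty))
  group_families(bind_rows(calls))
}
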