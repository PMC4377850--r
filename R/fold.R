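#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' The built-in backend is a dynamic program over nested (pseudoknot-free)
#' structures that minimizes a per-pair stacking energy: G:C -3, A:U -2,
#' G:U -1 kcal/mol, with a minimum hairpin loop of 3 nt. It is deliberately
#' simple, fully deterministic, and serves as the reference folder for the
#' whole pipeline; an external thermodynamic folder (ViennaRNA's RNAfold,
#' when on the PATH) can be substituted via `backend = "vienna"`.
#'
#' @param sequence RNA string (T accepted and transliterated); sequences
#'   too short to close a hairpin fold to the open chain (MFE 0).
#' @param backend "builtin" (default) or "vienna".
#' @param min_loop minimum hairpin loop length (builtin backend).
#' @return list with `structure` (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @export
fold_rna <- function(sequence, backend = c("builtin", "vienna"),
                     min_loop = 3L) {
  backend <- match.arg(backend)
  sequence <- assert_rna(sequence, "fold_rna input")
  if (grepl("N", sequence, fixed = TRUE)) {
    abort("fold_rna input must not contain N")
  }
  if (backend == "vienna") {
    return(fold_rna_vienna(sequence))
  }
  res <- fold_backend_cpp(sequence, as.integer(min_loop))
  list(structure = res$structure, mfe = res$mfe)
}

fold_rna_vienna <- function(sequence) {
  if (!nzchar(Sys.which("RNAfold"))) {
    abort("RNAfold not found on PATH; use backend = 'builtin'")
  }
  out <- system2("RNAfold", c("--noPS"), input = sequence, stdout = TRUE)
  m <- stringr::str_match(out[2], "^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)")
  list(structure = m[2], mfe = as.numeric(m[3]))
}

# pairing partner table from a dot-bracket string (0 = unpaired), 1-based
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) abort("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) abort("unbalanced dot-bracket structure")
  pt
}

#' Adjusted MFE and the minimal folding free energy index (MFEI)
#'
#' AMFE = -MFE / length x 100 (kcal/mol per 100 nt); MFEI = AMFE / GC%.
#' A precursor qualifies as a candidate hairpin when MFEI strictly exceeds
#' `threshold` (default 0.80).
#'
#' @param mfe minimum folding free energy, kcal/mol (<= 0).
#' @param length precursor length, nt.
#' @param gc_percent GC content as a percentage in (0, 100].
#' @param threshold candidacy threshold on MFEI (strict inequality).
#' @return tibble with `amfe`, `mfei`, `candidate`.
#' @export
compute_mfei <- function(mfe, length, gc_percent, threshold = 0.80) {
  if (any(gc_percent <= 0)) abort("gc_percent must be positive")
  amfe <- -mfe / length * 100
  mfei <- amfe / gc_percent
  tibble(amfe = amfe, mfei = mfei, candidate = mfei > threshold)
}
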