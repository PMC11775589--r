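#' Alignment scoring scheme
#'
#' Penalties are stored as magnitudes and applied subtractively; a gap of
#' length L costs `gap_open + L * gap_extend`. The defaults (match +1,
#' mismatch -2, gap open -4, gap extend -1) favour substitution calls over
#' spurious compensating indel pairs at the per-site error rates this assay
#' operates at (roughly 2% and below).
#'
#' @param match Positive match reward.
#' @param mismatch,gap_open,gap_extend Non-negative penalty magnitudes;
#'   `gap_open >= gap_extend`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = 2L, gap_open = 4L,
                           gap_extend = 1L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (match <= 0L) stop("match reward must be > 0", call. = FALSE)
  if (mismatch < 0L || gap_open < 0L || gap_extend < 0L)
    stop("penalties are magnitudes and must be >= 0", call. = FALSE)
  if (gap_open < gap_extend)
    stop("gap_open must be >= gap_extend", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "scoring_scheme")
}

check_dna_input <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty sequence", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop(what, " must be over A/C/G/T/N", call. = FALSE)
  invisible(x)
}

#' Global affine-gap alignment of a clone to the template
#'
#' Needleman-Wunsch/Gotoh global (end-to-end) alignment — clones are full
#' amplicons of a known template, so local alignment is not appropriate. N
#' aligned against anything scores 0 (neither match nor mismatch). Traceback
#' ties are broken deterministically: diagonal over gap-in-clone over
#' gap-in-template.
#'
#' @param template,clone Sequences over A/C/G/T/N.
#' @param scoring A [scoring_scheme()].
#' @return An object of class `alignment`: `aligned_template` and
#'   `aligned_clone` (equal-length gapped strings; no column is gap in both),
#'   integer `score`, `identity` (fraction of base/base columns that match),
#'   and `column_map` (per-column 0-based template coordinate, `NA` at
#'   insertion columns).
#' @examples
#' a <- align_global("ACGTACGTAC", "ACGTACGTAC")
#' a$score     # 10
#' @export
align_global <- function(template, clone, scoring = scoring_scheme()) {
  check_dna_input(template, "template")
  check_dna_input(clone, "clone")
  stopifnot(inherits(scoring, "scoring_scheme"))
  raw <- gotoh_align_cpp(template, clone, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  new_alignment(raw$aligned_template, raw$aligned_clone, raw$score, scoring)
}

new_alignment <- function(aligned_template, aligned_clone, score, scoring) {
  tch <- strsplit(aligned_template, "")[[1]]
  cch <- strsplit(aligned_clone, "")[[1]]
  column_map <- cumsum(tch != "-") - 1L
  column_map[tch == "-"] <- NA_integer_
  both <- tch != "-" & cch != "-"
  identity <- if (any(both)) mean(tch[both] == cch[both]) else 0
  structure(list(aligned_template = aligned_template,
                 aligned_clone = aligned_clone,
                 score = as.integer(score),
                 identity = identity,
                 column_map = column_map,
                 scoring = scoring),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment: score", x$score, " identity",
      format(x$identity, digits = 4), "\n")
  cat(" T:", x$aligned_template, "\n C:", x$aligned_clone, "\n")
  invisible(x)
}

#' Orient a clone against the template
#'
#' TOPO-TA inserts ligate in either orientation, so each clone is aligned
#' both as-is and reverse-complemented; whichever scores higher is kept
#' (ties go forward).
#'
#' @inheritParams align_global
#' @return A list with `sequence` (the template-strand sequence), `strand`
#'   (`"forward"` or `"reverse"`) and `alignment` (the winning [align_global()]
#'   result).
#' @export
orient_clone <- function(clone, template, scoring = scoring_scheme()) {
  fwd <- align_global(template, clone, scoring)
  rc <- revcomp(clone)
  rev <- align_global(template, rc, scoring)
  if (rev$score > fwd$score)
    list(sequence = rc, strand = "reverse", alignment = rev)
  else
    list(sequence = clone, strand = "forward", alignment = fwd)
}

#' Left-normalize indel placement in an alignment
#'
#' Within a homopolymer (or any repeat) an indel of equal score can sit at
#' several columns; MEGA-style aligners place it arbitrarily. This shifts
#' every gap run to its leftmost score-equivalent position so event
#' coordinates are reproducible. The score and the degapped sequences are
#' unchanged; the operation is idempotent.
#'
#' @param alignment An `alignment` from [align_global()].
#' @return A left-normalized `alignment`.
#' @export
left_normalize_indels <- function(alignment) {
  stopifnot(inherits(alignment, "alignment"))
  sc <- alignment$scoring
  rows <- list(strsplit(alignment$aligned_template, "")[[1]],
               strsplit(alignment$aligned_clone, "")[[1]])
  s <- function(x, y) {
    if (x == "N" || y == "N") 0L
    else if (x == y) sc$match else -sc$mismatch
  }
  repeat {
    moved <- FALSE
    for (r in 1:2) {
      gapped <- rows[[r]]; other <- rows[[3 - r]]
      i <- 2L
      n <- length(gapped)
      while (i <= n) {
        if (gapped[i] == "-" && gapped[i - 1L] != "-" && other[i - 1L] != "-" &&
            (i == 2L || gapped[i - 2L] != "-")) {
          j <- i
          while (j < n && gapped[j + 1L] == "-") j <- j + 1L
          # run [i..j]; shifting left swaps the base at i-1 to column j:
          # score-neutral iff its pairing status against the other row is
          # unchanged (the gap cost depends only on run length)
          b <- gapped[i - 1L]
          if (other[j] != "-" && s(b, other[i - 1L]) == s(b, other[j])) {
            gapped[i - 1L] <- "-"
            gapped[j] <- b
            moved <- TRUE
            i <- max(2L, i - 1L)
            next
          }
          i <- j + 1L
        } else i <- i + 1L
      }
      rows[[r]] <- gapped
    }
    if (!moved) break
  }
  new_alignment(paste(rows[[1]], collapse = ""),
                paste(rows[[2]], collapse = ""),
                alignment$score, sc)
}

#' Exhaustive-enumeration alignment score (testing oracle)
#'
#' Computes the optimal global affine-gap score by enumerating every gapped
#' pairing of the two sequences. Exponential — intended only for verifying
#' [align_global()] on short sequences.
#'
#' @inheritParams align_global
#' @return Integer optimal score.
#' @export
brute_force_align_score <- function(template, clone,
                                    scoring = scoring_scheme()) {
  check_dna_input(template, "template")
  check_dna_input(clone, "clone")
  brute_force_align_score_cpp(template, clone, scoring$match,
                              scoring$mismatch, scoring$gap_open,
                              scoring$gap_extend)
}
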