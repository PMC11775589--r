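#' Read the clone bases aligned to each watermark and apply the filter
#'
#' A clone passes only if the bases aligned to both watermark dinucleotides
#' read exactly as the converted state with no gap in (or insertion between)
#' either watermark: only sequences carrying both converted watermarks have
#' demonstrably passed through the XNA intermediate, and a gap makes the
#' conversion unverifiable.
#'
#' @param alignment A (preferably left-normalized) [align_global()] result
#'   for an oriented clone.
#' @param design An [assay_design()].
#' @param clone_id Identifier recorded in the result.
#' @return One-row data.frame: `clone_id`, `observed5`, `observed3`,
#'   `passed`, `failure_reason` (one of `none`, `watermark5_unconverted`,
#'   `watermark3_unconverted`, `both_unconverted`, `gap_in_watermark`,
#'   `low_identity`).
#' @export
check_watermarks <- function(alignment, design, clone_id = "clone") {
  stopifnot(inherits(alignment, "alignment"), inherits(design, "assay_design"))
  obs5 <- watermark_observed(alignment, design$watermark5)
  obs3 <- watermark_observed(alignment, design$watermark3)
  gap <- grepl("-", obs5, fixed = TRUE) || grepl("-", obs3, fixed = TRUE)
  un5 <- obs5 != design$watermark5$to
  un3 <- obs3 != design$watermark3$to
  passed <- !gap && !un5 && !un3
  reason <- if (passed) "none"
    else if (gap) "gap_in_watermark"
    else if (un5 && un3) "both_unconverted"
    else if (un5) "watermark5_unconverted"
    else "watermark3_unconverted"
  data.frame(clone_id = clone_id, observed5 = obs5, observed3 = obs3,
             passed = passed, failure_reason = reason,
             stringsAsFactors = FALSE)
}

# Clone characters aligned to the watermark's two template positions,
# including any inserted bases between them (an insertion inside the
# watermark also breaks the exact dinucleotide read).
watermark_observed <- function(alignment, wm) {
  cols <- which(!is.na(alignment$column_map) &
                  alignment$column_map %in% c(wm$start, wm$start + 1L))
  cch <- strsplit(alignment$aligned_clone, "")[[1]]
  paste(cch[seq.int(min(cols), max(cols))], collapse = "")
}

# Clone character aligned to each analysis-span template position:
# a base, "N", or "-" when the position is deleted in the clone.
span_profile <- function(alignment, design) {
  a0 <- design$analysis[1]; a1 <- design$analysis[2]
  cch <- strsplit(alignment$aligned_clone, "")[[1]]
  keep <- !is.na(alignment$column_map) &
    alignment$column_map >= a0 & alignment$column_map < a1
  prof <- cch[keep][order(alignment$column_map[keep])]
  names(prof) <- as.character(seq.int(a0, a1 - 1L))
  prof
}

#' Call mutation events inside the analysis region
#'
#' Scans only alignment columns mapping into the analysis span.
#' Base-against-base columns that differ are substitutions; a maximal run of
#' clone gaps is one deletion event of that length; a maximal run of
#' template gaps is one insertion event anchored after the last template
#' position before it (counted when that anchor lies in the span). Columns
#' where the clone reads N are skipped — N never counts as a match, a
#' mismatch, or an error. Deletion runs straddling a span boundary are
#' clipped to the span.
#'
#' @param alignment A left-normalized [align_global()] result (see
#'   [left_normalize_indels()]) for an oriented clone.
#' @param design An [assay_design()].
#' @param clone_id Identifier recorded in the events.
#' @return data.frame of events: `clone_id`, `kind` (`substitution`,
#'   `insertion`, `deletion`), `template_pos` (0-based; for insertions the
#'   position the inserted bases follow), `from_base`, `to_base`, `length`.
#' @export
call_mutations <- function(alignment, design, clone_id = "clone") {
  stopifnot(inherits(alignment, "alignment"), inherits(design, "assay_design"))
  a0 <- design$analysis[1]; a1 <- design$analysis[2]
  prof <- span_profile(alignment, design)
  pos <- seq.int(a0, a1 - 1L)
  tpl <- strsplit(span_seq(design$template, design$analysis), "")[[1]]

  is_sub <- prof %in% BASES & prof != tpl
  subs <- if (any(is_sub)) data.frame(
    clone_id = clone_id, kind = "substitution", template_pos = pos[is_sub],
    from_base = tpl[is_sub], to_base = unname(prof[is_sub]), length = 1L,
    stringsAsFactors = FALSE)

  dels <- NULL
  if (any(prof == "-")) {
    dpos <- pos[prof == "-"]
    run_id <- cumsum(c(1L, diff(dpos) != 1L))
    dels <- do.call(rbind, lapply(split(dpos, run_id), function(p) {
      data.frame(clone_id = clone_id, kind = "deletion", template_pos = p[1],
                 from_base = paste(tpl[p - a0 + 1L], collapse = ""),
                 to_base = "", length = length(p), stringsAsFactors = FALSE)
    }))
  }

  ins <- NULL
  map <- alignment$column_map
  if (anyNA(map)) {
    cch <- strsplit(alignment$aligned_clone, "")[[1]]
    gap_cols <- which(is.na(map))
    run_id <- cumsum(c(1L, diff(gap_cols) != 1L))
    ins <- do.call(rbind, lapply(split(gap_cols, run_id), function(cols) {
      before <- map[seq_len(cols[1] - 1L)]
      anchor <- if (any(!is.na(before))) max(before, na.rm = TRUE) else -1L
      if (anchor < a0 || anchor >= a1) return(NULL)
      bases <- cch[cols]
      bases <- bases[bases != "N"]          # N insertions are uninformative
      if (!length(bases)) return(NULL)
      data.frame(clone_id = clone_id, kind = "insertion",
                 template_pos = anchor, from_base = "",
                 to_base = paste(bases, collapse = ""),
                 length = length(bases), stringsAsFactors = FALSE)
    }))
  }

  ev <- rbind(subs, dels, ins)
  if (is.null(ev)) return(empty_events())
  ev <- ev[order(ev$template_pos, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Summarize a no-RT control dataset for DNA contamination
#'
#' In the wet assay a control reaction omitting reverse transcription should
#' yield no watermark-converted product; any clone from it that passes the
#' watermark filter indicates DNA contamination arising through PCR. This
#' runs each control clone through orientation, alignment and the watermark
#' filter and reports the passing fraction.
#'
#' @param records A `clone_records` data.frame (e.g. from [read_fasta()]).
#' @param design An [assay_design()].
#' @param scoring A [scoring_scheme()].
#' @return A list: `n`, `n_pass`, `pass_fraction`, `contaminated`
#'   (`TRUE` when any control clone passes) and the per-clone `watermarks`
#'   table.
#' @export
detect_no_rt_contamination <- function(records, design,
                                       scoring = scoring_scheme()) {
  stopifnot(inherits(design, "assay_design"))
  if (is.null(records) || nrow(records) == 0)
    stop("control dataset is empty", call. = FALSE)
  wm <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    ori <- orient_clone(records$sequence[i], design$template, scoring)
    aln <- left_normalize_indels(ori$alignment)
    check_watermarks(aln, design, records$id[i])
  }))
  n_pass <- sum(wm$passed)
  list(n = nrow(records), n_pass = n_pass,
       pass_fraction = n_pass / nrow(records),
       contaminated = n_pass > 0, watermarks = wm)
}
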