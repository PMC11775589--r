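#' Assay design: template, primer-binding sites, and watermarks
#'
#' An `assay_design` bundles everything the pipeline needs to know about the
#' replication assay: the reference DNA template (5'->3'), the two
#' primer-binding-site (PBS) spans, the watermark dinucleotides inside them,
#' and the analysis region between the PBS spans over which polymerase errors
#' are counted. All coordinates are 0-based, half-open intervals on the
#' template, so `c(20, 76)` covers template positions 20..75.
#'
#' Genuine replication products carry both watermarks in their *converted*
#' state (the 5' PBS AA read as TT and the 3' PBS TT read as AA); carried-over
#' template DNA retains the template state and is rejected by the watermark
#' filter.
#'
#' @param template DNA string over A/C/G/T (no ambiguity codes: design
#'   sequences are synthetic oligonucleotides).
#' @param pbs5,pbs3,analysis Integer length-2 vectors, 0-based half-open
#'   spans on the template. `analysis` must lie strictly between the two PBS
#'   spans and overlap neither.
#' @param watermark5,watermark3 Watermark specifications created with
#'   [watermark_spec()]; each must lie inside its PBS span.
#' @return An object of class `assay_design`.
#' @seealso [load_design()], [default_design()]
#' @examples
#' d <- default_design()
#' substr(d$template, d$watermark5$start + 1, d$watermark5$start + 2)  # "AA"
#' @export
assay_design <- function(template, pbs5, pbs3, analysis, watermark5, watermark3) {
  template <- toupper(as.character(template))
  if (!grepl("^[ACGT]+$", template))
    stop("template: must contain only A/C/G/T", call. = FALSE)
  n <- nchar(template)
  pbs5 <- check_span(pbs5, n, "pbs5")
  pbs3 <- check_span(pbs3, n, "pbs3")
  analysis <- check_span(analysis, n, "analysis")
  if (spans_overlap(pbs5, pbs3))
    stop("pbs5/pbs3: primer-binding-site spans overlap", call. = FALSE)
  if (pbs5[1] > pbs3[1]) stop("pbs5: must precede pbs3 on the template", call. = FALSE)
  if (!(analysis[1] >= pbs5[2] && analysis[2] <= pbs3[1]))
    stop("analysis: span must lie strictly between pbs5 and pbs3", call. = FALSE)
  check_watermark(watermark5, "watermark5")
  check_watermark(watermark3, "watermark3")
  if (!(watermark5$start >= pbs5[1] && watermark5$start + 2L <= pbs5[2]))
    stop("watermark5: positions must fall inside pbs5", call. = FALSE)
  if (!(watermark3$start >= pbs3[1] && watermark3$start + 2L <= pbs3[2]))
    stop("watermark3: positions must fall inside pbs3", call. = FALSE)
  for (nm in c("watermark5", "watermark3")) {
    wm <- if (nm == "watermark5") watermark5 else watermark3
    seen <- substr(template, wm$start + 1L, wm$start + 2L)
    if (seen != wm$from)
      stop(nm, ": template reads ", seen, " at its positions, expected ", wm$from,
           call. = FALSE)
  }
  structure(
    list(template = template, pbs5 = pbs5, pbs3 = pbs3, analysis = analysis,
         watermark5 = watermark5, watermark3 = watermark3),
    class = "assay_design"
  )
}

#' Watermark specification
#'
#' One engineered dinucleotide mismatch in a primer-binding site. `from` is
#' the state in the starting DNA template, `to` the state a clone reads after
#' a genuine replication cycle through the XNA intermediate.
#'
#' @param start 0-based template position of the first watermark base.
#' @param from,to Dinucleotides over A/C/G/T; must differ.
#' @return An object of class `watermark_spec`.
#' @export
watermark_spec <- function(start, from, to) {
  from <- toupper(from); to <- toupper(to)
  if (!grepl("^[ACGT]{2}$", from) || !grepl("^[ACGT]{2}$", to))
    stop("watermark states must be dinucleotides over A/C/G/T", call. = FALSE)
  if (from == to)
    stop("watermark template and converted states must differ", call. = FALSE)
  structure(list(start = as.integer(start), from = from, to = to),
            class = "watermark_spec")
}

check_span <- function(x, n, field) {
  x <- as.integer(x)
  if (length(x) != 2L || anyNA(x) || x[1] < 0L || x[2] > n || x[1] >= x[2])
    stop(field, ": invalid span (need 0 <= start < end <= ", n, ")", call. = FALSE)
  x
}

spans_overlap <- function(a, b) a[1] < b[2] && b[1] < a[2]

check_watermark <- function(wm, field) {
  if (!inherits(wm, "watermark_spec"))
    stop(field, ": must be a watermark_spec", call. = FALSE)
  invisible(wm)
}

span_length <- function(span) span[2] - span[1]

span_seq <- function(template, span) substr(template, span[1] + 1L, span[2])

#' @export
print.assay_design <- function(x, ...) {
  cat("assay_design:", nchar(x$template), "nt template\n")
  cat("  pbs5     [", x$pbs5[1], ",", x$pbs5[2], ")  watermark ",
      x$watermark5$from, "->", x$watermark5$to, " @", x$watermark5$start, "\n", sep = "")
  cat("  analysis [", x$analysis[1], ",", x$analysis[2], ")  (",
      span_length(x$analysis), " nt scored)\n", sep = "")
  cat("  pbs3     [", x$pbs3[1], ",", x$pbs3[2], ")  watermark ",
      x$watermark3$from, "->", x$watermark3$to, " @", x$watermark3$start, "\n", sep = "")
  invisible(x)
}

#' Load an assay design from a YAML config file
#'
#' The config carries the template sequence, the three spans (0-based
#' half-open `[start, end]` pairs) and the two watermark blocks:
#'
#' ```yaml
#' template: GCAACT...
#' pbs5: [0, 20]
#' pbs3: [76, 96]
#' analysis: [20, 76]
#' watermark5: {start: 2, from: AA, to: TT}
#' watermark3: {start: 80, from: TT, to: AA}
#' ```
#'
#' All `assay_design` invariants are checked; a violation raises an error
#' naming the offending field.
#'
#' @param path Path to a YAML file.
#' @return An [assay_design()].
#' @export
load_design <- function(path) {
  if (!file.exists(path)) stop("design config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  need <- c("template", "pbs5", "pbs3", "analysis", "watermark5", "watermark3")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("design config missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  wm <- function(block, field) {
    if (!all(c("start", "from", "to") %in% names(block)))
      stop(field, ": needs start, from, to", call. = FALSE)
    watermark_spec(block$start, block$from, block$to)
  }
  assay_design(
    template = cfg$template,
    pbs5 = unlist(cfg$pbs5), pbs3 = unlist(cfg$pbs3),
    analysis = unlist(cfg$analysis),
    watermark5 = wm(cfg$watermark5, "watermark5"),
    watermark3 = wm(cfg$watermark3, "watermark3")
  )
}

#' Bundled stand-in assay design
#'
#' The assay's real primer sequences are not published, so the package ships
#' a structurally equivalent synthetic design: a 96-nt template made of a
#' 20-nt 5' PBS carrying the AA->TT watermark at PBS positions 2-3, a 56-nt
#' analysis region with uniform base composition (14 of each base), and a
#' 20-nt 3' PBS carrying the TT->AA watermark. Real designs are supplied via
#' [load_design()].
#'
#' @return An [assay_design()].
#' @export
default_design <- function() {
  pbs5 <- "GCAACTGGTACGTCAGATCG"
  analysis <- "CGGTGCGCTGTTCTATTCCCTTATGATGGATCTGACGGAAACACGATCAGACAGCA"
  pbs3 <- "GATCTTGCAGCATGCACGTC"
  assay_design(
    template = paste0(pbs5, analysis, pbs3),
    pbs5 = c(0L, 20L), analysis = c(20L, 76L), pbs3 = c(76L, 96L),
    watermark5 = watermark_spec(2L, "AA", "TT"),
    watermark3 = watermark_spec(80L, "TT", "AA")
  )
}

# Template with both watermarks set to their converted state: the sequence a
# perfect (error-free) genuine replication product reads.
converted_template <- function(design) {
  tpl <- design$template
  for (wm in list(design$watermark5, design$watermark3))
    substr(tpl, wm$start + 1L, wm$start + 2L) <- wm$to
  tpl
}
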