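#' Simulate one clone sequence from the assay design
#'
#' A genuine clone is the template with both watermarks set to their
#' converted state — watermark positions are dictated by primer synthesis,
#' not polymerization, so they are exempt from the error model — and with
#' per-site errors drawn independently at every analysis-region position:
#' deletion with probability `del_rate`, otherwise a base drawn from the
#' substitution matrix row of the template base, plus (independently) a
#' single uniform-random inserted base after the position with probability
#' `ins_rate`. A contaminant clone is an exact copy of the starting template
#' (watermarks unconverted, no errors), emulating template carryover.
#'
#' At most one of substitution/deletion occurs per template position and
#' insertions are single-base, so planted events have unambiguous template
#' coordinates (0-based).
#'
#' @param design An [assay_design()].
#' @param model An [error_model()].
#' @param id Clone identifier recorded in the output.
#' @param contaminant If `TRUE`, emit a template-carryover contaminant.
#' @param seed Optional integer; when given, draws come from a private
#'   `set.seed(seed)` stream so clones are reproducible individually.
#' @return A list with `record` (one-row `clone_records`) and `events`
#'   (data.frame of planted mutations: `clone_id`, `kind`, `template_pos`,
#'   `from_base`, `to_base`, `length`).
#' @export
simulate_clone <- function(design, model, id = "clone", contaminant = FALSE,
                           seed = NULL) {
  stopifnot(inherits(design, "assay_design"), inherits(model, "error_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (contaminant) {
    return(list(
      record = clone_records(id, design$template, "synthetic_contaminant"),
      events = empty_events()
    ))
  }
  chars <- strsplit(converted_template(design), "")[[1]]
  a0 <- design$analysis[1]; a1 <- design$analysis[2]
  pos <- seq.int(a0, a1 - 1L)               # 0-based analysis positions
  L <- length(pos)
  src <- chars[pos + 1L]
  src_idx <- match(src, BASES)

  deleted <- runif(L) < model$del_rate
  # substitution draw happens for every site (stream stability); ignored at
  # deleted sites — deletion and substitution are exclusive per position
  cum <- t(apply(model$sub_matrix, 1, cumsum))
  u <- runif(L)
  new_idx <- rowSums(u > cum[src_idx, , drop = FALSE]) + 1L
  new_base <- BASES[new_idx]
  substituted <- !deleted & new_base != src

  inserted <- runif(L) < model$ins_rate
  ins_base <- BASES[floor(runif(L) * 4) + 1L]

  events <- rbind(
    if (any(substituted)) data.frame(
      clone_id = id, kind = "substitution", template_pos = pos[substituted],
      from_base = src[substituted], to_base = new_base[substituted],
      length = 1L, stringsAsFactors = FALSE),
    if (any(deleted)) data.frame(
      clone_id = id, kind = "deletion", template_pos = pos[deleted],
      from_base = src[deleted], to_base = "", length = 1L,
      stringsAsFactors = FALSE),
    if (any(inserted)) data.frame(
      clone_id = id, kind = "insertion", template_pos = pos[inserted],
      from_base = "", to_base = ins_base[inserted], length = 1L,
      stringsAsFactors = FALSE)
  )
  if (is.null(events)) events <- empty_events()
  events <- events[order(events$template_pos, events$kind), , drop = FALSE]
  rownames(events) <- NULL

  out <- chars
  out[pos[substituted] + 1L] <- new_base[substituted]
  out[pos[deleted] + 1L] <- ""
  ins_at <- pos[inserted]
  out[ins_at + 1L] <- paste0(out[ins_at + 1L], ins_base[inserted])
  seq <- paste(out, collapse = "")

  list(record = clone_records(id, seq, "synthetic_genuine"), events = events)
}

empty_events <- function() {
  data.frame(clone_id = character(), kind = character(),
             template_pos = integer(), from_base = character(),
             to_base = character(), length = integer(),
             stringsAsFactors = FALSE)
}

# Per-clone RNG sub-stream: mixes the dataset seed with the clone index so a
# subset of clones regenerates identically regardless of dataset size.
clone_seed <- function(seed, index) {
  as.integer((as.numeric(seed %% 1000003L) * 2039 + as.numeric(index) * 7919) %%
               2147483629)
}

#' Simulate a clone dataset with ground truth
#'
#' Generates `n` clones: `ceiling(contaminant_fraction * n)` are exact
#' template copies retaining the unconverted (template-state) watermarks —
#' the signature of carried-over template DNA a no-RT control is designed to
#' expose — and the rest are genuine replication products drawn from the
#' error model. Each clone is independently emitted reverse-complemented
#' with probability `flip_fraction` (cloning orientation is random). Output
#' is fully determined by `seed`; each clone draws from a sub-stream keyed by
#' `(seed, clone index)`.
#'
#' @param design An [assay_design()].
#' @param model An [error_model()].
#' @param n Number of clones (>= 1).
#' @param contaminant_fraction,flip_fraction Fractions in \[0,1\].
#' @param seed Integer seed (mandatory: datasets must be reproducible).
#' @return A list of class `sim_dataset` with `records` (a `clone_records`
#'   data.frame), `truth` (planted-event table with clone source labels) and
#'   `params` (generator parameters incl. the seed).
#' @examples
#' ds <- simulate_dataset(default_design(), uniform_model(0.01), n = 5, seed = 1)
#' table(ds$records$source)
#' @export
simulate_dataset <- function(design, model, n, contaminant_fraction = 0,
                             flip_fraction = 0, seed) {
  stopifnot(inherits(design, "assay_design"), inherits(model, "error_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (contaminant_fraction < 0 || contaminant_fraction > 1 ||
      flip_fraction < 0 || flip_fraction > 1)
    stop("fractions must be in [0,1]", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("seed is required", call. = FALSE)
  seed <- as.integer(seed)

  n_contam <- as.integer(ceiling(contaminant_fraction * n))
  ids <- sprintf("clone_%05d", seq_len(n))
  recs <- vector("list", n)
  evts <- vector("list", n)
  flipped <- logical(n)
  for (i in seq_len(n)) {
    set.seed(clone_seed(seed, i))
    sim <- simulate_clone(design, model, id = ids[i],
                          contaminant = i <= n_contam, seed = NULL)
    flipped[i] <- runif(1) < flip_fraction
    if (flipped[i]) sim$record$sequence <- revcomp(sim$record$sequence)
    recs[[i]] <- sim$record
    evts[[i]] <- sim$events
  }
  records <- do.call(rbind, recs)
  class(records) <- c("clone_records", "data.frame")
  truth <- do.call(rbind, evts)
  rownames(truth) <- NULL
  structure(list(
    records = records,
    truth = truth,
    params = list(n = n, contaminant_fraction = contaminant_fraction,
                  flip_fraction = flip_fraction, seed = seed,
                  n_contaminant = n_contam, flipped = flipped,
                  sub_matrix = model$sub_matrix,
                  ins_rate = model$ins_rate, del_rate = model$del_rate)
  ), class = "sim_dataset")
}

#' Write a simulated dataset to disk
#'
#' Writes the clone FASTA, a TSV truth table (`clone_id`, `source`,
#' `event_kind`, `template_pos`, `from_base`, `to_base`, `length`) and a JSON
#' sidecar with all generator parameters and the seed.
#'
#' @param dataset A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "clones.fasta")
  truth <- file.path(dir, "truth.tsv")
  params <- file.path(dir, "params.json")
  write_fasta(dataset$records, fasta)
  tt <- merge(dataset$records[, c("id", "source")], dataset$truth,
              by.x = "id", by.y = "clone_id", all.x = TRUE)
  names(tt) <- c("clone_id", "source", "event_kind", "template_pos",
                 "from_base", "to_base", "length")
  tt <- tt[order(tt$clone_id, tt$template_pos), ]
  write.table(tt, truth, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  p <- dataset$params
  p$flipped <- NULL
  p$sub_matrix <- as.vector(p$sub_matrix)
  jsonlite::write_json(p, params, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, truth = truth, params = params))
}
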