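#' Run the full fidelity pipeline on a set of clones
#'
#' Executes, per clone: orientation (forward vs reverse-complement), global
#' affine-gap alignment to the template, indel left-normalization, the
#' alignment-identity filter, the watermark filter, and mutation calling;
#' then tallies the mutation spectrum over passing clones and computes the
#' fidelity report. Failure of an individual clone never aborts the run —
#' every exclusion is tallied with its reason in the watermark table.
#'
#' @param design An [assay_design()].
#' @param records A `clone_records` data.frame ([read_fasta()],
#'   [simulate_dataset()]`$records`); alternatively give `fasta`.
#' @param fasta Path to a clone FASTA, read with [read_fasta()].
#' @param scoring A [scoring_scheme()].
#' @param identity_threshold Clones whose alignment identity falls below
#'   this are excluded as failed sequencing reads (default 0.7) and tallied
#'   under `low_identity`.
#' @param level Confidence level for per-type rate intervals.
#' @param outdir If given, artifact files are written there: `events.tsv`,
#'   `watermarks.tsv`, `spectrum.tsv`, `report.json` (timestamp-free, so
#'   identical runs are byte-identical), and `log.txt`.
#' @param verbose Emit one progress message per pipeline stage.
#' @return A list of class `fidelity_run`: `report` (a `fidelity_report`),
#'   `spectrum`, `events`, `watermarks`, `counts` (clones in/out at each
#'   stage).
#' @section Errors:
#' If no clone passes the watermark filter the run stops with a classed
#' error (`xnafid_no_passing_clones`): "no watermark-validated sequences".
#' Fewer than 1000 analyzed positions is a warning flag in the report, not
#' an error.
#' @export
run_pipeline <- function(design, records = NULL, fasta = NULL,
                         scoring = scoring_scheme(),
                         identity_threshold = 0.7, level = 0.95,
                         outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(design, "assay_design"))
  if (is.null(records)) {
    if (is.null(fasta)) stop("give either records or fasta", call. = FALSE)
    records <- read_fasta(fasta)
  }
  say <- function(...) if (verbose) message(...)
  n <- nrow(records)
  say("read: ", n, " clones")

  wm_rows <- vector("list", n)
  events <- vector("list", n)
  alignments <- list()
  n_reverse <- 0L; n_low_identity <- 0L

  for (i in seq_len(n)) {
    ori <- orient_clone(records$sequence[i], design$template, scoring)
    if (ori$strand == "reverse") n_reverse <- n_reverse + 1L
    aln <- left_normalize_indels(ori$alignment)
    if (aln$identity < identity_threshold) {
      n_low_identity <- n_low_identity + 1L
      wm_rows[[i]] <- data.frame(
        clone_id = records$id[i], observed5 = "", observed3 = "",
        passed = FALSE, failure_reason = "low_identity",
        stringsAsFactors = FALSE)
      next
    }
    wm <- check_watermarks(aln, design, records$id[i])
    wm_rows[[i]] <- wm
    if (wm$passed) {
      alignments[[records$id[i]]] <- aln
      events[[i]] <- call_mutations(aln, design, records$id[i])
    }
  }
  watermarks <- do.call(rbind, wm_rows)
  rownames(watermarks) <- NULL
  n_passed <- sum(watermarks$passed)
  say("oriented: ", n_reverse, " reverse-complemented")
  say("identity filter: ", n_low_identity, " excluded")
  say("watermark filter: ", n_passed, " of ", n, " clones passed")

  if (n_passed == 0) {
    cond <- structure(
      class = c("xnafid_no_passing_clones", "error", "condition"),
      list(message = "no watermark-validated sequences", call = NULL))
    stop(cond)
  }

  events <- do.call(rbind, events)
  if (is.null(events)) events <- empty_events()
  say("events called: ", nrow(events))

  spectrum <- build_spectrum(events, alignments, design,
                             n_clones_failed = n - n_passed)
  report <- summarize_fidelity(spectrum, level = level)
  if (report$low_coverage)
    warning("fewer than 1000 analyzed positions; rates are low-coverage",
            call. = FALSE)

  counts <- list(n_read = n, n_reverse = n_reverse,
                 n_low_identity = n_low_identity,
                 n_watermark_failed = n - n_low_identity - n_passed,
                 n_passed = n_passed, n_events = nrow(events))
  run <- structure(list(report = report, spectrum = spectrum,
                        events = events, watermarks = watermarks,
                        counts = counts,
                        params = list(identity_threshold = identity_threshold,
                                      scoring = unclass(scoring),
                                      level = level)),
                   class = "fidelity_run")
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' @export
print.fidelity_run <- function(x, ...) {
  cat("fidelity_run: ", x$counts$n_read, " clones -> ",
      x$counts$n_passed, " watermark-validated (",
      x$counts$n_low_identity, " low-identity, ",
      x$counts$n_watermark_failed, " watermark-failed)\n", sep = "")
  print(x$report)
  invisible(x)
}

# Fig. 4-style spectrum layout: one row per substitution type plus
# insertion/deletion rows with their per-1000 rates.
spectrum_tsv_table <- function(run) {
  r <- run$report$rates
  sub <- data.frame(type = paste0(r$from, ">", r$to), observed = r$observed,
                    expected = r$expected, mu = r$mu,
                    stringsAsFactors = FALSE)
  tot <- run$spectrum$total_positions
  indel <- data.frame(
    type = c("insertion", "deletion"),
    observed = c(run$spectrum$ins_count, run$spectrum$del_count),
    expected = tot,
    mu = c(run$spectrum$ins_count, run$spectrum$del_count) / tot * 1000,
    stringsAsFactors = FALSE)
  rbind(sub, indel)
}

write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name)
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  tsv(run$events, "events.tsv")
  tsv(run$watermarks, "watermarks.tsv")
  tsv(spectrum_tsv_table(run), "spectrum.tsv")

  rep <- run$report
  json <- list(
    aggregate_fidelity_pct = rep$aggregate_fidelity_pct,
    aggregate_fidelity_rounded = rep$aggregate_fidelity_rounded,
    mu_total = rep$mu_total,
    indel_rate = rep$indel_rate,
    aggregate_errors = rep$aggregate_errors,
    total_positions = rep$total_positions,
    low_coverage = rep$low_coverage,
    n_clones_passed = rep$n_clones_passed,
    n_clones_failed = rep$n_clones_failed,
    ins_count = rep$ins_count,
    del_count = rep$del_count,
    rates = rep$rates,
    counts = run$counts,
    params = run$params
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(
    paste0("xnafidelity ", as.character(utils::packageVersion("xnafidelity"))),
    paste0("time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("clones_read: ", run$counts$n_read),
    paste0("reverse_oriented: ", run$counts$n_reverse),
    paste0("low_identity_excluded: ", run$counts$n_low_identity),
    paste0("watermark_failed: ", run$counts$n_watermark_failed),
    paste0("watermark_passed: ", run$counts$n_passed),
    paste0("events_called: ", run$counts$n_events)
  )
  writeLines(log, file.path(outdir, "log.txt"))
  invisible(outdir)
}
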