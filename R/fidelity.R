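#' Per-1000 error rate
#'
#' The assay's rate statistic: `mu = (#observed / #expected) * 1000`,
#' mutations of one substitution type per 1000 opportunities. With no
#' opportunities the rate is not estimable and an error is raised — it is
#' never reported as 0.
#'
#' @param observed_count Events observed (0 <= observed <= expected).
#' @param expected_count Opportunities (> 0).
#' @return The rate per 1000 as a double.
#' @examples
#' error_rate(2, 1000)  # 2.0
#' @export
error_rate <- function(observed_count, expected_count) {
  if (expected_count <= 0)
    stop("error rate not estimable: expected_count is 0", call. = FALSE)
  if (observed_count < 0 || observed_count > expected_count)
    stop("observed_count must be in [0, expected_count]", call. = FALSE)
  (observed_count / expected_count) * 1000
}

#' Exact Poisson (Garwood) interval for a per-1000 rate
#'
#' Confidence interval on the event count treated as Poisson, scaled to the
#' per-1000 rate. The lower bound is 0 when no events were observed.
#'
#' @param observed_count Events observed (>= 0).
#' @param expected_count Opportunities (> 0).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(low, high)` per 1000.
#' @export
rate_interval <- function(observed_count, expected_count, level = 0.95) {
  if (expected_count <= 0)
    stop("interval not estimable: expected_count is 0", call. = FALSE)
  if (length(level) != 1 || is.na(level) || level <= 0 || level >= 1)
    stop("level must be in (0,1)", call. = FALSE)
  alpha <- 1 - level
  low <- if (observed_count == 0) 0 else qgamma(alpha / 2, observed_count)
  high <- qgamma(1 - alpha / 2, observed_count + 1)
  c(low = low * 1000 / expected_count, high = high * 1000 / expected_count)
}

#' Tally the mutation spectrum over watermark-validated clones
#'
#' Builds the 12-substitution-type observed/expected table behind the
#' fidelity report. `expected[X]` counts analyzed template positions carrying
#' base X across passing clones, where "analyzed" excludes positions aligned
#' to N and deleted positions (neither offers a substitution observation).
#' Insertion/deletion events contribute their base counts to `ins_count` /
#' `del_count`.
#'
#' @param events Combined [call_mutations()] table from passing clones only.
#' @param alignments List of the same clones' left-normalized alignments.
#' @param design An [assay_design()].
#' @param n_clones_failed Number of clones excluded upstream (identity or
#'   watermark filter), carried into the report metadata.
#' @return An object of class `spectrum_table`: `observed` (4x4 matrix,
#'   from-base rows), `expected` (named length-4 vector), `ins_count`,
#'   `del_count`, `total_positions`, `n_clones_passed`, `n_clones_failed`.
#' @export
build_spectrum <- function(events, alignments, design, n_clones_failed = 0L) {
  stopifnot(inherits(design, "assay_design"))
  a0 <- design$analysis[1]; a1 <- design$analysis[2]
  if (nrow(events) > 0 &&
      any(events$template_pos < a0 | events$template_pos >= a1))
    stop("event outside the analysis span: internal consistency error",
         call. = FALSE)

  tpl <- strsplit(span_seq(design$template, design$analysis), "")[[1]]
  expected <- stats::setNames(numeric(4), BASES)
  for (aln in alignments) {
    prof <- span_profile(aln, design)
    analyzed <- prof %in% c(BASES)          # excludes "-" and "N"
    expected <- expected + table(factor(tpl[analyzed], levels = BASES))
  }

  observed <- matrix(0, 4, 4, dimnames = list(from = BASES, to = BASES))
  subs <- events[events$kind == "substitution", , drop = FALSE]
  if (nrow(subs))
    for (i in seq_len(nrow(subs)))
      observed[subs$from_base[i], subs$to_base[i]] <-
        observed[subs$from_base[i], subs$to_base[i]] + 1

  structure(list(
    observed = observed,
    expected = c(expected),
    ins_count = sum(events$length[events$kind == "insertion"]),
    del_count = sum(events$length[events$kind == "deletion"]),
    total_positions = sum(expected),
    n_clones_passed = length(alignments),
    n_clones_failed = as.integer(n_clones_failed)
  ), class = "spectrum_table")
}

#' Fidelity report: per-type rates, total error rate, aggregate fidelity
#'
#' For each of the 12 substitution types, `mu = (#observed / #expected[from
#' base]) * 1000`; the total error rate is the sum of the 12 substitution
#' rates. The aggregate fidelity score counts substitutions *and* indel
#' bases: `(1 - (substitutions + inserted + deleted bases) / analyzed
#' positions) * 100`, reported both at full precision and rounded to one
#' decimal (round-half-even). Reports resting on fewer than 1000 analyzed
#' positions are flagged as low-coverage.
#'
#' @param spectrum A [build_spectrum()] result.
#' @param level Confidence level for the per-type Poisson intervals.
#' @return An object of class `fidelity_report`: `rates` (data.frame with
#'   `from`, `to`, `observed`, `expected`, `mu`, `ci_low`, `ci_high`),
#'   `mu_total`, `indel_rate`, `aggregate_errors`, `aggregate_fidelity_pct`,
#'   `aggregate_fidelity_rounded`, `low_coverage`, and the clone tallies.
#' @export
summarize_fidelity <- function(spectrum, level = 0.95) {
  stopifnot(inherits(spectrum, "spectrum_table"))
  if (spectrum$total_positions < 1)
    stop("no analyzed positions: cannot summarize fidelity", call. = FALSE)

  types <- expand.grid(to = BASES, from = BASES, stringsAsFactors = FALSE)
  types <- types[types$from != types$to, c("from", "to")]
  rates <- do.call(rbind, lapply(seq_len(nrow(types)), function(i) {
    fr <- types$from[i]; to <- types$to[i]
    obs <- unname(spectrum$observed[fr, to])
    exp <- unname(spectrum$expected[fr])
    if (exp > 0) {
      ci <- rate_interval(obs, exp, level)
      data.frame(from = fr, to = to, observed = obs, expected = exp,
                 mu = error_rate(obs, exp), ci_low = ci[["low"]],
                 ci_high = ci[["high"]], stringsAsFactors = FALSE)
    } else {
      data.frame(from = fr, to = to, observed = obs, expected = 0,
                 mu = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(rates) <- NULL

  agg_errors <- sum(spectrum$observed) + spectrum$ins_count + spectrum$del_count
  fidelity <- (1 - agg_errors / spectrum$total_positions) * 100
  structure(list(
    rates = rates,
    mu_total = sum(rates$mu, na.rm = TRUE),
    indel_rate = (spectrum$ins_count + spectrum$del_count) /
      spectrum$total_positions * 1000,
    aggregate_errors = agg_errors,
    aggregate_fidelity_pct = fidelity,
    aggregate_fidelity_rounded = round(fidelity, 1),
    low_coverage = spectrum$total_positions < 1000,
    total_positions = spectrum$total_positions,
    n_clones_passed = spectrum$n_clones_passed,
    n_clones_failed = spectrum$n_clones_failed,
    ins_count = spectrum$ins_count,
    del_count = spectrum$del_count
  ), class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("fidelity_report:", x$n_clones_passed, "clones passed,",
      x$n_clones_failed, "excluded;", x$total_positions,
      "positions analyzed\n")
  cat("  total substitution error rate:",
      format(x$mu_total, digits = 4), "per 1000\n")
  cat("  indel rate:", format(x$indel_rate, digits = 4), "per 1000\n")
  cat("  aggregate fidelity:",
      sprintf("%.1f%%", x$aggregate_fidelity_rounded), "\n")
  if (x$low_coverage)
    cat("  WARNING: fewer than 1000 analyzed positions\n")
  invisible(x)
}
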