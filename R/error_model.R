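#' Per-site replication error model
#'
#' Describes the error process of one (or several composed) polymerization
#' steps: a 4x4 row-stochastic base-transition matrix (rows = template base
#' A,C,G,T; the diagonal is the no-change probability) plus per-site
#' single-base insertion and deletion probabilities. The assay's observed
#' errors are the composite of XNA transcription and reverse transcription
#' (and PCR background); the paper-style uncorrected totals correspond to a
#' single composite model built with [compose_models()].
#'
#' @param sub_matrix 4x4 numeric matrix with rows/cols in order A,C,G,T; each
#'   row must sum to 1 (tolerance 1e-12) with entries in \[0,1\].
#' @param ins_rate,del_rate Per-site insertion/deletion probabilities;
#'   `ins_rate + del_rate` must not exceed 1 (deletion and substitution are
#'   mutually exclusive per site in the simulator).
#' @return An object of class `error_model`.
#' @seealso [uniform_model()], [compose_models()]
#' @export
error_model <- function(sub_matrix, ins_rate = 0, del_rate = 0) {
  sub_matrix <- as.matrix(sub_matrix)
  if (!identical(dim(sub_matrix), c(4L, 4L)))
    stop("sub_matrix must be 4x4", call. = FALSE)
  dimnames(sub_matrix) <- list(BASES, BASES)
  if (any(sub_matrix < 0 | sub_matrix > 1))
    stop("sub_matrix entries must be in [0,1]", call. = FALSE)
  if (any(abs(rowSums(sub_matrix) - 1) > 1e-12))
    stop("sub_matrix rows must each sum to 1", call. = FALSE)
  ins_rate <- as.numeric(ins_rate); del_rate <- as.numeric(del_rate)
  if (ins_rate < 0 || ins_rate > 1 || del_rate < 0 || del_rate > 1)
    stop("indel rates must be in [0,1]", call. = FALSE)
  if (ins_rate + del_rate > 1)
    stop("ins_rate + del_rate must be <= 1", call. = FALSE)
  structure(list(sub_matrix = sub_matrix, ins_rate = ins_rate,
                 del_rate = del_rate),
            class = "error_model")
}

#' Uniform substitution error model
#'
#' Convenience constructor: every base missubstitutes with total probability
#' `p_sub`, split evenly over the three alternative bases.
#'
#' @param p_sub Total per-site substitution probability, in \[0,1).
#' @param ins_rate,del_rate Per-site indel probabilities.
#' @return An [error_model()].
#' @examples
#' m <- uniform_model(0.021)
#' m$sub_matrix["A", ]  # diagonal 0.979, off-diagonals 0.007
#' @export
uniform_model <- function(p_sub, ins_rate = 0, del_rate = 0) {
  if (p_sub < 0 || p_sub >= 1) stop("p_sub must be in [0,1)", call. = FALSE)
  m <- matrix(p_sub / 3, 4, 4)
  diag(m) <- 1 - p_sub
  error_model(m, ins_rate = ins_rate, del_rate = del_rate)
}

#' Compose two sequential error models
#'
#' Models the two-step replication cycle: errors of the first step (DNA ->
#' XNA transcription) are compounded by the second (XNA -> DNA reverse
#' transcription). The substitution matrices multiply —
#' `combined[a,b] = sum_x first[a,x] * second[x,b]` — and the indel rates
#' combine as `1 - (1 - r1)(1 - r2)` (an indel survives unless neither step
#' introduces one).
#'
#' @param first,second [error_model()]s, applied in that order.
#' @return The composite [error_model()].
#' @export
compose_models <- function(first, second) {
  stopifnot(inherits(first, "error_model"), inherits(second, "error_model"))
  error_model(first$sub_matrix %*% second$sub_matrix,
              ins_rate = 1 - (1 - first$ins_rate) * (1 - second$ins_rate),
              del_rate = 1 - (1 - first$del_rate) * (1 - second$del_rate))
}

#' @export
print.error_model <- function(x, ...) {
  cat("error_model: mean p_sub =",
      format(mean(1 - diag(x$sub_matrix)), digits = 4),
      " ins =", format(x$ins_rate, digits = 4),
      " del =", format(x$del_rate, digits = 4), "\n")
  print(round(x$sub_matrix, 6))
  invisible(x)
}
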