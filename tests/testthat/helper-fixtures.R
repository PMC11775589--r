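# Small fixtures built in code: a 28-nt design for fast unit tests and a
# helper producing the error-free genuine clone sequence for a design.

tiny_design <- function() {
  assay_design(
    template = paste0("GCAACTGA", "ACGTTGCAGTCA", "TGTTGCAC"),
    pbs5 = c(0L, 8L), analysis = c(8L, 20L), pbs3 = c(20L, 28L),
    watermark5 = watermark_spec(2L, "AA", "TT"),
    watermark3 = watermark_spec(22L, "TT", "AA")
  )
}

# Error-free genuine replication product: template with converted watermarks.
genuine_sequence <- function(design) {
  simulate_clone(design, uniform_model(0), seed = 1)$record$sequence
}

# A valid design config as a plain list, for perturbation in tests.
valid_config <- function() {
  list(template = paste0("GCAACTGA", "ACGTTGCAGTCA", "TGTTGCAC"),
       pbs5 = c(0L, 8L), pbs3 = c(20L, 28L), analysis = c(8L, 20L),
       watermark5 = list(start = 2L, from = "AA", to = "TT"),
       watermark3 = list(start = 22L, from = "TT", to = "AA"))
}

write_config <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
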