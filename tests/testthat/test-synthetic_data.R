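test_that("uniform_model builds the expected transition matrix", {
  expect_equal(uniform_model(0)$sub_matrix, diag(4),
               ignore_attr = TRUE)
  m <- uniform_model(0.021)$sub_matrix
  expect_equal(unname(diag(m)), rep(0.979, 4))
  expect_equal(unname(m[upper.tri(m) | lower.tri(m)]), rep(0.007, 12))
  set.seed(3)
  for (p in runif(10)) {
    expect_equal(unname(rowSums(uniform_model(p * 0.99)$sub_matrix)),
                 rep(1, 4))
  }
  expect_error(uniform_model(1), "p_sub")
  expect_error(error_model(diag(4), ins_rate = 0.6, del_rate = 0.6), "<= 1")
})

test_that("compose_models matches the exhaustive 4-term sum and identity law", {
  m1 <- uniform_model(0.01, ins_rate = 0.002, del_rate = 0.001)
  m2 <- uniform_model(0.02, ins_rate = 0.003, del_rate = 0.004)
  comp <- compose_models(m1, m2)

  bases <- c("A", "C", "G", "T")
  for (a in bases) for (b in bases) {
    # independent oracle: enumerate the 4 intermediate bases by brute force
    expect_equal(comp$sub_matrix[a, b],
                 sum(vapply(bases, function(x)
                   m1$sub_matrix[a, x] * m2$sub_matrix[x, b], 0)))
  }
  expect_equal(comp$ins_rate, 1 - (1 - 0.002) * (1 - 0.003))
  expect_equal(comp$del_rate, 1 - (1 - 0.001) * (1 - 0.004))
  expect_equal(unname(rowSums(comp$sub_matrix)), rep(1, 4))

  ident <- uniform_model(0)
  expect_equal(compose_models(m1, ident)$sub_matrix, m1$sub_matrix)
})

test_that("an error-free model yields the converted template and no events", {
  d <- tiny_design()
  sim <- simulate_clone(d, uniform_model(0), seed = 5)
  expect_identical(nrow(sim$events), 0L)
  seq <- sim$record$sequence
  # watermarks converted, everything else identical to the template
  expect_identical(substr(seq, 3, 4), "TT")
  expect_identical(substr(seq, 23, 24), "AA")
  tpl <- d$template
  substr(tpl, 3, 4) <- "TT"; substr(tpl, 23, 24) <- "AA"
  expect_identical(seq, tpl)
})

test_that("del_rate = 1 deletes the whole analysis span", {
  d <- tiny_design()  # 12-nt analysis span
  sim <- simulate_clone(d, uniform_model(0, del_rate = 1), seed = 5)
  expect_identical(sum(sim$events$kind == "deletion"), 12L)
  expect_identical(nchar(sim$record$sequence), 28L - 12L)
})

test_that("planted substitution counts follow the binomial oracle", {
  d <- default_design()
  n <- 200; L <- 56; p <- 0.1
  ds <- simulate_dataset(d, uniform_model(p), n = n, seed = 21)
  k <- sum(ds$truth$kind == "substitution")
  expect_lt(abs(k - n * L * p), 3 * sqrt(n * L * p * (1 - p)))
})

test_that("datasets are deterministic in seed and stable under subsetting", {
  d <- tiny_design()
  m <- uniform_model(0.05, ins_rate = 0.01, del_rate = 0.01)
  a <- simulate_dataset(d, m, n = 30, flip_fraction = 0.5, seed = 9)
  b <- simulate_dataset(d, m, n = 30, flip_fraction = 0.5, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)

  fa <- tempfile(); fb <- tempfile()
  write_fasta(a$records, fa); write_fasta(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))

  different <- simulate_dataset(d, m, n = 30, flip_fraction = 0.5, seed = 10)
  expect_false(identical(a$records$sequence, different$records$sequence))

  # per-clone streams keyed by (seed, index): a larger run reproduces the
  # smaller run's clones exactly
  big <- simulate_dataset(d, m, n = 60, flip_fraction = 0.5, seed = 9)
  expect_identical(big$records$sequence[1:30], a$records$sequence)
})

test_that("contaminant clones retain the template-state watermarks exactly", {
  d <- tiny_design()
  ds <- simulate_dataset(d, uniform_model(0.1), n = 10,
                         contaminant_fraction = 0.5, seed = 4)
  contam <- ds$records[ds$records$source == "synthetic_contaminant", ]
  expect_identical(nrow(contam), 5L)
  expect_true(all(contam$sequence == d$template))
  expect_false(any(ds$truth$clone_id %in% contam$id))
  expect_error(simulate_dataset(d, uniform_model(0.1), n = 10,
                                contaminant_fraction = 1.5, seed = 1),
               "fraction")
  expect_error(simulate_dataset(d, uniform_model(0.1), n = 10), "seed")
})

test_that("per-clone mass is conserved: subs + deletions + unchanged = span", {
  d <- tiny_design()
  L <- d$analysis[2] - d$analysis[1]
  ds <- simulate_dataset(d, uniform_model(0.2, ins_rate = 0.05,
                                          del_rate = 0.1),
                         n = 40, seed = 31)
  for (id in unique(ds$records$id)) {
    ev <- ds$truth[ds$truth$clone_id == id, ]
    n_sub <- sum(ev$kind == "substitution")
    n_del <- sum(ev$kind == "deletion")
    expect_lte(n_sub + n_del, L)
    # sequence length bookkeeping: template length - deletions + insertions
    n_ins <- sum(ev$kind == "insertion")
    expect_identical(nchar(ds$records$sequence[ds$records$id == id]),
                     28L - n_del + n_ins)
  }
})

test_that("composed model and two sequential passes are indistinguishable", {
  d <- default_design()
  m1 <- uniform_model(0.05)
  m2 <- uniform_model(0.08)
  n <- 100  # 100 clones x 56 nt = 5600 sites per arm

  # arm 1: the package's generator under the composed model
  ds <- simulate_dataset(d, compose_models(m1, m2), n = n, seed = 41)
  tpl <- strsplit(d$template, "")[[1]]
  arm1 <- table(factor(paste0(
    ds$truth$from_base[ds$truth$kind == "substitution"], ">",
    ds$truth$to_base[ds$truth$kind == "substitution"]),
    levels = sub_type_levels <- apply(
      expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1,
      function(r) paste0(r[1], ">", r[2]))))
  sites1 <- n * 56

  # arm 2: independent two-pass site-level sampler
  set.seed(42)
  a0 <- d$analysis[1]; a1 <- d$analysis[2]
  src <- rep(tpl[(a0 + 1):a1], n)
  pass <- function(bases, model) {
    cum <- t(apply(model$sub_matrix, 1, cumsum))
    idx <- match(bases, c("A","C","G","T"))
    u <- runif(length(bases))
    c("A","C","G","T")[rowSums(u > cum[idx, , drop = FALSE]) + 1L]
  }
  final <- pass(pass(src, m1), m2)
  changed <- final != src
  arm2 <- table(factor(paste0(src[changed], ">", final[changed]),
                       levels = sub_type_levels))

  counts <- rbind(
    c(as.vector(arm1), sites1 - sum(arm1)),
    c(as.vector(arm2), length(src) - sum(arm2)))
  counts <- counts[, colSums(counts) > 0]
  expect_gt(chisq.test(counts)$p.value, 0.01)
})
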