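aligned_to <- function(design, seq) {
  left_normalize_indels(align_global(design$template, seq))
}

test_that("watermark filter classifies genuine, contaminant, and partial clones", {
  d <- tiny_design()
  genuine <- genuine_sequence(d)

  wm <- check_watermarks(aligned_to(d, genuine), d, "g")
  expect_true(wm$passed)
  expect_identical(wm$failure_reason, "none")
  expect_identical(wm$observed5, "TT")
  expect_identical(wm$observed3, "AA")

  wm <- check_watermarks(aligned_to(d, d$template), d, "c")
  expect_false(wm$passed)
  expect_identical(wm$failure_reason, "both_unconverted")

  # 5' converted, 3' still template state
  half <- genuine
  substr(half, 23, 24) <- "TT"
  wm <- check_watermarks(aligned_to(d, half), d, "h")
  expect_false(wm$passed)
  expect_identical(wm$failure_reason, "watermark3_unconverted")

  # a deletion spanning a watermark base makes conversion unverifiable
  gapped <- paste0(substr(genuine, 1, 2), substr(genuine, 4, nchar(genuine)))
  wm <- check_watermarks(aligned_to(d, gapped), d, "gap")
  expect_false(wm$passed)
  expect_identical(wm$failure_reason, "gap_in_watermark")
})

test_that("an error-free clone yields no mutation events", {
  d <- tiny_design()
  ev <- call_mutations(aligned_to(d, genuine_sequence(d)), d, "g")
  expect_identical(nrow(ev), 0L)
})

test_that("a planted substitution is called at its position with its bases", {
  d <- default_design()
  g <- genuine_sequence(d)
  # analysis span starts at 20; its third base (template pos 22) is G
  expect_identical(substr(d$template, 23, 23), "G")
  mutant <- g
  substr(mutant, 23, 23) <- "A"
  ev <- call_mutations(aligned_to(d, mutant), d, "m")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$kind, "substitution")
  expect_identical(ev$template_pos, 22L)
  expect_identical(ev$from_base, "G")
  expect_identical(ev$to_base, "A")
})

test_that("errors outside the analysis span are never counted", {
  d <- default_design()
  g <- genuine_sequence(d)
  mutant <- g
  substr(mutant, 10, 10) <- "A"   # inside pbs5, pos 9
  substr(mutant, 90, 90) <- "A"   # inside pbs3, pos 89
  ev <- call_mutations(aligned_to(d, mutant), d, "m")
  expect_identical(nrow(ev), 0L)
})

test_that("N columns are skipped, not called", {
  d <- default_design()
  g <- genuine_sequence(d)
  mutant <- g
  substr(mutant, 30, 30) <- "N"
  ev <- call_mutations(aligned_to(d, mutant), d, "m")
  expect_identical(nrow(ev), 0L)
})

test_that("gap runs are one event each, with per-base lengths", {
  d <- default_design()
  g <- genuine_sequence(d)
  # delete template positions 40,41 (a 2-nt deletion)
  del2 <- paste0(substr(g, 1, 40), substr(g, 43, nchar(g)))
  ev <- call_mutations(aligned_to(d, del2), d, "del")
  expect_identical(ev$kind, "deletion")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$length, 2L)

  # 2-nt insertion after template position 49
  ins2 <- paste0(substr(g, 1, 50), "GG", substr(g, 51, nchar(g)))
  ev <- call_mutations(aligned_to(d, ins2), d, "ins")
  expect_identical(ev$kind, "insertion")
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$length, 2L)
  expect_identical(ev$to_base, "GG")
})

test_that("calling twice on a normalized alignment is stable", {
  d <- default_design()
  ds <- simulate_dataset(d, uniform_model(0.05, ins_rate = 0.01,
                                          del_rate = 0.01), n = 5, seed = 3)
  for (i in 1:5) {
    a <- aligned_to(d, ds$records$sequence[i])
    expect_identical(call_mutations(a, d, "x"), call_mutations(a, d, "x"))
  }
})

test_that("called events reproduce the planted truth on a simulated dataset", {
  d <- default_design()
  ds <- simulate_dataset(d, uniform_model(0.01, ins_rate = 0.002,
                                          del_rate = 0.002),
                         n = 200, flip_fraction = 0.5, seed = 51)
  run <- run_pipeline(d, ds$records)
  expect_identical(run$counts$n_passed, 200L)

  truth <- ds$truth
  called <- run$events
  # aggregate base counts by kind match exactly
  for (k in c("substitution", "insertion", "deletion")) {
    expect_identical(sum(called$length[called$kind == k]),
                     sum(truth$length[truth$kind == k]))
  }
  # substitutions match position-by-position for clones without indels
  # (indel-bearing clones may shift coordinates within repeats)
  indel_clones <- unique(truth$clone_id[truth$kind != "substitution"])
  ts <- truth[truth$kind == "substitution" &
                !(truth$clone_id %in% indel_clones), ]
  cs <- called[called$kind == "substitution" &
                 !(called$clone_id %in% indel_clones), ]
  key <- function(x) sort(paste(x$clone_id, x$template_pos, x$from_base,
                                x$to_base))
  expect_identical(key(cs), key(ts))
})

test_that("no-RT control summaries report the contaminant pass fraction", {
  d <- tiny_design()
  m <- uniform_model(0.02)
  contam <- simulate_dataset(d, m, n = 6, contaminant_fraction = 1,
                             seed = 61)$records
  genuine <- simulate_dataset(d, m, n = 6, seed = 62)$records
  expect_identical(detect_no_rt_contamination(contam, d)$pass_fraction, 0)
  expect_identical(detect_no_rt_contamination(genuine, d)$pass_fraction, 1)

  genuine$id <- paste0("g_", genuine$id)
  mix <- rbind(contam, genuine)
  res <- detect_no_rt_contamination(mix, d)
  expect_identical(res$pass_fraction, 0.5)
  expect_true(res$contaminated)
  expect_error(detect_no_rt_contamination(contam[0, ], d), "empty")
})

test_that("analyzed positions + deleted bases account for the whole span", {
  d <- default_design()
  ds <- simulate_dataset(d, uniform_model(0.02, del_rate = 0.01),
                         n = 50, seed = 71)
  run <- run_pipeline(d, ds$records)
  span <- d$analysis[2] - d$analysis[1]
  expect_equal(run$spectrum$total_positions + run$spectrum$del_count,
               span * run$counts$n_passed)
})
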