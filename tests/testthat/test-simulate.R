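test_that("locus generation is deterministic and matches its own detection", {
  g1 <- generate_locus(seed = 7)
  g2 <- generate_locus(seed = 7)
  expect_identical(g1$locus$sequence, g2$locus$sequence)
  expect_identical(g1$truth$cassettes, g2$truth$cassettes)
  g3 <- generate_locus(seed = 8)
  expect_false(identical(g1$locus$sequence, g3$locus$sequence))
  # written FASTA files are byte-identical for the same seed
  p1 <- withr::local_tempfile(fileext = ".fasta")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(g1$locus$sequence, p1)
  write_locus(g2$locus$sequence, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generator architecture follows its configuration", {
  gen <- test_locus()
  expect_equal(nrow(gen$locus$cassettes), 4L)
  expect_equal(nrow(gen$locus$sites), 5L)
  expect_equal(nrow(extract_variants(gen$locus)$variants), 8L)
  gen1 <- test_locus(seed = 9, n = 1)
  expect_equal(nrow(extract_variants(gen1$locus)$variants), 2L)
  expect_error(generator_config(variant_codon_range = c(2, 3)), "at least 5")
  expect_error(generator_config(error_rate = 0.5), "error_rate")
})

test_that("a shufflase-free population stays locked in one conformation", {
  pop <- simulate_dynamics(4, n_cells = 500, n_steps = 50, inversion_prob = 0, seed = 2)
  expect_equal(sum(pop$frequency > 0), 1L)
  locked <- pop[pop$frequency > 0, ]
  expect_equal(locked$conformation, "1+,2+,3+,4+")
  expect_equal(locked$frequency, 1)
  expect_equal(locked$active_variant, "A")
})

test_that("a one-cassette shufflon equilibrates to a symmetric two-state law", {
  n_cells <- 4000
  pop <- simulate_dynamics(1, n_cells = n_cells, n_steps = 100,
                           inversion_prob = 0.5, seed = 4)
  expect_equal(nrow(pop), 2L)
  se <- sqrt(0.25 / n_cells)
  expect_true(all(abs(pop$frequency - 0.5) < 3 * se))
})

test_that("inversion dynamics approach the uniform stationary distribution", {
  model <- shufflon_model(n = 3)
  n_cells <- 6000
  pop <- simulate_dynamics(model, n_cells = n_cells, n_steps = 300,
                           inversion_prob = 0.5, seed = 6)
  marg <- pop |>
    dplyr::group_by(active_variant) |>
    dplyr::summarise(frequency = sum(frequency), .groups = "drop")
  p0 <- 1 / 6
  se <- sqrt(p0 * (1 - p0) / n_cells)
  expect_true(all(abs(marg$frequency - p0) < 3 * se))
})

test_that("transfer selection reweights donor frequencies multiplicatively", {
  out <- simulate_selection(c(A = 0.5, B = 0.5), c(A = 4, B = 1))
  expect_equal(out$frequency, c(0.8, 0.2))
  # uniform weights are neutral
  donor <- c(A = 0.6, B = 0.3, C = 0.1)
  neut <- simulate_selection(donor, c(A = 1, B = 1, C = 1))
  expect_equal(setNames(neut$frequency, neut$variant), donor)
  # a single permissive variant takes all the mass
  mono <- simulate_selection(c(A = 0.25, B = 0.25, C = 0.5), c(B = 2))
  expect_equal(mono$frequency[mono$variant == "B"], 1)
  expect_error(simulate_selection(c(A = 1), c(A = 0)), "zero weight|positive")
  expect_error(simulate_selection(c(A = 1), c(A = -1)), "non-negative")
})

test_that("read simulation is deterministic and honours the truth table", {
  gen <- test_locus()
  cfg <- generator_config(depth = 400L, error_rate = 0)
  f1 <- withr::local_tempfile(fileext = ".fastq.gz")
  f2 <- withr::local_tempfile(fileext = ".fastq.gz")
  s1 <- simulate_reads(gen$locus, c(A = 1), cfg, seed = 5, fastq = f1)
  s2 <- simulate_reads(gen$locus, c(A = 1), cfg, seed = 5, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$reads$sequence, s2$reads$sequence)
  expect_true(all(s1$truth$variant == "A"))
  # with no errors, every read is an exact substring of its source sequence
  conf_seq <- conformation_sequence(gen$locus, s1$truth$conformation[1])
  idx <- sample(seq_len(400), 25)
  for (i in idx) {
    r <- s1$reads$sequence[i]
    if (s1$truth$strand[i] == "-") {
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    expect_identical(r, substring(conf_seq, s1$truth$start[i], s1$truth$start[i] + 149L))
  }
  expect_error(
    simulate_reads(gen$locus, c(A = 1), generator_config(read_length = 10000L), seed = 1),
    "read_length"
  )
})

test_that("a single-conformation population yields only its own variant", {
  gen <- test_locus()
  sig <- make_signatures(gen$locus)
  sim <- simulate_reads(
    gen$locus, c("C'" = 1),
    generator_config(depth = 4000L, error_rate = 0), seed = 12
  )
  ab <- relative_abundance(count_footprints(sim$reads$sequence, sig))
  expect_equal(ab$frequency[ab$variant == "C'"], 1)
  expect_true(all(ab$count[ab$variant != "C'"] == 0L))
})

test_that("substitution errors break exact junction matches at the binomial rate", {
  gen <- test_locus()
  sig <- make_signatures(gen$locus)
  err <- 0.01
  cfg <- generator_config(depth = 20000L, error_rate = err)
  sim <- simulate_reads(gen$locus, c(A = 1), cfg, seed = 23)
  # junction-spanning reads fully cover the 39-bp window around the core
  core_end <- gen$locus$constant5[["end"]]
  w1 <- core_end - 18L
  w2 <- core_end + 20L
  spans <- sim$truth$start <= w1 & sim$truth$start + cfg$read_length - 1L >= w2
  n_span <- sum(spans)
  ct <- count_footprints(sim$reads$sequence, sig)
  observed_fail <- 1 - attr(ct, "total_positive") / n_span
  p_fail <- 1 - (1 - err)^39
  se <- sqrt(p_fail * (1 - p_fail) / n_span)
  expect_lt(abs(observed_fail - p_fail), 3 * se)
})

test_that("the full pipeline recovers population variant frequencies", {
  gen <- test_locus()
  # rebuild the locus from scratch through detection, as a user would
  p <- withr::local_tempfile(fileext = ".fasta")
  write_locus(gen$locus$sequence, p)
  rec <- read_locus(p)
  locus <- build_locus(rec$sequence,
                       find_sfx_sites(rec$sequence, gen$truth$config$sfx_consensus),
                       constant5_hint = gen$truth$pilv_start)
  sig <- make_signatures(locus)
  pop <- simulate_dynamics(locus$model, n_cells = 3000, n_steps = 150,
                           inversion_prob = 0.3, seed = 8)
  cfg <- generator_config(depth = 10000L, error_rate = 0.005)
  f <- withr::local_tempfile(fileext = ".fastq.gz")
  sim <- simulate_reads(locus, pop, cfg, seed = 9, fastq = f)
  ab <- relative_abundance(count_footprints(f, sig))
  truth_marg <- pop |>
    dplyr::group_by(active_variant) |>
    dplyr::summarise(frequency = sum(frequency), .groups = "drop")
  npos <- attr(ab, "total_positive")
  for (v in truth_marg$active_variant) {
    f_true <- truth_marg$frequency[truth_marg$active_variant == v]
    f_obs <- ab$frequency[ab$variant == v]
    se <- sqrt(f_true * (1 - f_true) / npos)
    expect_lt(abs(f_obs - f_true), 3 * se + 1e-9)
  }
})

test_that("variant-frequency populations map to representative conformations", {
  model <- shufflon_model(n = 4)
  pop <- population_from_variant_freqs(model, c("C'" = 0.7, B = 0.3))
  expect_equal(sort(pop$active_variant), c("B", "C'"))
  expect_equal(sum(pop$frequency), 1)
  expect_equal(pop$conformation[pop$active_variant == "C'"], "3-,2+,1+,4+")
  expect_error(population_from_variant_freqs(model, c(Z = 1)), "unknown")
})
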