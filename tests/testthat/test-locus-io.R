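test_that("FASTA output round-trips through read_locus", {
  gen <- test_locus()
  p1 <- withr::local_tempfile(fileext = ".fasta")
  write_locus(gen$locus$sequence, p1, name = "syn")
  rec <- read_locus(p1)
  expect_identical(rec$sequence, gen$locus$sequence)
  expect_equal(rec$name, "syn")

  pgz <- withr::local_tempfile(fileext = ".fasta.gz")
  write_locus(gen$locus$sequence, pgz)
  expect_identical(read_locus(pgz)$sequence, gen$locus$sequence)
})

test_that("GenBank output round-trips sequence and features", {
  gen <- test_locus()
  p <- withr::local_tempfile(fileext = ".gb")
  feats <- tibble::tibble(
    type = "misc_recomb",
    start = gen$locus$sites$start,
    end = gen$locus$sites$end,
    strand = gen$locus$sites$strand,
    label = paste0("sfx", seq_len(nrow(gen$locus$sites)))
  )
  write_locus(gen$locus$sequence, p, name = "synthetic_shufflon",
              features = feats, format = "genbank")
  rec <- read_locus(p, format = "genbank")
  expect_identical(rec$sequence, gen$locus$sequence)
  got <- rec$features[rec$features$type == "misc_recomb", ]
  expect_equal(got$start, feats$start)
  expect_equal(got$end, feats$end)
  expect_equal(got$label, feats$label)
})

test_that("unreadable input is rejected with a format error", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines("this is not genbank", p)
  expect_error(read_locus(p, format = "genbank"), "GenBank")
  expect_error(read_locus(tempfile()), "not found")
})

test_that("sfx detection recovers planted sites exactly", {
  gen <- test_locus()
  cons <- gen$truth$config$sfx_consensus
  sites <- find_sfx_sites(gen$locus$sequence, cons)
  expect_equal(nrow(sites), 5L)
  expect_equal(sites$start, gen$truth$sites$start)
  expect_equal(sites$end, gen$truth$sites$end)
  expect_true(all(sites$strand == "+"))
  expect_true(all(sites$end - sites$start + 1L == 31L))
  expect_true(all(sites$variable_triplet %in% c("GTG", "ATC", "TCG")))
  expect_true(all(sites$triplet_label %in% c("e", "f", "g")))
  expect_true(all(sites$core_seq == cons$core))
})

test_that("no sites are reported in motif-free sequence", {
  withr::with_seed(5, {
    s <- paste(sample(c("A", "C"), 4000, replace = TRUE), collapse = "")
  })
  expect_equal(nrow(find_sfx_sites(s)), 0L)
})

test_that("detection on the reverse complement mirrors coordinates and strands", {
  gen <- test_locus()
  cons <- gen$truth$config$sfx_consensus
  fwd <- find_sfx_sites(gen$locus$sequence, cons)
  L <- nchar(gen$locus$sequence)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gen$locus$sequence)
  ))
  rev <- find_sfx_sites(rc, cons)
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(sort(L - fwd$end + 1L), sort(rev$start))
  expect_true(all(rev$strand == "-"))
  expect_equal(sort(rev$variable_triplet), sort(fwd$variable_triplet))
})

test_that("locus segmentation places cassettes between consecutive cores", {
  gen <- test_locus()
  locus <- gen$locus
  expect_equal(nrow(locus$cassettes), 4L)
  expect_equal(locus$cassettes$start, gen$truth$cassettes$start)
  expect_equal(locus$cassettes$end, gen$truth$cassettes$end)
  expect_equal(unname(locus$constant5["end"]), unname(gen$truth$constant5["end"]))
  # cassettes plus 7-bp cores tile the span between first and last core
  core_starts <- locus$sites$start + 12L
  core_ends <- locus$sites$start + 18L
  covered <- sum(locus$cassettes$length_bp) + 7L * nrow(locus$sites)
  expect_equal(covered, core_ends[length(core_ends)] - core_starts[1] + 1L)
  # two sites give one cassette; fewer than two is an error
  two <- build_locus(locus$sequence, locus$sites[1:2, ])
  expect_equal(nrow(two$cassettes), 1L)
  expect_error(build_locus(locus$sequence, locus$sites[1, ]), "at least 2")
})

test_that("variant translation matches generator ground truth", {
  gen <- test_locus()
  ev <- extract_variants(gen$locus)
  expect_equal(nchar(ev$constant_aa), gen$truth$constant5_aa)
  expect_equal(nrow(ev$variants), 8L)
  plus <- ev$variants[ev$variants$orientation == "+", ]
  minus <- ev$variants[ev$variants$orientation == "-", ]
  expect_equal(plus$length_aa, gen$truth$cassettes$orf_plus_aa)
  expect_equal(minus$length_aa, gen$truth$cassettes$orf_minus_aa)
  expect_true(all(ev$variants$length_aa >= 69 & ev$variants$length_aa <= 113))
  expect_false(any(grepl("\\*", ev$variants$aa_seq)))
})

test_that("consensus matrix flags exactly the variable positions", {
  base_site <- list(left = strrep("A", 12), core = "ACCGGTC")
  arm <- function(trip) paste0("CTGCAA", trip, "GCT")
  sites <- tibble::tibble(
    left_arm = base_site$left,
    core_seq = base_site$core,
    right_arm = c(arm("GTG"), arm("ATC"), arm("TCG"))
  )
  cm <- consensus_matrix(sites)
  expect_equal(sum(!cm$conserved), 3L)
  expect_equal(which(!cm$conserved), 12L + 7L + 7:9)
  # identical sites: everything conserved; single site: one-hot matrix
  same <- sites[c(1, 1, 1), ]
  expect_true(all(consensus_matrix(same)$conserved))
  one <- consensus_matrix(sites[1, ])
  expect_true(all(colSums(one$counts) == 1L))
  expect_equal(one$consensus, paste0(sites$left_arm[1], sites$core_seq[1], sites$right_arm[1]))
  expect_error(consensus_matrix(tibble::tibble(
    left_arm = c("A", "AA"), core_seq = "ACCGGTC", right_arm = "CTGCAAGTGGCT"
  )), "mixed")
})

test_that("locus tidiers expose features and summary counts", {
  gen <- test_locus()
  td <- tidy(gen$locus)
  expect_equal(sum(td$feature == "cassette"), 4L)
  expect_equal(sum(td$feature == "sfx_site"), 5L)
  gl <- glance(gen$locus)
  expect_equal(gl$n_conformations, 384)
  expect_equal(gl$n_variants, 8L)
})
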