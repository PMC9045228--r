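#' Synthetic-data generator configuration
#'
#' Bundles the knobs of the synthetic shufflon generator and read simulator.
#' Defaults emulate the TP114-like architecture: four invertible cassettes,
#' a 345-codon constant *pilV* N-terminus, variant C-termini of 69-113
#' codons, sfx sites with variable triplets cycled over GTG/ATC/TCG, and a
#' substitution-only error model with uniform base qualities.
#'
#' @param n_cassettes Number of invertible cassettes (default 4).
#' @param constant5_codons Codons in the constant pilV region, counted up to
#'   and including the first sfx core (default 345).
#' @param variant_codon_range Two integers: min and max variant ORF length
#'   in codons, stop excluded (default 69, 113).
#' @param sfx_consensus An [sfx_consensus()] describing the planted sites.
#' @param read_length Simulated read length in bases (default 150).
#' @param error_rate Per-base substitution probability (default 0.001;
#'   must be `< 0.25`).
#' @param depth Reads per simulated sample (default 10000).
#' @param gc GC content of random background sequence (default 0.5).
#' @param spacer_len Bases between the two convergent ORFs of a cassette.
#' @param flank5_len,flank3_len Random flanking sequence outside the locus.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cassettes = 4L,
                             constant5_codons = 345L,
                             variant_codon_range = c(69L, 113L),
                             sfx_consensus = shufflonr::sfx_consensus(),
                             read_length = 150L,
                             error_rate = 0.001,
                             depth = 10000L,
                             gc = 0.5,
                             spacer_len = 45L,
                             flank5_len = 100L,
                             flank3_len = 150L) {
  n_cassettes <- stopifnot_scalar_int(n_cassettes, "n_cassettes", min = 1L)
  constant5_codons <- stopifnot_scalar_int(constant5_codons, "constant5_codons", min = 8L)
  if (length(variant_codon_range) != 2L || variant_codon_range[1] > variant_codon_range[2]) {
    abort("`variant_codon_range` must be c(min, max) with min <= max")
  }
  if (variant_codon_range[1] < 5L) abort("variant ORFs need at least 5 codons")
  if (error_rate < 0 || error_rate >= 0.25) abort("`error_rate` must be in [0, 0.25)")
  structure(
    list(
      n_cassettes = n_cassettes,
      constant5_codons = constant5_codons,
      variant_codon_range = as.integer(variant_codon_range),
      sfx_consensus = sfx_consensus,
      read_length = as.integer(read_length),
      error_rate = error_rate,
      depth = as.integer(depth),
      gc = gc,
      spacer_len = as.integer(spacer_len),
      flank5_len = as.integer(flank5_len),
      flank3_len = as.integer(flank3_len)
    ),
    class = "generator_config"
  )
}

# an arm whose reverse complement is translated in the fused frame must be
# stop-free over its 4 codons, and must not create spurious core matches
sample_left_arm <- function(cons, gc) {
  avoid <- c(cons$core, revcomp(cons$core))
  repeat {
    arm <- random_dna(12L, gc = gc, avoid = avoid)
    if (!has_inframe_stop(revcomp(arm))) return(arm)
  }
}

arm_from_template <- function(cons, triplet) {
  chars <- strsplit(cons$right_arm_template, "")[[1]]
  chars[arm_wildcards(cons)] <- strsplit(triplet, "")[[1]]
  paste(chars, collapse = "")
}

#' Generate a synthetic shufflon locus
#'
#' Builds a locus with a random flank, a constant *pilV* region of
#' `constant5_codons` in-frame codons ending at the first sfx core,
#' `n_cassettes` invertible cassettes each carrying two convergent
#' stop-terminated ORFs (total lengths drawn uniformly from
#' `variant_codon_range`), and `n_cassettes + 1` planted sfx sites with
#' variable triplets cycled over the consensus repeat set. The first base of
#' each cassette lies on a codon boundary of the fused *pilV* frame, so the
#' variable C-terminus is the in-frame translation of the cassette. The
#' generated sequence is verified by running the package's own site
#' detection; deterministic given `seed`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A list: `locus` (a `shufflon_locus` built from the detected
#'   sites) and `truth` (planted site coordinates, cassette intervals,
#'   per-variant ORF lengths, labels, pilV start, seed and config).
#' @export
generate_locus <- function(config = generator_config(), seed = 1L) {
  cons <- config$sfx_consensus
  triplets <- names(cons$triplet_labels)
  n <- config$n_cassettes
  out <- withr::with_seed(seed, {
    result <- NULL
    for (attempt in 1:20) {
      avoid <- c(cons$core, revcomp(cons$core))
      flank5 <- random_dna(config$flank5_len, gc = config$gc, avoid = avoid)
      larm <- character(n + 1L)
      for (i in seq_len(n + 1L)) larm[i] <- sample_left_arm(cons, config$gc)
      # constant region: head codons, then a 7-codon tail = pad(2) + left
      # arm(12) + core(7), all stop-free in frame
      head <- random_codons(config$constant5_codons - 7L, gc = config$gc)
      repeat {
        pad <- random_dna(2L, gc = config$gc)
        tail <- paste0(pad, larm[1], cons$core)
        if (!has_inframe_stop(tail)) break
        larm[1] <- sample_left_arm(cons, config$gc)
      }
      constant5 <- paste0(head, tail)

      lens_plus <- sample(seq(config$variant_codon_range[1], config$variant_codon_range[2]),
                          n, replace = TRUE)
      lens_minus <- sample(seq(config$variant_codon_range[1], config$variant_codon_range[2]),
                           n, replace = TRUE)
      cassettes <- character(n)
      for (i in seq_len(n)) {
        trip <- triplets[(i - 1L) %% length(triplets) + 1L]
        arm <- arm_from_template(cons, trip)
        body_p <- random_codons(lens_plus[i] - 4L, gc = config$gc)
        stop_p <- sample(STOP_CODONS, 1L)
        spacer <- random_dna(config$spacer_len, gc = config$gc, avoid = avoid)
        body_m <- random_codons(lens_minus[i] - 4L, gc = config$gc)
        stop_m <- sample(STOP_CODONS, 1L)
        cassettes[i] <- paste0(
          arm, body_p, stop_p, spacer,
          revcomp(stop_m), revcomp(body_m), larm[i + 1L]
        )
      }
      final_trip <- triplets[n %% length(triplets) + 1L]
      flank3 <- paste0(arm_from_template(cons, final_trip),
                       random_dna(config$flank3_len, gc = config$gc, avoid = avoid))
      sequence <- paste0(
        flank5, constant5,
        paste(cassettes, collapse = cons$core),
        cons$core, flank3
      )

      pilv_start <- config$flank5_len + 1L
      core1_end <- config$flank5_len + 3L * config$constant5_codons
      cas_start <- core1_end + 1L + cumsum(c(0L, nchar(cassettes[-n]) + 7L))
      cas_end <- cas_start + nchar(cassettes) - 1L
      core_starts <- c(core1_end - 6L, cas_end + 1L)
      planted <- tibble(
        start = core_starts - 12L,
        end = core_starts + 18L,
        strand = "+"
      )
      detected <- find_sfx_sites(sequence, cons)
      ok <- nrow(detected) == n + 1L &&
        all(detected$start == planted$start) &&
        all(detected$strand == "+")
      if (ok) {
        truth_cassettes <- tibble(
          id = seq_len(n),
          start = cas_start,
          end = cas_end,
          length_bp = nchar(cassettes),
          label_plus = LETTERS[seq_len(n)],
          label_minus = paste0(LETTERS[seq_len(n)], "'"),
          orf_plus_aa = lens_plus,
          orf_minus_aa = lens_minus
        )
        locus <- build_locus(sequence, detected, constant5_hint = pilv_start)
        locus$model$length_bp <- locus$cassettes$length_bp
        result <- list(
          locus = locus,
          truth = list(
            sites = planted,
            cassettes = truth_cassettes,
            pilv_start = pilv_start,
            constant5 = c(start = pilv_start, end = core1_end),
            constant5_aa = config$constant5_codons,
            seed = seed,
            attempt = attempt,
            config = config
          )
        )
        break
      }
    }
    result
  })
  if (is.null(out)) abort("could not generate a clean locus in 20 attempts; adjust the config")
  out
}

#' Simulate per-cell shufflon inversion dynamics
#'
#' Each of `n_cells` cells starts at the identity conformation; at every
#' step a cell undergoes, with probability `inversion_prob`, one block
#' inversion drawn uniformly over all contiguous blocks. With
#' `inversion_prob = 0` the population stays locked in the starting
#' conformation (the shufflase-deletion analogue). The move set is
#' symmetric, so the stationary distribution is uniform over all
#' `n! * 2^n` conformations.
#'
#' @param model A `shufflon_model` or cassette count.
#' @param n_cells,n_steps Positive integers.
#' @param inversion_prob Per-cell, per-step inversion probability in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return A tibble of class `shufflon_population` with `conformation`,
#'   `active_variant`, `count`, `frequency` over the observed states.
#' @export
simulate_dynamics <- function(model, n_cells, n_steps, inversion_prob, seed = 1L) {
  if (!inherits(model, "shufflon_model")) model <- shufflon_model(n = model)
  n <- n_cassettes(model)
  stopifnot_scalar_int(n_cells, "n_cells", min = 1L)
  stopifnot_scalar_int(n_steps, "n_steps", min = 1L)
  if (inversion_prob < 0 || inversion_prob > 1) abort("`inversion_prob` must be in [0, 1]")
  confs <- enumerate_conformations(model)
  key_index <- setNames(seq_len(nrow(confs)), confs$conformation)
  moves <- block_moves(n)
  move_to <- matrix(0L, nrow = nrow(confs), ncol = nrow(moves))
  for (s in seq_len(nrow(confs))) {
    for (m in seq_len(nrow(moves))) {
      nxt <- invert_block(conformation(confs$arrangement[[s]]), moves[m, 1L], moves[m, 2L])
      move_to[s, m] <- key_index[[conformation_key(nxt)]]
    }
  }
  start_idx <- key_index[[conformation_key(identity_conformation(n))]]
  counts <- withr::with_seed(seed, {
    cells <- rep.int(start_idx, n_cells)
    if (inversion_prob > 0 && nrow(moves) > 0L) {
      for (step in seq_len(n_steps)) {
        flip <- runif(n_cells) < inversion_prob
        nf <- sum(flip)
        if (nf) {
          mv <- sample.int(nrow(moves), nf, replace = TRUE)
          cells[flip] <- move_to[cbind(cells[flip], mv)]
        }
      }
    }
    tabulate(cells, nbins = nrow(confs))
  })
  out <- tibble(
    conformation = confs$conformation,
    active_variant = confs$active_variant,
    count = counts,
    frequency = counts / sum(counts)
  )
  structure(out, class = c("shufflon_population", class(tibble())), model = model)
}

#' Transfer selection on variant frequencies
#'
#' Reweights donor variant frequencies by variant-specific relative
#' transfer efficiencies toward a given recipient:
#' `f_trans(v) = f(v) w(v) / sum_u f(u) w(u)`.
#'
#' @param donor_variant_freq Named numeric vector or tibble
#'   (`variant`, `frequency`) summing to 1.
#' @param weights Named numeric vector or tibble (`variant`, `weight`) of
#'   non-negative compatibility weights; missing variants get weight 0.
#' @return A tibble (`variant`, `frequency`) of transconjugant frequencies.
#' @export
simulate_selection <- function(donor_variant_freq, weights) {
  f <- as_variant_vector(donor_variant_freq, "frequency")
  w <- as_variant_vector(weights, "weight")
  if (any(w < 0)) abort("weights must be non-negative")
  if (!any(w > 0)) abort("at least one weight must be positive")
  labels <- names(f)
  wv <- setNames(rep(0, length(labels)), labels)
  common <- intersect(labels, names(w))
  wv[common] <- w[common]
  num <- f * wv
  if (sum(num) <= 0) abort("no transfer: every donor variant has zero weight")
  tibble(variant = labels, frequency = unname(num / sum(num)))
}

as_variant_vector <- function(x, value_col) {
  if (is.data.frame(x)) {
    cols <- intersect(c(value_col, "frequency", "weight", "value"), names(x))
    if (!"variant" %in% names(x) || !length(cols)) {
      abort(sprintf("data frame input needs columns variant and %s", value_col))
    }
    setNames(x[[cols[1]]], x$variant)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    abort("expected a named numeric vector or a variant/value data frame")
  }
}

#' Conformations expressing a given variant frequency profile
#'
#' Maps per-variant frequencies onto one representative conformation per
#' variant (the identity arrangement with the variant's cassette swapped to
#' position 1 in the required orientation), producing a population usable
#' by [simulate_reads()].
#'
#' @param model A `shufflon_model`.
#' @param freqs Named numeric vector or tibble (`variant`, `frequency`).
#' @return A tibble of class `shufflon_population`.
#' @export
population_from_variant_freqs <- function(model, freqs) {
  f <- as_variant_vector(freqs, "frequency")
  if (any(f < 0)) abort("frequencies must be non-negative")
  if (sum(f) <= 0) abort("frequencies must not all be zero")
  f <- f / sum(f)
  n <- n_cassettes(model)
  rows <- lapply(names(f), function(lab) {
    plus <- match(lab, model$label_plus)
    minus <- match(lab, model$label_minus)
    if (is.na(plus) && is.na(minus)) abort(sprintf("unknown variant label '%s'", lab))
    id <- if (!is.na(plus)) model$id[plus] else model$id[minus]
    v <- seq_len(n)
    pos <- which(v == id)
    v[pos] <- v[1L]
    v[1L] <- if (!is.na(plus)) id else -id
    tibble(
      conformation = conformation_key(conformation(v)),
      active_variant = lab,
      frequency = unname(f[[lab]])
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("shufflon_population", class(tibble())), model = model)
}

#' Simulate reads from a shufflon population
#'
#' Draws each read's source conformation multinomially from the population,
#' samples a uniform start position and strand on that conformation's
#' full-locus sequence, applies independent substitution errors at
#' `error_rate`, and assigns uniform high base qualities. Deterministic
#' given `seed`.
#'
#' @param locus A `shufflon_locus`.
#' @param population A `shufflon_population` (conformation frequencies), or
#'   per-variant frequencies (named vector or `variant`/`frequency` tibble),
#'   which are mapped to representative conformations.
#' @param config A [generator_config()] supplying `read_length`,
#'   `error_rate` and `depth`.
#' @param seed Integer seed.
#' @param fastq Optional output FASTQ path (`.gz` for gzip).
#' @return A list: `reads` (tibble `read_id`, `sequence`, `quality`),
#'   `truth` (tibble `read_id`, `conformation`, `variant`, `start`,
#'   `strand`, `n_errors`), and `fastq` (path or `NULL`).
#' @export
simulate_reads <- function(locus, population, config = generator_config(),
                           seed = 1L, fastq = NULL) {
  if (!inherits(population, "shufflon_population")) {
    population <- population_from_variant_freqs(locus$model, population)
  }
  pop <- population[population$frequency > 0, , drop = FALSE]
  if (!nrow(pop)) abort("population has no mass")
  conf_seqs <- vapply(pop$conformation, function(k) conformation_sequence(locus, k),
                      character(1), USE.NAMES = FALSE)
  lens <- nchar(conf_seqs)
  rl <- config$read_length
  if (any(lens < rl)) {
    abort(sprintf("read_length %d exceeds a conformation sequence (%d bp)", rl, min(lens)))
  }
  depth <- config$depth
  if (depth < 1L) abort("depth must be positive")
  if (!"active_variant" %in% names(pop)) {
    pop$active_variant <- vapply(pop$conformation,
                                 function(k) active_variant(k, locus$model), character(1))
  }
  res <- withr::with_seed(seed, {
    ci <- sample.int(nrow(pop), depth, replace = TRUE, prob = pop$frequency)
    starts <- 1L + floor(runif(depth) * (lens[ci] - rl + 1L))
    strands <- sample(c("+", "-"), depth, replace = TRUE)
    seqs <- substring(conf_seqs[ci], starts, starts + rl - 1L)
    neg <- strands == "-"
    if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
    n_err <- if (config$error_rate > 0) rbinom(depth, rl, config$error_rate) else integer(depth)
    idx <- which(n_err > 0L)
    for (i in idx) {
      pos <- sample.int(rl, n_err[i])
      chars <- strsplit(seqs[i], "")[[1]]
      for (p in pos) chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      seqs[i] <- paste(chars, collapse = "")
    }
    list(ci = ci, starts = starts, strands = strands, seqs = seqs, n_err = n_err)
  })
  ids <- sprintf("read%06d", seq_len(depth))
  reads <- tibble(
    read_id = ids,
    sequence = res$seqs,
    quality = strrep("I", rl)
  )
  truth <- tibble(
    read_id = ids,
    conformation = pop$conformation[res$ci],
    variant = pop$active_variant[res$ci],
    start = res$starts,
    strand = res$strands,
    n_errors = res$n_err
  )
  if (!is.null(fastq)) {
    con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "w") else file(fastq, "w")
    recs <- as.vector(rbind(paste0("@", ids), res$seqs, "+", reads$quality))
    writeLines(recs, con)
    close(con)
  }
  list(reads = reads, truth = truth, fastq = fastq)
}
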