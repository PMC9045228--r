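#' Count variant footprints directly in reads
#'
#' Scans reads for the per-variant junction signatures on both strands
#' (a read matches a variant when the read or its reverse complement
#' contains the signature; exact substring match by default). A read
#' matching two or more distinct variants is tallied as ambiguous and
#' excluded from the per-variant counts. No quality or length filtering is
#' applied by default; reads shorter than the signature simply cannot match
#' but are still counted as scanned.
#'
#' @param reads FASTQ path(s) (plain or `.gz`; multiple files are pooled),
#'   a `Biostrings::DNAStringSet`, or a character vector of read sequences.
#' @param signatures Tibble with `label` and `kmer` columns
#'   ([make_signatures()] or [read_signatures()]).
#' @param max_mismatches Substitutions tolerated per signature match
#'   (default 0, exact).
#' @param count_mode `"per_read"` (a read counts at most once per variant;
#'   default) or `"per_occurrence"` (sums all occurrences over both strands
#'   in unambiguous reads).
#' @param min_mean_qual Optional minimum mean Phred quality; reads below it
#'   are excluded from matching (FASTQ input only).
#' @return A tibble (`variant`, `count`) of class `shufflon_counts` with
#'   attributes `total_positive`, `n_reads_scanned`, `ambiguous`,
#'   `unmatched`.
#' @export
count_footprints <- function(reads, signatures,
                             max_mismatches = 0L,
                             count_mode = c("per_read", "per_occurrence"),
                             min_mean_qual = NULL) {
  count_mode <- match.arg(count_mode)
  if (!nrow(signatures)) abort("`signatures` is empty")
  if (anyDuplicated(signatures$kmer)) abort("signatures must be pairwise distinct")
  if (anyDuplicated(signatures$label)) abort("signature labels must be distinct")

  qual_keep <- NULL
  if (is.character(reads)) {
    missing <- reads[!file.exists(reads)]
    looks_like_path <- grepl("\\.(fastq|fq)(\\.gz)?$", reads, ignore.case = TRUE)
    if (any(looks_like_path) || all(file.exists(reads))) {
      if (length(missing)) abort(sprintf("FASTQ not found: %s", missing[1]))
      sets <- lapply(reads, function(p) {
        tryCatch(
          Biostrings::readDNAStringSet(p, format = "fastq"),
          error = function(e) abort(sprintf("malformed FASTQ '%s': %s", p, conditionMessage(e)))
        )
      })
      if (!is.null(min_mean_qual)) {
        qual_keep <- unlist(lapply(reads, function(p) {
          qs <- Biostrings::readQualityScaledDNAStringSet(p)
          iq <- methods::as(Biostrings::quality(qs), "IntegerList")
          as.numeric(mean(iq)) >= min_mean_qual
        }))
      }
      reads <- do.call(c, sets)
    } else {
      reads <- Biostrings::DNAStringSet(toupper(reads))
    }
  }
  if (!methods::is(reads, "DNAStringSet")) {
    abort("`reads` must be FASTQ path(s), a DNAStringSet, or read sequences")
  }
  n_scanned <- length(reads)
  active <- if (is.null(qual_keep)) rep(TRUE, n_scanned) else qual_keep
  sub <- reads[active]

  n_sig <- nrow(signatures)
  occ <- matrix(0L, nrow = length(sub), ncol = n_sig)
  if (length(sub)) {
    for (s in seq_len(n_sig)) {
      fwd <- Biostrings::vcountPattern(signatures$kmer[s], sub,
                                       max.mismatch = max_mismatches)
      rev <- Biostrings::vcountPattern(revcomp(signatures$kmer[s]), sub,
                                       max.mismatch = max_mismatches)
      occ[, s] <- fwd + rev
    }
  }
  matched <- occ > 0L
  n_match <- rowSums(matched)
  unambig <- n_match == 1L
  counts <- if (count_mode == "per_read") {
    colSums(matched & unambig)
  } else {
    colSums(occ * unambig)
  }
  out <- tibble(variant = signatures$label, count = as.integer(counts))
  structure(
    out,
    class = c("shufflon_counts", class(tibble())),
    total_positive = sum(out$count),
    n_positive_reads = sum(unambig),
    n_reads_scanned = n_scanned,
    ambiguous = sum(n_match >= 2L),
    unmatched = sum(n_match == 0L) + sum(!active)
  )
}

#' @export
print.shufflon_counts <- function(x, ...) {
  cat(sprintf(
    "<footprint counts: %d/%d reads positive, %d ambiguous>\n",
    attr(x, "n_positive_reads"), attr(x, "n_reads_scanned"), attr(x, "ambiguous")
  ))
  NextMethod()
}

#' Relative variant abundances
#'
#' Frequency of each variant among footprint-positive reads: the count of
#' reads carrying that variant's footprint divided by the total number of
#' reads positive for any variant footprint.
#'
#' @param table A `shufflon_counts` object, or a tibble with `variant` and
#'   `count` columns.
#' @return A tibble (`variant`, `count`, `frequency`) of class
#'   `shufflon_abundance` with attribute `total_positive`; frequencies sum
#'   to 1.
#' @export
relative_abundance <- function(table) {
  if (!all(c("variant", "count") %in% names(table))) {
    abort("`table` needs columns variant, count")
  }
  if (any(table$count < 0)) abort("counts must be non-negative")
  total <- sum(table$count)
  if (total == 0) {
    abort("no footprint-positive reads: relative abundance is undefined")
  }
  out <- tibble(
    variant = table$variant,
    count = as.integer(table$count),
    frequency = table$count / total
  )
  structure(
    out,
    class = c("shufflon_abundance", class(tibble())),
    total_positive = total
  )
}

#' Donor-versus-transconjugant enrichment
#'
#' Log2 ratio of transconjugant to donor relative frequencies with a
#' pseudocount: `log2((f_trans + eps) / (f_donor + eps))`. The pseudocount
#' defaults to one read's worth of frequency in the smaller sample
#' (1 / min(total positive reads)). The label sets are unioned; a variant
#' absent from one sample has frequency 0 there.
#'
#' @param donor,trans `shufflon_abundance` tables (or tibbles with
#'   `variant`, `frequency`).
#' @param pseudocount Positive real `eps`; see above for the default.
#' @return A tibble (`variant`, `freq_donor`, `freq_trans`, `log2fc`) of
#'   class `shufflon_enrichment` with attribute `pseudocount`.
#' @export
enrichment <- function(donor, trans, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    t1 <- attr(donor, "total_positive")
    t2 <- attr(trans, "total_positive")
    if (is.null(t1) || is.null(t2)) {
      abort("give `pseudocount` explicitly when inputs carry no read totals")
    }
    pseudocount <- 1 / min(t1, t2)
  }
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be a positive number")
  }
  labels <- union(donor$variant, trans$variant)
  fd <- setNames(rep(0, length(labels)), labels)
  ft <- fd
  fd[donor$variant] <- donor$frequency
  ft[trans$variant] <- trans$frequency
  out <- tibble(
    variant = labels,
    freq_donor = unname(fd),
    freq_trans = unname(ft),
    log2fc = log2((unname(ft) + pseudocount) / (unname(fd) + pseudocount))
  )
  structure(
    out,
    class = c("shufflon_enrichment", class(tibble())),
    pseudocount = pseudocount
  )
}

#' Conjugation frequency with detection-limit censoring
#'
#' Transconjugants per recipient CFU. When no transconjugants are observed
#' or the ratio falls below the limit of detection, the value is reported
#' at the limit with `censored = TRUE` (the "below LOD" convention used for
#' transfer-rate figures; typical limits are 1e-8 for in vitro matings and
#' 1e-5 in vivo).
#'
#' @param transconjugant_cfu,recipient_cfu CFU counts per unit volume
#'   (vectors recycle).
#' @param lod Positive limit of detection (default `1e-8`).
#' @return A tibble with `transconjugant_cfu`, `recipient_cfu`, `value`,
#'   `censored`.
#' @export
conjugation_frequency <- function(transconjugant_cfu, recipient_cfu, lod = 1e-8) {
  if (any(transconjugant_cfu < 0) || any(recipient_cfu < 0)) {
    abort("CFU counts must be non-negative")
  }
  if (any(recipient_cfu <= 0)) abort("recipient CFU must be positive")
  if (!is.numeric(lod) || length(lod) != 1L || lod <= 0) {
    abort("`lod` must be a single positive number")
  }
  raw <- transconjugant_cfu / recipient_cfu
  censored <- transconjugant_cfu == 0 | raw < lod
  tibble(
    transconjugant_cfu = transconjugant_cfu,
    recipient_cfu = recipient_cfu,
    value = ifelse(censored, lod, raw),
    censored = censored
  )
}
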