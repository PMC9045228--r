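#' sfx site consensus description
#'
#' An sfx recombination site is modelled as a 31-bp footprint: a
#' nonconserved 12-bp left arm, a perfectly conserved 7-bp core (where DNA
#' crossover occurs) and a conserved 12-bp right arm whose positions 7-9
#' form a variable triplet. The bundled default letters are synthetic (the
#' real TP114 letters appear only in a graphical supplement and are never
#' hard-coded); detection is driven entirely by this configurable object.
#'
#' @param core 7-base conserved core sequence.
#' @param right_arm_template 12-base right-arm template with `N` at the
#'   variable positions (7-9 by default).
#' @param left_arm_len Left-arm length recorded per site (not matched).
#' @param max_mismatches Substitutions tolerated at non-wildcard right-arm
#'   positions (the core always matches exactly).
#' @param triplet_labels Named character vector mapping variable triplets to
#'   short repeat labels, as used for the e/f/g repeats.
#' @return A list of class `sfx_consensus`.
#' @examples
#' sfx_consensus()
#' @export
sfx_consensus <- function(core = "ACCGGTC",
                          right_arm_template = "CTGCAANNNGCT",
                          left_arm_len = 12L,
                          max_mismatches = 0L,
                          triplet_labels = c(GTG = "e", ATC = "f", TCG = "g")) {
  core <- toupper(core)
  right_arm_template <- toupper(right_arm_template)
  if (nchar(core) != 7L) abort("`core` must be 7 bases")
  if (nchar(right_arm_template) != 12L) abort("`right_arm_template` must be 12 bases")
  structure(
    list(
      core = core,
      right_arm_template = right_arm_template,
      left_arm_len = as.integer(left_arm_len),
      max_mismatches = as.integer(max_mismatches),
      triplet_labels = triplet_labels
    ),
    class = "sfx_consensus"
  )
}

# positions (1-based within the right arm) that are wildcards
arm_wildcards <- function(consensus) {
  which(strsplit(consensus$right_arm_template, "")[[1]] == "N")
}

# scan one strand of `sequence` (given in plus-strand letters) for
# core + right-arm matches; returns plus-strand footprint coordinates
scan_strand <- function(sequence, consensus, strand) {
  subject <- if (strand == "+") sequence else revcomp(sequence)
  L <- nchar(subject)
  core_hits <- Biostrings::matchPattern(consensus$core, Biostrings::DNAString(subject))
  starts <- BiocGenerics::start(core_hits)
  arm_chars <- strsplit(consensus$right_arm_template, "")[[1]]
  fixed_pos <- which(arm_chars != "N")
  wild_pos <- which(arm_chars == "N")
  out <- list()
  for (s in starts) {
    arm_start <- s + 7L
    arm_end <- arm_start + 11L
    left_start <- s - consensus$left_arm_len
    if (left_start < 1L || arm_end > L) next
    arm <- substring(subject, arm_start, arm_end)
    mism <- sum(strsplit(arm, "")[[1]][fixed_pos] != arm_chars[fixed_pos])
    if (mism > consensus$max_mismatches) next
    site_start <- left_start
    site_end <- arm_end
    # map back to plus-strand coordinates for minus-strand hits
    if (strand == "-") {
      tmp <- L - site_end + 1L
      site_end <- L - site_start + 1L
      site_start <- tmp
    }
    out[[length(out) + 1L]] <- tibble(
      start = site_start,
      end = site_end,
      strand = strand,
      left_arm = substring(subject, left_start, s - 1L),
      core_seq = substring(subject, s, s + 6L),
      right_arm = arm,
      variable_triplet = paste(strsplit(arm, "")[[1]][wild_pos], collapse = "")
    )
  }
  if (!length(out)) {
    return(tibble(
      start = integer(0), end = integer(0), strand = character(0),
      left_arm = character(0), core_seq = character(0),
      right_arm = character(0), variable_triplet = character(0)
    ))
  }
  dplyr::bind_rows(out)
}

#' Detect sfx sites by motif scan
#'
#' Scans both strands for sites whose 7-bp core matches exactly and whose
#' 12-bp right arm matches the consensus template at non-wildcard positions
#' with at most `max_mismatches` substitutions. The 3-bp variable triplet is
#' extracted from right-arm positions 7-9 and labelled when it matches a
#' known repeat (e/f/g by default). Overlapping candidates are resolved
#' leftmost-first.
#'
#' @param sequence Locus nucleotide sequence (character string), or the list
#'   returned by [read_locus()].
#' @param consensus An [sfx_consensus()] object.
#' @return A tibble of sites sorted by `start`, with 1-based inclusive
#'   coordinates of the 31-bp footprint on the plus strand, the arm/core
#'   sequences in site orientation, `variable_triplet` and `triplet_label`.
#' @export
find_sfx_sites <- function(sequence, consensus = sfx_consensus()) {
  if (is.list(sequence) && !is.null(sequence$sequence)) sequence <- sequence$sequence
  if (!is.character(sequence) || length(sequence) != 1L) {
    abort("`sequence` must be a single character string")
  }
  sequence <- toupper(sequence)
  hits <- dplyr::bind_rows(
    scan_strand(sequence, consensus, "+"),
    scan_strand(sequence, consensus, "-")
  )
  hits <- dplyr::arrange(hits, .data$start, .data$strand)
  # leftmost-first resolution of overlapping footprints
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$end[i]
    }
  }
  hits <- hits[keep, , drop = FALSE]
  lab <- consensus$triplet_labels[hits$variable_triplet]
  hits$triplet_label <- unname(ifelse(is.na(lab), NA_character_, lab))
  hits
}

#' Position-frequency matrix over aligned sfx sites
#'
#' Stacks the 31-base site footprints (left arm + core + right arm, in site
#' orientation), tallies base counts per position, and reports the majority
#' consensus with fully conserved positions flagged.
#'
#' @param sites Tibble from [find_sfx_sites()] (needs `left_arm`,
#'   `core_seq`, `right_arm`).
#' @return A list of class `sfx_matrix`: `counts` (4 x 31 matrix),
#'   `consensus` (string), `conserved` (logical per position), `n_sites`.
#' @export
consensus_matrix <- function(sites) {
  if (!nrow(sites)) abort("need at least one site")
  seqs <- paste0(sites$left_arm, sites$core_seq, sites$right_arm)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) abort("sites have mixed footprint lengths")
  w <- widths[1]
  mat <- do.call(rbind, strsplit(seqs, ""))
  counts <- vapply(
    seq_len(w),
    function(p) {
      tab <- table(factor(mat[, p], levels = DNA_BASES))
      as.integer(tab)
    },
    integer(4)
  )
  rownames(counts) <- DNA_BASES
  colnames(counts) <- seq_len(w)
  consensus <- unname(apply(counts, 2, function(col) DNA_BASES[which.max(col)]))
  conserved <- unname(apply(counts, 2, function(col) sum(col > 0) == 1L))
  structure(
    list(
      counts = counts,
      consensus = paste(consensus, collapse = ""),
      conserved = conserved,
      n_sites = nrow(sites)
    ),
    class = "sfx_matrix"
  )
}

#' @export
print.sfx_matrix <- function(x, ...) {
  cat(sprintf(
    "<sfx consensus matrix: %d sites, %d/%d conserved positions>\n%s\n",
    x$n_sites, sum(x$conserved), length(x$conserved), x$consensus
  ))
  invisible(x)
}
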