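#' Assemble a segmented shufflon locus
#'
#' Given a locus sequence and its detected (or annotated) sfx sites,
#' partitions the region into the constant 5' *pilV* side (ending at the
#' first site core), the invertible cassettes (the intervals strictly
#' between consecutive site cores, so each cassette interval begins with the
#' upstream site's right arm and ends with the downstream site's left arm)
#' and the constant 3' side toward *rci* (beginning after the last core).
#'
#' @param sequence Locus nucleotide sequence, or the list from
#'   [read_locus()].
#' @param sites Tibble of sfx sites from [find_sfx_sites()]; at least two.
#' @param constant5_hint 1-based position where the *pilV* CDS starts
#'   (defines the reading frame of the constant region). Defaults to 1.
#' @param model Optional [shufflon_model()] supplying variant labels; a
#'   default labelled model is built otherwise.
#' @return An object of class `shufflon_locus`: a list with `sequence`,
#'   `sites`, `cassettes` (tibble `id`, `start`, `end`, `length_bp`),
#'   `constant5`, `constant3` (1-based inclusive intervals) and `model`.
#' @export
build_locus <- function(sequence, sites, constant5_hint = 1L, model = NULL) {
  if (is.list(sequence) && !is.null(sequence$sequence)) sequence <- sequence$sequence
  if (nrow(sites) < 2L) {
    abort(sprintf("need at least 2 sfx sites to delimit a cassette, got %d", nrow(sites)))
  }
  sites <- dplyr::arrange(sites, .data$start)
  # the core is the middle 7 bases of the 31-bp footprint
  core_start <- sites$start + 12L
  core_end <- sites$start + 18L
  n <- nrow(sites) - 1L
  cassettes <- tibble(
    id = seq_len(n),
    start = core_end[-nrow(sites)] + 1L,
    end = core_start[-1L] - 1L
  )
  cassettes$length_bp <- cassettes$end - cassettes$start + 1L
  if (any(cassettes$length_bp <= 0L)) abort("overlapping site cores: empty cassette interval")
  if (is.null(model)) {
    model <- shufflon_model(n = n)
    model$length_bp <- cassettes$length_bp
  }
  structure(
    list(
      sequence = toupper(sequence),
      sites = sites,
      cassettes = cassettes,
      constant5 = c(start = as.integer(constant5_hint), end = core_end[1]),
      constant3 = c(start = core_end[nrow(sites)] + 1L, end = nchar(sequence)),
      model = model
    ),
    class = "shufflon_locus"
  )
}

#' @export
print.shufflon_locus <- function(x, ...) {
  cat(sprintf(
    "<shufflon locus: %d bp, %d sfx sites, %d cassettes (%d variants)>\n",
    nchar(x$sequence), nrow(x$sites), nrow(x$cassettes), 2L * nrow(x$cassettes)
  ))
  invisible(x)
}

# cassette sequence in a given orientation ('+' as on the locus,
# '-' reverse-complemented)
cassette_seq <- function(locus, id, orientation) {
  row <- which(locus$cassettes$id == id)
  if (!length(row)) abort(sprintf("cassette %d not in locus", id))
  s <- substring(locus$sequence, locus$cassettes$start[row], locus$cassettes$end[row])
  if (orientation == "-") revcomp(s) else s
}

#' Full sequence of a rearranged locus
#'
#' Reconstructs the nucleotide sequence the locus would have in a given
#' conformation: the constant 5' side up to the first core, the cassette
#' segments in the conformation's order and orientations separated by the
#' conserved 7-bp cores, then the constant 3' side.
#'
#' @param locus A `shufflon_locus`.
#' @param conf A conformation over the locus cassettes.
#' @return A character string.
#' @export
conformation_sequence <- function(locus, conf) {
  conf <- conformation(conf)
  v <- unclass(conf)
  if (length(v) != nrow(locus$cassettes)) {
    abort("conformation and locus have different cassette counts")
  }
  core <- locus$sites$core_seq[1]
  prefix <- substring(locus$sequence, 1L, locus$constant5[["end"]])
  suffix <- substring(locus$sequence, locus$constant3[["start"]], locus$constant3[["end"]])
  segs <- vapply(
    v,
    function(s) cassette_seq(locus, abs(s), if (s > 0) "+" else "-"),
    character(1)
  )
  paste0(prefix, paste(segs, collapse = core), suffix)
}

#' Translate the constant region and the variant C-termini
#'
#' Translates the constant *pilV* region (from `constant5` start, which must
#' be in frame, to the first sfx core) and, for each cassette and
#' orientation, the C-terminal continuation that would be fused in frame
#' when that cassette sits adjacent to the constant region: translation of
#' the oriented cassette sequence from the junction reading frame to its
#' first stop codon.
#'
#' @param locus A `shufflon_locus`.
#' @param genetic_code NCBI translation table id (default `"11"`, bacterial).
#' @return A list: `constant_aa` (protein string) and `variants`, a tibble
#'   with `label`, `cassette_id`, `orientation`, `aa_seq`, `length_aa`
#'   (stop codon excluded).
#' @export
extract_variants <- function(locus, genetic_code = "11") {
  code <- Biostrings::getGeneticCode(genetic_code)
  c5 <- substring(locus$sequence, locus$constant5[["start"]], locus$constant5[["end"]])
  L5 <- nchar(c5)
  usable <- 3L * (L5 %/% 3L)
  const_codons <- codons_of(substring(c5, 1L, usable))
  const_aa <- paste(code[const_codons], collapse = "")
  if (grepl("\\*", const_aa)) {
    abort("internal stop codon in the constant pilV region")
  }
  # reading-frame offset into a cassette that directly follows the core
  p0 <- (3L - L5 %% 3L) %% 3L
  rows <- list()
  for (r in seq_len(nrow(locus$cassettes))) {
    id <- locus$cassettes$id[r]
    mrow <- which(locus$model$id == id)
    for (o in c("+", "-")) {
      s <- cassette_seq(locus, id, o)
      cds <- substring(s, p0 + 1L, nchar(s))
      cods <- codons_of(cds)
      aas <- code[cods]
      stop_at <- which(aas == "*")[1]
      if (is.na(stop_at)) {
        abort(sprintf("cassette %d (%s): no stop codon in the fused reading frame", id, o))
      }
      aa_seq <- paste(aas[seq_len(stop_at - 1L)], collapse = "")
      rows[[length(rows) + 1L]] <- tibble(
        label = if (o == "+") locus$model$label_plus[mrow] else locus$model$label_minus[mrow],
        cassette_id = id,
        orientation = o,
        aa_seq = aa_seq,
        length_aa = nchar(aa_seq)
      )
    }
  }
  list(constant_aa = const_aa, variants = dplyr::bind_rows(rows))
}
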