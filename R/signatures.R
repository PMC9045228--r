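#' Build per-variant junction signatures
#'
#' Each expressible variant is identified by a short footprint spanning the
#' junction between the constant *pilV* 3' end and the adjacent cassette:
#' the last `c` bases of the constant side (ending at, and including, the
#' 7-bp sfx core) concatenated with the first `k - c` bases of the cassette
#' in the relevant orientation. With the defaults (`k = 39`, `c = 19`) this
#' is the classic 39-bp variant signature. If two signatures collide (or one
#' equals another's reverse complement), `k` is grown symmetrically (one
#' base on each side) until all are unique; the final `k` is reported in the
#' result.
#'
#' @param locus A `shufflon_locus`.
#' @param k Total signature length (default 39).
#' @param c Bases contributed by the constant side (default 19); requires
#'   `1 <= c < k`.
#' @return A tibble with one row per (cassette, orientation): `label`,
#'   `cassette_id`, `orientation`, `kmer`, `k`, `c`.
#' @export
make_signatures <- function(locus, k = 39L, c = 19L) {
  k <- stopifnot_scalar_int(k, "k", min = 2L)
  c <- stopifnot_scalar_int(c, "c", min = 1L)
  if (c >= k) abort("`c` must satisfy 1 <= c < k")
  core_end <- locus$constant5[["end"]]
  n <- nrow(locus$cassettes)
  if (n < 1L) abort("locus has no cassettes")
  min_cas <- min(locus$cassettes$length_bp)
  if (min_cas < k - c) {
    abort(sprintf(
      "cassette of %d bp shorter than the %d cassette-side signature bases",
      min_cas, k - c
    ))
  }
  build <- function(k, c) {
    const_side <- substring(locus$sequence, core_end - c + 1L, core_end)
    rows <- list()
    for (r in seq_len(n)) {
      id <- locus$cassettes$id[r]
      mrow <- which(locus$model$id == id)
      for (o in c("+", "-")) {
        cs <- cassette_seq(locus, id, o)
        rows[[length(rows) + 1L]] <- tibble(
          label = if (o == "+") locus$model$label_plus[mrow] else locus$model$label_minus[mrow],
          cassette_id = id,
          orientation = o,
          kmer = paste0(const_side, substring(cs, 1L, k - c)),
          k = k,
          c = c
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  colliding_pair <- function(sig) {
    rc <- revcomp(sig$kmer)
    for (a in seq_len(nrow(sig) - 1L)) {
      for (b in seq((a + 1L), nrow(sig))) {
        if (sig$kmer[a] == sig$kmer[b] || sig$kmer[a] == rc[b]) {
          return(c(sig$label[a], sig$label[b]))
        }
      }
    }
    NULL
  }
  repeat {
    sig <- build(k, c)
    pair <- if (n > 0L) colliding_pair(sig) else NULL
    if (is.null(pair)) return(sig)
    k2 <- k + 2L
    c2 <- c + 1L
    if (c2 > core_end - locus$constant5[["start"]] + 1L || k2 - c2 > min_cas) {
      abort(sprintf(
        "irreducible signature collision between variants %s and %s",
        pair[1], pair[2]
      ))
    }
    k <- k2
    c <- c2
  }
}

#' Write signatures as FASTA
#'
#' @param signatures Tibble from [make_signatures()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  set <- Biostrings::DNAStringSet(setNames(signatures$kmer, signatures$label))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read signatures from FASTA
#'
#' @param path FASTA path with one record per variant, label as header.
#' @return A tibble with `label`, `kmer`, `k`.
#' @export
read_signatures <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(
    label = sub("\\s.*$", "", names(set)),
    kmer = unname(as.character(set)),
    k = Biostrings::width(set)
  )
}
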