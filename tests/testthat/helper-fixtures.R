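# Brute-force oracle: all signed permutations of 1..n as canonical keys,
# built without the package's BFS enumeration.
all_signed_perms <- function(n) {
  if (n == 0L) return("")
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  keys <- character(0)
  signs <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
  for (p in perms(seq_len(n))) {
    for (r in seq_len(nrow(signs))) {
      v <- p * signs[r, ]
      keys <- c(keys, paste0(abs(v), ifelse(v > 0, "+", "-"), collapse = ","))
    }
  }
  sort(unique(keys))
}

# Cache of generated loci so the suite builds each architecture once.
.locus_cache <- new.env(parent = emptyenv())
test_locus <- function(seed = 42L, n = 4L) {
  key <- paste0("s", seed, "n", n)
  if (is.null(.locus_cache[[key]])) {
    .locus_cache[[key]] <- generate_locus(
      generator_config(n_cassettes = n), seed = seed
    )
  }
  .locus_cache[[key]]
}

# Write a minimal FASTQ file from read sequences.
write_test_fastq <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(seqs)) {
    ids <- sprintf("@r%03d", seq_along(seqs))
    writeLines(as.vector(rbind(ids, seqs, "+", strrep("I", nchar(seqs)))), con)
  }
  invisible(path)
}

# Plain-R counting oracle, independent of the Biostrings matching path:
# a read is positive for a signature if it or its reverse complement
# contains the k-mer as an exact substring.
oracle_counts <- function(reads, signatures) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  reads_rc <- vapply(reads, rc, character(1))
  sapply(signatures$kmer, function(k) {
    sum(vapply(seq_along(reads), function(i) {
      grepl(k, reads[i], fixed = TRUE) || grepl(k, reads_rc[i], fixed = TRUE)
    }, logical(1)))
  })
}
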