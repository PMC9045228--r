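#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise ungroup left_join pull rename distinct n
#' @importFrom stats rbinom runif sd
#' @importFrom stats setNames
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# reverse complement for plain character vectors (ACGTN only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sample a random DNA string avoiding a set of motifs (both given verbatim);
# uses the current RNG stream, resampling whole string on a hit
random_dna <- function(len, gc = 0.5, avoid = character(0), max_tries = 100L) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  for (i in seq_len(max_tries)) {
    s <- paste(sample(DNA_BASES, len, replace = TRUE, prob = probs), collapse = "")
    if (!length(avoid) || !any(vapply(avoid, grepl, logical(1), x = s, fixed = TRUE))) {
      return(s)
    }
  }
  abort(sprintf("could not sample %d bp avoiding the given motifs", len))
}

# n random sense-strand codons, none of them stop codons
random_codons <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  codons <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cd <- random_dna(3L, gc = gc)
      if (!cd %in% STOP_CODONS) break
    }
    codons[i] <- cd
  }
  paste(codons, collapse = "")
}

# split a string into its in-frame codons
codons_of <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

has_inframe_stop <- function(x) any(codons_of(x) %in% STOP_CODONS)

stopifnot_scalar_int <- function(x, name, min = NULL) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer", name))
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %d", name, min))
  }
  invisible(as.integer(x))
}
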