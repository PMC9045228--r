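#' Read a shufflon locus sequence
#'
#' Reads a nucleotide sequence plus any feature annotations from a FASTA
#' file (plain or gzip-compressed; via Biostrings) or a GenBank flat file
#' (minimal built-in reader covering LOCUS, FEATURES and ORIGIN). GenBank
#' features are surfaced so that annotated recombination sites
#' (`misc_recomb`) or an annotated CDS start can seed downstream steps
#' instead of de novo detection.
#'
#' @param path Path to the file.
#' @param format `"auto"` (from extension), `"fasta"` or `"genbank"`.
#' @return A list with elements `name`, `sequence` (uppercase character
#'   string) and `features` (tibble with columns `type`, `start`, `end`,
#'   `strand`, `label`; empty for FASTA).
#' @export
read_locus <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(gb|gbk|genbank)$", base, ignore.case = TRUE)) "genbank" else "fasta"
  }
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) abort(sprintf("cannot parse FASTA '%s': %s", path, conditionMessage(e)))
    )
    if (!length(set) || Biostrings::width(set)[1] == 0L) {
      abort(sprintf("no sequence in '%s'", path))
    }
    list(
      name = sub("\\s.*$", "", names(set)[1]),
      sequence = toupper(as.character(set[[1]])),
      features = empty_features()
    )
  } else {
    read_genbank_flat(path)
  }
}

empty_features <- function() {
  tibble(
    type = character(0), start = integer(0), end = integer(0),
    strand = character(0), label = character(0)
  )
}

# Minimal GenBank flat-file reader: LOCUS name, FEATURES with simple
# "start..end" / "complement(start..end)" locations and /label= or /gene=
# qualifiers, ORIGIN sequence. Enough for annotated shufflon records.
read_genbank_flat <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    abort(sprintf("'%s' does not look like a GenBank flat file", path))
  }
  name <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) abort(sprintf("no ORIGIN section in '%s'", path))
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(sequence)) abort(sprintf("empty sequence in '%s'", path))

  feats <- empty_features()
  if (length(fstart)) {
    block <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # feature lines start at column 6; continuation/qualifier at column 22
    is_new <- grepl("^ {5}\\S", block)
    idx <- which(is_new)
    rows <- list()
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      header <- trimws(block[from])
      parts <- strsplit(header, "\\s+")[[1]]
      type <- parts[1]
      loc <- paste(parts[-1], collapse = "")
      quals <- block[(from + 1L):to]
      quals <- if (from < to) trimws(quals) else character(0)
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) < 1L) next
      start <- min(nums); end <- max(nums)
      lab <- NA_character_
      for (q in quals) {
        m <- regmatches(q, regexec('^/(label|gene|note|product)="?([^"]*)"?$', q))[[1]]
        if (length(m) == 3L) { lab <- m[3]; break }
      }
      rows[[length(rows) + 1L]] <- tibble(
        type = type, start = start, end = end, strand = strand, label = lab
      )
    }
    if (length(rows)) feats <- dplyr::bind_rows(rows)
  }
  list(name = name, sequence = sequence, features = feats)
}

#' Write a locus sequence to FASTA or GenBank
#'
#' @param sequence Nucleotide sequence (character string).
#' @param path Output path; a `.gz` suffix gzip-compresses FASTA output.
#' @param name Record name.
#' @param features Optional tibble (`type`, `start`, `end`, `strand`,
#'   `label`) written as GenBank features.
#' @param format `"fasta"` or `"genbank"`.
#' @return `path`, invisibly.
#' @export
write_locus <- function(sequence, path, name = "locus",
                        features = NULL, format = c("fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(setNames(sequence, name))
    Biostrings::writeXStringSet(set, path, compress = grepl("\\.gz$", path))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    n <- nchar(sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   SYN", name, n), con)
    writeLines(sprintf("DEFINITION  %s.", name), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    if (!is.null(features) && nrow(features)) {
      for (i in seq_len(nrow(features))) {
        loc <- sprintf("%d..%d", features$start[i], features$end[i])
        if (!is.na(features$strand[i]) && features$strand[i] == "-") {
          loc <- sprintf("complement(%s)", loc)
        }
        writeLines(sprintf("     %-15s %s", features$type[i], loc), con)
        if (!is.na(features$label[i])) {
          writeLines(sprintf("                     /label=\"%s\"", features$label[i]), con)
        }
      }
    }
    writeLines("ORIGIN", con)
    starts <- seq(1L, n, by = 60L)
    for (s in starts) {
      chunk <- substring(sequence, s, min(s + 59L, n))
      tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", s, paste(tolower(tens), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}
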