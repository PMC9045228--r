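#' Construct a shufflon model
#'
#' A shufflon is a set of `n` invertible DNA cassettes downstream of the
#' constant 5' region of *pilV*, each carrying two convergent open reading
#' frames. The cassette adjacent to the constant region contributes the
#' C-terminal variant of the PilV adhesin that is actually expressed; which
#' ORF is used depends on the cassette's orientation. The model records, per
#' cassette, the variant label expressed in each orientation.
#'
#' @param cassettes Optional data frame with columns `id` (1..n),
#'   `label_plus`, `label_minus` and optionally `length_bp`. If omitted, a
#'   default n-cassette model is built with labels `A/A'`, `B/B'`, ...
#' @param n Number of cassettes used when `cassettes` is omitted (default 4,
#'   the TP114-like architecture with 8 variants).
#' @return A tibble of cassette specifications with class `shufflon_model`.
#' @examples
#' shufflon_model(n = 4)
#' @export
shufflon_model <- function(cassettes = NULL, n = 4L) {
  if (is.null(cassettes)) {
    n <- stopifnot_scalar_int(n, "n", min = 0L)
    if (n > 26L) abort("default labels support at most 26 cassettes")
    cassettes <- tibble(
      id = seq_len(n),
      label_plus = LETTERS[seq_len(n)],
      label_minus = paste0(LETTERS[seq_len(n)], "'"),
      length_bp = NA_integer_
    )
  }
  cassettes <- as_tibble(cassettes)
  required <- c("id", "label_plus", "label_minus")
  if (!all(required %in% names(cassettes))) {
    abort("`cassettes` needs columns id, label_plus, label_minus")
  }
  if (!"length_bp" %in% names(cassettes)) cassettes$length_bp <- NA_integer_
  if (anyDuplicated(cassettes$id)) abort("cassette ids must be distinct")
  labels <- c(cassettes$label_plus, cassettes$label_minus)
  if (anyDuplicated(labels)) abort("variant labels must be unique across the model")
  if (any(cassettes$label_plus == cassettes$label_minus)) {
    abort("label_plus and label_minus must differ within a cassette")
  }
  cassettes <- cassettes[order(cassettes$id), , drop = FALSE]
  structure(cassettes, class = c("shufflon_model", class(tibble())))
}

n_cassettes <- function(model) nrow(model)

#' Parse or construct a conformation
#'
#' A conformation is one physical arrangement of the shufflon cassettes:
#' an ordered list of (cassette id, orientation). It is represented as a
#' signed integer vector (sign = orientation) and serialises to a compact
#' key such as `"1+,3-,2+,4-"`.
#'
#' @param x A signed integer vector, a key string like `"1+,2-,..."`, or an
#'   existing conformation.
#' @return An integer vector of class `shufflon_conformation`.
#' @examples
#' conformation("1+,3-,2+,4-")
#' identity_conformation(4)
#' @export
conformation <- function(x) {
  if (inherits(x, "shufflon_conformation")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x == "") {
      v <- integer(0)
    } else {
      toks <- strsplit(x, ",", fixed = TRUE)[[1]]
      ok <- grepl("^[0-9]+[+-]$", toks)
      if (!all(ok)) abort(sprintf("cannot parse conformation key '%s'", x))
      ids <- as.integer(sub("[+-]$", "", toks))
      sgn <- ifelse(grepl("\\+$", toks), 1L, -1L)
      v <- ids * sgn
    }
  } else if (is.numeric(x)) {
    if (any(x == 0) || any(x != as.integer(x))) {
      abort("a conformation is a vector of signed non-zero integers")
    }
    v <- as.integer(x)
  } else {
    abort("cannot interpret `x` as a conformation")
  }
  if (anyDuplicated(abs(v))) abort("cassette ids must appear exactly once")
  structure(v, class = "shufflon_conformation")
}

#' @rdname conformation
#' @param n Number of cassettes.
#' @export
identity_conformation <- function(n) {
  n <- stopifnot_scalar_int(n, "n", min = 0L)
  conformation(seq_len(n))
}

#' Serialise a conformation to its canonical key
#'
#' @param conf A conformation (or anything [conformation()] accepts).
#' @return A string such as `"1+,3-,2+,4-"`; the empty conformation gives `""`.
#' @export
conformation_key <- function(conf) {
  v <- unclass(conformation(conf))
  if (!length(v)) return("")
  paste0(abs(v), ifelse(v > 0, "+", "-"), collapse = ",")
}

#' @export
format.shufflon_conformation <- function(x, ...) {
  paste0("<conformation [", conformation_key(x), "]>")
}

#' @export
print.shufflon_conformation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.shufflon_conformation <- function(x, ...) conformation_key(x)

#' Invert a contiguous block of cassettes
#'
#' Models one Rci-mediated recombination event between two sfx sites: the
#' cassettes at positions `i..j` (1-based, inclusive) appear in reversed
#' order with every orientation flipped. Applying the same inversion twice
#' restores the input (the operation is an involution).
#'
#' @param conf A conformation.
#' @param i,j Block boundaries, `1 <= i <= j <= n`.
#' @return A new conformation; the input is not modified.
#' @examples
#' invert_block(conformation("1+,2+,3+,4+"), 2, 3)
#' @export
invert_block <- function(conf, i, j) {
  conf <- conformation(conf)
  v <- unclass(conf)
  n <- length(v)
  i <- stopifnot_scalar_int(i, "i")
  j <- stopifnot_scalar_int(j, "j")
  if (i < 1L || j > n || i > j) {
    abort(sprintf("block [%d, %d] out of range for %d cassettes", i, j, n))
  }
  v[i:j] <- -rev(v[i:j])
  conformation(v)
}

# all contiguous block reversals (i, j) for an n-cassette shufflon
block_moves <- function(n) {
  if (n == 0L) return(matrix(integer(0), ncol = 2L))
  idx <- which(upper.tri(matrix(0L, n, n), diag = TRUE), arr.ind = TRUE)
  cbind(i = idx[, "row"], j = idx[, "col"])
}

#' Enumerate all reachable shufflon conformations
#'
#' Computes the closure of the identity conformation under all contiguous
#' block inversions by breadth-first search. For `n >= 1` cassettes this
#' closure is the full set of signed permutations, of size `n! * 2^n`
#' (384 for the four-cassette TP114-like shufflon).
#'
#' @param model A `shufflon_model`, or a single integer taken as the number
#'   of cassettes of a default model.
#' @param moves Optional two-column matrix of allowed `(i, j)` block
#'   reversals; defaults to every contiguous block.
#' @return A tibble with one row per conformation: `conformation` (canonical
#'   key), `arrangement` (list column of signed integer vectors) and, when
#'   labels are available, `active_variant`. Rows are sorted
#'   deterministically by arrangement.
#' @examples
#' nrow(enumerate_conformations(3)) # 48
#' @export
enumerate_conformations <- function(model = 4L, moves = NULL) {
  if (!inherits(model, "shufflon_model")) model <- shufflon_model(n = model)
  n <- n_cassettes(model)
  if (n == 0L) {
    return(tibble(conformation = "", arrangement = list(integer(0))))
  }
  moves <- moves %||% block_moves(n)
  start <- identity_conformation(n)
  seen <- new.env(parent = emptyenv())
  queue <- list(start)
  assign(conformation_key(start), TRUE, envir = seen)
  out <- list(start)
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (m in seq_len(nrow(moves))) {
      nxt <- invert_block(cur, moves[m, 1L], moves[m, 2L])
      key <- conformation_key(nxt)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- nxt
        out[[length(out) + 1L]] <- nxt
      }
    }
  }
  arr <- lapply(out, unclass)
  # deterministic order: lexicographic on (|id|, sign) pairs
  ord_mat <- do.call(rbind, lapply(arr, function(v) as.vector(rbind(abs(v), v < 0))))
  ord <- do.call(order, as.data.frame(ord_mat))
  arr <- arr[ord]
  res <- tibble(
    conformation = vapply(arr, function(v) conformation_key(conformation(v)), character(1)),
    arrangement = arr
  )
  if (!all(is.na(model$label_plus))) {
    res$active_variant <- vapply(
      res$arrangement,
      function(v) active_variant(conformation(v), model),
      character(1)
    )
  }
  res
}

#' Variant expressed by a conformation
#'
#' Returns the PilV C-terminus variant fused in frame to the constant *pilV*
#' region: the cassette at position 1 contributes `label_plus` in `+`
#' orientation and `label_minus` in `-` orientation.
#'
#' @param conf A conformation.
#' @param model The `shufflon_model` providing cassette labels.
#' @return A variant label (length-1 character).
#' @export
active_variant <- function(conf, model) {
  conf <- conformation(conf)
  v <- unclass(conf)
  if (!length(v)) abort("the empty conformation expresses no variant")
  id <- abs(v[1L])
  row <- which(model$id == id)
  if (!length(row)) abort(sprintf("cassette %d not in model", id))
  if (v[1L] > 0) model$label_plus[row] else model$label_minus[row]
}

#' Number of distinct expressible variants
#'
#' Evaluates [active_variant()] over the full conformation enumeration and
#' counts the distinct labels; equals `2n` for an n-cassette shufflon
#' (8 for TP114).
#'
#' @inheritParams enumerate_conformations
#' @return An integer count.
#' @export
count_active_variants <- function(model = 4L) {
  if (!inherits(model, "shufflon_model")) model <- shufflon_model(n = model)
  if (n_cassettes(model) == 0L) return(0L)
  confs <- enumerate_conformations(model)
  length(unique(confs$active_variant))
}
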