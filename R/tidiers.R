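#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname shufflonr-tidiers
#' @param x A `shufflon_locus`, `shufflon_counts` or `shufflon_abundance`.
#' @param ... Unused.
#' @method tidy shufflon_locus
#' @export
tidy.shufflon_locus <- function(x, ...) {
  bind_rows(
    tibble(
      feature = "constant5", start = x$constant5[["start"]],
      end = x$constant5[["end"]], strand = "+", name = "pilV constant region"
    ),
    tibble(
      feature = "sfx_site", start = x$sites$start, end = x$sites$end,
      strand = x$sites$strand,
      name = paste0("sfx", seq_len(nrow(x$sites)))
    ),
    tibble(
      feature = "cassette", start = x$cassettes$start, end = x$cassettes$end,
      strand = "+", name = paste0("cassette", x$cassettes$id)
    ),
    tibble(
      feature = "constant3", start = x$constant3[["start"]],
      end = x$constant3[["end"]], strand = "+", name = "toward rci"
    )
  ) |> arrange(.data$start)
}

#' Tidiers for shufflon objects
#'
#' [tidy()] returns per-element tables (locus features, per-variant counts);
#' [glance()] returns one-row summaries.
#'
#' @name shufflonr-tidiers
NULL

#' @rdname shufflonr-tidiers
#' @method glance shufflon_locus
#' @export
glance.shufflon_locus <- function(x, ...) {
  n <- nrow(x$cassettes)
  tibble(
    length_bp = nchar(x$sequence),
    n_sites = nrow(x$sites),
    n_cassettes = n,
    n_variants = 2L * n,
    n_conformations = factorial(n) * 2^n
  )
}

#' @rdname shufflonr-tidiers
#' @method tidy shufflon_counts
#' @export
tidy.shufflon_counts <- function(x, ...) {
  tibble(variant = x$variant, count = x$count)
}

#' @rdname shufflonr-tidiers
#' @method glance shufflon_counts
#' @export
glance.shufflon_counts <- function(x, ...) {
  tibble(
    n_reads_scanned = attr(x, "n_reads_scanned"),
    total_positive = attr(x, "total_positive"),
    ambiguous = attr(x, "ambiguous"),
    unmatched = attr(x, "unmatched")
  )
}

#' @rdname shufflonr-tidiers
#' @method glance shufflon_abundance
#' @export
glance.shufflon_abundance <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_detected = sum(x$count > 0),
    total_positive = attr(x, "total_positive"),
    max_frequency = max(x$frequency)
  )
}
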