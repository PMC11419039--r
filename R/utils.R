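#' The eight alternative-splicing event categories
#'
#' Category labels used throughout the package, in canonical order: cassette
#' exon, mutually exclusive exons, coordinate cassette exons, alternative
#' 5'/3' splice site, alternative first/last exon, and intron retention.
#'
#' @format Character vector of length 8.
#' @export
EVENT_TYPES <- c(
  "cassette", "mutually_exclusive", "coordinate_cassette",
  "alt_5ss", "alt_3ss", "alt_first_exon", "alt_last_exon",
  "intron_retention"
)

# argument order matters: pmin/pmax take attributes (matrix dims) from
# their first argument
clamp_psi <- function(x) pmin(pmax(x, 0), 100)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# derive a deterministic sub-stream from a master seed; keeps the effective
# seed inside 32-bit integer range
with_sub_seed <- function(seed, offset, code) {
  s <- as.integer((as.numeric(seed) + as.numeric(offset)) %% 2147483647)
  withr::with_seed(s, code)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(miss, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_fraction <- function(x, name) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  invisible(x)
}
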