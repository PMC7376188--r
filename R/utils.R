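#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# GRCh38 coordinates are printed with thousands separators ("84,160,226")
# and an en dash between interval ends, as forensic nomenclature guides do.
fmt_coord <- function(x) {
  formatC(x, big.mark = ",", format = "d")
}

parse_coord <- function(x) {
  as.integer(gsub(",", "", x, fixed = TRUE))
}

# en dash used between coordinates in canonical names
EN_DASH <- "–"

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ..., class = "forenseqr_error") {
  abort(sprintf(fmt, ...), class = class)
}
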