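# Internal helpers: argument checks and circular-interval arithmetic.
# Coordinates are 0-based; intervals are half-open [start, start+length)
# taken modulo the plasmid length.

stop_bad <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_bad(name, " must be a single non-missing number")
  if (x < lower || x > upper)
    stop_bad(name, " must be in [", lower, ", ", upper, "], got ", x)
  if (!allow_zero && x == 0)
    stop_bad(name, " must be non-zero")
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_bad(name, " must be TRUE or FALSE")
  invisible(x)
}

#' @noRd
circ_dist <- function(a, b, length_bp) {
  d <- abs(a - b) %% length_bp
  pmin(d, length_bp - d)
}

# Is position `pos` inside the circular half-open interval [start, start+len)?
circ_contains <- function(start, len, pos, length_bp) {
  ((pos - start) %% length_bp) < len
}

# Split a circular interval into 1 or 2 linear segments within [0, L).
# Returns a matrix with columns start, end (half-open, linear).
circ_segments <- function(start, len, length_bp) {
  start <- start %% length_bp
  len <- min(len, length_bp)
  if (start + len <= length_bp) {
    cbind(start = start, end = start + len)
  } else {
    cbind(start = c(start, 0), end = c(length_bp, (start + len) %% length_bp))
  }
}

# Overlap length between two circular intervals.
circ_overlap_len <- function(s1, l1, s2, l2, length_bp) {
  a <- circ_segments(s1, l1, length_bp)
  b <- circ_segments(s2, l2, length_bp)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      tot <- tot + max(0, min(a[i, "end"], b[j, "end"]) -
                          max(a[i, "start"], b[j, "start"]))
    }
  }
  tot
}

# Round to the 2-significant-figure convention used for headline estimates.
#' Round a value to two significant figures
#'
#' Headline genome-scale estimates are conventionally printed at two
#' significant figures; this helper applies that rounding while the
#' calculators themselves always return full-precision values.
#'
#' @param x numeric vector.
#' @return `signif(x, 2)`.
#' @export
paper_round <- function(x) signif(x, 2)
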