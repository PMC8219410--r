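#' The five-level attention scale
#'
#' Attention states are scored on a five-level ordinal scale. Internally
#' levels are integer codes 0 (low) through 4 (high); user-facing functions
#' also accept the level names.
#'
#' @return Character vector of the five level names, ordered from low (code 0)
#'   to high (code 4).
#' @export
#' @examples
#' attention_levels()
attention_levels <- function() {
  c("low", "medium-low", "medium", "medium-high", "high")
}

#' Coerce to attention level codes
#'
#' @param x Integer codes in 0..4, level names, or a factor over the level
#'   names.
#' @return Integer vector of codes in 0..4.
#' @export
as_attention_level <- function(x) {
  lv <- attention_levels()
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    m <- match(x, lv)
    if (anyNA(m)) {
      abort_fmt("unknown attention level(s): %s (expected one of %s)",
                paste(unique(x[is.na(m)]), collapse = ", "),
                paste(lv, collapse = ", "))
    }
    return(m - 1L)
  }
  if (!is.numeric(x) || anyNA(x) || any(x != as.integer(x)) ||
      any(x < 0) || any(x > 4)) {
    abort_fmt("attention level codes must be integers in 0..4")
  }
  as.integer(x)
}

#' Attention level names from codes
#' @param code Integer codes in 0..4.
#' @return Character vector of level names.
#' @export
attention_level_name <- function(code) {
  attention_levels()[as_attention_level(code) + 1L]
}
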