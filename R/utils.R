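`%||%` <- function(x, y) if (is.null(x)) y else x

trim_ws <- function(x) gsub("^[[:space:]]+|[[:space:]]+$", "", x)

# canonical gene symbol form used everywhere: trimmed, upper case
normalize_symbols <- function(x) toupper(trim_ws(x))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}
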