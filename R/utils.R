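#' @importFrom rlang %||% abort warn
#' @importFrom stats setNames
NULL

# Byte-order (C locale) sort, deterministic across platforms/locales.
radix_order <- function(...) order(..., method = "radix")

radix_sort <- function(x) x[radix_order(x)]

# Collapse a character vector into the "a|b|c" cell form used by the CSV
# serialisation of list-columns; "" encodes the empty list.
pack_list_col <- function(x) {
  vapply(x, function(v) {
    v <- v[!is.na(v) & nzchar(v)]
    if (any(grepl("|", v, fixed = TRUE))) {
      abort("list values may not contain the reserved character '|'")
    }
    paste(v, collapse = "|")
  }, character(1))
}

unpack_list_col <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, "|", fixed = TRUE)[[1]]
  })
}

# Portions serialise as "label=amount|label=amount". Amounts use %.17g so the
# numeric round-trips exactly through text.
pack_portions <- function(x) {
  vapply(x, function(p) {
    if (is.null(p) || nrow(p) == 0) return("")
    if (any(grepl("[|=]", p$label))) {
      abort("portion labels may not contain the reserved characters '|' or '='")
    }
    paste(sprintf("%s=%.17g", p$label, p$amount), collapse = "|")
  }, character(1))
}

unpack_portions <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) return(empty_portions())
    parts <- strsplit(strsplit(v, "|", fixed = TRUE)[[1]], "=", fixed = TRUE)
    tibble::tibble(
      label = vapply(parts, `[`, character(1), 1),
      amount = as.numeric(vapply(parts, `[`, character(1), 2))
    )
  })
}

empty_portions <- function() tibble::tibble(label = character(0), amount = numeric(0))

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)
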