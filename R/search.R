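#' Normalise a food name or query
#'
#' Canonicalisation applied identically to indexed names and incoming
#' queries, so the failure modes seen in usability testing cannot recur:
#' lowercase; apostrophes deleted (`"cow's milk"` and `"cows milk"` agree);
#' `"&"` expanded to `" and "`; hyphens deleted so the fragments join
#' (`"Weet-Bix"` matches `"weetbix"`); all other punctuation becomes a
#' space; whitespace collapses to single spaces. The function is
#' deterministic and idempotent.
#'
#' @param text Character vector of raw names or queries.
#' @return Normalised character vector.
#' @export
#' @examples
#' normalize_food_text(c("Weet-Bix", "cow's milk", "ham & pineapple"))
normalize_food_text <- function(text) {
  x <- tolower(text)
  x <- gsub("['’ʼ]", "", x)
  x <- gsub("&", " and ", x, fixed = TRUE)
  x <- gsub("-", "", x, fixed = TRUE)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub(" +", " ", x))
}

#' Build a search index
#'
#' Indexes every food under its normalised display name, a space-collapsed
#' variant of it (so `"icecream"` finds `"Ice cream, vanilla"`), its word
#' tokens, and all its synonyms (also normalised and collapsed). Curated
#' keyword shortlists — ordered food-ID lists surfaced when the query
#' exactly equals the keyword — are normalised and checked against the
#' database.
#'
#' @param records Validated food database tibble.
#' @param keyword_map Named list: keyword -> ordered character vector of
#'   food IDs to surface for that keyword.
#' @return A `search_index`.
#' @export
build_search_index <- function(records, keyword_map = list()) {
  norm_name <- normalize_food_text(records$display_name)
  collapse <- function(x) gsub(" ", "", x, fixed = TRUE)
  syn_norm <- lapply(records$synonyms, normalize_food_text)
  kw <- list()
  if (length(keyword_map)) {
    names(keyword_map) <- normalize_food_text(names(keyword_map))
    unknown <- setdiff(unlist(keyword_map), records$food_id)
    if (length(unknown)) {
      abort(paste0("config error: keyword shortlist references unknown food ID(s): ",
                   paste(unknown, collapse = ", ")))
    }
    kw <- keyword_map
  }
  # per-record keyword annotations also become shortlist entries (appended
  # after any curated list, in food-ID order)
  rec_kw <- lapply(records$keywords, normalize_food_text)
  for (i in radix_order(records$food_id)) {
    for (k in rec_kw[[i]]) {
      if (!nzchar(k)) next
      kw[[k]] <- c(kw[[k]], records$food_id[i])
    }
  }
  kw <- lapply(kw, unique)

  structure(list(
    food_id = records$food_id,
    display_name = records$display_name,
    norm_name = norm_name,
    norm_name_collapsed = collapse(norm_name),
    tokens = strsplit(norm_name, " ", fixed = TRUE),
    synonyms = syn_norm,
    synonyms_collapsed = lapply(syn_norm, collapse),
    keyword_map = kw
  ), class = "search_index")
}

#' @export
print.search_index <- function(x, ...) {
  cat(sprintf("<search_index> %d foods, %d keyword shortlists\n",
              length(x$food_id), length(x$keyword_map)))
  invisible(x)
}

#' Search the food database
#'
#' Deterministic tiered ranking. Tier 0: if the normalised query equals a
#' curated keyword, that shortlist in curated order. Tier 1: foods whose
#' normalised display name equals the normalised query. Tier 2: foods whose
#' name contains every query token as a whole word (AND semantics),
#' alphabetically by normalised name. Tier 3: foods whose normalised or
#' space-collapsed name or synonyms contain the query as a substring,
#' alphabetically. A food appearing in several tiers keeps its best tier;
#' the list is truncated to `limit`.
#'
#' @param index A [build_search_index()] index.
#' @param query Raw query text.
#' @param limit Maximum results to return (>= 1).
#' @return Tibble `rank`, `tier`, `food_id`, `display_name`; zero rows when
#'   the query normalises to nothing or matches nothing.
#' @export
search_foods <- function(index, query, limit = 20L) {
  stopifnot(inherits(index, "search_index"))
  if (!is_count(limit) || limit < 1) abort("limit must be >= 1")
  q <- normalize_food_text(query)
  empty <- tibble(rank = integer(0), tier = integer(0),
                  food_id = character(0), display_name = character(0))
  if (!nzchar(q)) return(empty)
  qc <- gsub(" ", "", q, fixed = TRUE)
  alpha <- function(i) i[radix_order(index$norm_name[i], index$food_id[i])]

  tier0 <- match(index$keyword_map[[q]] %||% character(0), index$food_id)
  tier1 <- alpha(which(index$norm_name == q))
  qtok <- strsplit(q, " ", fixed = TRUE)[[1]]
  tier2 <- alpha(which(vapply(index$tokens, function(tk) all(qtok %in% tk), logical(1))))
  tier3 <- alpha(which(
    grepl(q, index$norm_name, fixed = TRUE) |
      grepl(qc, index$norm_name_collapsed, fixed = TRUE) |
      vapply(index$synonyms, function(s) any(grepl(q, s, fixed = TRUE)), logical(1)) |
      vapply(index$synonyms_collapsed, function(s) any(grepl(qc, s, fixed = TRUE)), logical(1))
  ))

  rows <- c(tier0, tier1, tier2, tier3)
  tiers <- rep(c(0L, 1L, 2L, 3L), c(length(tier0), length(tier1),
                                    length(tier2), length(tier3)))
  keep <- !duplicated(rows)
  rows <- rows[keep][seq_len(min(limit, sum(keep)))]
  tiers <- tiers[keep][seq_along(rows)]
  tibble(
    rank = seq_along(rows),
    tier = tiers,
    food_id = index$food_id[rows],
    display_name = index$display_name[rows]
  )
}
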