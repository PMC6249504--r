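#' Default chain pseudo-classification
#'
#' Branded chain items have no position in the generic 8-character hierarchy,
#' so they are filed under a reserved pseudo major group ("90", branded
#' ready-to-eat) with one sub-major per menu category. Codes are
#' configuration, not data: pass a modified copy to [chain_to_food_records()]
#' to re-map categories.
#'
#' @return Tibble with `category`, `major_code`, `sub_major_code`,
#'   `minor_code` and level labels.
#' @export
chain_categories <- function() {
  cats <- c("burger", "chicken", "pizza", "bakery", "salad",
            "ice_cream", "beverage", "cafe", "other")
  tibble(
    category = cats,
    major_code = "90",
    sub_major_code = paste0("90", LETTERS[seq_along(cats)]),
    minor_code = paste0("90", LETTERS[seq_along(cats)], "01"),
    major_label = "Branded ready-to-eat foods",
    sub_major_label = paste("Chain", gsub("_", " ", cats), "items"),
    minor_label = gsub("_", " ", cats)
  )
}

#' Load a chain menu file
#'
#' Reads one chain's menu CSV. Nutrition information for chain items covers
#' only the seven mandatory label nutrients (energy, protein, total and
#' saturated fat, carbohydrate, sugars, sodium); values may arrive per
#' 100 g/mL or per serve — per-serve values are rescaled to per-100 using
#' the serve size. Rows flagged unavailable (column `available` = `FALSE`/
#' `no`/`0`) are dropped; per-serve rows without a serve size are rejected
#' row-by-row with a reason rather than failing the file.
#'
#' @param path CSV with columns `item_name`, `basis` (`per_100` or
#'   `per_serve`), `serve_size`, `unit` (`g`/`mL`), optional `category`,
#'   optional `available`, and the seven nutrient columns.
#' @param chain_name Chain the menu belongs to.
#' @return Tibble of menu items (per-100 basis) with attribute `rejected`
#'   holding the rejected rows and reasons.
#' @export
load_chain_menu <- function(path, chain_name) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!nzchar(chain_name)) abort("chain_name must be non-empty")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = c("", "NA"))
  nut <- c("energy", label_nutrients())
  need <- c("item_name", "basis", nut)
  miss <- setdiff(c("item_name", "basis"), names(raw))
  if (length(miss)) abort(paste0("schema error: missing column(s): ", paste(miss, collapse = ", ")))
  n <- nrow(raw)
  if (n == 0) {
    out <- tibble(chain_name = character(0), item_name = character(0),
                  category = character(0), unit = character(0),
                  serve_size = numeric(0))
    for (nm in nut) out[[nm]] <- numeric(0)
    attr(out, "rejected") <- tibble(item_name = character(0), reason = character(0))
    return(out)
  }

  num <- function(col) if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else rep(NA_real_, n)
  serve <- num("serve_size")
  unit <- if ("unit" %in% names(raw)) raw$unit else rep("g", n)
  unit[is.na(unit)] <- "g"
  category <- if ("category" %in% names(raw)) raw$category else rep("other", n)
  category[is.na(category)] <- "other"
  available <- if ("available" %in% names(raw)) {
    !tolower(raw$available) %in% c("false", "no", "0")
  } else rep(TRUE, n)

  per_serve <- raw$basis == "per_serve"
  rejected <- per_serve & (is.na(serve) | serve <= 0)

  vals <- vapply(nut, num, numeric(n))
  if (n == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, nut))
  scale <- ifelse(per_serve, 100 / serve, 1)
  vals <- vals * scale

  keep <- available & !rejected
  out <- tibble(
    chain_name = chain_name,
    item_name = raw$item_name[keep],
    category = category[keep],
    unit = unit[keep],
    serve_size = serve[keep]
  )
  for (nm in nut) {
    v <- unname(vals[keep, nm])
    if (any(!is.na(v) & v < 0)) abort(sprintf("negative %s in chain menu %s", nm, path))
    out[[nm]] <- v
  }
  attr(out, "rejected") <- tibble(
    item_name = raw$item_name[rejected],
    reason = "per_serve basis without a positive serve_size"
  )
  out
}

#' Drop label-incomplete chain items
#'
#' Chain items missing any of the seven mandatory label nutrients are
#' omitted from the database. The split is a partition: every input item
#' lands in exactly one of `kept` or `dropped`, and dropped items carry the
#' names of their missing fields.
#'
#' @param items Menu tibble from [load_chain_menu()].
#' @return List with `kept` (complete items) and `dropped` (items plus a
#'   `missing` column naming absent nutrients).
#' @export
drop_incomplete <- function(items) {
  nut <- c("energy", label_nutrients())
  m <- as.matrix(items[, nut])
  missing <- apply(m, 1, function(r) paste(nut[is.na(r)], collapse = ","))
  ok <- !nzchar(missing)
  dropped <- items[!ok, ]
  dropped$missing <- missing[!ok]
  list(kept = items[ok, ], dropped = dropped)
}

#' Convert chain menu items to food records
#'
#' Items get namespaced IDs `CHAIN:<chain-slug>:<seq>`, the chain name
#' appended to the display name (`"Big Mac burger, McDonald's"`), a pseudo
#' classification from the category map, and — when the serve size is known —
#' a "1 serve" portion option. Only the seven label nutrients are stored;
#' the rest of the panel stays absent.
#'
#' @param items Label-complete menu tibble.
#' @param categories Category -> pseudo-classification map
#'   ([chain_categories()]).
#' @return Food database tibble with `source = "chain"`.
#' @export
chain_to_food_records <- function(items, categories = chain_categories()) {
  if (nrow(items) == 0) return(empty_food_db())
  slug <- function(x) gsub("[^a-z0-9]+", "-", tolower(x))
  recs <- vector("list", nrow(items))
  seqno <- stats::ave(seq_len(nrow(items)), items$chain_name, FUN = seq_along)
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    cat_row <- categories[match(it$category, categories$category), ]
    if (is.na(cat_row$major_code)) cat_row <- categories[categories$category == "other", ]
    basis <- if (it$unit == "mL") "per_100_mL" else "per_100_g"
    portions <- if (!is.na(it$serve_size) && it$serve_size > 0) {
      tibble(label = "1 serve", amount = it$serve_size)
    } else empty_portions()
    nutrients <- unlist(it[c("energy", label_nutrients())])
    recs[[i]] <- food_record(
      food_id = sprintf("CHAIN:%s:%04d", slug(it$chain_name), seqno[i]),
      display_name = paste0(it$item_name, ", ", it$chain_name),
      original_name = it$item_name,
      nutrients = nutrients[!is.na(nutrients)],
      major_code = cat_row$major_code, sub_major_code = cat_row$sub_major_code,
      minor_code = cat_row$minor_code,
      major_label = cat_row$major_label, sub_major_label = cat_row$sub_major_label,
      minor_label = cat_row$minor_label,
      basis = basis, source = "chain", chain_name = it$chain_name,
      portions = portions
    )
  }
  bind_rows(recs)
}

#' Combine curated generic foods with chain records
#'
#' Concatenates the two databases, sorted by (source, food ID) in byte
#' order, after checking that no food ID occurs in both. Source counts are
#' attached for reporting.
#'
#' @param generic Curated generic food tibble.
#' @param chain Chain food tibble from [chain_to_food_records()].
#' @return Combined food tibble with attribute `source_counts`.
#' @export
integrate_databases <- function(generic, chain) {
  clash <- intersect(generic$food_id, chain$food_id)
  if (length(clash)) {
    abort(paste0("integrity error: food_id(s) present in both inputs: ",
                 paste(clash, collapse = ", ")))
  }
  out <- bind_rows(generic, chain)
  out <- out[radix_order(out$source, out$food_id), ]
  attr(out, "source_counts") <- c(
    generic = sum(out$source == "generic"),
    chain = sum(out$source == "chain")
  )
  out
}

#' Published-style composition shares
#'
#' Shares of the final database contributed by each source, as whole
#' percentages (the convention used when reporting database composition).
#'
#' @param n_generic,n_chain Record counts per source.
#' @param final_total Total the shares are computed against; defaults to
#'   `n_generic + n_chain`.
#' @return Tibble with `source`, `n`, `pct` (0 dp).
#' @export
database_composition <- function(n_generic, n_chain, final_total = n_generic + n_chain) {
  tibble(
    source = c("generic", "chain"),
    n = c(n_generic, n_chain),
    pct = round(100 * c(n_generic, n_chain) / final_total)
  )
}
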