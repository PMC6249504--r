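#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows coalesce
NULL

# Canonical column order of a food database tibble (and of its CSV form).
food_db_columns <- function() {
  c(
    "food_id", "display_name", "original_name", "synonyms", "keywords",
    "major_code", "sub_major_code", "minor_code",
    "major_label", "sub_major_label", "minor_label",
    "basis", "unit", "source", "chain_name", "portions",
    nutrient_columns()
  )
}

#' Construct a single food record
#'
#' A food database is a tibble with one row per food: an 8-character
#' hierarchical food code (chain items use namespaced `CHAIN:<slug>:<seq>`
#' IDs instead), display and original names, synonym/keyword list-columns, a
#' three-level classification, a per-100 g or per-100 mL nutrient panel
#' (energy in kJ plus the [tracked_nutrients()] panel; absent values are `NA`,
#' which is distinct from a true zero), portion options, and provenance
#' (generic reference food vs branded chain item).
#'
#' @param food_id Food identifier. Generic foods use the 8-character
#'   hierarchical code whose leading 2/3/5 characters are the major,
#'   sub-major and minor classification codes.
#' @param display_name Name shown to app users; must be non-empty. Chain
#'   items must end with `", <chain_name>"`.
#' @param nutrients Named numeric vector of per-100 g/mL amounts. Must
#'   include `energy` (kJ); other names must come from [tracked_nutrients()].
#'   Omitted nutrients are stored as `NA` (unknown), not zero.
#' @param original_name Name as it appeared in the source table (defaults to
#'   `display_name`).
#' @param synonyms,keywords Character vectors of alternative names and
#'   curated search keywords.
#' @param major_code,sub_major_code,minor_code Classification codes; derived
#'   from the leading characters of `food_id` when `NULL` and the ID is an
#'   8-character code.
#' @param major_label,sub_major_label,minor_label Free-text level labels.
#' @param basis `"per_100_g"` or `"per_100_mL"`.
#' @param unit Unit of measurement for amounts of this food, `"g"` or
#'   `"mL"`; must agree with `basis`.
#' @param source `"generic"` or `"chain"`.
#' @param chain_name Chain the item belongs to (chain records only).
#' @param portions Tibble with columns `label`, `amount` (grams or
#'   millilitres, matching `unit`).
#' @return A one-row food database tibble.
#' @export
#' @examples
#' food_record("16A10001", "Apple, green", c(energy = 250, protein = 0.3))
food_record <- function(food_id, display_name, nutrients = c(energy = NA_real_),
                        original_name = display_name,
                        synonyms = character(0), keywords = character(0),
                        major_code = NULL, sub_major_code = NULL,
                        minor_code = NULL,
                        major_label = "", sub_major_label = "", minor_label = "",
                        basis = "per_100_g", unit = if (basis == "per_100_g") "g" else "mL",
                        source = "generic", chain_name = NA_character_,
                        portions = NULL) {
  stopifnot(is.character(food_id), length(food_id) == 1)
  if (!nzchar(display_name)) abort("display_name must be non-empty")
  if (is.null(major_code)) {
    if (!grepl("^[0-9]{2}", food_id) || nchar(food_id) < 5) {
      abort(sprintf("cannot derive classification codes from food_id '%s'; supply them explicitly", food_id))
    }
    major_code <- substr(food_id, 1, 2)
    sub_major_code <- substr(food_id, 1, 3)
    minor_code <- substr(food_id, 1, 5)
  }
  check_classification(major_code, sub_major_code, minor_code)
  if (!basis %in% c("per_100_g", "per_100_mL")) abort("basis must be per_100_g or per_100_mL")
  expected_unit <- if (basis == "per_100_g") "g" else "mL"
  if (unit != expected_unit) {
    abort(sprintf("unit '%s' inconsistent with basis '%s'", unit, basis))
  }
  if (!source %in% c("generic", "chain")) abort("source must be generic or chain")
  if (source == "chain") {
    if (is.na(chain_name) || !nzchar(chain_name)) abort("chain records need a chain_name")
    if (!endsWith(display_name, paste0(", ", chain_name))) {
      abort(sprintf("chain display_name '%s' must end with ', %s'", display_name, chain_name))
    }
  }
  bad <- setdiff(names(nutrients), nutrient_columns())
  if (length(bad)) abort(paste0("unknown nutrient(s): ", paste(bad, collapse = ", ")))
  panel <- setNames(rep(NA_real_, length(nutrient_columns())), nutrient_columns())
  panel[names(nutrients)] <- as.numeric(nutrients)
  if (any(!is.na(panel) & panel < 0)) abort("nutrient amounts must be >= 0")
  portions <- portions %||% empty_portions()

  rec <- tibble(
    food_id = food_id, display_name = display_name, original_name = original_name,
    synonyms = list(as.character(synonyms)), keywords = list(as.character(keywords)),
    major_code = major_code, sub_major_code = sub_major_code, minor_code = minor_code,
    major_label = major_label, sub_major_label = sub_major_label,
    minor_label = minor_label,
    basis = basis, unit = unit, source = source, chain_name = chain_name,
    portions = list(as_tibble(portions))
  )
  for (nm in nutrient_columns()) rec[[nm]] <- unname(panel[nm])
  rec[food_db_columns()]
}

# Zero-row food database with the full column layout.
empty_food_db <- function() {
  food_record("00000000", "placeholder", c(energy = 0))[0, ]
}

check_classification <- function(major, sub_major, minor) {
  ok <- nchar(major) == 2 & nchar(sub_major) == 3 & nchar(minor) == 5 &
    startsWith(sub_major, major) & startsWith(minor, sub_major)
  if (!all(ok)) {
    abort("classification codes must nest: 2-char major, 3-char sub-major prefixed by it, 5-char minor prefixed by the sub-major")
  }
  invisible(TRUE)
}

# The default column mapping for AUSNUT-style CSV ingest: canonical field ->
# column name in the file. Classification code/label columns are optional;
# codes fall back to slicing the leading 2/3/5 characters of the food ID.
#' Default ingest schema
#'
#' [read_food_table()] is schema-driven so the toolkit survives drift in
#' file dialects: the schema names, for each canonical field, the column
#' that carries it. The default expects canonical names (`food_id`,
#' `display_name`, `energy`, the [tracked_nutrients()] codes, ...).
#' Override entries to ingest a differently-headed file, e.g.
#' `default_schema(food_id = "Food ID", display_name = "Food Name")`.
#'
#' @param ... Named overrides, canonical field = column name in the file.
#' @return Named character vector mapping canonical fields to file columns.
#' @export
default_schema <- function(...) {
  schema <- setNames(food_db_columns(), food_db_columns())
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad)) abort(paste0("unknown schema field(s): ", paste(bad, collapse = ", ")))
    schema[names(over)] <- over
  }
  schema
}

#' Read an AUSNUT-style food table
#'
#' Reads a delimited food-nutrient file into a food database tibble. Ingest
#' is schema-driven (see [default_schema()]); when the file lacks explicit
#' classification columns the major/sub-major/minor codes are derived from
#' the leading 2/3/5 characters of the 8-character food ID. Row order is
#' preserved. Empty nutrient cells are stored as `NA` (unknown), never zero.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Column mapping from [default_schema()].
#' @return A food database tibble, one row per input row.
#' @export
read_food_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character(0))
  mandatory <- c("food_id", "display_name")
  for (f in mandatory) {
    if (!schema[[f]] %in% names(raw)) {
      abort(sprintf("schema error: mandatory column '%s' (field %s) missing", schema[[f]], f))
    }
  }
  n <- nrow(raw)
  get <- function(field, default = NA_character_) {
    col <- schema[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(default, n)
  }
  blank_na <- function(x) {
    x <- as.character(x)
    x[is.na(x) | !nzchar(x)] <- NA_character_
    x
  }

  ids <- get("food_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("integrity error: duplicate food_id(s): ", paste(dup, collapse = ", ")))
  }

  num_field <- function(field) {
    col <- schema[[field]]
    if (!col %in% names(raw)) return(rep(NA_real_, n))
    x <- blank_na(raw[[col]])
    val <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(val))
    if (length(bad)) {
      abort(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                    x[bad[1]], col, bad[1]))
    }
    val
  }

  major <- blank_na(get("major_code"))
  sub_major <- blank_na(get("sub_major_code"))
  minor <- blank_na(get("minor_code"))
  derive <- is.na(major)
  major[derive] <- substr(ids[derive], 1, 2)
  sub_major[is.na(sub_major)] <- substr(ids[is.na(sub_major)], 1, 3)
  minor[is.na(minor)] <- substr(ids[is.na(minor)], 1, 5)
  check_classification(major, sub_major, minor)

  basis <- get("basis", "per_100_g")
  basis[is.na(basis) | !nzchar(basis)] <- "per_100_g"
  source_col <- get("source", "generic")
  source_col[is.na(source_col) | !nzchar(source_col)] <- "generic"

  db <- tibble(
    food_id = ids,
    display_name = get("display_name"),
    original_name = dplyr::coalesce(blank_na(get("original_name")), get("display_name")),
    synonyms = unpack_list_col(get("synonyms", "")),
    keywords = unpack_list_col(get("keywords", "")),
    major_code = major, sub_major_code = sub_major, minor_code = minor,
    major_label = dplyr::coalesce(blank_na(get("major_label")), ""),
    sub_major_label = dplyr::coalesce(blank_na(get("sub_major_label")), ""),
    minor_label = dplyr::coalesce(blank_na(get("minor_label")), ""),
    basis = basis,
    unit = ifelse(basis == "per_100_g", "g", "mL"),
    source = source_col,
    chain_name = blank_na(get("chain_name")),
    portions = unpack_portions(get("portions", ""))
  )
  explicit_unit <- blank_na(get("unit"))
  db$unit[!is.na(explicit_unit)] <- explicit_unit[!is.na(explicit_unit)]
  for (nm in nutrient_columns()) db[[nm]] <- num_field(nm)
  db[food_db_columns()]
}

#' Write a food database to CSV
#'
#' Emits a deterministic CSV: canonical column order, rows sorted by food ID
#' in byte order, list-columns packed as `a|b` cells and portions as
#' `label=amount|...` with full numeric precision, so writing the same
#' records twice yields byte-identical files and
#' `read_food_table(write_database(x))` reproduces `x` field-for-field.
#'
#' @param records Food database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database <- function(records, path) {
  out <- records[radix_order(records$food_id), food_db_columns()]
  out$synonyms <- pack_list_col(out$synonyms)
  out$keywords <- pack_list_col(out$keywords)
  out$portions <- pack_portions(out$portions)
  readr::write_csv(out, path, na = "", eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a household-measures file
#'
#' Each row links a food to one household measure (cup, slice, glass, ...)
#' and supplies either a gram weight for one measure, or a volume together
#' with a density so the weight can be derived. Rows providing neither path
#' are rejected. Entries keep file order within each food.
#'
#' @param path CSV with columns `food_id`, `measure_label`, and at least one
#'   of `grams_per_measure` or (`volume_per_measure` + `density`).
#' @return Tibble of measure entries.
#' @export
read_measures <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  m <- readr::read_csv(path, col_types = readr::cols(
    food_id = readr::col_character(),
    measure_label = readr::col_character(),
    grams_per_measure = readr::col_double(),
    volume_per_measure = readr::col_double(),
    density = readr::col_double()
  ), progress = FALSE)
  ok <- !is.na(m$grams_per_measure) | (!is.na(m$volume_per_measure) & !is.na(m$density))
  if (any(!ok)) {
    abort(paste0("measure rows lacking both a gram weight and volume+density: row(s) ",
                 paste(which(!ok), collapse = ", ")))
  }
  m
}

#' Validate a food database
#'
#' Report-only consistency check run before a database is handed to the app:
#' duplicate IDs, negative nutrient amounts, generic foods missing any of
#' energy + the 25 tracked nutrients (`panel_incomplete`), chain foods
#' missing any of energy + the six label nutrients (`label_incomplete`),
#' chain foods whose display name does not end with `", <chain>"`
#' (`chain_suffix_missing`), and portion options with non-positive amounts.
#'
#' @param records Food database tibble.
#' @return A `validation_report`: tibble of issues (`code`, `food_id`,
#'   `message`) with a per-code count table attached. Zero rows means the
#'   database passes every check.
#' @export
validate_database <- function(records) {
  issues <- list()
  add <- function(code, ids, msg) {
    if (length(ids)) {
      issues[[length(issues) + 1]] <<- tibble(code = code, food_id = ids, message = msg)
    }
  }

  add("duplicate_id", unique(records$food_id[duplicated(records$food_id)]),
      "food_id occurs more than once")

  panel <- as.matrix(records[, nutrient_columns()])
  neg <- rowSums(!is.na(panel) & panel < 0) > 0
  add("negative_nutrient", records$food_id[neg], "negative nutrient amount")

  generic <- records$source == "generic"
  add("panel_incomplete",
      records$food_id[generic & rowSums(is.na(panel)) > 0],
      "generic food missing tracked nutrient value(s)")

  lab <- as.matrix(records[, c("energy", label_nutrients())])
  chain <- records$source == "chain"
  add("label_incomplete",
      records$food_id[chain & rowSums(is.na(lab)) > 0],
      "chain food missing mandatory label nutrient(s)")

  suffix_ok <- !chain | (!is.na(records$chain_name) &
                           mapply(function(nm, ch) !is.na(ch) && endsWith(nm, paste0(", ", ch)),
                                  records$display_name, records$chain_name))
  add("chain_suffix_missing", records$food_id[!suffix_ok],
      "chain food name does not end with ', <chain_name>'")

  bad_portion <- vapply(records$portions, function(p) {
    nrow(p) > 0 && any(!is.finite(p$amount) | p$amount <= 0)
  }, logical(1))
  add("nonpositive_portion", records$food_id[bad_portion],
      "portion option with non-positive amount")

  add("empty_name", records$food_id[!nzchar(records$display_name)],
      "empty display name")

  report <- if (length(issues)) bind_rows(issues) else
    tibble(code = character(0), food_id = character(0), message = character(0))
  structure(report, class = c("validation_report", class(report)))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("<validation_report> no issues\n")
  } else {
    cat(sprintf("<validation_report> %d issue(s)\n", nrow(x)))
    print(as_tibble(table(code = x$code)), ...)
  }
  invisible(x)
}
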