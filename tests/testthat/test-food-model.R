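test_that("classification codes derive from the leading 2/3/5 characters of the ID", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,display_name,energy",
               "16A10001,\"Apple, green\",250"), path)
  db <- read_food_table(path)
  expect_equal(db$major_code, "16")
  expect_equal(db$sub_major_code, "16A")
  expect_equal(db$minor_code, "16A10")
  expect_equal(db$energy, 250)
  expect_equal(db$source, "generic")
  # nesting invariant holds on everything the reader emits
  expect_true(all(startsWith(db$sub_major_code, db$major_code)))
  expect_true(all(startsWith(db$minor_code, db$sub_major_code)))
})

test_that("a header-only file yields an empty database", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("food_id,display_name,energy", path)
  expect_equal(nrow(read_food_table(path)), 0)
})

test_that("ingest errors name the offending column or row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,energy", "16A10001,250"), path)
  expect_error(read_food_table(path), "display_name")

  writeLines(c("food_id,display_name,energy", "16A10001,Apple,oops"), path)
  expect_error(read_food_table(path), "row 1")

  writeLines(c("food_id,display_name,energy",
               "16A10001,Apple,1", "16A10001,Apple again,2"), path)
  expect_error(read_food_table(path), "duplicate")
})

test_that("schema overrides remap file columns to canonical fields", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Food ID,Food Name,Energy kJ", "16A10001,Apple,250"), path)
  db <- read_food_table(path, default_schema(
    food_id = "Food ID", display_name = "Food Name", energy = "Energy kJ"))
  expect_equal(db$display_name, "Apple")
  expect_equal(db$energy, 250)
})

test_that("write_database round-trips generated records and is byte-deterministic", {
  fx <- generate_fixture(fixture_params(n_foods = 20, n_clusters = 2,
                                        cluster_sizes = c(2, 2)), seed = 7)
  db <- assign_all_portions(fx$foods, fx$measures)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_database(db, p1)
  back <- read_food_table(p1)
  expect_equal(as.data.frame(back),
               as.data.frame(db[order(db$food_id, method = "radix"), ]),
               ignore_attr = TRUE)
  write_database(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("empty record list writes a header-only file", {
  fx <- generate_fixture(fixture_params(n_foods = 5, n_clusters = 0,
                                        removal_props = c(ingredient = 0)), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_database(fx$foods[0, ], path)
  expect_length(readLines(path), 1)
})

test_that("measures reader handles both weight paths and rejects rows with neither", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("food_id,measure_label,grams_per_measure,volume_per_measure,density",
               "16A10001,1 cup,250,,",
               "16A10002,1 glass,,200,1.04"), path)
  m <- read_measures(path)
  expect_equal(m$grams_per_measure[1], 250)
  expect_equal(m$volume_per_measure[2], 200)
  expect_equal(m$density[2], 1.04)

  writeLines(c("food_id,measure_label,grams_per_measure,volume_per_measure,density",
               "16A10001,1 cup,250,,",
               "16A10003,1 handful,,,"), path)
  expect_error(read_measures(path), "row\\(s\\) 2")
})

test_that("validate_database flags each planted defect class and is clean on clean fixtures", {
  clean <- generate_fixture(fixture_params(n_foods = 30, n_clusters = 0), seed = 3)
  expect_equal(nrow(validate_database(clean$foods)), 0)

  dc <- c(negative_nutrient = 2, panel_incomplete = 3,
          nonpositive_portion = 1, duplicate_id = 1)
  bad <- generate_fixture(fixture_params(n_foods = 30, n_clusters = 0,
                                         defect_counts = dc), seed = 3)
  rep <- validate_database(bad$foods)
  got <- table(rep$code)
  for (code in names(dc)) {
    expect_equal(unname(got[[code]]), unname(dc[[code]]), label = code)
  }
  # planted IDs are exactly the flagged IDs, per defect class
  for (code in names(dc)) {
    expect_setequal(rep$food_id[rep$code == code],
                    bad$defects$food_id[bad$defects$code == code])
  }
})

test_that("chain records missing label nutrients or the chain suffix are flagged", {
  ch <- food_record("CHAIN:x:0001", "Thing, X",
                    nutrients = c(energy = 100, protein = 1, total_fat = 1,
                                  saturated_fat = 1, carbohydrate = 1, sodium = 10),
                    major_code = "90", sub_major_code = "90A", minor_code = "90A01",
                    source = "chain", chain_name = "X")  # sugars absent
  rep <- validate_database(ch)
  expect_true("label_incomplete" %in% rep$code)

  ch2 <- ch
  ch2$display_name <- "Thing"
  rep2 <- validate_database(ch2)
  expect_true("chain_suffix_missing" %in% rep2$code)

  neg <- make_food("16A10001", "Apple")
  neg$sodium <- -1   # the constructor refuses this; ingest defects can carry it
  expect_true("negative_nutrient" %in% validate_database(neg)$code)
})

test_that("food_record enforces the record invariants", {
  expect_error(food_record("16A10001", ""), "non-empty")
  expect_error(food_record("16A10001", "Apple", basis = "per_100_mL", unit = "g"),
               "inconsistent")
  expect_error(food_record("16A10001", "Thing", source = "chain", chain_name = "X"),
               "must end with")
  expect_error(food_record("16A10001", "Apple", c(energy = 1, bogus = 2)), "unknown")
})
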