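ts <- function(x) as.POSIXct(x, tz = "UTC")

entry_at <- function(when, pid = "P01", food = "16A10001", manual = FALSE) {
  diary_entry(pid, ts(when), food, amount = 1, unit = "100 g",
              location = "home", is_manual = manual)
}

test_that("the logging day rolls over at exactly 3 a.m.", {
  expect_equal(logging_day(ts("2018-01-02 02:59:00")), as.Date("2018-01-01"))
  expect_equal(logging_day(ts("2018-01-02 03:00:00")), as.Date("2018-01-02"))
  expect_equal(logging_day(ts("2018-01-02 13:00:00")), as.Date("2018-01-02"))
  expect_equal(logging_day(ts("2018-01-02 00:00:00")), as.Date("2018-01-01"))
})

test_that("logging_day is monotone with one discontinuity per day", {
  times <- ts("2018-01-01 00:00:00") + seq(0, 3 * 86400, by = 900)
  days <- logging_day(times)
  expect_true(all(diff(as.integer(days)) >= 0))
  jumps <- which(diff(as.integer(days)) == 1)
  expect_equal(format(times[jumps + 1], "%H:%M", tz = "UTC"),
               rep("03:00", length(jumps)))
})

test_that("entries for the current logging day are accepted, retrospective ones rejected", {
  store <- diary_store()
  store <- add_entry(store, entry_at("2018-03-05 12:00:00"), now = ts("2018-03-05 13:00:00"))
  expect_equal(nrow(store$entries), 1)

  # yesterday's intake submitted at 10:00 today: the day is closed
  err <- expect_error(
    add_entry(store, entry_at("2018-03-04 20:00:00"), now = ts("2018-03-05 10:00:00")),
    class = "eatkit_retrospective_entry")
  expect_equal(err$entry_day, as.Date("2018-03-04"))
  expect_equal(err$current_day, as.Date("2018-03-05"))

  # 02:30 submitted at 02:45 the same night: both sit on the previous logging day
  store <- add_entry(store, entry_at("2018-03-06 02:30:00"), now = ts("2018-03-06 02:45:00"))
  expect_equal(store$entries$logging_day[2], as.Date("2018-03-05"))
})

test_that("accepted entries are never mutated by later appends", {
  store <- diary_store()
  store <- add_entry(store, entry_at("2018-03-05 08:00:00"), now = ts("2018-03-05 08:00:01"))
  snapshot <- store$entries[1, ]
  store <- add_entry(store, entry_at("2018-03-05 09:00:00", food = "16A10002"),
                     now = ts("2018-03-05 09:00:01"))
  expect_identical(store$entries[1, ], snapshot)
  expect_equal(nrow(store$entries), 2)
})

test_that("history deduplicates by latest use, most recent first", {
  store <- diary_store()
  for (e in list(entry_at("2018-03-05 08:00:00", food = "A"),
                 entry_at("2018-03-05 09:00:00", food = "B"),
                 entry_at("2018-03-05 10:00:00", food = "A"))) {
    store <- add_entry(store, e, now = e$timestamp)
  }
  expect_equal(diary_history(store, "P01", 10), c("A", "B"))
  expect_equal(diary_history(store, "P01", 1), "A")
  expect_equal(diary_history(store, "P99", 5), character(0))
  expect_error(diary_history(store, "P01", 0), ">= 1")
})

test_that("the manual review queue is exactly the manual entries, in time order", {
  store <- diary_store()
  specs <- list(
    list(t = "2018-03-05 09:00:00", manual = FALSE),
    list(t = "2018-03-05 10:00:00", manual = TRUE),
    list(t = "2018-03-05 11:00:00", manual = FALSE),
    list(t = "2018-03-05 12:00:00", manual = TRUE),
    list(t = "2018-03-05 13:00:00", manual = FALSE),
    list(t = "2018-03-05 14:00:00", manual = FALSE),
    list(t = "2018-03-05 15:00:00", manual = FALSE)
  )
  for (s in specs) {
    store <- add_entry(store, entry_at(s$t, manual = s$manual,
                                       food = if (s$manual) "unknown dish" else "16A10001"),
                       now = ts(s$t))
  }
  q <- manual_review_queue(store)
  expect_equal(nrow(q), 2)
  expect_true(all(q$is_manual))
  expect_true(!is.unsorted(q$timestamp))
  # partition: manual queue plus non-manual rows account for every entry
  expect_equal(nrow(q) + sum(!store$entries$is_manual), nrow(store$entries))
})

test_that("diary entries validate amount and location", {
  expect_error(diary_entry("P01", ts("2018-03-05 08:00:00"), "x", 0, "g", "home"),
               "positive")
  expect_error(diary_entry("P01", ts("2018-03-05 08:00:00"), "x", 1, "g", "space station"),
               "taxonomy")
})

test_that("the diary log round-trips through JSON lines", {
  fx <- generate_fixture(fixture_params(n_foods = 10, n_clusters = 0,
                                        removal_props = c(ingredient = 0)), seed = 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_diary_log(fx$diary, path)
  back <- read_diary_log(path)
  expect_equal(as.data.frame(back$entries), as.data.frame(fx$diary$entries))
})

test_that("SUS scoring matches the standard arithmetic", {
  expect_equal(sus_score(rep(c(5, 1), 5)), 100)   # best odd, best even
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_equal(sus_score(rep(c(4, 2), 5)), 75)    # (3x5 + 3x5) x 2.5
  expect_equal(sus_score(rep(c(1, 5), 5)), 0)
  expect_error(sus_score(rep(6, 10)), "1..5")
  expect_error(sus_score(rep(3, 9)), "10")
  expect_error(sus_score(c(rep(3, 9), 3.5)), "integer")
})

test_that("SUS scores stay within [0, 100] across random and 2-level exhaustive grids", {
  set.seed(11)
  for (i in 1:200) {
    s <- sus_score(sample(1:5, 10, replace = TRUE))
    expect_gte(s, 0); expect_lte(s, 100)
  }
  grid <- as.matrix(expand.grid(rep(list(c(1L, 5L)), 10)))
  scores <- apply(grid, 1, sus_score)
  expect_equal(range(scores), c(0, 100))
  expect_equal(length(scores), 1024)
})

test_that("SUS summaries report rounded mean, range and above-threshold count", {
  # build a response whose score is any given multiple of 2.5: spread the
  # needed contribution points (4 max per item) across the ten items
  mk <- function(target) {
    t <- target / 2.5
    stopifnot(t == floor(t), t >= 0, t <= 40)
    pts <- integer(10)
    for (i in 1:10) { p <- min(4, t); pts[i] <- p; t <- t - p }
    resp <- integer(10)
    odd <- c(1, 3, 5, 7, 9); even <- c(2, 4, 6, 8, 10)
    resp[odd] <- pts[odd] + 1
    resp[even] <- 5 - pts[even]
    stopifnot(sus_score(resp) == target)
    resp
  }
  s <- sus_summary(list(mk(45), mk(90)))
  expect_equal(s$mean_raw, 67.5)
  expect_equal(s$mean_score, 68)    # rounds half-even to the integer convention
  expect_equal(s$min, 45)
  expect_equal(s$max, 90)
  expect_equal(s$n_above_threshold, 1)

  one <- sus_summary(list(mk(70)))
  expect_equal(one$mean_score, 70)
  expect_equal(one$n_above_threshold, 1)

  same <- sus_summary(list(rep(3, 10), rep(3, 10)))
  expect_equal(same$min, same$max)
  expect_equal(same$min, same$mean_raw)
  expect_error(sus_summary(list()), "at least one")
})
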