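# followup: person-period conversion, repeat bins, mortality, 2x2 tables.

index_rows_for <- function(ids, when) {
  data.frame(person_id = ids, index_datetime = ts(when),
             stringsAsFactors = FALSE)
}

test_that("repeat counting honours the one-year window boundaries", {
  idx <- index_rows_for("P1", "2011-01-10 12:00")
  calls <- make_calls(
    sprintf("S%d", 1:4), "P1",
    c("2011-01-10 12:00",   # the index call itself: delta = 0, excluded
      "2011-01-11 12:00",   # day 1: counted
      "2012-01-10 12:00",   # exactly 365 days: counted
      "2012-01-10 12:01"))  # 365 days + 1 min: excluded
  pp <- to_person_period(idx, calls)
  expect_identical(pp$n_repeats_1yr, 2L)
})

test_that("all-cause repeats count non-inclusion codes; mh scope does not", {
  idx <- index_rows_for("P1", "2011-01-10 12:00")
  calls <- rbind(
    make_calls("S1", "P1", "2011-02-01 12:00", code = "12D01"),
    make_calls("S2", "P1", "2011-03-01 12:00", code = "25A01"))
  expect_identical(to_person_period(idx, calls)$n_repeats_1yr, 2L)
  expect_identical(
    to_person_period(idx, calls, repeat_scope = "mh")$n_repeats_1yr, 1L)
})

test_that("repeat bins follow the documented cut points", {
  n <- c(0L, 1L, 4L, 5L, 9L, 10L, 14L, 15L, 40L)
  got <- as.character(carepath:::.bin_repeats(n))
  expect_identical(got, c("0", "1", "4", "5-9", "5-9", "10-14", "10-14",
                          "15+", "15+"))
})

test_that("repeat_distribution covers all bins and sums to the cohort", {
  idx <- index_rows_for(paste0("P", 1:3), rep("2011-01-10 12:00", 3))
  calls <- make_calls(sprintf("S%d", 1:5), c("P2", rep("P3", 4)),
                      sprintf("2011-02-%02d 10:00", 1:5))
  pp <- to_person_period(idx, calls)
  d <- repeat_distribution(pp)
  expect_identical(d$bin, c("0", "1", "2", "3", "4", "5-9", "10-14", "15+"))
  expect_identical(sum(d$count), 3L)
  expect_identical(d$count[d$bin == "0"], 1L)
  expect_identical(d$count[d$bin == "4"], 1L)
  expect_equal(sum(d$pct), 100)
})

test_that("duplicate persons in index rows are rejected", {
  idx <- index_rows_for(c("P1", "P1"), rep("2011-01-10 12:00", 2))
  expect_error(to_person_period(idx, empty_tab("calls")), "one row per")
})

test_that("mortality day boundaries follow the calendar-day rule", {
  cohort <- data.frame(person_id = paste0("P", 1:5),
                       index_datetime = rep(ts("2011-03-10 23:00"), 5),
                       stringsAsFactors = FALSE)
  deaths <- make_deaths(paste0("P", 1:5),
                        c("2011-03-10",   # same day: within 1 day
                          "2011-03-11",   # next day: within 1 day
                          "2011-03-12",   # two days: late
                          "2012-03-09",   # exactly 365 days: late
                          "2012-03-10"),  # 366 days: outside the year
                        cause = c("other", "suicide", "suicide",
                                  "mental_behavioural", "other"))
  classes <- data.frame(person_id = paste0("P", 1:5),
                        pathway_class = c("S", "SE", "S", "SE", "SEA"),
                        stringsAsFactors = FALSE)
  mo <- mortality_outcomes(cohort, deaths, classes)
  expect_identical(mo$outcomes$died_within_1day,
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(mo$outcomes$died_1day_to_1yr,
                   c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_identical(mo$derived$deaths_within_year, c(4L, 5L))
  expect_identical(mo$derived$late_deaths, c(2L, 5L))
  expect_identical(mo$derived$late_deaths_S_SE, c(2L, 2L))
  expect_identical(mo$derived$suicides_within_year, c(2L, 4L))
  expect_true(is.na(mo$outcomes$cause_category[5L]))
})

test_that("death before the index call is flagged, not counted", {
  cohort <- data.frame(person_id = "P1",
                       index_datetime = ts("2011-06-01 10:00"),
                       stringsAsFactors = FALSE)
  deaths <- make_deaths("P1", "2011-05-01")
  classes <- data.frame(person_id = "P1", pathway_class = "S",
                        stringsAsFactors = FALSE)
  mo <- mortality_outcomes(cohort, deaths, classes)
  expect_true(mo$outcomes$death_before_index)
  expect_false(mo$outcomes$died_within_1day)
  expect_false(mo$outcomes$died_1day_to_1yr)
})

test_that("mortality tallies by pathway class reconcile", {
  cohort <- data.frame(person_id = paste0("P", 1:4),
                       index_datetime = rep(ts("2011-03-10 12:00"), 4),
                       stringsAsFactors = FALSE)
  deaths <- make_deaths(c("P1", "P2"), c("2011-03-10", "2011-08-01"))
  classes <- data.frame(person_id = paste0("P", 1:4),
                        pathway_class = c("S", "S", "SE", "OTHER"),
                        stringsAsFactors = FALSE)
  mo <- mortality_outcomes(cohort, deaths, classes)
  bc <- mo$by_class
  expect_identical(sum(bc$n), 4L)
  expect_identical(bc$deaths_within_1day[bc$pathway_class == "S"], 1L)
  expect_identical(bc$deaths_1day_to_1yr[bc$pathway_class == "S"], 1L)
  expect_identical(sum(bc$deaths_within_1day) + sum(bc$deaths_1day_to_1yr),
                   mo$derived$deaths_within_year[1L])
})

test_that("selfdischarge_analysis builds both 2x2 tables", {
  pp <- data.frame(
    person_id = paste0("P", 1:6),
    reached_ed_at_index = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    had_selfdischarge_at_index = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    n_repeats_1yr = c(2L, 0L, 1L, 0L, 5L, 0L),
    stringsAsFactors = FALSE)
  ed_rows <- data.frame(
    alcohol_flag = c(TRUE, TRUE, FALSE, FALSE),
    final_ed_disposition = c("self_discharge", "completed",
                             "self_discharge", "completed"),
    stringsAsFactors = FALSE)
  sda <- selfdischarge_analysis(pp, ed_rows)
  # person P5 never reached the ED: excluded from table (i)
  expect_identical(sda$repeat_table$a, 1L)
  expect_identical(sda$repeat_table$b, 1L)
  expect_identical(sda$repeat_table$c, 1L)
  expect_identical(sda$repeat_table$d, 2L)
  expect_identical(sda$alcohol_table$a, 1L)
  expect_identical(sda$alcohol_table$c, 1L)
})

test_that("degenerate exposure yields a note instead of a table", {
  pp <- data.frame(person_id = "P1", reached_ed_at_index = TRUE,
                   had_selfdischarge_at_index = TRUE, n_repeats_1yr = 1L,
                   stringsAsFactors = FALSE)
  ed_rows <- data.frame(alcohol_flag = TRUE,
                        final_ed_disposition = "self_discharge",
                        stringsAsFactors = FALSE)
  sda <- selfdischarge_analysis(pp, ed_rows)
  expect_null(sda$repeat_table)
  expect_null(sda$alcohol_table)
  expect_match(sda$repeat_note, "degenerate")
  expect_match(sda$alcohol_note, "degenerate")
})
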