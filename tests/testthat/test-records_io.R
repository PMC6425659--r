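# records_io: schemas, CSV round trip, parse errors, validation findings.

test_that("bundle round-trips through CSV field-identically", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  for (nm in c("persons", "calls", "ed", "admissions", "deaths")) {
    lhs <- b[[nm]][order(b[[nm]]$person_id), , drop = FALSE]
    rhs <- b2[[nm]][order(b2[[nm]]$person_id), , drop = FALSE]
    rownames(lhs) <- rownames(rhs) <- NULL
    expect_equal(lhs, rhs, info = nm)
  }
})

test_that("writing the same bundle twice is byte-identical", {
  b <- small_bundle()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(b, d1)
  write_bundle(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("missing table file is fatal and names the file", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  unlink(file.path(dir, "ed.csv"))
  expect_error(read_bundle(dir), "ed\\.csv")
})

test_that("missing column is fatal and names table and column", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  tab <- utils::read.csv(file.path(dir, "calls.csv"),
                         colClasses = "character")
  tab$final_ampds_code <- NULL
  utils::write.csv(tab, file.path(dir, "calls.csv"), row.names = FALSE)
  expect_error(read_bundle(dir), "calls.*final_ampds_code")
})

test_that("unparseable timestamp reports table, column and row number", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  tab <- utils::read.csv(file.path(dir, "ed.csv"), colClasses = "character")
  tab$start_datetime[2L] <- "not-a-time"
  utils::write.csv(tab, file.path(dir, "ed.csv"), row.names = FALSE)
  expect_error(read_bundle(dir), "'ed'.*'start_datetime'.*row.*2")
})

test_that("unknown enumerated value is fatal and names value and row", {
  p <- make_persons("P1", sex = "robot")
  expect_error(
    record_bundle(p, empty_tab("calls"), empty_tab("ed"),
                  empty_tab("admissions"), empty_tab("deaths")),
    "'persons'.*'sex'.*'robot'.*row 1")
  e <- make_ed("E1", "P1", "2011-01-01 10:00", "2011-01-01 11:00",
               disposition = "eloped")
  expect_error(
    record_bundle(make_persons("P1"), empty_tab("calls"), e,
                  empty_tab("admissions"), empty_tab("deaths")),
    "'ed'.*'disposition'.*'eloped'")
  a <- make_admissions("A1", "P1", "2011-01-01 10:00", "2011-01-02 10:00",
                       ward = "surgical")
  expect_error(
    record_bundle(make_persons("P1"), empty_tab("calls"), empty_tab("ed"),
                  a, empty_tab("deaths")),
    "'admissions'.*'ward_type'.*'surgical'")
  d <- make_deaths("P1", "2011-02-01", cause = "unknown_cause")
  expect_error(
    record_bundle(make_persons("P1"), empty_tab("calls"), empty_tab("ed"),
                  empty_tab("admissions"), d),
    "'deaths'.*'cause_category'.*'unknown_cause'")
})

test_that("blank optional flags read as FALSE", {
  dir <- withr::local_tempdir()
  write_bundle(small_bundle(), dir)
  tab <- utils::read.csv(file.path(dir, "calls.csv"),
                         colClasses = "character")
  tab$alcohol_flag <- ""
  tab$drug_flag <- ""
  utils::write.csv(tab, file.path(dir, "calls.csv"), row.names = FALSE)
  b <- read_bundle(dir)
  expect_false(any(b$calls$alcohol_flag))
  expect_false(any(b$calls$drug_flag))
  expect_type(b$calls$alcohol_flag, "logical")
})

test_that("empty final AMPDS code is fatal", {
  cl <- make_calls("S1", "P1", "2011-01-01 10:00", code = "")
  expect_error(
    record_bundle(make_persons("P1"), cl, empty_tab("ed"),
                  empty_tab("admissions"), empty_tab("deaths")),
    "final_ampds_code")
})

test_that("validate_bundle reports every documented finding", {
  persons <- rbind(make_persons(c("P1", "P2")), make_persons("P1"))
  calls <- rbind(
    make_calls("S1", "P1", "2011-01-01 10:00"),
    # ends before it starts
    make_calls("S2", "P2", "2011-01-02 10:00", end = "2011-01-02 09:00"),
    # orphan person
    make_calls("S3", "P9", "2011-01-03 10:00"))
  deaths <- rbind(make_deaths("P1", "2010-12-01"),   # before P1's contact
                  make_deaths("P2", "2011-06-01"),
                  make_deaths("P2", "2011-06-02"))   # duplicate
  v <- validate_bundle(record_bundle(persons, calls, empty_tab("ed"),
                                     empty_tab("admissions"), deaths))
  expect_false(v$is_clean)
  msgs <- v$issues$message
  expect_true(any(grepl("duplicate person_id 'P1'", msgs)))
  expect_true(any(grepl("'P9' not present", msgs)))
  expect_true(any(grepl("'S2' ends before it starts", msgs)))
  expect_true(any(grepl("multiple death records for person 'P2'", msgs)))
  warn <- v$issues[v$issues$severity == "warning", ]
  expect_true(any(grepl("contact starting after the death date",
                        warn$message)))
})

test_that("clean bundle validates with zero findings", {
  v <- validate_bundle(small_bundle())
  expect_true(v$is_clean)
  expect_identical(nrow(v$issues), 0L)
})

test_that("empty bundle round-trips and validates", {
  b <- empty_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_identical(nrow(b2$calls), 0L)
  expect_true(validate_bundle(b2)$is_clean)
})

test_that("missing end_datetime survives the round trip as NA", {
  cl <- make_calls("S1", "P1", "2011-01-01 10:00")
  cl$end_datetime <- as.POSIXct(NA, tz = "UTC")
  b <- record_bundle(make_persons("P1"), cl, empty_tab("ed"),
                     empty_tab("admissions"), empty_tab("deaths"))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(is.na(read_bundle(dir)$calls$end_datetime[1L]))
})
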