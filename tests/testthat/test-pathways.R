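# pathways: chaining rule, encoding, classification, duplication, metrics.

# Independent sequential reference for the 24-hour chaining rule.
oracle_chain <- function(start, end, gap_hours = 24) {
  n <- length(start)
  ids <- integer(n)
  ids[1L] <- 1L
  ref <- if (is.na(end[1L])) start[1L] else end[1L]
  for (i in seq_len(n)[-1L]) {
    gap <- as.numeric(difftime(start[i], ref, units = "hours"))
    ids[i] <- ids[i - 1L] + (gap > gap_hours)
    ref <- if (is.na(end[i])) start[i] else end[i]
  }
  ids
}

contacts_from <- function(letters_, starts, ends) {
  data.frame(contact_id = sprintf("C%02d", seq_along(letters_)),
             person_id = "P1", service_class = letters_,
             start_datetime = starts, end_datetime = ends,
             stringsAsFactors = FALSE)
}

test_that("chaining matches the brute-force oracle on sequences up to 5", {
  t0 <- ts("2011-01-01 08:00")
  gaps <- c(-0.5, 0, 1, 23.99, 24, 24.02, 60) * 3600  # start minus prev end
  durations <- c(0.5, 2, 30) * 3600
  set.seed(11)
  for (len in 1:5) {
    grid <- if (len == 1L) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(gaps), len - 1L)))
    for (r in seq_len(nrow(grid))) {
      dur <- sample(durations, len, replace = TRUE)
      starts <- rep(t0, len)
      ends <- starts + dur
      if (len > 1L) {
        for (i in 2:len) {
          starts[i] <- ends[i - 1L] + grid[r, i - 1L]
          ends[i] <- starts[i] + dur[i]
        }
      }
      # occasionally drop an end time (chain from the start instead)
      drop <- stats::runif(len) < 0.2
      ends[drop] <- NA
      if (len > 1L) for (i in 2:len) {
        if (drop[i - 1L]) starts[i] <- starts[i - 1L] + grid[r, i - 1L]
      }
      if (is.unsorted(as.numeric(starts))) next
      letters_ <- sample(c("S", "E", "A", "M"), len, replace = TRUE)
      got <- assign_pathways(contacts_from(letters_, starts, ends))
      # the oracle chains the contacts in the same canonical time order
      want <- oracle_chain(got$start_datetime, got$end_datetime)
      expect_identical(got$pathway_id, want)
    }
  }
})

test_that("exactly 24 hours still links; one minute more does not", {
  t0 <- ts("2011-01-01 08:00")
  co <- contacts_from(c("S", "E"), c(t0, t0 + 30 * 60 + 24 * 3600),
                      c(t0 + 30 * 60, t0 + 30 * 60 + 26 * 3600))
  expect_identical(assign_pathways(co)$pathway_id, c(1L, 1L))
  co$start_datetime[2L] <- co$start_datetime[2L] + 60
  expect_identical(assign_pathways(co)$pathway_id, c(1L, 2L))
})

test_that("overlapping contacts chain rather than fail", {
  t0 <- ts("2011-01-01 08:00")
  co <- contacts_from(c("S", "E"), c(t0, t0 + 10 * 60),
                      c(t0 + 60 * 60, t0 + 3 * 3600))
  expect_identical(assign_pathways(co)$pathway_id, c(1L, 1L))
})

test_that("contacts of different persons never chain", {
  t0 <- ts("2011-01-01 08:00")
  co <- rbind(contacts_from("S", t0, t0 + 1800),
              contacts_from("E", t0 + 3600, t0 + 7200))
  co$person_id <- c("P1", "P2")
  co$contact_id <- c("C01", "C02")
  expect_identical(assign_pathways(co)$pathway_id, c(1L, 2L))
})

test_that("the SEE worked example encodes as one pathway 'SEE'", {
  t0 <- ts("2011-02-01 21:00")
  co <- contacts_from(c("S", "E", "E"),
                      c(t0, t0 + 45 * 60, t0 + 20 * 3600),
                      c(t0 + 40 * 60, t0 + 4 * 3600, t0 + 23 * 3600))
  paths <- link_contacts(co)
  expect_length(paths, 1L)
  expect_identical(attr(paths[[1L]], "code_string"), "SEE")
})

test_that("code strings truncate at 11 letters, pathway keeps all contacts", {
  t0 <- ts("2011-01-01 08:00")
  n <- 13L
  starts <- t0 + (seq_len(n) - 1L) * 3600
  co <- contacts_from(rep(c("S", "E"), length.out = n), starts,
                      starts + 1800)
  paths <- link_contacts(co)
  expect_length(paths, 1L)
  expect_identical(nchar(attr(paths[[1L]], "code_string")), 11L)
  expect_identical(nrow(paths[[1L]]), 13L)
  expect_identical(encode_pathway(rep("S", 20)),
                   paste(rep("S", 11), collapse = ""))
})

test_that("classification matches the five-way rule exhaustively to length 3", {
  letters_ <- c("S", "E", "A", "M")
  suffixes <- c(letters_,
                as.vector(outer(letters_, letters_, paste0)),
                as.vector(outer(as.vector(outer(letters_, letters_, paste0)),
                                letters_, paste0)))
  rule <- function(s) {
    if (s == "S") "S" else if (s == "SE") "SE" else if (s == "SEA") "SEA"
    else if (s %in% c("SEM", "SM")) "SEM_SM" else "OTHER"
  }
  anchored <- suffixes[startsWith(suffixes, "S")]
  expect_identical(classify_pathway(anchored, 1L),
                   vapply(anchored, rule, character(1), USE.NAMES = FALSE))
  # anchored mid-string: the suffix, not the whole string, is classified
  expect_identical(classify_pathway("SEESE", 4L), "SE")
  expect_identical(classify_pathway("SEESEM", 4L), "SEM_SM")
})

test_that("classification rejects bad anchors", {
  expect_error(classify_pathway("SE", 3L), "outside")
  expect_error(classify_pathway("SE", 0L), "outside")
  expect_error(classify_pathway("SEA", 2L), "ambulance")
})

test_that("pathways duplicate once per mental-health call", {
  t0 <- ts("2011-03-05 09:00")
  co <- contacts_from(c("S", "E", "E", "S", "E"),
                      t0 + c(0, 1, 2, 20, 21) * 3600,
                      t0 + c(0.5, 1.5, 2.5, 20.5, 21.5) * 3600)
  calls <- make_calls(c("C01", "C04"), "P1",
                      c("2011-03-05 09:00", "2011-03-06 05:00"))
  rows <- duplicate_per_mh_call(link_contacts(co), calls)
  expect_identical(nrow(rows), 2L)
  expect_identical(rows$code_string, c("SEESE", "SEESE"))
  expect_identical(rows$anchor_position, c(1L, 4L))
  expect_identical(rows$pathway_class, c("OTHER", "SE"))
})

test_that("pathways with no mental-health call yield no rows", {
  t0 <- ts("2011-03-05 09:00")
  co <- contacts_from(c("S", "E"), c(t0, t0 + 3600),
                      c(t0 + 1800, t0 + 7200))
  calls <- make_calls("C01", "P1", "2011-03-05 09:00", code = "12D01")
  rows <- duplicate_per_mh_call(link_contacts(co), calls)
  expect_identical(nrow(rows), 0L)
})

test_that("anchors beyond the 11-letter truncation are dropped", {
  t0 <- ts("2011-03-05 09:00")
  n <- 13L
  co <- contacts_from(rep("S", n), t0 + (seq_len(n) - 1L) * 3600,
                      t0 + (seq_len(n) - 1L) * 3600 + 600)
  calls <- make_calls(c("C01", "C13"), "P1",
                      c("2011-03-05 09:00", "2011-03-05 21:00"))
  rows <- duplicate_per_mh_call(link_contacts(co), calls)
  expect_identical(rows$anchor_position, 1L)
})

test_that("interval metrics use the first subsequent contact of each class", {
  t0 <- ts("2011-04-01 10:00")
  co <- contacts_from(c("S", "E", "A", "M"),
                      c(t0, t0 + 35 * 60, t0 + 5 * 3600, t0 + 30 * 3600),
                      c(t0 + 30 * 60, t0 + 35 * 60 + 150 * 60,
                        t0 + 29 * 3600, t0 + 30 * 3600 + 8 * 86400))
  p <- link_contacts(co)[[1L]]
  m <- interval_metrics(p, 1L)
  expect_equal(m$call_to_ed_minutes, 35)
  expect_equal(m$ed_los_minutes, 150)
  expect_equal(m$acute_los_days, 1)
  expect_equal(m$psych_los_days, 8)
  # S-only pathway: everything absent
  m2 <- interval_metrics(link_contacts(contacts_from("S", t0,
                                                     t0 + 1800))[[1L]], 1L)
  expect_true(all(is.na(unlist(m2))))
})

test_that("link_contacts refuses multi-person input", {
  t0 <- ts("2011-01-01 08:00")
  co <- contacts_from(c("S", "S"), c(t0, t0 + 3600), c(t0 + 1800, t0 + 5400))
  co$person_id <- c("P1", "P2")
  expect_error(link_contacts(co), "single person")
})

test_that("bundle_contacts stacks and orders the three contact tables", {
  co <- bundle_contacts(small_bundle())
  expect_identical(nrow(co), 11L)
  expect_setequal(unique(co$service_class), c("S", "E", "A", "M"))
  expect_false(is.unsorted(co$person_id))
  p4 <- co[co$person_id == "P4", ]
  expect_identical(p4$service_class, c("S", "E", "M"))
})
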