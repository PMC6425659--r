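# Index cohort selection: AMPDS inclusion coding and first qualifying call.

#' AMPDS inclusion list for mental-health / self-harm emergencies
#'
#' The ten final-AMPDS dispatch codes used to identify ambulance calls for
#' psychiatric emergencies or self-harm. Nine are full five-character codes;
#' "23" (intentional poisoning) is a chapter-level entry that, under the
#' default prefix matching mode, covers every code beginning "23".
#'
#' @return data frame with columns `code` and `description`.
#' @export
ampds_inclusion_list <- function() {
  data.frame(
    code = c("09E03", "17D02J", "17D03J", "23", "25A01",
             "25B01", "25B02", "25B03", "25B04", "25D01"),
    description = c(
      "Hanging",
      "Falls, long fall (>= 6 ft/2 m) - Jumper",
      "Falls, unconscious or not alert - Jumper",
      "Intentional poisoning",
      "Psychiatric, non-suicidal without 1st party verification (alert & awake)",
      "Psychiatric, serious haemorrhage",
      "Psychiatric, minor haemorrhage",
      "Psychiatric, threatening suicide",
      "Psychiatric, jumper (threatening)",
      "Psychiatric, not alert"),
    stringsAsFactors = FALSE
  )
}

#' Test whether an AMPDS code marks a mental-health / self-harm call
#'
#' Pure membership test against the inclusion list. Full codes are matched
#' exactly. Chapter-level entries (two characters, such as "23") match any
#' code starting with that chapter under `mode = "prefix"` (the default);
#' under `mode = "exact"` only the literal string matches.
#'
#' @param code character vector of final AMPDS codes.
#' @param codes inclusion list, as from [ampds_inclusion_list()], or a
#'   character vector of codes.
#' @param mode `"prefix"` (chapter entries match by prefix) or `"exact"`.
#' @return logical vector.
#' @examples
#' is_mh_code(c("25B03", "12D01", "23C01"))
#' is_mh_code("23C01", mode = "exact")
#' @export
is_mh_code <- function(code, codes = ampds_inclusion_list(),
                       mode = c("prefix", "exact")) {
  mode <- match.arg(mode)
  if (is.data.frame(codes)) codes <- codes$code
  codes <- as.character(codes)
  code <- as.character(code)
  hit <- code %in% codes
  if (mode == "prefix") {
    chapters <- codes[nchar(codes) <= 2L]
    for (ch in chapters) {
      hit <- hit | startsWith(code, ch)
    }
  }
  hit & !is.na(code) & nzchar(code)
}

.year_window <- function(year) {
  lo <- as.POSIXct(sprintf("%d-01-01 00:00", year), tz = "UTC")
  hi <- as.POSIXct(sprintf("%d-01-01 00:00", year + 1L), tz = "UTC")
  list(lo = lo, hi = hi)
}

#' Select mental-health ambulance calls in the index year
#'
#' Returns every ambulance (S-class) contact in the stated calendar year
#' whose final AMPDS code is on the inclusion list. The year window is
#' inclusive of Jan 1 00:00 and Dec 31 23:59.
#'
#' @param bundle a `record_bundle`.
#' @param codes inclusion list (see [ampds_inclusion_list()]).
#' @param year index calendar year.
#' @param mode code matching mode, see [is_mh_code()].
#' @return The qualifying rows of `bundle$calls`, with attributes `n_calls`
#'   and `n_callers` (distinct persons).
#' @export
select_mh_calls <- function(bundle, codes = ampds_inclusion_list(),
                            year = 2011L, mode = c("prefix", "exact")) {
  stopifnot(inherits(bundle, "record_bundle"))
  mode <- match.arg(mode)
  w <- .year_window(year)
  calls <- bundle$calls
  keep <- calls$start_datetime >= w$lo & calls$start_datetime < w$hi &
    is_mh_code(calls$final_ampds_code, codes, mode)
  out <- calls[which(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_calls") <- nrow(out)
  attr(out, "n_callers") <- length(unique(out$person_id))
  attr(out, "year") <- as.integer(year)
  out
}

.age_at <- function(dob, when) {
  when <- as.POSIXlt(when, tz = "UTC")
  dob <- as.POSIXlt(dob, tz = "UTC")
  age <- when$year - dob$year
  pre_birthday <- (when$mon < dob$mon) |
    (when$mon == dob$mon & when$mday < dob$mday)
  age - as.integer(pre_birthday)
}

#' Select the index cohort
#'
#' One index episode per eligible person: the earliest qualifying
#' mental-health call in the index year. Persons under 16 (attained age in
#' completed years at the index call), persons not resident in scope, and
#' persons with no usable date of birth are excluded, with exclusion
#' reasons tallied.
#'
#' @param mh_calls output of [select_mh_calls()].
#' @param persons the persons table of the bundle.
#' @param year index calendar year (for bookkeeping only; `mh_calls` is
#'   already restricted to the year).
#' @return list with `cohort` (data frame: `person_id`, `index_contact_id`,
#'   `index_datetime`, `age_at_index`, `sex`) and `exclusions` (data frame
#'   of reason and count; reasons are `unknown_age`, `under_16`,
#'   `non_resident`).
#' @export
select_index_cohort <- function(mh_calls, persons, year = 2011L) {
  if (nrow(mh_calls) == 0L) {
    return(list(
      cohort = data.frame(person_id = character(),
                          index_contact_id = character(),
                          index_datetime = as.POSIXct(character(), tz = "UTC"),
                          age_at_index = integer(),
                          sex = character()),
      exclusions = data.frame(reason = c("unknown_age", "under_16",
                                         "non_resident"),
                              count = c(0L, 0L, 0L))))
  }
  ord <- order(mh_calls$person_id, mh_calls$start_datetime,
               mh_calls$contact_id)
  calls <- mh_calls[ord, , drop = FALSE]
  first <- calls[!duplicated(calls$person_id), , drop = FALSE]

  idx <- match(first$person_id, persons$person_id)
  dob <- persons$date_of_birth[idx]
  resident <- persons$resident_in_scope[idx]
  sex <- persons$sex[idx]
  age <- rep(NA_integer_, nrow(first))
  ok_dob <- !is.na(idx) & !is.na(dob)
  age[ok_dob] <- .age_at(dob[ok_dob], first$start_datetime[ok_dob])

  reason <- rep(NA_character_, nrow(first))
  reason[!ok_dob] <- "unknown_age"
  reason[is.na(reason) & age < 16L] <- "under_16"
  reason[is.na(reason) & (is.na(resident) | !resident)] <- "non_resident"

  keep <- is.na(reason)
  cohort <- data.frame(person_id = first$person_id[keep],
                       index_contact_id = first$contact_id[keep],
                       index_datetime = first$start_datetime[keep],
                       age_at_index = age[keep],
                       sex = sex[keep],
                       stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  tally <- table(factor(reason[!keep],
                        levels = c("unknown_age", "under_16", "non_resident")))
  exclusions <- data.frame(reason = names(tally),
                           count = as.integer(tally),
                           stringsAsFactors = FALSE)
  list(cohort = cohort, exclusions = exclusions)
}

#' Tabulate reasons for emergency call
#'
#' Frequency of final AMPDS descriptions over a set of mental-health calls,
#' optionally restricted to calls with a direct ambulance-to-ED transfer
#' (`transported = TRUE`). Percentages are of the respective totals.
#'
#' @param mh_calls output of [select_mh_calls()] (possibly restricted to
#'   the cohort).
#' @param codes inclusion list supplying descriptions.
#' @param transport_filter if `TRUE`, restrict to transported calls.
#' @return data frame with `code`, `description`, `count`, `pct`, ordered
#'   by descending count.
#' @export
tabulate_reasons <- function(mh_calls, codes = ampds_inclusion_list(),
                             transport_filter = FALSE) {
  calls <- mh_calls
  if (transport_filter) calls <- calls[which(calls$transported), , drop = FALSE]
  if (nrow(calls) == 0L) {
    return(data.frame(code = character(), description = character(),
                      count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  # map each call to its inclusion entry (chapter codes by prefix)
  entry <- rep(NA_character_, nrow(calls))
  for (i in seq_len(nrow(codes))) {
    cd <- codes$code[i]
    m <- if (nchar(cd) <= 2L) startsWith(calls$final_ampds_code, cd)
         else calls$final_ampds_code == cd
    entry[is.na(entry) & m] <- cd
  }
  entry[is.na(entry)] <- "other"
  counts <- table(entry)
  out <- data.frame(code = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$description <- codes$description[match(out$code, codes$code)]
  out$description[is.na(out$description)] <- "Other"
  out$pct <- 100 * out$count / sum(out$count)
  out <- out[order(-out$count, out$code), c("code", "description", "count",
                                            "pct")]
  rownames(out) <- NULL
  out
}
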