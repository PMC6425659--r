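# Shared fixture builders for the test suite.

ts <- function(x) as.POSIXct(x, tz = "UTC",
                             tryFormats = c("%Y-%m-%d %H:%M:%S",
                                            "%Y-%m-%d %H:%M",
                                            "%Y-%m-%d"))

make_persons <- function(ids, dob = "1980-06-15", sex = "female",
                         resident = TRUE) {
  n <- length(ids)
  data.frame(person_id = ids,
             date_of_birth = as.Date(rep_len(dob, n)),
             sex = rep_len(sex, n),
             resident_in_scope = rep_len(resident, n),
             stringsAsFactors = FALSE)
}

make_calls <- function(ids, person, start, end = NULL, code = "25B03",
                       alcohol = FALSE, drug = FALSE, lowp = FALSE,
                       transported = FALSE) {
  n <- length(ids)
  start <- ts(start)
  end <- if (is.null(end)) start + 30 * 60 else ts(end)
  data.frame(contact_id = ids, person_id = rep_len(person, n),
             start_datetime = start, end_datetime = end,
             final_ampds_code = rep_len(code, n),
             alcohol_flag = rep_len(alcohol, n),
             drug_flag = rep_len(drug, n),
             lowest_priority_flag = rep_len(lowp, n),
             transported = rep_len(transported, n),
             stringsAsFactors = FALSE)
}

make_ed <- function(ids, person, start, end, disposition = "completed",
                    triage = NA_integer_) {
  n <- length(ids)
  data.frame(contact_id = ids, person_id = rep_len(person, n),
             start_datetime = ts(start), end_datetime = ts(end),
             disposition = rep_len(disposition, n),
             triage_category = rep_len(as.integer(triage), n),
             stringsAsFactors = FALSE)
}

make_admissions <- function(ids, person, start, end, ward = "acute") {
  n <- length(ids)
  data.frame(contact_id = ids, person_id = rep_len(person, n),
             start_datetime = ts(start), end_datetime = ts(end),
             ward_type = rep_len(ward, n),
             stringsAsFactors = FALSE)
}

make_deaths <- function(person, date, cause = "suicide") {
  data.frame(person_id = person, date_of_death = as.Date(date),
             cause_category = rep_len(cause, length(person)),
             stringsAsFactors = FALSE)
}

empty_tab <- function(name) empty_bundle()[[name]]

# A five-person bundle exercising every pathway class, used across files.
small_bundle <- function() {
  persons <- make_persons(paste0("P", 1:5))
  calls <- rbind(
    make_calls("S1", "P1", "2011-03-01 10:00"),                    # S only
    make_calls("S2", "P2", "2011-04-02 09:00", transported = TRUE),  # SE
    make_calls("S3", "P3", "2011-05-03 08:00", transported = TRUE,
               alcohol = TRUE),                                    # SEA
    make_calls("S4", "P4", "2011-06-04 07:00", transported = TRUE),  # SEM
    make_calls("S5", "P5", "2011-07-05 06:00")                     # SM
  )
  ed <- rbind(
    make_ed("E1", "P2", "2011-04-02 10:00", "2011-04-02 12:30",
            "self_discharge"),
    make_ed("E2", "P3", "2011-05-03 09:00", "2011-05-03 11:30", "admitted"),
    make_ed("E3", "P4", "2011-06-04 08:00", "2011-06-04 10:00", "admitted")
  )
  admissions <- rbind(
    make_admissions("A1", "P3", "2011-05-03 12:00", "2011-05-04 12:00",
                    "acute"),
    make_admissions("M1", "P4", "2011-06-04 11:00", "2011-06-12 11:00",
                    "psychiatric"),
    make_admissions("M2", "P5", "2011-07-05 08:00", "2011-07-15 08:00",
                    "psychiatric")
  )
  deaths <- make_deaths("P1", "2011-09-20", "other")
  record_bundle(persons, calls, ed, admissions, deaths)
}
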