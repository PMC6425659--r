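# Canonical record schemas for the five linked tables and their CSV I/O.
#
# A bundle holds person-level linked service records: persons, ambulance
# calls (S), emergency-department attendances (E), hospital admissions
# (A = acute, M = psychiatric) and death records, joined by person_id.
# Timestamps are minute-resolution POSIXct in UTC; calendar fields are Date.

.bundle_columns <- list(
  persons    = c("person_id", "date_of_birth", "sex", "resident_in_scope"),
  calls      = c("contact_id", "person_id", "start_datetime", "end_datetime",
                 "final_ampds_code", "alcohol_flag", "drug_flag",
                 "lowest_priority_flag", "transported"),
  ed         = c("contact_id", "person_id", "start_datetime", "end_datetime",
                 "disposition", "triage_category"),
  admissions = c("contact_id", "person_id", "start_datetime", "end_datetime",
                 "ward_type"),
  deaths     = c("person_id", "date_of_death", "cause_category")
)

.enum_levels <- list(
  sex            = c("male", "female", "unknown"),
  disposition    = c("completed", "self_discharge", "admitted"),
  ward_type      = c("acute", "psychiatric"),
  cause_category = c("suicide", "mental_behavioural", "other")
)

.ts_format <- "%Y-%m-%dT%H:%M"

.parse_ts <- function(x, table, col, required = FALSE) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  blank <- is.na(x) | !nzchar(x)
  parsed <- as.POSIXct(x[!blank], format = .ts_format, tz = "UTC")
  # second pass: allow a space separator and optional seconds
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%S")) {
    bad <- is.na(parsed)
    if (!any(bad)) break
    parsed[bad] <- as.POSIXct(x[!blank][bad], format = fmt, tz = "UTC")
  }
  if (anyNA(parsed)) {
    rows <- which(!blank)[is.na(parsed)]
    stop(sprintf("table '%s', column '%s': unparseable timestamp at row(s) %s",
                 table, col, paste(utils::head(rows, 10L), collapse = ", ")),
         call. = FALSE)
  }
  out[!blank] <- parsed
  if (required && any(blank)) {
    stop(sprintf("table '%s', column '%s': missing timestamp at row(s) %s",
                 table, col,
                 paste(utils::head(which(blank), 10L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

.parse_date <- function(x, table, col) {
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & nzchar(x) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("table '%s', column '%s': unparseable date at row(s) %s",
                 table, col, paste(utils::head(bad, 10L), collapse = ", ")),
         call. = FALSE)
  }
  out
}

# Lenient boolean parse for optional flags: absent/blank reads as FALSE,
# mirroring optional free-field items that are frequently not completed.
.parse_flag <- function(x, table, col, blank_is = FALSE) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  blank <- is.na(x) | !nzchar(x)
  if (is.na(blank_is) && any(blank)) {
    stop(sprintf("table '%s', column '%s': missing boolean at row(s) %s",
                 table, col,
                 paste(utils::head(which(blank), 10L), collapse = ", ")),
         call. = FALSE)
  }
  out[blank] <- blank_is
  bad <- which(is.na(out) & !blank)
  if (length(bad)) {
    stop(sprintf(
      "table '%s', column '%s': unparseable boolean value '%s' at row %d",
      table, col, x[bad[1L]], bad[1L]), call. = FALSE)
  }
  out
}

.check_enum <- function(x, table, col) {
  levels <- .enum_levels[[col]]
  x <- as.character(x)
  bad <- which(!is.na(x) & nzchar(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf(
      "table '%s', column '%s': unknown value '%s' at row %d (expected one of %s)",
      table, col, x[bad[1L]], bad[1L], paste(levels, collapse = ", ")),
      call. = FALSE)
  }
  x[!nzchar(x)] <- NA_character_
  x
}

#' Construct a linked record bundle
#'
#' Assembles the five linked tables (persons, ambulance calls,
#' emergency-department attendances, hospital admissions, deaths) into a
#' single typed bundle after enforcing column layout and enumerated values.
#' Structural problems that are reportable rather than fatal (orphan keys,
#' inverted intervals, duplicate deaths) are left to [validate_bundle()].
#'
#' @param persons data frame with columns `person_id`, `date_of_birth`
#'   (`Date`), `sex` (`male`/`female`/`unknown`), `resident_in_scope`
#'   (logical).
#' @param calls data frame of ambulance calls (service class S) with
#'   `contact_id`, `person_id`, `start_datetime`, `end_datetime`,
#'   `final_ampds_code` and the logical flags `alcohol_flag`, `drug_flag`,
#'   `lowest_priority_flag`, `transported`.
#' @param ed data frame of emergency-department attendances (class E) with
#'   `disposition` (`completed`/`self_discharge`/`admitted`) and optional
#'   ordinal `triage_category`.
#' @param admissions data frame of inpatient episodes with `ward_type`
#'   (`acute` maps to class A, `psychiatric` to class M).
#' @param deaths data frame with `person_id`, `date_of_death` (`Date`) and
#'   `cause_category` (`suicide`/`mental_behavioural`/`other`).
#' @return An object of class `record_bundle`: a list of the five typed
#'   tables.
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
record_bundle <- function(persons, calls, ed, admissions, deaths) {
  tables <- list(persons = persons, calls = calls, ed = ed,
                 admissions = admissions, deaths = deaths)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (!is.data.frame(tab)) {
      stop(sprintf("'%s' must be a data frame", nm), call. = FALSE)
    }
    missing <- setdiff(.bundle_columns[[nm]], names(tab))
    if (length(missing)) {
      stop(sprintf("table '%s' is missing column(s): %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tab <- tab[.bundle_columns[[nm]]]
    rownames(tab) <- NULL
    tables[[nm]] <- tab
  }

  p <- tables$persons
  p$person_id <- as.character(p$person_id)
  p$date_of_birth <- as.Date(p$date_of_birth)
  p$sex <- .check_enum(p$sex, "persons", "sex")
  if (!is.logical(p$resident_in_scope)) {
    p$resident_in_scope <- .parse_flag(p$resident_in_scope, "persons",
                                       "resident_in_scope", blank_is = NA)
  }
  tables$persons <- p

  for (nm in c("calls", "ed", "admissions")) {
    tab <- tables[[nm]]
    tab$contact_id <- as.character(tab$contact_id)
    tab$person_id <- as.character(tab$person_id)
    for (col in c("start_datetime", "end_datetime")) {
      if (!inherits(tab[[col]], "POSIXct")) {
        tab[[col]] <- .parse_ts(tab[[col]], nm, col,
                                required = col == "start_datetime")
      } else {
        attr(tab[[col]], "tzone") <- "UTC"
      }
    }
    tables[[nm]] <- tab
  }

  cl <- tables$calls
  cl$final_ampds_code <- as.character(cl$final_ampds_code)
  if (nrow(cl) && any(is.na(cl$final_ampds_code) | !nzchar(cl$final_ampds_code))) {
    stop("table 'calls': final_ampds_code must be non-empty", call. = FALSE)
  }
  for (col in c("alcohol_flag", "drug_flag", "lowest_priority_flag",
                "transported")) {
    if (!is.logical(cl[[col]])) {
      cl[[col]] <- .parse_flag(cl[[col]], "calls", col)
    } else {
      cl[[col]][is.na(cl[[col]])] <- FALSE
    }
  }
  tables$calls <- cl

  e <- tables$ed
  e$disposition <- .check_enum(e$disposition, "ed", "disposition")
  if (nrow(e) && anyNA(e$disposition)) {
    stop("table 'ed': disposition must always be present", call. = FALSE)
  }
  e$triage_category <- suppressWarnings(as.integer(e$triage_category))
  tables$ed <- e

  a <- tables$admissions
  a$ward_type <- .check_enum(a$ward_type, "admissions", "ward_type")
  if (nrow(a) && anyNA(a$ward_type)) {
    stop("table 'admissions': ward_type must always be present", call. = FALSE)
  }
  tables$admissions <- a

  d <- tables$deaths
  d$person_id <- as.character(d$person_id)
  d$date_of_death <- as.Date(d$date_of_death)
  d$cause_category <- .check_enum(d$cause_category, "deaths", "cause_category")
  tables$deaths <- d

  structure(tables, class = "record_bundle")
}

#' Create an empty linked record bundle
#'
#' @return A `record_bundle` whose five tables have the documented columns
#'   and zero rows.
#' @export
empty_bundle <- function() {
  ts0 <- as.POSIXct(character(), tz = "UTC")
  record_bundle(
    persons = data.frame(person_id = character(),
                         date_of_birth = as.Date(character()),
                         sex = character(),
                         resident_in_scope = logical()),
    calls = data.frame(contact_id = character(), person_id = character(),
                       start_datetime = ts0, end_datetime = ts0,
                       final_ampds_code = character(),
                       alcohol_flag = logical(), drug_flag = logical(),
                       lowest_priority_flag = logical(),
                       transported = logical()),
    ed = data.frame(contact_id = character(), person_id = character(),
                    start_datetime = ts0, end_datetime = ts0,
                    disposition = character(),
                    triage_category = integer()),
    admissions = data.frame(contact_id = character(), person_id = character(),
                            start_datetime = ts0, end_datetime = ts0,
                            ward_type = character()),
    deaths = data.frame(person_id = character(),
                        date_of_death = as.Date(character()),
                        cause_category = character())
  )
}

#' Read a linked record bundle from a directory of CSV files
#'
#' Expects `persons.csv`, `calls.csv`, `ed.csv`, `admissions.csv` and
#' `deaths.csv` in the documented dialect (comma separated, UTF-8, header
#' row, ISO-8601 timestamps to minute resolution). A missing file is fatal;
#' unparseable timestamps are reported with their row numbers; unknown
#' enumerated values are fatal and name the offending value. Blank optional
#' flags read as `FALSE`.
#'
#' @param path directory containing the five CSV files.
#' @return A `record_bundle`.
#' @export
read_bundle <- function(path) {
  files <- file.path(path, paste0(names(.bundle_columns), ".csv"))
  names(files) <- names(.bundle_columns)
  absent <- !file.exists(files)
  if (any(absent)) {
    stop("missing table file(s): ",
         paste(basename(files[absent]), collapse = ", "), call. = FALSE)
  }
  raw <- lapply(names(files), function(nm) {
    tab <- utils::read.csv(files[[nm]], colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
    missing <- setdiff(.bundle_columns[[nm]], names(tab))
    if (length(missing)) {
      stop(sprintf("table '%s' is missing column(s): %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    tab
  })
  names(raw) <- names(files)
  raw$persons$date_of_birth <- .parse_date(raw$persons$date_of_birth,
                                           "persons", "date_of_birth")
  raw$deaths$date_of_death <- .parse_date(raw$deaths$date_of_death,
                                          "deaths", "date_of_death")
  record_bundle(raw$persons, raw$calls, raw$ed, raw$admissions, raw$deaths)
}

.fmt_ts <- function(x) {
  out <- format(x, .ts_format, tz = "UTC")
  out[is.na(x)] <- ""
  out
}

.fmt_flag <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

#' Write a linked record bundle to a directory of CSV files
#'
#' Writes the five tables with their documented headers, ISO-8601
#' minute-resolution timestamps and a deterministic row order (person_id,
#' then start time, then contact_id), so that writing the same bundle twice
#' produces byte-identical files.
#'
#' @param bundle a `record_bundle`.
#' @param path output directory (created if needed).
#' @return Invisibly, the paths of the five files written.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "record_bundle"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) {
      stop("cannot create output directory: ", path, call. = FALSE)
    }
  }
  out <- character(0)

  p <- bundle$persons
  p <- p[order(p$person_id), , drop = FALSE]
  p$date_of_birth <- format(p$date_of_birth, "%Y-%m-%d")
  p$resident_in_scope <- .fmt_flag(p$resident_in_scope)

  fmt_contacts <- function(tab) {
    tab <- tab[order(tab$person_id, tab$start_datetime, tab$contact_id), ,
               drop = FALSE]
    tab$start_datetime <- .fmt_ts(tab$start_datetime)
    tab$end_datetime <- .fmt_ts(tab$end_datetime)
    tab
  }
  cl <- fmt_contacts(bundle$calls)
  for (col in c("alcohol_flag", "drug_flag", "lowest_priority_flag",
                "transported")) {
    cl[[col]] <- .fmt_flag(cl[[col]])
  }
  e <- fmt_contacts(bundle$ed)
  e$triage_category <- ifelse(is.na(e$triage_category), "",
                              as.character(e$triage_category))
  a <- fmt_contacts(bundle$admissions)
  d <- bundle$deaths
  d <- d[order(d$person_id), , drop = FALSE]
  d$date_of_death <- format(d$date_of_death, "%Y-%m-%d")

  tabs <- list(persons = p, calls = cl, ed = e, admissions = a, deaths = d)
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(nm, ".csv"))
    tab <- tabs[[nm]]
    tab[] <- lapply(tab, function(x) ifelse(is.na(x), "", as.character(x)))
    utils::write.csv(tab, f, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    out <- c(out, f)
  }
  invisible(out)
}

#' Validate a linked record bundle
#'
#' Checks cross-table referential integrity and within-record invariants.
#' Validation never raises on data problems: every finding is returned as a
#' row of the report, with severity `"error"` (orphan foreign keys,
#' duplicate person identifiers, intervals ending before they start,
#' multiple death records for one person) or `"warning"` (a death dated
#' before one of that person's contacts started).
#'
#' @param bundle a `record_bundle`.
#' @return An object of class `bundle_validation`: a list with `issues`
#'   (data frame of `table`, `row`, `severity`, `message`) and `is_clean`
#'   (`TRUE` iff there are zero errors).
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "record_bundle"))
  issues <- list()
  add <- function(table, row, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, row = as.integer(row), severity = severity,
      message = message, stringsAsFactors = FALSE)
  }

  p <- bundle$persons
  dup <- which(duplicated(p$person_id))
  for (i in dup) {
    add("persons", i, "error",
        sprintf("duplicate person_id '%s'", p$person_id[i]))
  }
  known <- unique(p$person_id)

  for (nm in c("calls", "ed", "admissions", "deaths")) {
    tab <- bundle[[nm]]
    orphan <- which(!(tab$person_id %in% known))
    for (i in orphan) {
      add(nm, i, "error",
          sprintf("person_id '%s' not present in persons", tab$person_id[i]))
    }
  }

  for (nm in c("calls", "ed", "admissions")) {
    tab <- bundle[[nm]]
    bad <- which(!is.na(tab$end_datetime) &
                   tab$end_datetime < tab$start_datetime)
    for (i in bad) {
      add(nm, i, "error",
          sprintf("contact '%s' ends before it starts", tab$contact_id[i]))
    }
  }

  d <- bundle$deaths
  dup <- which(duplicated(d$person_id))
  for (i in dup) {
    add("deaths", i, "error",
        sprintf("multiple death records for person '%s'", d$person_id[i]))
  }
  if (nrow(d)) {
    starts <- rbind(
      data.frame(person_id = bundle$calls$person_id,
                 day = as.Date(bundle$calls$start_datetime)),
      data.frame(person_id = bundle$ed$person_id,
                 day = as.Date(bundle$ed$start_datetime)),
      data.frame(person_id = bundle$admissions$person_id,
                 day = as.Date(bundle$admissions$start_datetime))
    )
    if (nrow(starts)) {
      last <- tapply(starts$day, starts$person_id, max)
      idx <- match(d$person_id, names(last))
      late <- which(!is.na(idx) &
                      d$date_of_death < as.Date(last[idx], origin = "1970-01-01"))
      for (i in late) {
        add("deaths", i, "warning",
            sprintf("person '%s' has a contact starting after the death date",
                    d$person_id[i]))
      }
    }
  }

  issues <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(table = character(), row = integer(), severity = character(),
               message = character(), stringsAsFactors = FALSE)
  }
  structure(list(issues = issues,
                 is_clean = !any(issues$severity == "error")),
            class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_warn <- sum(x$issues$severity == "warning")
  cat(sprintf("Bundle validation: %s (%d error(s), %d warning(s))\n",
              if (x$is_clean) "clean" else "NOT clean", n_err, n_warn))
  if (nrow(x$issues)) {
    print(utils::head(x$issues, 20L), row.names = FALSE)
    if (nrow(x$issues) > 20L) cat("...", nrow(x$issues) - 20L, "more\n")
  }
  invisible(x)
}

#' @export
print.record_bundle <- function(x, ...) {
  cat("Linked record bundle\n")
  for (nm in names(.bundle_columns)) {
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
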