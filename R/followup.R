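# Follow-up: person-period conversion, repeat-attendance counting within one
# year of the index call, one-year mortality by pathway class, and the two
# 2x2 tables behind the self-discharge analyses.

.bin_repeats <- function(n) {
  cut(n, breaks = c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, 9.5, 14.5, Inf),
      labels = .repeat_bins)
}

#' Convert index rows to person-period format
#'
#' One row per cohort person, counting that person's subsequent ambulance
#' calls against the index timestamp. By default every later ambulance call
#' counts as a repeat regardless of its AMPDS code (repeat calls by these
#' people are not necessarily mental-health coded); `repeat_scope = "mh"`
#' restricts repeats to inclusion-coded calls. "Within one year" means at
#' most `window_days` (default 365) days after the index timestamp.
#'
#' @param index_rows data frame with one row per person: `person_id`,
#'   `index_datetime`, and optionally `had_selfdischarge_at_index` and
#'   `alcohol_at_index` (carried through).
#' @param calls the bundle's calls table.
#' @param window_days follow-up window in days.
#' @param repeat_scope `"all"` (default) or `"mh"`.
#' @param codes,mode inclusion-list matching for `repeat_scope = "mh"`.
#' @return data frame with `person_id`, `index_datetime`, `n_repeats_1yr`,
#'   `repeat_bin`, plus any carried flags.
#' @export
to_person_period <- function(index_rows, calls, window_days = 365,
                             repeat_scope = c("all", "mh"),
                             codes = ampds_inclusion_list(),
                             mode = c("prefix", "exact")) {
  repeat_scope <- match.arg(repeat_scope)
  mode <- match.arg(mode)
  if (anyDuplicated(index_rows$person_id)) {
    stop("index_rows must contain one row per person", call. = FALSE)
  }
  cand <- calls[calls$person_id %in% index_rows$person_id, , drop = FALSE]
  if (repeat_scope == "mh") {
    cand <- cand[is_mh_code(cand$final_ampds_code, codes, mode), ,
                 drop = FALSE]
  }
  idx <- index_rows$index_datetime[match(cand$person_id,
                                         index_rows$person_id)]
  delta <- as.numeric(difftime(cand$start_datetime, idx, units = "days"))
  in_window <- delta > 0 & delta <= window_days
  counts <- table(factor(cand$person_id[in_window],
                         levels = index_rows$person_id))
  out <- index_rows
  out$n_repeats_1yr <- as.integer(counts[match(out$person_id,
                                               names(counts))])
  out$n_repeats_1yr[is.na(out$n_repeats_1yr)] <- 0L
  out$repeat_bin <- as.character(.bin_repeats(out$n_repeats_1yr))
  rownames(out) <- NULL
  out
}

#' Binned repeat-attendance distribution
#'
#' @param person_period output of [to_person_period()].
#' @return data frame with `bin`, `count`, `pct` in bin order
#'   (0, 1, 2, 3, 4, 5-9, 10-14, 15+); empty input gives an empty table.
#' @export
repeat_distribution <- function(person_period) {
  if (nrow(person_period) == 0L) {
    return(data.frame(bin = character(), count = integer(), pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(factor(person_period$repeat_bin, levels = .repeat_bins))
  data.frame(bin = names(counts), count = as.integer(counts),
             pct = 100 * as.integer(counts) / nrow(person_period),
             stringsAsFactors = FALSE)
}

#' One-year mortality outcomes by pathway class
#'
#' Categorizes each cohort person's death as within one day of the index
#' call (death date at most the index calendar date plus one day) or as
#' later but within one year (at most 365 days after the index date), and
#' cross-tabulates by pathway class. Also derives the headline mortality
#' quantities: late deaths in the S or SE classes, suicides among the late
#' deaths, and suicides among late deaths whose index pathway left them at
#' home or discharged them from the ED (classes S and SE).
#'
#' @param cohort data frame with `person_id`, `index_datetime`.
#' @param deaths the bundle's deaths table.
#' @param classes data frame with `person_id`, `pathway_class`.
#' @return list with `outcomes` (one row per person: flags and cause),
#'   `by_class` (counts of persons, 1-day deaths and late deaths per
#'   class), and `derived` (named list of numerator/denominator pairs).
#' @export
mortality_outcomes <- function(cohort, deaths, classes) {
  out <- data.frame(person_id = cohort$person_id,
                    index_datetime = cohort$index_datetime,
                    stringsAsFactors = FALSE)
  out$pathway_class <- classes$pathway_class[match(out$person_id,
                                                   classes$person_id)]
  m <- match(out$person_id, deaths$person_id)
  death_date <- deaths$date_of_death[m]
  cause <- deaths$cause_category[m]
  index_date <- as.Date(out$index_datetime)

  flagged <- which(!is.na(death_date) & death_date < index_date)
  out$death_before_index <- FALSE
  out$death_before_index[flagged] <- TRUE

  out$died_within_1day <- !is.na(death_date) &
    death_date >= index_date & death_date <= index_date + 1L
  out$died_1day_to_1yr <- !is.na(death_date) &
    death_date > index_date + 1L & death_date <= index_date + 365L
  out$cause_category <- ifelse(out$died_within_1day | out$died_1day_to_1yr,
                               cause, NA_character_)

  lev <- .pathway_classes
  cls <- factor(out$pathway_class, levels = lev)
  by_class <- data.frame(
    pathway_class = lev,
    n = as.integer(table(cls)),
    deaths_within_1day = as.integer(tapply(out$died_within_1day, cls, sum,
                                           default = 0L)),
    deaths_1day_to_1yr = as.integer(tapply(out$died_1day_to_1yr, cls, sum,
                                           default = 0L)),
    stringsAsFactors = FALSE)

  late <- out[out$died_1day_to_1yr, , drop = FALSE]
  dead <- out[out$died_within_1day | out$died_1day_to_1yr, , drop = FALSE]
  derived <- list(
    deaths_within_year = c(sum(out$died_within_1day) + nrow(late),
                           nrow(out)),
    late_deaths = c(nrow(late), nrow(out)),
    late_deaths_S_SE = c(sum(late$pathway_class %in% c("S", "SE")),
                         nrow(late)),
    suicides_within_year = c(sum(dead$cause_category == "suicide",
                                 na.rm = TRUE), nrow(dead)),
    late_suicides = c(sum(late$cause_category == "suicide", na.rm = TRUE),
                      nrow(late)),
    late_suicides_S_SE = c(
      sum(late$cause_category == "suicide" &
            late$pathway_class %in% c("S", "SE"), na.rm = TRUE),
      sum(late$cause_category == "suicide", na.rm = TRUE))
  )
  list(outcomes = out, by_class = by_class, derived = derived)
}

#' Two-by-two tables for the self-discharge analyses
#'
#' Builds (i) the self-discharge-at-index by repeat-call table over persons
#' whose index pathway reached an emergency department, and (ii) the
#' alcohol by self-discharge table over ED-ending pathway rows, ready for
#' [chi_squared_2x2()] and [relative_risk()].
#'
#' @param person_period output of [to_person_period()], carrying
#'   `had_selfdischarge_at_index` and `reached_ed_at_index`.
#' @param ed_rows data frame of ED-ending pathway rows with `alcohol_flag`
#'   and `final_ed_disposition`.
#' @return list with `repeat_table` and `alcohol_table` (each a
#'   `two_by_two` or `NULL` with a reason when degenerate).
#' @export
selfdischarge_analysis <- function(person_period, ed_rows) {
  pp <- person_period[person_period$reached_ed_at_index, , drop = FALSE]
  rep_tab <- NULL
  rep_note <- NULL
  exp1 <- pp$had_selfdischarge_at_index
  out1 <- pp$n_repeats_1yr > 0L
  if (nrow(pp) == 0L || !any(exp1) || all(exp1)) {
    rep_note <- "degenerate: all persons identical on exposure"
  } else {
    rep_tab <- two_by_two(sum(exp1 & out1), sum(exp1 & !out1),
                          sum(!exp1 & out1), sum(!exp1 & !out1))
  }
  alc_tab <- NULL
  alc_note <- NULL
  sd <- ed_rows$final_ed_disposition == "self_discharge"
  alc <- ed_rows$alcohol_flag
  if (nrow(ed_rows) == 0L || !any(alc) || all(alc)) {
    alc_note <- "degenerate: all rows identical on exposure"
  } else {
    alc_tab <- two_by_two(sum(alc & sd), sum(alc & !sd),
                          sum(!alc & sd), sum(!alc & !sd))
  }
  list(repeat_table = rep_tab, repeat_note = rep_note,
       alcohol_table = alc_tab, alcohol_note = alc_note)
}
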