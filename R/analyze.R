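# End-to-end analysis: cohort selection, pathway construction, follow-up,
# statistics and report tables, packaged as a classed result object.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse a linked record bundle
#'
#' Runs the full pipeline on a bundle: select mental-health ambulance calls
#' in the index year, pick the index cohort (adults 16+, resident, first
#' qualifying call), chain every cohort person's contacts into 24-hour care
#' pathways, encode and classify them, count repeat calls within one year,
#' derive one-year mortality, run the self-discharge analyses, and build
#' the three report tables with headline ratios.
#'
#' @param bundle a `record_bundle`.
#' @param year index calendar year.
#' @param codes AMPDS inclusion list (see [ampds_inclusion_list()]).
#' @param mode AMPDS matching mode, see [is_mh_code()].
#' @param gap_hours pathway chaining threshold in hours.
#' @param window_days follow-up window in days.
#' @param repeat_scope `"all"` (any-cause repeat calls; default) or `"mh"`.
#' @param suppress small-cell suppression threshold for rendered tables
#'   (0 = off).
#' @param validate if `TRUE` (default), stop when [validate_bundle()]
#'   reports errors.
#' @return object of class `carepath_analysis`; see the package vignette
#'   for the components.
#' @export
analyze_bundle <- function(bundle, year = 2011L,
                           codes = ampds_inclusion_list(),
                           mode = c("prefix", "exact"),
                           gap_hours = 24, window_days = 365,
                           repeat_scope = c("all", "mh"),
                           suppress = 0L, validate = TRUE) {
  stopifnot(inherits(bundle, "record_bundle"))
  mode <- match.arg(mode)
  repeat_scope <- match.arg(repeat_scope)

  checks <- validate_bundle(bundle)
  if (validate && !checks$is_clean) {
    stop(sprintf("bundle fails validation with %d error(s); see validate_bundle()",
                 sum(checks$issues$severity == "error")), call. = FALSE)
  }

  mh <- select_mh_calls(bundle, codes, year, mode)
  sel <- select_index_cohort(mh, bundle$persons, year)
  cohort <- sel$cohort
  mh_cohort <- mh[mh$person_id %in% cohort$person_id, , drop = FALSE]

  params <- list(year = as.integer(year), mode = mode,
                 gap_hours = gap_hours, window_days = window_days,
                 repeat_scope = repeat_scope, suppress = suppress)

  if (nrow(cohort) == 0L) {
    return(.empty_analysis(bundle, sel, mh, checks, params))
  }

  # ---- pathway construction -------------------------------------------
  contacts <- bundle_contacts(bundle, cohort$person_id)
  pw <- assign_pathways(contacts, gap_hours)
  n_pw <- max(pw$pathway_id)
  code_full <- unname(tapply(pw$service_class, pw$pathway_id, paste,
                             collapse = ""))
  code_str <- substr(code_full, 1L, 11L)
  last_idx <- cumsum(nchar(code_full))
  final_letter <- pw$service_class[last_idx]
  final_contact <- pw$contact_id[last_idx]
  pw_person <- pw$person_id[last_idx]

  # one row per (pathway, mental-health call in the index year)
  anchors <- pw[pw$service_class == "S" &
                  pw$contact_id %in% mh_cohort$contact_id, , drop = FALSE]
  anchors <- anchors[anchors$position <= nchar(code_str[anchors$pathway_id]), ,
                     drop = FALSE]
  rows <- data.frame(
    row_id = seq_len(nrow(anchors)),
    person_id = anchors$person_id,
    pathway_id = anchors$pathway_id,
    anchor_contact_id = anchors$contact_id,
    anchor_position = anchors$position,
    anchor_datetime = anchors$start_datetime,
    code_string = code_str[anchors$pathway_id],
    stringsAsFactors = FALSE)
  rows$pathway_class <- classify_pathway(rows$code_string,
                                         rows$anchor_position)
  rows$ends_in_ed <- final_letter[rows$pathway_id] == "E"
  ed_match <- match(final_contact[rows$pathway_id], bundle$ed$contact_id)
  rows$final_ed_disposition <- ifelse(rows$ends_in_ed,
                                      bundle$ed$disposition[ed_match],
                                      NA_character_)
  rows$final_ed_los_min <- ifelse(
    rows$ends_in_ed,
    as.numeric(difftime(bundle$ed$end_datetime[ed_match],
                        bundle$ed$start_datetime[ed_match], units = "mins")),
    NA_real_)
  cmatch <- match(rows$anchor_contact_id, bundle$calls$contact_id)
  rows$alcohol_flag <- bundle$calls$alcohol_flag[cmatch]
  rows$lowest_priority_flag <- bundle$calls$lowest_priority_flag[cmatch]

  rows <- .add_interval_metrics(rows, pw, bundle)

  # ---- index rows and person-period -----------------------------------
  im <- match(cohort$index_contact_id, rows$anchor_contact_id)
  index_rows <- rows[im[!is.na(im)], , drop = FALSE]
  dropped <- cohort$person_id[is.na(im)]
  if (length(dropped)) {
    message(length(dropped),
            " cohort person(s) without an index pathway row were dropped")
  }
  live_cohort <- cohort[!is.na(im), , drop = FALSE]

  # self-discharge anywhere after the anchor in the index pathway
  sd_paths <- .pathways_with_selfdischarge(pw, bundle, index_rows)
  index_small <- data.frame(
    person_id = index_rows$person_id,
    index_datetime = index_rows$anchor_datetime,
    pathway_class = index_rows$pathway_class,
    reached_ed_at_index = !is.na(index_rows$call_to_ed_min),
    had_selfdischarge_at_index = index_rows$pathway_id %in% sd_paths,
    alcohol_at_index = index_rows$alcohol_flag,
    stringsAsFactors = FALSE)

  pp <- to_person_period(index_small, bundle$calls, window_days,
                         repeat_scope, codes, mode)
  rdist <- repeat_distribution(pp)

  mort <- mortality_outcomes(live_cohort, bundle$deaths,
                             index_small[c("person_id", "pathway_class")])

  sda <- selfdischarge_analysis(pp, rows[rows$ends_in_ed, , drop = FALSE])

  # ---- statistics -------------------------------------------------------
  stats_out <- list()
  if (!is.null(sda$repeat_table)) {
    stats_out$chi_repeat <- chi_squared_2x2(sda$repeat_table)
    stats_out$rr_repeat <- relative_risk(sda$repeat_table)
  }
  if (!is.null(sda$alcohol_table)) {
    stats_out$chi_alcohol <- chi_squared_2x2(sda$alcohol_table)
    stats_out$rr_alcohol <- relative_risk(sda$alcohol_table)
  }
  ed_rows <- rows[rows$ends_in_ed & !is.na(rows$final_ed_los_min), ,
                  drop = FALSE]
  los_sd <- ed_rows$final_ed_los_min[ed_rows$final_ed_disposition ==
                                       "self_discharge"]
  los_comp <- ed_rows$final_ed_los_min[ed_rows$final_ed_disposition ==
                                         "completed"]
  if (length(los_sd) && length(los_comp)) {
    stats_out$ranksum_los <- rank_sum_test(los_sd, los_comp)
    stats_out$median_los_selfdischarge <- median_iqr(los_sd)
    stats_out$median_los_completed <- median_iqr(los_comp)
  }
  if (nrow(ed_rows)) {
    stats_out$median_los_all <- median_iqr(ed_rows$final_ed_los_min)
  }

  # ---- tables and headlines --------------------------------------------
  per_person <- data.frame(
    person_id = index_small$person_id,
    pathway_class = index_small$pathway_class,
    lowest_priority = index_rows$lowest_priority_flag,
    any_repeat = pp$n_repeats_1yr > 0L,
    died_within_1day = mort$outcomes$died_within_1day[
      match(index_small$person_id, mort$outcomes$person_id)],
    died_1day_to_1yr = mort$outcomes$died_1day_to_1yr[
      match(index_small$person_id, mort$outcomes$person_id)],
    stringsAsFactors = FALSE)

  table1 <- build_table1(tabulate_reasons(mh_cohort, codes),
                         tabulate_reasons(mh_cohort, codes,
                                          transport_filter = TRUE),
                         suppress = suppress)
  table2 <- build_table2(rdist, suppress = suppress)
  table3 <- build_table3(per_person, suppress = suppress)

  n_ed_rows <- sum(rows$ends_in_ed, na.rm = TRUE)
  n_sd_rows <- sum(rows$final_ed_disposition == "self_discharge",
                   na.rm = TRUE)
  d <- mort$derived
  hl <- data.frame(
    name = c("selfdischarge_of_ed_rows", "died_within_year",
             "suicide_of_deaths", "late_deaths_S_SE", "any_repeat",
             "alcohol_of_calls", "male_of_calls"),
    numerator = c(n_sd_rows, d$deaths_within_year[1L],
                  d$suicides_within_year[1L], d$late_deaths_S_SE[1L],
                  sum(pp$n_repeats_1yr > 0L),
                  sum(mh_cohort$alcohol_flag),
                  sum(bundle$persons$sex[match(
                    mh_cohort$person_id, bundle$persons$person_id)] == "male")),
    denominator = c(max(1L, n_ed_rows), d$deaths_within_year[2L],
                    max(1L, d$suicides_within_year[2L]),
                    max(1L, d$late_deaths_S_SE[2L]),
                    nrow(pp), nrow(mh_cohort), nrow(mh_cohort)),
    digits = c(0, 1, 1, 0, 1, 2, 0),
    stringsAsFactors = FALSE)
  headlines <- headline_ratios(hl)

  structure(list(
    cohort = live_cohort, exclusions = sel$exclusions, mh_calls = mh_cohort,
    n_mh_calls = nrow(mh), n_mh_callers = attr(mh, "n_callers"),
    pathway_rows = rows, index_rows = index_rows,
    person_period = pp, repeat_distribution = rdist,
    mortality = mort, tables_2x2 = sda, stats = stats_out,
    table1 = table1, table2 = table2, table3 = table3,
    headlines = headlines, validation = checks, params = params
  ), class = "carepath_analysis")
}

# first E/A/M contact after the anchor, per pathway row
.add_interval_metrics <- function(rows, pw, bundle) {
  rows$call_to_ed_min <- NA_real_
  rows$ed_los_min <- NA_real_
  rows$acute_los_days <- NA_real_
  rows$psych_los_days <- NA_real_
  sub <- pw[pw$pathway_id %in% rows$pathway_id &
              pw$service_class != "S", , drop = FALSE]
  if (!nrow(sub)) return(rows)
  mm <- merge(rows[c("row_id", "pathway_id", "anchor_position",
                     "anchor_datetime")],
              sub[c("pathway_id", "position", "service_class",
                    "start_datetime", "end_datetime")],
              by = "pathway_id")
  mm <- mm[mm$position > mm$anchor_position, , drop = FALSE]
  if (!nrow(mm)) return(rows)
  mm <- mm[order(mm$row_id, mm$service_class, mm$position), , drop = FALSE]
  first <- mm[!duplicated(paste(mm$row_id, mm$service_class)), , drop = FALSE]

  e <- first[first$service_class == "E", , drop = FALSE]
  if (nrow(e)) {
    i <- match(e$row_id, rows$row_id)
    rows$call_to_ed_min[i] <- as.numeric(difftime(
      e$start_datetime, e$anchor_datetime, units = "mins"))
    rows$ed_los_min[i] <- as.numeric(difftime(
      e$end_datetime, e$start_datetime, units = "mins"))
  }
  a <- first[first$service_class == "A", , drop = FALSE]
  if (nrow(a)) {
    rows$acute_los_days[match(a$row_id, rows$row_id)] <- as.numeric(difftime(
      a$end_datetime, a$start_datetime, units = "days"))
  }
  m <- first[first$service_class == "M", , drop = FALSE]
  if (nrow(m)) {
    rows$psych_los_days[match(m$row_id, rows$row_id)] <- as.numeric(difftime(
      m$end_datetime, m$start_datetime, units = "days"))
  }
  rows
}

# pathway ids of index rows containing a self-discharge E after the anchor
.pathways_with_selfdischarge <- function(pw, bundle, index_rows) {
  e <- pw[pw$pathway_id %in% index_rows$pathway_id &
            pw$service_class == "E", , drop = FALSE]
  if (!nrow(e)) return(integer())
  disp <- bundle$ed$disposition[match(e$contact_id, bundle$ed$contact_id)]
  anchor_pos <- index_rows$anchor_position[match(e$pathway_id,
                                                 index_rows$pathway_id)]
  unique(e$pathway_id[disp == "self_discharge" & e$position > anchor_pos])
}

.empty_analysis <- function(bundle, sel, mh, checks, params) {
  empty_pp <- data.frame(person_id = character(),
                         index_datetime = as.POSIXct(character(), tz = "UTC"),
                         pathway_class = character(),
                         reached_ed_at_index = logical(),
                         had_selfdischarge_at_index = logical(),
                         alcohol_at_index = logical(),
                         n_repeats_1yr = integer(),
                         repeat_bin = character(),
                         stringsAsFactors = FALSE)
  per_person <- data.frame(person_id = character(),
                           pathway_class = character(),
                           lowest_priority = logical(),
                           any_repeat = logical(),
                           died_within_1day = logical(),
                           died_1day_to_1yr = logical(),
                           stringsAsFactors = FALSE)
  structure(list(
    cohort = sel$cohort, exclusions = sel$exclusions, mh_calls = mh,
    n_mh_calls = nrow(mh), n_mh_callers = attr(mh, "n_callers") %||% 0L,
    pathway_rows = data.frame(), index_rows = data.frame(),
    person_period = empty_pp,
    repeat_distribution = repeat_distribution(empty_pp),
    mortality = mortality_outcomes(sel$cohort, bundle$deaths,
                                   data.frame(person_id = character(),
                                              pathway_class = character())),
    tables_2x2 = list(repeat_table = NULL, alcohol_table = NULL),
    stats = list(),
    table1 = build_table1(tabulate_reasons(mh),
                          tabulate_reasons(mh, transport_filter = TRUE),
                          suppress = params$suppress),
    table2 = build_table2(repeat_distribution(empty_pp),
                          suppress = params$suppress),
    table3 = build_table3(per_person, suppress = params$suppress),
    headlines = NULL, validation = checks, params = params
  ), class = "carepath_analysis")
}

#' @export
print.carepath_analysis <- function(x, ...) {
  cat("Care-pathway analysis of ambulance mental-health emergencies\n")
  cat(sprintf("  index year %d: %d qualifying calls from %d people; cohort %d\n",
              x$params$year, x$n_mh_calls, x$n_mh_callers, nrow(x$cohort)))
  if (nrow(x$cohort) == 0L) return(invisible(x))
  cls <- prop.table(table(factor(x$index_rows$pathway_class,
                                 levels = .pathway_classes)))
  cat("  index pathway mixture:",
      paste(sprintf("%s %.1f%%", names(cls), 100 * cls), collapse = ", "),
      "\n")
  if (!is.null(x$headlines)) {
    cat("  headline ratios:\n")
    print(x$headlines)
  }
  for (nm in c("rr_alcohol", "rr_repeat", "ranksum_los")) {
    if (!is.null(x$stats[[nm]])) {
      cat("  "); print(x$stats[[nm]])
    }
  }
  invisible(x)
}

#' @export
summary.carepath_analysis <- function(object, ...) {
  print(object)
  cat("\n")
  print(object$table2)
  cat("\n")
  print(object$table3)
  invisible(object)
}

#' Run the whole pipeline and write its artifacts
#'
#' Either analyses an existing bundle or first simulates one from a
#' configuration, then writes every analysis artifact as CSV into the
#' output directory: the (possibly simulated) bundle, cohort and
#' exclusions, pathway rows, person-period rows, mortality outcomes, the
#' three rendered tables, headline ratios, test statistics and a run log.
#' Identical inputs and seed produce byte-identical output files.
#'
#' @param out_dir output directory (created if needed).
#' @param bundle a `record_bundle` (analyse mode), or `NULL` to simulate.
#' @param config a `simulation_config` (simulate mode).
#' @param seed seed for simulate mode (defaults to the config's seed).
#' @param ... further arguments passed to [analyze_bundle()].
#' @return the `carepath_analysis`, invisibly.
#' @export
run_pipeline <- function(out_dir, bundle = NULL, config = NULL, seed = NULL,
                         ...) {
  if (is.null(bundle)) {
    if (is.null(config)) config <- default_config()
    seed <- seed %||% config$seed
    bundle <- generate_bundle(config, seed = seed)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_bundle(bundle, file.path(out_dir, "bundle"))
  an <- analyze_bundle(bundle, ...)

  wcsv <- function(x, name) {
    df <- as.data.frame(x)
    for (col in names(df)) {
      if (inherits(df[[col]], "POSIXct")) df[[col]] <- .fmt_ts(df[[col]])
    }
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  wcsv(an$cohort, "cohort")
  wcsv(an$exclusions, "exclusions")
  if (is.data.frame(an$pathway_rows) && nrow(an$pathway_rows)) {
    wcsv(an$pathway_rows[setdiff(names(an$pathway_rows), "row_id")],
         "pathway_rows")
  } else {
    wcsv(data.frame(), "pathway_rows")
  }
  wcsv(an$person_period, "person_period")
  wcsv(an$mortality$outcomes, "mortality")
  wcsv(render_table(an$table1), "table1")
  wcsv(render_table(an$table2), "table2")
  wcsv(render_table(an$table3), "table3")
  if (!is.null(an$headlines)) wcsv(an$headlines, "headlines")

  stat_rows <- lapply(names(an$stats), function(nm) {
    s <- an$stats[[nm]]
    if (inherits(s, "carepath_stat")) {
      data.frame(name = nm, method = s$method, statistic = s$statistic,
                 p_value = s$p_value, effect = s$effect,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = nm, method = "median_iqr", statistic = s$median,
                 p_value = NA_real_, effect = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  if (length(stat_rows)) wcsv(do.call(rbind, stat_rows), "stats")

  log_lines <- c(
    "carepath pipeline run",
    paste0("package version: ",
           as.character(utils::packageVersion("carepath"))),
    paste0("seed: ", if (is.null(seed)) "none (analyse mode)" else seed),
    paste0("index year: ", an$params$year),
    paste0("persons: ", nrow(bundle$persons)),
    paste0("qualifying calls: ", an$n_mh_calls),
    paste0("cohort: ", nrow(an$cohort)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(an)
}
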