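# Output surfaces: the three summary tables, headline ratios, half-up
# rounding at the printed precision and small-cell disclosure suppression.

#' Round half-up at a fixed number of decimals
#'
#' Commercial (half-up) rounding, matching how the published percentages
#' were rendered; `round_half_up(42.5, 0)` is 43.
#'
#' @param x numeric vector.
#' @param digits decimal places (vectorized).
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

.report_table <- function(name, data, count_cols, suppression_threshold = 0L,
                          total_label = "Total") {
  structure(list(name = name, data = data, count_cols = count_cols,
                 suppression_threshold = as.integer(suppression_threshold),
                 total_label = total_label),
            class = "report_table")
}

#' Render a report table with small-cell suppression
#'
#' Counts strictly between zero and the suppression threshold are rendered
#' as `"< threshold"`; totals are rendered unsuppressed. Suppression only
#' affects rendering — the stored data are never altered.
#'
#' @param x a `report_table`.
#' @return data frame of character columns, ready for printing or CSV.
#' @export
render_table <- function(x) {
  stopifnot(inherits(x, "report_table"))
  out <- x$data
  thr <- x$suppression_threshold
  is_total <- if (nrow(out)) {
    apply(out, 1L, function(r) any(r == x$total_label, na.rm = TRUE))
  } else logical(0)
  for (col in names(out)) {
    v <- out[[col]]
    if (col %in% x$count_cols && thr > 0L) {
      ch <- as.character(v)
      hide <- !is.na(v) & v > 0 & v < thr & !is_total
      ch[hide] <- paste0("< ", thr)
      out[[col]] <- ch
    } else {
      out[[col]] <- as.character(v)
    }
  }
  out
}

#' @export
print.report_table <- function(x, ...) {
  cat(x$name, "\n")
  print(render_table(x), row.names = FALSE)
  invisible(x)
}

#' Build the reasons-for-call table
#'
#' Final AMPDS description frequencies over all calls and over direct
#' ambulance-to-ED transfers, in descending overall frequency.
#'
#' @param reasons output of [tabulate_reasons()] over all calls.
#' @param reasons_transported output over transported calls.
#' @param suppress suppression threshold (0 = off; 15 matches the published
#'   disclosure rule).
#' @param digits decimal places for percentages (default 0).
#' @return a `report_table`.
#' @export
build_table1 <- function(reasons, reasons_transported, suppress = 0L,
                         digits = 0) {
  all_tab <- reasons
  tr <- reasons_transported
  n_count <- tr$count[match(all_tab$code, tr$code)]
  n_count[is.na(n_count)] <- 0L
  total_all <- sum(all_tab$count)
  total_tr <- sum(n_count)
  data <- data.frame(
    description = all_tab$description,
    n = all_tab$count,
    pct = round_half_up(all_tab$pct, digits),
    transported_n = n_count,
    transported_pct = round_half_up(
      if (total_tr > 0) 100 * n_count / total_tr else 0 * n_count, digits),
    stringsAsFactors = FALSE)
  if (nrow(data)) {
    data <- rbind(data, data.frame(
      description = "Total", n = total_all, pct = 100,
      transported_n = total_tr, transported_pct = if (total_tr > 0) 100 else 0,
      stringsAsFactors = FALSE))
  }
  .report_table("Reasons for emergency call", data,
                count_cols = c("n", "transported_n"),
                suppression_threshold = suppress)
}

#' Build the repeat-attendance table
#'
#' Eight repeat-count bins plus a total row; percentages are rendered
#' half-up at the published per-bin precision (mixed one and two decimal
#' places) by default.
#'
#' @param dist output of [repeat_distribution()].
#' @param suppress suppression threshold (0 = off).
#' @param digits decimal places per bin row (recycled).
#' @return a `report_table`.
#' @export
build_table2 <- function(dist, suppress = 0L,
                         digits = c(1, 1, 1, 2, 1, 2, 2, 2)) {
  if (nrow(dist) == 0L) {
    return(.report_table("Repeat attendances within 12 months",
                         data.frame(bin = character(), count = integer(),
                                    pct = numeric()),
                         count_cols = "count",
                         suppression_threshold = suppress))
  }
  digits <- rep_len(digits, nrow(dist))
  data <- data.frame(bin = dist$bin, count = dist$count,
                     pct = round_half_up(dist$pct, digits),
                     stringsAsFactors = FALSE)
  total <- sum(dist$count)
  if (sum(data$count) != total) stop("bin counts do not reconcile")
  data <- rbind(data, data.frame(bin = "Total", count = total, pct = 100,
                                 stringsAsFactors = FALSE))
  .report_table("Repeat attendances within 12 months", data,
                count_cols = "count", suppression_threshold = suppress)
}

#' Build the pathway-by-outcome table
#'
#' Five pathway-class rows plus a total: pathway frequency, lowest
#' dispatch priority at the index call, persons with additional ambulance
#' calls, deaths within one day, and deaths after one day but within one
#' year — counts with row percentages.
#'
#' @param per_person data frame with one row per cohort person and logical
#'   columns `lowest_priority`, `any_repeat`, `died_within_1day`,
#'   `died_1day_to_1yr`, plus `pathway_class`.
#' @param suppress suppression threshold (0 = off; the published table
#'   used 15).
#' @param digits decimal places for percentages.
#' @return a `report_table`.
#' @export
build_table3 <- function(per_person, suppress = 0L, digits = 1) {
  lev <- .pathway_classes
  cls <- factor(per_person$pathway_class, levels = lev)
  count_of <- function(flag) {
    as.integer(tapply(flag, cls, sum, default = 0L))
  }
  n <- as.integer(table(cls))
  data <- data.frame(
    pathway_class = lev,
    n = n,
    pct = round_half_up(if (sum(n) > 0) 100 * n / sum(n) else 0 * n, digits),
    lowest_priority_n = count_of(per_person$lowest_priority),
    repeat_n = count_of(per_person$any_repeat),
    deaths_1day_n = count_of(per_person$died_within_1day),
    deaths_late_n = count_of(per_person$died_1day_to_1yr),
    stringsAsFactors = FALSE)
  pct_of_row <- function(x) {
    round_half_up(ifelse(data$n > 0, 100 * x / data$n, 0), digits)
  }
  data$lowest_priority_pct <- pct_of_row(data$lowest_priority_n)
  data$repeat_pct <- pct_of_row(data$repeat_n)
  data$deaths_1day_pct <- pct_of_row(data$deaths_1day_n)
  data$deaths_late_pct <- pct_of_row(data$deaths_late_n)

  totals <- data.frame(
    pathway_class = "Total",
    n = sum(data$n),
    pct = if (sum(data$n) > 0) 100 else 0,
    lowest_priority_n = sum(data$lowest_priority_n),
    repeat_n = sum(data$repeat_n),
    deaths_1day_n = sum(data$deaths_1day_n),
    deaths_late_n = sum(data$deaths_late_n),
    stringsAsFactors = FALSE)
  tp <- function(x) {
    round_half_up(if (totals$n > 0) 100 * x / totals$n else 0, digits)
  }
  totals$lowest_priority_pct <- tp(totals$lowest_priority_n)
  totals$repeat_pct <- tp(totals$repeat_n)
  totals$deaths_1day_pct <- tp(totals$deaths_1day_n)
  totals$deaths_late_pct <- tp(totals$deaths_late_n)

  if (totals$n != nrow(per_person) ||
      totals$deaths_1day_n != sum(per_person$died_within_1day) ||
      totals$deaths_late_n != sum(per_person$died_1day_to_1yr)) {
    stop("internal-consistency error: table totals do not reconcile",
         call. = FALSE)
  }
  cols <- c("pathway_class", "n", "pct", "lowest_priority_n",
            "lowest_priority_pct", "repeat_n", "repeat_pct", "deaths_1day_n",
            "deaths_1day_pct", "deaths_late_n", "deaths_late_pct")
  .report_table("Pathway of first call, repeat attendance and mortality",
                rbind(data, totals)[cols],
                count_cols = c("n", "lowest_priority_n", "repeat_n",
                               "deaths_1day_n", "deaths_late_n"),
                suppression_threshold = suppress)
}

#' Headline ratios at their printed precision
#'
#' Renders each named numerator/denominator pair as a percentage rounded
#' half-up at its own precision, reproducing the published arithmetic when
#' fed the printed counts.
#'
#' @param counts data frame with columns `name`, `numerator`,
#'   `denominator` and `digits` (decimal places; 0 for integer
#'   percentages).
#' @return the input with an added `pct` column; class `headline_ratios`.
#' @export
headline_ratios <- function(counts) {
  stopifnot(all(c("name", "numerator", "denominator", "digits") %in%
                  names(counts)))
  if (any(counts$denominator <= 0)) {
    stop("zero denominator in headline ratio", call. = FALSE)
  }
  if (any(counts$numerator < 0)) {
    stop("negative numerator in headline ratio", call. = FALSE)
  }
  counts$pct <- round_half_up(100 * counts$numerator / counts$denominator,
                              counts$digits)
  class(counts) <- c("headline_ratios", "data.frame")
  counts
}

#' @export
print.headline_ratios <- function(x, ...) {
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s %6d / %-6d = %s%%\n", x$name[i], x$numerator[i],
                x$denominator[i],
                format(x$pct[i], nsmall = x$digits[i])))
  }
  invisible(x)
}
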