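# Care-pathway engine: chain service contacts with the 24-hour rule, encode
# them as S/E/A/M strings (truncated at 11 letters), duplicate rows per
# mental-health call and classify the anchored suffix.

.class_order <- c(S = 1L, E = 2L, A = 3L, M = 4L)
.pathway_classes <- c("S", "SE", "SEA", "SEM_SM", "OTHER")

#' Assemble the unified contact table of a bundle
#'
#' Stacks ambulance calls (S), emergency-department attendances (E) and
#' admissions (A for acute wards, M for psychiatric wards) into one table
#' of timed service contacts.
#'
#' @param bundle a `record_bundle`.
#' @param person_ids optional character vector restricting the persons.
#' @return data frame with `contact_id`, `person_id`, `service_class`,
#'   `start_datetime`, `end_datetime`, sorted by person, start time,
#'   class (S < E < A < M at identical times), contact id.
#' @export
bundle_contacts <- function(bundle, person_ids = NULL) {
  stopifnot(inherits(bundle, "record_bundle"))
  pick <- function(tab, cls) {
    data.frame(contact_id = tab$contact_id, person_id = tab$person_id,
               service_class = cls,
               start_datetime = tab$start_datetime,
               end_datetime = tab$end_datetime,
               stringsAsFactors = FALSE)
  }
  adm_class <- ifelse(bundle$admissions$ward_type == "psychiatric", "M", "A")
  out <- rbind(pick(bundle$calls, "S"),
               pick(bundle$ed, "E"),
               pick(bundle$admissions, adm_class))
  if (!is.null(person_ids)) {
    out <- out[out$person_id %in% person_ids, , drop = FALSE]
  }
  out <- out[order(out$person_id, out$start_datetime,
                   .class_order[out$service_class], out$contact_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition contacts into care pathways (24-hour rule), bulk form
#'
#' Adds `pathway_id` and `position` columns to a sorted contact table.
#' A contact continues the current pathway when it starts no more than
#' `gap_hours` after the previous contact's end (its start, if the end is
#' absent); exactly `gap_hours` still links. Overlapping contacts (next
#' starts before the previous ends) are chained, not rejected.
#'
#' @param contacts data frame as from [bundle_contacts()] (any number of
#'   persons).
#' @param gap_hours chaining threshold in hours (default 24).
#' @return `contacts` with added integer `pathway_id` (unique across the
#'   table) and `position` (1-based within pathway).
#' @export
assign_pathways <- function(contacts, gap_hours = 24) {
  contacts <- contacts[order(contacts$person_id, contacts$start_datetime,
                             .class_order[contacts$service_class],
                             contacts$contact_id), , drop = FALSE]
  rownames(contacts) <- NULL
  n <- nrow(contacts)
  if (n == 0L) {
    contacts$pathway_id <- integer()
    contacts$position <- integer()
    return(contacts)
  }
  ref_end <- ifelse(is.na(contacts$end_datetime),
                    as.numeric(contacts$start_datetime),
                    as.numeric(contacts$end_datetime))
  start <- as.numeric(contacts$start_datetime)
  prev_end <- c(NA_real_, ref_end[-n])
  same_person <- c(FALSE, contacts$person_id[-1L] == contacts$person_id[-n])
  linked <- same_person & (start - prev_end <= gap_hours * 3600)
  contacts$pathway_id <- cumsum(!linked)
  contacts$position <- stats::ave(seq_len(n), contacts$pathway_id,
                                  FUN = seq_along)
  contacts
}

#' Chain one person's contacts into care pathways
#'
#' @param contacts data frame of one person's contacts (columns as in
#'   [bundle_contacts()]).
#' @param gap_hours chaining threshold in hours (default 24).
#' @return list of data frames, one per pathway, in chronological order;
#'   each carries its code string as attribute `code_string`.
#' @export
link_contacts <- function(contacts, gap_hours = 24) {
  if (length(unique(contacts$person_id)) > 1L) {
    stop("link_contacts expects contacts from a single person", call. = FALSE)
  }
  tagged <- assign_pathways(contacts, gap_hours)
  out <- split(tagged[setdiff(names(tagged), c("pathway_id", "position"))],
               tagged$pathway_id)
  out <- unname(out)
  lapply(out, function(p) {
    rownames(p) <- NULL
    attr(p, "code_string") <- encode_pathway(p)
    p
  })
}

#' Encode a pathway as its letter string
#'
#' Concatenates the service-class letters of the contacts in time order and
#' truncates at 11 characters. Contacts beyond the 11th remain part of the
#' pathway but are absent from the code string.
#'
#' @param pathway a pathway data frame (or a character vector of class
#'   letters in time order).
#' @return single string over the alphabet S, E, A, M, length 1-11.
#' @export
encode_pathway <- function(pathway) {
  letters_ <- if (is.data.frame(pathway)) pathway$service_class else pathway
  if (length(letters_) == 0L) stop("empty pathway", call. = FALSE)
  paste(utils::head(letters_, 11L), collapse = "")
}

#' Classify a pathway from its anchored suffix
#'
#' Reads the code string from the anchor position (the mental-health
#' ambulance call the row is keyed to) to the end, and matches it exactly:
#' `"S"`, `"SE"`, `"SEA"` map to their own classes, `"SEM"` and `"SM"` to
#' `"SEM_SM"`, and every other suffix to `"OTHER"`. The anchor letter must
#' be `S`.
#'
#' @param code_string pathway code string(s).
#' @param anchor_position 1-based position of the anchor call within the
#'   code string (recycled).
#' @return character vector of class labels among
#'   `r paste(dQuote(c("S","SE","SEA","SEM_SM","OTHER")), collapse = ", ")`.
#' @export
classify_pathway <- function(code_string, anchor_position = 1L) {
  n <- max(length(code_string), length(anchor_position))
  code_string <- rep_len(as.character(code_string), n)
  anchor_position <- rep_len(as.integer(anchor_position), n)
  if (any(anchor_position < 1L | anchor_position > nchar(code_string))) {
    stop("anchor position outside the code string", call. = FALSE)
  }
  suffix <- substr(code_string, anchor_position, nchar(code_string))
  if (any(substr(suffix, 1L, 1L) != "S")) {
    stop("anchor must be an ambulance call (letter 'S')", call. = FALSE)
  }
  out <- rep("OTHER", n)
  out[suffix == "S"] <- "S"
  out[suffix == "SE"] <- "SE"
  out[suffix == "SEA"] <- "SEA"
  out[suffix %in% c("SEM", "SM")] <- "SEM_SM"
  out
}

#' Duplicate pathways per mental-health call
#'
#' One row is produced per (pathway, inclusion-coded ambulance call) pair,
#' so a pathway such as "SEESE" whose two S contacts are both
#' mental-health coded appears as two rows, each anchored at one of the
#' calls. Pathways with no inclusion-coded call yield no rows.
#'
#' @param pathways list of pathway data frames (as from [link_contacts()]).
#' @param calls the calls table supplying `final_ampds_code` per contact.
#' @param codes inclusion list, see [is_mh_code()].
#' @param mode code matching mode, see [is_mh_code()].
#' @return data frame with one row per anchored pathway: `person_id`,
#'   `anchor_contact_id`, `anchor_position`, `anchor_datetime`,
#'   `code_string`, `pathway_class`.
#' @export
duplicate_per_mh_call <- function(pathways, calls,
                                  codes = ampds_inclusion_list(),
                                  mode = c("prefix", "exact")) {
  mode <- match.arg(mode)
  mh_ids <- calls$contact_id[is_mh_code(calls$final_ampds_code, codes, mode)]
  rows <- lapply(pathways, function(p) {
    anchor <- which(p$service_class == "S" & p$contact_id %in% mh_ids)
    if (!length(anchor)) return(NULL)
    code <- encode_pathway(p)
    usable <- anchor[anchor <= nchar(code)]
    if (!length(usable)) return(NULL)
    data.frame(person_id = p$person_id[usable],
               anchor_contact_id = p$contact_id[usable],
               anchor_position = usable,
               anchor_datetime = p$start_datetime[usable],
               code_string = code,
               pathway_class = classify_pathway(rep(code, length(usable)),
                                                usable),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(person_id = character(),
                      anchor_contact_id = character(),
                      anchor_position = integer(),
                      anchor_datetime = as.POSIXct(character(), tz = "UTC"),
                      code_string = character(),
                      pathway_class = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Interval metrics along a pathway
#'
#' Times from the anchored ambulance call to the subsequent services: call
#' to first ED arrival and that attendance's length of stay, in minutes,
#' and lengths of stay of the first subsequent acute and psychiatric
#' admissions, in days. Metrics use all contacts of the pathway, including
#' any beyond the 11-letter code truncation; absent components give `NA`.
#'
#' @param pathway a pathway data frame.
#' @param anchor_position 1-based position of the anchor call.
#' @return list with `call_to_ed_minutes`, `ed_los_minutes`,
#'   `acute_los_days`, `psych_los_days`.
#' @export
interval_metrics <- function(pathway, anchor_position = 1L) {
  stopifnot(anchor_position >= 1L, anchor_position <= nrow(pathway))
  if (pathway$service_class[anchor_position] != "S") {
    stop("anchor must be an ambulance call (letter 'S')", call. = FALSE)
  }
  after <- pathway[-seq_len(anchor_position), , drop = FALSE]
  anchor_start <- pathway$start_datetime[anchor_position]
  first_of <- function(cls) {
    i <- which(after$service_class == cls)
    if (length(i)) after[i[1L], , drop = FALSE] else NULL
  }
  mins <- function(a, b) as.numeric(difftime(b, a, units = "mins"))
  days <- function(a, b) as.numeric(difftime(b, a, units = "days"))
  e <- first_of("E")
  a <- first_of("A")
  m <- first_of("M")
  list(
    call_to_ed_minutes = if (is.null(e)) NA_real_
                         else mins(anchor_start, e$start_datetime),
    ed_los_minutes = if (is.null(e) || is.na(e$end_datetime)) NA_real_
                     else mins(e$start_datetime, e$end_datetime),
    acute_los_days = if (is.null(a) || is.na(a$end_datetime)) NA_real_
                     else days(a$start_datetime, a$end_datetime),
    psych_los_days = if (is.null(m) || is.na(m$end_datetime)) NA_real_
                     else days(m$start_datetime, m$end_datetime)
  )
}
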