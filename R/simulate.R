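# Seeded synthetic linked-record generator. The defaults are calibrated to
# published national distributions of a 2011 index cohort: the
# repeat-attendance bins, the pathway-class mixture, ED length-of-stay
# medians for completed versus self-discharged attendances, the
# self-discharge proportion with its alcohol risk ratio, the self-discharge
# to repeat-call risk ratio, and the one-year mortality mix.

.repeat_bins <- c("0", "1", "2", "3", "4", "5-9", "10-14", "15+")
.nonmh_codes <- c("06D01", "10D04", "12D01", "17A01", "26A01", "29B01",
                  "31D02")

#' Build a simulation configuration
#'
#' Validates and packages every distribution, effect size and seed that
#' drives [generate_bundle()]. See [default_config()] for the calibrated
#' defaults and the meaning of each field.
#'
#' @param ... configuration fields; unknown names are rejected.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- utils::modifyList(.config_skeleton(), list(...))
  extra <- setdiff(names(cfg), names(.config_skeleton()))
  if (length(extra)) {
    stop("unknown configuration field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg$n_persons <- as.integer(cfg$n_persons)
  cfg$index_year <- as.integer(cfg$index_year)
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(cfg$n_persons >= 0L)

  check_probvec <- function(p, nm, len, labels = NULL) {
    if (length(p) != len) {
      stop(sprintf("%s must have %d entries", nm, len), call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop(nm, " entries must be probabilities in [0, 1]", call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-9) {
      stop(nm, " must sum to 1 (tolerance 1e-9)", call. = FALSE)
    }
    if (!is.null(labels) && !identical(names(p), labels)) {
      stop(nm, " must be named: ", paste(labels, collapse = ", "),
           call. = FALSE)
    }
    p
  }
  cfg$repeat_call_distribution <- check_probvec(
    cfg$repeat_call_distribution, "repeat_call_distribution", 8L,
    .repeat_bins)
  cfg$pathway_mixture <- check_probvec(
    cfg$pathway_mixture, "pathway_mixture", 5L,
    c("S", "SE", "SEA", "SEM_SM", "OTHER"))
  cfg$cause_mixture <- check_probvec(
    cfg$cause_mixture, "cause_mixture", 3L,
    c("suicide", "mental_behavioural", "other"))
  cfg$mh_code_mixture <- check_probvec(
    cfg$mh_code_mixture, "mh_code_mixture", 10L)

  for (nm in c("selfdischarge_prob", "alcohol_prob", "drug_prob",
               "lowest_priority_prob", "triage_missing_prob",
               "death_within_1day_prob", "death_within_year_prob",
               "repeat_nonmh_prob", "prop_under_16", "prop_male")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$death_within_1day_prob + cfg$death_within_year_prob > 1) {
    stop("mortality probabilities sum to more than 1", call. = FALSE)
  }
  for (nm in c("ed_los_completed_median_min", "ed_los_selfdischarge_median_min",
               "acute_los_median_days", "psych_los_median_days")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be positive", call. = FALSE)
  }
  for (nm in c("rr_alcohol_on_selfdischarge", "rr_selfdischarge_on_repeat")) {
    if (cfg[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

.config_skeleton <- function() {
  list(
    n_persons = 6802L,
    index_year = 2011L,
    # per-bin probabilities of the count of repeat ambulance calls within
    # one year of the index call (bins 0,1,2,3,4,5-9,10-14,15+)
    repeat_call_distribution = stats::setNames(
      c(3564, 1294, 646, 366, 218, 459, 155, 100) / 6802, .repeat_bins),
    # index-pathway class mixture
    pathway_mixture = c(S = 800, SE = 3369, SEA = 995, SEM_SM = 656,
                        OTHER = 982) / 6802,
    # ED length of stay: log-normal, re-parameterized by the target median
    ed_los_completed_median_min = 150.7,
    ed_los_selfdischarge_median_min = 100.5,
    ed_los_sigma = 0.6,
    acute_los_median_days = 1,
    psych_los_median_days = 8,
    los_days_sigma = 0.6,
    # marginal probability that an ED-ending pathway ends in self-discharge
    selfdischarge_prob = 0.17,
    alcohol_prob = 1816 / 9014,
    drug_prob = 94 / 9014,
    lowest_priority_prob = 3303 / 6802,
    triage_missing_prob = 0.339,
    rr_alcohol_on_selfdischarge = 1.49,
    rr_selfdischarge_on_repeat = 1.25,
    death_within_1day_prob = 39 / 6802,
    death_within_year_prob = 240 / 6802,
    cause_mixture = c(suicide = 97, mental_behavioural = 64,
                      other = 118) / 279,
    # relative frequency of the ten inclusion codes (suppressed small cells
    # taken as 7)
    mh_code_mixture = local({
      counts <- c(`25A01` = 4315, `25B02` = 2615, `25B01` = 1117, `23` = 697,
                  `25B03` = 129, `25B04` = 79, `09E03` = 43, `17D02J` = 7,
                  `17D03J` = 7, `25D01` = 7)
      counts / sum(counts)
    }),
    # probability that a repeat call is not mental-health coded
    repeat_nonmh_prob = 0.2,
    prop_under_16 = 0.05,
    prop_male = 4708 / 9014,
    seed = 1L
  )
}

#' Default (calibrated) simulation configuration
#'
#' Returns a configuration whose distributions are calibrated to published
#' national values: the repeat-attendance bin proportions, the
#' pathway-class mixture (S 0.118, SE 0.495, SEA 0.146, SEM/SM 0.096,
#' other 0.144), a 17% marginal self-discharge proportion with risk ratios
#' 1.49 (alcohol on self-discharge) and 1.25 (self-discharge on repeat
#' calling), ED length-of-stay medians of 150.7 min (completed) and
#' 100.5 min (self-discharge), one-year mortality of 0.6% within one day
#' plus 3.5% later, and a cause-of-death mixture of roughly 35% suicide,
#' 23% mental/behavioural, 42% other.
#'
#' @return a `simulation_config`.
#' @export
default_config <- function() simulation_config()

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  persons: %d, index year: %d, seed: %d\n",
              x$n_persons, x$index_year, x$seed))
  cat("  pathway mixture:",
      paste(sprintf("%s %.3f", names(x$pathway_mixture), x$pathway_mixture),
            collapse = ", "), "\n")
  cat(sprintf("  self-discharge %.3f (RR alcohol %.2f, RR on repeat %.2f)\n",
              x$selfdischarge_prob, x$rr_alcohol_on_selfdischarge,
              x$rr_selfdischarge_on_repeat))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a `simulation_config`; `write_config()`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("repeat_call_distribution", "pathway_mixture", "cause_mixture",
               "mh_code_mixture")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(simulation_config, raw)
}

#' @rdname read_config
#' @param config a `simulation_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  out <- unclass(config)
  for (nm in names(out)) {
    if (!is.null(names(out[[nm]]))) out[[nm]] <- as.list(out[[nm]])
  }
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Random admissible "other" pathway string: one ambulance call followed by
# 2-10 letters over {E, A, M}, excluding the named classes SEA and SEM.
.random_other_strings <- function(m) {
  if (m == 0L) return(character())
  out <- character(m)
  todo <- seq_len(m)
  while (length(todo)) {
    len <- sample(2:10, length(todo), replace = TRUE, prob = (9:1) / 45)
    tails <- vapply(len, function(l) {
      paste(sample(c("E", "A", "M"), l, replace = TRUE,
                   prob = c(0.60, 0.25, 0.15)), collapse = "")
    }, character(1))
    out[todo] <- paste0("S", tails)
    todo <- todo[out[todo] %in% c("SEA", "SEM", "SM", "SE")]
  }
  out
}

.class_strings <- function(cls) {
  out <- character(length(cls))
  out[cls == "S"] <- "S"
  out[cls == "SE"] <- "SE"
  out[cls == "SEA"] <- "SEA"
  sem <- which(cls == "SEM_SM")
  if (length(sem)) {
    out[sem] <- sample(c("SEM", "SM"), length(sem), replace = TRUE)
  }
  oth <- which(cls == "OTHER")
  out[oth] <- .random_other_strings(length(oth))
  out
}

# Materialize pathway strings into relative contact times (seconds from the
# anchor call start). Intra-pathway gaps are uniform on (5 min, 20 h) so the
# 24-h chaining rule holds by construction; `fast` pathways (index pathways
# of persons dying within one day) use short gaps and capped non-final
# durations so the whole pathway spans under 24 h and every contact starts
# no later than the death date.
.materialize <- function(strings, sd_flag, fast, cfg) {
  m <- length(strings)
  L <- nchar(strings)
  pw <- rep(seq_len(m), L)
  pos <- sequence(L)
  letter <- unlist(strsplit(strings, ""), use.names = FALSE)
  kk <- length(letter)
  last_of_pathway <- cumsum(L)

  nxt <- c(letter[-1L], NA_character_)
  nxt[last_of_pathway] <- NA_character_

  isS <- letter == "S"; isE <- letter == "E"
  isA <- letter == "A"; isM <- letter == "M"

  disp <- rep(NA_character_, kk)
  disp[isE & !is.na(nxt) & nxt %in% c("A", "M")] <- "admitted"
  disp[isE & !is.na(nxt) & !(nxt %in% c("A", "M"))] <- "completed"
  final_e <- isE & is.na(nxt)
  disp[final_e] <- ifelse(sd_flag[pw[final_e]], "self_discharge", "completed")

  dur <- numeric(kk)
  dur[isS] <- stats::runif(sum(isS), 20, 60) * 60
  if (any(isE)) {
    med <- ifelse(disp[isE] == "self_discharge",
                  cfg$ed_los_selfdischarge_median_min,
                  cfg$ed_los_completed_median_min)
    dur[isE] <- stats::rlnorm(sum(isE), log(med), cfg$ed_los_sigma) * 60
  }
  if (any(isA)) {
    dur[isA] <- stats::rlnorm(sum(isA), log(cfg$acute_los_median_days),
                              cfg$los_days_sigma) * 86400
  }
  if (any(isM)) {
    dur[isM] <- stats::rlnorm(sum(isM), log(cfg$psych_los_median_days),
                              cfg$los_days_sigma) * 86400
  }

  gap <- numeric(kk)
  notfirst <- pos > 1L
  lo <- ifelse(fast[pw], 60, 5 * 60)
  hi <- ifelse(fast[pw], 15 * 60, 20 * 3600)
  gap[notfirst] <- stats::runif(sum(notfirst),
                                lo[notfirst], hi[notfirst])

  # cap non-final durations of fast pathways so the span stays under 24 h
  not_last <- !(seq_len(kk) %in% last_of_pathway)
  cap <- fast[pw] & not_last
  dur[cap] <- pmin(dur[cap], 1800)

  lag_dur <- c(0, dur[-kk])
  inc <- gap + lag_dur
  inc[pos == 1L] <- 0
  cs <- cumsum(inc)
  rel_start <- cs - cs[match(pw, pw)]
  rel_start <- floor(rel_start / 60) * 60
  rel_end <- rel_start + pmax(60, round(dur / 60) * 60)

  list(contacts = data.frame(pw = pw, pos = pos, letter = letter,
                             rel_start = rel_start, rel_end = rel_end,
                             disposition = disp, stringsAsFactors = FALSE),
       span = rel_end[last_of_pathway])
}

#' Generate a synthetic linked record bundle
#'
#' Simulates `n_persons` persons, each with one index mental-health
#' ambulance call in the index year plus a number of repeat calls drawn
#' from the configured bin distribution. Every call spawns a care pathway
#' drawn from the pathway mixture, materialized as contacts whose
#' inter-contact gaps are under 24 h; distinct calls are separated by at
#' least 48 h so pathways never chain accidentally. Self-discharge,
#' alcohol and repeat-call dependence are induced multiplicatively so the
#' configured marginal proportions and risk ratios are recovered by the
#' analysis pipeline. Deaths are assigned per the two mortality
#' probabilities with causes from the cause mixture. The same seed always
#' yields a field-identical bundle.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a `record_bundle`.
#' @export
generate_bundle <- function(config = default_config(), seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_persons == 0L) return(empty_bundle())
  .with_seed(as.integer(seed), .generate_bundle_impl(config))
}

.generate_bundle_impl <- function(cfg) {
  n <- cfg$n_persons
  person_id <- sprintf("P%06d", seq_len(n))
  year0 <- as.POSIXct(sprintf("%d-01-01 00:00", cfg$index_year), tz = "UTC")
  days_in_year <- as.integer(as.Date(sprintf("%d-01-01", cfg$index_year + 1L)) -
                               as.Date(sprintf("%d-01-01", cfg$index_year)))

  index_start <- year0 +
    (sample.int(days_in_year, n, replace = TRUE) - 1L) * 86400 +
    (sample.int(1440L, n, replace = TRUE) - 1L) * 60

  under16 <- stats::runif(n) < cfg$prop_under_16
  age <- integer(n)
  age[under16] <- sample(5:15, sum(under16), replace = TRUE)
  age[!under16] <- sample(18:88, sum(!under16), replace = TRUE)
  dob <- as.Date(index_start) - (age * 365L +
                                   sample(30:300, n, replace = TRUE))
  sex <- ifelse(stats::runif(n) < cfg$prop_male, "male", "female")

  died_cat <- sample(c("d1", "late", "none"), n, replace = TRUE,
                     prob = c(cfg$death_within_1day_prob,
                              cfg$death_within_year_prob,
                              1 - cfg$death_within_1day_prob -
                                cfg$death_within_year_prob))
  died_cat[under16] <- "none"

  # --- index pathways -------------------------------------------------
  cls_idx <- sample(names(cfg$pathway_mixture), n, replace = TRUE,
                    prob = cfg$pathway_mixture)
  str_idx <- .class_strings(cls_idx)
  alcohol_idx <- stats::runif(n) < cfg$alcohol_prob
  ends_e_idx <- endsWith(str_idx, "E")
  # unexposed baseline chosen so the configured marginal is recovered
  rr_alc <- cfg$rr_alcohol_on_selfdischarge
  p_sd_base <- cfg$selfdischarge_prob /
    (1 - cfg$alcohol_prob + cfg$alcohol_prob * rr_alc)
  p_sd <- pmin(1, p_sd_base * ifelse(alcohol_idx, rr_alc, 1))
  if (p_sd_base * rr_alc > 1) {
    message("self-discharge probability capped at 1 for alcohol-flagged calls")
  }
  sd_idx <- ends_e_idx & (stats::runif(n) < p_sd)

  # --- repeat-call counts ---------------------------------------------
  # persons dying within one day make no further calls; the survivor
  # distribution is renormalized so the marginal over all persons still
  # equals the configured bin distribution
  p <- cfg$repeat_call_distribution
  p1d <- cfg$death_within_1day_prob
  p0_adj <- max(0, (p[[1L]] - p1d) / (1 - p1d))
  p_any <- 1 - p0_adj
  eligible <- !under16 & died_cat != "d1"
  rr_rep <- cfg$rr_selfdischarge_on_repeat
  f <- if (any(eligible)) mean(sd_idx[eligible]) else 0
  base_any <- if (p_any > 0) p_any / (1 - f + f * rr_rep) else 0
  pr_any <- pmin(1, base_any * ifelse(sd_idx, rr_rep, 1))
  if (base_any * rr_rep > 1) {
    message("repeat-call probability capped at 1 for self-discharged persons")
  }
  any_rep <- eligible & (stats::runif(n) < pr_any)

  k <- integer(n)
  if (any(any_rep)) {
    cond <- p[-1L] / sum(p[-1L])
    bin <- sample(names(cond), sum(any_rep), replace = TRUE, prob = cond)
    cnt <- integer(length(bin))
    exact <- bin %in% c("1", "2", "3", "4")
    cnt[exact] <- as.integer(bin[exact])
    b59 <- bin == "5-9"
    cnt[b59] <- sample(5:9, sum(b59), replace = TRUE)
    b1014 <- bin == "10-14"
    cnt[b1014] <- sample(10:14, sum(b1014), replace = TRUE)
    b15 <- bin == "15+"
    cnt[b15] <- sample(15:101, sum(b15), replace = TRUE)
    k[any_rep] <- cnt
  }

  # --- repeat pathways -------------------------------------------------
  n_rep <- sum(k)
  rep_person <- rep(seq_len(n), k)
  if (n_rep) {
    rep_mh <- stats::runif(n_rep) >= cfg$repeat_nonmh_prob
    cls_rep <- sample(names(cfg$pathway_mixture), n_rep, replace = TRUE,
                      prob = cfg$pathway_mixture)
    str_rep <- .class_strings(cls_rep)
    alcohol_rep <- stats::runif(n_rep) < cfg$alcohol_prob
    ends_e_rep <- endsWith(str_rep, "E")
    p_sd_rep <- pmin(1, p_sd_base * ifelse(alcohol_rep, rr_alc, 1))
    sd_rep <- ends_e_rep & (stats::runif(n_rep) < p_sd_rep)
  } else {
    rep_mh <- logical(); str_rep <- character()
    alcohol_rep <- logical(); sd_rep <- logical()
  }

  strings <- c(str_idx, str_rep)
  sd_flag <- c(sd_idx, sd_rep)
  fast <- c(died_cat == "d1", rep(FALSE, n_rep))
  mat <- .materialize(strings, sd_flag, fast, cfg)

  # --- absolute call start times ---------------------------------------
  call_start <- numeric(n + n_rep)
  call_start[seq_len(n)] <- as.numeric(index_start)
  if (n_rep) {
    cand <- stats::runif(n_rep, 2, 363) * 86400
    ord <- order(rep_person, cand)
    cand <- cand[ord]
    jit <- stats::runif(n_rep, 0, 3600)
    idx_end <- as.numeric(index_start) + mat$span[seq_len(n)]
    starts <- numeric(n_rep)
    j <- 1L
    for (i in which(k > 0L)) {
      prev_end <- idx_end[i]
      base <- as.numeric(index_start[i])
      for (q in seq_len(k[i])) {
        t <- max(base + cand[j], prev_end + 48 * 3600 + jit[j])
        t <- floor(t / 60) * 60
        starts[j] <- t
        prev_end <- t + mat$span[n + j]
        j <- j + 1L
      }
    }
    call_start[n + seq_len(n_rep)] <- starts
  }

  # --- AMPDS codes ------------------------------------------------------
  draw_mh_codes <- function(m) {
    key <- sample(names(cfg$mh_code_mixture), m, replace = TRUE,
                  prob = cfg$mh_code_mixture)
    chapter <- key == "23"
    key[chapter] <- paste0("23", sample(c("B01", "C01", "D01"),
                                        sum(chapter), replace = TRUE))
    key
  }
  code <- character(n + n_rep)
  code[seq_len(n)] <- draw_mh_codes(n)
  if (n_rep) {
    code[n + which(rep_mh)] <- draw_mh_codes(sum(rep_mh))
    code[n + which(!rep_mh)] <- sample(.nonmh_codes, sum(!rep_mh),
                                       replace = TRUE)
  }

  # --- pathway-level call attributes -----------------------------------
  pw_person <- c(seq_len(n), rep_person)
  alcohol <- c(alcohol_idx, alcohol_rep)
  n_pw <- n + n_rep
  drug <- stats::runif(n_pw) < cfg$drug_prob
  lowp <- stats::runif(n_pw) < cfg$lowest_priority_prob
  transported <- nchar(strings) > 1L & substr(strings, 2L, 2L) == "E"

  # --- contact tables ---------------------------------------------------
  cc <- mat$contacts
  cc$person_id <- person_id[pw_person[cc$pw]]
  cc$start <- as.POSIXct(call_start[cc$pw] + cc$rel_start, tz = "UTC",
                         origin = "1970-01-01")
  cc$end <- as.POSIXct(call_start[cc$pw] + cc$rel_end, tz = "UTC",
                       origin = "1970-01-01")
  ord <- order(cc$person_id, cc$start, .class_order[cc$letter], cc$pw)
  cc <- cc[ord, , drop = FALSE]
  cc$contact_id <- sprintf("C%08d", seq_len(nrow(cc)))

  s_rows <- cc[cc$letter == "S", , drop = FALSE]
  calls <- data.frame(
    contact_id = s_rows$contact_id,
    person_id = s_rows$person_id,
    start_datetime = s_rows$start,
    end_datetime = s_rows$end,
    final_ampds_code = code[s_rows$pw],
    alcohol_flag = alcohol[s_rows$pw],
    drug_flag = drug[s_rows$pw],
    lowest_priority_flag = lowp[s_rows$pw],
    transported = transported[s_rows$pw],
    stringsAsFactors = FALSE)

  e_rows <- cc[cc$letter == "E", , drop = FALSE]
  n_e <- nrow(e_rows)
  triage <- sample(1:5, n_e, replace = TRUE)
  triage[stats::runif(n_e) < cfg$triage_missing_prob] <- NA_integer_
  ed <- data.frame(
    contact_id = e_rows$contact_id,
    person_id = e_rows$person_id,
    start_datetime = e_rows$start,
    end_datetime = e_rows$end,
    disposition = e_rows$disposition,
    triage_category = triage,
    stringsAsFactors = FALSE)

  am_rows <- cc[cc$letter %in% c("A", "M"), , drop = FALSE]
  admissions <- data.frame(
    contact_id = am_rows$contact_id,
    person_id = am_rows$person_id,
    start_datetime = am_rows$start,
    end_datetime = am_rows$end,
    ward_type = ifelse(am_rows$letter == "M", "psychiatric", "acute"),
    stringsAsFactors = FALSE)

  # --- deaths -----------------------------------------------------------
  dead <- which(died_cat != "none")
  if (length(dead)) {
    index_date <- as.Date(index_start)
    last_day <- tapply(as.numeric(as.Date(cc$start)), cc$person_id, max)
    death_date <- as.Date(rep(NA_integer_, length(dead)),
                          origin = "1970-01-01")
    is_d1 <- died_cat[dead] == "d1"
    if (any(is_d1)) {
      d1 <- dead[is_d1]
      draw <- as.numeric(index_date[d1]) + (stats::runif(length(d1)) < 0.5)
      # never before the last contact of the (compressed, < 24 h) pathway
      hit1 <- match(person_id[d1], names(last_day))
      draw <- pmax(draw, as.numeric(last_day[hit1]))
      death_date[is_d1] <- as.Date(draw, origin = "1970-01-01")
    }
    late <- dead[!is_d1]
    if (length(late)) {
      last <- as.numeric(index_date[late])
      hit <- match(person_id[late], names(last_day))
      got <- !is.na(hit)
      last[got] <- pmax(last[got], last_day[hit[got]])
      lo <- pmax(as.numeric(index_date[late]) + 2, last + 1)
      hi <- pmax(lo, as.numeric(index_date[late]) + 365)
      draw <- lo + floor(stats::runif(length(late)) * (hi - lo + 1))
      death_date[!is_d1] <- as.Date(pmin(draw, hi), origin = "1970-01-01")
    }
    cause <- sample(names(cfg$cause_mixture), length(dead), replace = TRUE,
                    prob = cfg$cause_mixture)
    deaths <- data.frame(person_id = person_id[dead],
                         date_of_death = death_date,
                         cause_category = cause,
                         stringsAsFactors = FALSE)
  } else {
    deaths <- empty_bundle()$deaths
  }

  persons <- data.frame(person_id = person_id,
                        date_of_birth = dob,
                        sex = sex,
                        resident_in_scope = TRUE,
                        stringsAsFactors = FALSE)

  record_bundle(persons, calls, ed, admissions, deaths)
}

#' Empirical summary of a generated bundle
#'
#' Runs the full analysis pipeline on a bundle and reports the empirical
#' counterparts of every simulation-configuration distribution, for
#' parameter-recovery checks: pathway-class mixture, repeat-bin
#' proportions, self-discharge proportion and both risk ratios, ED
#' length-of-stay medians, mortality proportions and the cause mixture.
#'
#' @param bundle a `record_bundle`.
#' @param year index year (default 2011).
#' @param ... further arguments passed to [analyze_bundle()].
#' @return object of class `bundle_summary` (a list of empirical values),
#'   or a list of zero counts for an empty bundle.
#' @export
summarize_bundle <- function(bundle, year = 2011L, ...) {
  stopifnot(inherits(bundle, "record_bundle"))
  if (nrow(bundle$persons) == 0L) {
    return(structure(list(n_persons = 0L, n_calls = 0L, n_cohort = 0L),
                     class = "bundle_summary"))
  }
  an <- analyze_bundle(bundle, year = year, ...)
  pp <- an$person_period
  idx <- an$index_rows
  cls_prop <- prop.table(table(factor(idx$pathway_class,
                                      levels = .pathway_classes)))
  bin_prop <- prop.table(table(factor(pp$repeat_bin, levels = .repeat_bins)))

  ed_rows <- an$pathway_rows[an$pathway_rows$ends_in_ed, , drop = FALSE]
  sd_prop <- if (nrow(ed_rows)) mean(ed_rows$final_ed_disposition ==
                                       "self_discharge") else NA_real_
  med_sd <- med_comp <- NA_real_
  losc <- ed_rows$final_ed_los_min[ed_rows$final_ed_disposition == "completed"]
  loss <- ed_rows$final_ed_los_min[ed_rows$final_ed_disposition ==
                                     "self_discharge"]
  if (length(losc)) med_comp <- median_iqr(losc)$median
  if (length(loss)) med_sd <- median_iqr(loss)$median

  mo <- an$mortality$outcomes
  structure(list(
    n_persons = nrow(bundle$persons),
    n_calls = nrow(bundle$calls),
    n_cohort = nrow(an$cohort),
    prop_under_16 = an$exclusions$count[an$exclusions$reason == "under_16"] /
      (nrow(an$cohort) + sum(an$exclusions$count)),
    pathway_mixture = cls_prop,
    repeat_call_distribution = bin_prop,
    prop_any_repeat = mean(pp$n_repeats_1yr > 0),
    selfdischarge_prop = sd_prop,
    alcohol_prop = mean(an$mh_calls$alcohol_flag),
    rr_alcohol_on_selfdischarge = an$stats$rr_alcohol$effect,
    rr_selfdischarge_on_repeat = an$stats$rr_repeat$effect,
    ed_los_completed_median_min = med_comp,
    ed_los_selfdischarge_median_min = med_sd,
    death_within_1day_prop = mean(mo$died_within_1day),
    death_within_year_prop = mean(mo$died_1day_to_1yr),
    cause_mixture = prop.table(table(factor(
      mo$cause_category[mo$died_within_1day | mo$died_1day_to_1yr],
      levels = names(.config_skeleton()$cause_mixture))))
  ), class = "bundle_summary")
}

#' @export
print.bundle_summary <- function(x, ...) {
  cat("Bundle summary\n")
  cat(sprintf("  persons %d, ambulance calls %d, cohort %d\n",
              x$n_persons, x$n_calls, x$n_cohort))
  if (!is.null(x$pathway_mixture)) {
    cat("  pathway mixture:",
        paste(sprintf("%s %.3f", names(x$pathway_mixture), x$pathway_mixture),
              collapse = ", "), "\n")
    cat(sprintf("  self-discharge %.3f, RR(alcohol) %.2f, RR(repeat) %.2f\n",
                x$selfdischarge_prop, x$rr_alcohol_on_selfdischarge,
                x$rr_selfdischarge_on_repeat))
    cat(sprintf("  ED LOS medians: completed %.1f min, self-discharge %.1f min\n",
                x$ed_los_completed_median_min,
                x$ed_los_selfdischarge_median_min))
  }
  invisible(x)
}
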