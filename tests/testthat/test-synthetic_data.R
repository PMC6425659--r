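# synthetic_data: config validation, determinism, structural validity.

test_that("default config is valid and documents the calibrated values", {
  cfg <- default_config()
  expect_s3_class(cfg, "simulation_config")
  expect_equal(sum(cfg$pathway_mixture), 1)
  expect_equal(sum(cfg$repeat_call_distribution), 1)
  expect_equal(sum(cfg$cause_mixture), 1)
  expect_equal(cfg$selfdischarge_prob, 0.17)
  expect_equal(cfg$rr_alcohol_on_selfdischarge, 1.49)
  expect_equal(cfg$rr_selfdischarge_on_repeat, 1.25)
  expect_equal(cfg$ed_los_completed_median_min, 150.7)
  expect_equal(cfg$ed_los_selfdischarge_median_min, 100.5)
})

test_that("config validation rejects bad input", {
  expect_error(simulation_config(not_a_field = 1), "unknown configuration")
  expect_error(simulation_config(selfdischarge_prob = 1.2), "probability")
  expect_error(simulation_config(alcohol_prob = -0.1), "probability")
  bad_mix <- c(S = 0.5, SE = 0.2, SEA = 0.2, SEM_SM = 0.2, OTHER = 0.2)
  expect_error(simulation_config(pathway_mixture = bad_mix), "sum to 1")
  short <- c(S = 0.5, SE = 0.5)
  expect_error(simulation_config(pathway_mixture = short), "5 entries")
  expect_error(simulation_config(death_within_1day_prob = 0.6,
                                 death_within_year_prob = 0.6),
               "more than 1")
  expect_error(simulation_config(ed_los_sigma = 0.6,
                                 acute_los_median_days = 0), "positive")
})

test_that("configs round-trip through YAML", {
  cfg <- simulation_config(n_persons = 123L, seed = 77L,
                           selfdischarge_prob = 0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})

test_that("the same seed yields a field-identical bundle", {
  cfg <- simulation_config(n_persons = 300L)
  b1 <- generate_bundle(cfg, seed = 9L)
  b2 <- generate_bundle(cfg, seed = 9L)
  expect_equal(unclass(b1), unclass(b2))
  b3 <- generate_bundle(cfg, seed = 10L)
  expect_false(identical(b1$calls$start_datetime, b3$calls$start_datetime))
})

test_that("generation does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_bundle(simulation_config(n_persons = 50L), seed = 4L))
  expect_identical(.Random.seed, before)
})

test_that("generated bundles are structurally valid", {
  b <- generate_bundle(simulation_config(n_persons = 400L), seed = 2L)
  v <- validate_bundle(b)
  expect_true(v$is_clean)
  # no death dated before a contact of the same person
  expect_false(any(v$issues$severity == "warning"))
  # every person has exactly one index-year MH call at minimum
  mh <- select_mh_calls(b)
  expect_identical(attr(mh, "n_callers"), 400L)
  # contacts of one pathway never straddle the 24-hour rule accidentally:
  # distinct calls are at least 48 h apart
  for (pid in sample(unique(b$calls$person_id), 20)) {
    st <- sort(b$calls$start_datetime[b$calls$person_id == pid])
    if (length(st) > 1) {
      expect_true(all(diff(as.numeric(st)) >= 48 * 3600))
    }
  }
})

test_that("ED dispositions agree with what follows in the pathway", {
  b <- generate_bundle(simulation_config(n_persons = 300L), seed = 6L)
  contacts <- assign_pathways(bundle_contacts(b))
  nxt_class <- c(contacts$service_class[-1L], NA)
  nxt_path <- c(contacts$pathway_id[-1L], NA)
  e <- which(contacts$service_class == "E")
  disp <- b$ed$disposition[match(contacts$contact_id[e], b$ed$contact_id)]
  followed <- !is.na(nxt_path[e]) & nxt_path[e] == contacts$pathway_id[e]
  admit_next <- followed & nxt_class[e] %in% c("A", "M")
  expect_true(all(disp[admit_next] == "admitted"))
  expect_false(any(disp[!admit_next] == "admitted"))
})

test_that("deaths within one day occur on the index or following day", {
  b <- generate_bundle(simulation_config(n_persons = 2000L), seed = 12L)
  an <- analyze_bundle(b)
  mo <- an$mortality$outcomes
  expect_false(any(mo$death_before_index))
  d1 <- mo[mo$died_within_1day, ]
  dd <- b$deaths$date_of_death[match(d1$person_id, b$deaths$person_id)]
  expect_true(all(dd - as.Date(d1$index_datetime) <= 1))
})

test_that("n_persons = 0 yields an empty but valid bundle", {
  b <- generate_bundle(simulation_config(n_persons = 0L))
  expect_identical(nrow(b$persons), 0L)
  expect_true(validate_bundle(b)$is_clean)
})

test_that("under-16 persons are generated and excluded by the cohort step", {
  b <- generate_bundle(simulation_config(n_persons = 2000L,
                                         prop_under_16 = 0.2), seed = 3L)
  an <- analyze_bundle(b)
  ex <- an$exclusions
  expect_gt(ex$count[ex$reason == "under_16"], 0L)
  expect_true(all(an$cohort$age_at_index >= 16L))
})

test_that("summarize_bundle reports the empirical counterparts", {
  b <- generate_bundle(simulation_config(n_persons = 1500L), seed = 8L)
  s <- summarize_bundle(b)
  expect_s3_class(s, "bundle_summary")
  expect_equal(sum(s$pathway_mixture), 1)
  expect_equal(sum(s$repeat_call_distribution), 1)
  expect_true(s$selfdischarge_prop > 0 && s$selfdischarge_prop < 1)
  expect_true(is.finite(s$rr_alcohol_on_selfdischarge))
})
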