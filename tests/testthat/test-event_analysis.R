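test_that("detect_band finds an injected 8-sigma band at its position", {
  win <- biasers_windows()$nba1650
  tp <- species_template("x", list(peak_band(1650, 14, 5)))
  nm <- noise_quiet()
  hits <- lapply(1:20, function(i)
    detect_band_on(render_at_snr(tp, 8, seed = 500 + i, noise = nm), win))
  expect_true(all(vapply(hits, `[[`, FALSE, "present")))
  centers <- vapply(hits, `[[`, 0, "center")
  expect_true(all(abs(centers - 1650) <= 2))
  snrs <- vapply(hits, `[[`, 0, "snr")
  expect_true(all(snrs >= 3))
})

test_that("zero-noise detection flags infinite SNR and edge bands clip", {
  tp <- species_template("x", list(peak_band(1650, 14, 5)))
  s <- render_spectrum(tp, AX, noise_zero(), 1)
  hit <- detect_band(s, biasers_windows()$nba1650,
                     estimate_noise_sd(s))
  expect_true(hit$present)
  expect_identical(hit$snr, Inf)
  expect_true("sigma_zero" %in% hit$flags)
  # band pinned just outside the window edge: clipped center with a warning
  # (with a flank baseline the edge deviation survives; a chord would
  # anchor on the band itself)
  edge <- species_template("e", list(peak_band(1641, 14, 5)))
  se <- render_spectrum(edge, AX, noise_zero(), 1)
  w <- detection_window("w", 1642, 1662, baseline_region = c(1610, 1694),
                        baseline_exclude = c(1628, 1676))
  expect_warning(h <- detect_band(se, w, estimate_noise_sd(se)), "clipped")
  expect_gte(h$center, 1642)
  # a band clearly beyond the edge is rejected as a neighboring band
  far <- species_template("f", list(peak_band(1634, 14, 5)))
  sf <- render_spectrum(far, AX, noise_zero(), 1)
  hf <- detect_band(sf, w, estimate_noise_sd(sf))
  expect_false(hf$present)
  expect_true("neighbor_band" %in% hf$flags)
})

test_that("false-positive rate on pure noise is below 1% per window", {
  # Monte-Carlo over noise draws; the 3-consecutive-points rule plus the
  # flank-anchored baseline keep the multiplicity-controlled rate near zero
  n_draws <- 2000
  wins <- biasers_windows()
  fp <- matrix(FALSE, n_draws, length(wins))
  for (i in seq_len(n_draws)) {
    s <- render_spectrum(NULL, AX, noise_quiet(), 1, seed = 20000 + i)
    ns <- estimate_noise_sd(s)
    fp[i, ] <- vapply(wins, function(w)
      suppressWarnings(detect_band(s, w, ns)$present), logical(1))
  }
  expect_true(all(colMeans(fp) <= 0.01))
})

test_that("raising k_sigma never increases the detected fraction", {
  set <- simulate_biasers_set(150, event_process(p_event = 0.3), seed = 31)
  fracs <- vapply(c(2, 3, 4, 6), function(k)
    event_summary(set, classify_biasers_set(set, k_sigma = k)$label
                  )$detected_fraction, numeric(1))
  expect_true(all(diff(fracs) <= 1e-12))
})

test_that("classify_biasers implements the full decision table", {
  combos <- expand.grid(marker600 = c(FALSE, TRUE), mb1630 = c(FALSE, TRUE),
                        nba1650 = c(FALSE, TRUE))
  expected <- function(m600, mb, nba) {
    if (mb && nba) "dual_MB_NBA"
    else if (nba && m600) "single_NBA"
    else if (mb && !m600) "single_MB"
    else "none"
  }
  for (r in seq_len(nrow(combos))) {
    got <- classify_biasers(as.list(combos[r, ]))
    expect_identical(got, expected(combos$marker600[r], combos$mb1630[r],
                                   combos$nba1650[r]))
  }
  # the three canonical signatures
  expect_identical(classify_biasers(list(marker600 = TRUE, mb1630 = FALSE,
                                         nba1650 = TRUE)), "single_NBA")
  expect_identical(classify_biasers(list(marker600 = FALSE, mb1630 = TRUE,
                                         nba1650 = FALSE)), "single_MB")
  expect_identical(classify_biasers(list(marker600 = TRUE, mb1630 = TRUE,
                                         nba1650 = TRUE)), "dual_MB_NBA")
})

test_that("noise-free classification agrees with ground truth for all event types", {
  cases <- list(
    list(tpl = LIB$MB, label = "single_MB"),
    list(tpl = LIB$NBA, label = "single_NBA"),
    list(tpl = species_template("dual", c(LIB$MB$bands, LIB$NBA$bands)),
         label = "dual_MB_NBA"),
    list(tpl = NULL, label = "none"))
  for (cs in cases) {
    s <- render_spectrum(cs$tpl, AX, noise_zero(), 1)
    ns <- estimate_noise_sd(s)
    hits <- lapply(biasers_windows(), function(w) detect_band(s, w, ns))
    expect_identical(classify_biasers(hits), cs$label)
  }
})

test_that("event summary partitions the set and matches the event rate", {
  set <- simulate_biasers_set(3600, seed = 12)
  det <- classify_biasers_set(set)
  expect_equal(nrow(det), 3600)
  expect_true(all(det$label %in% c("none", "single_MB", "single_NBA",
                                   "dual_MB_NBA")))
  es <- event_summary(set, det$label)
  expect_equal(sum(unlist(es$counts)), 3600)
  # calibration: detected fraction within 3 binomial SE of p_event
  se <- sqrt(0.05 * 0.95 / 3600)
  expect_lt(abs(es$detected_fraction - 0.05), 3 * se)
  # dilute equal mix is dominated by single-dye events
  n_single <- es$counts$single_MB + es$counts$single_NBA
  expect_gt(n_single, es$counts$dual_MB_NBA)
  expect_error(event_summary(set, det$label[-1]), "one label per spectrum")
  empty <- event_summary(set, rep("none", 3600))
  expect_equal(empty$detected_fraction, 0)
})

test_that("switching RSD recovers the shot-to-shot variation", {
  # cv = 0, no noise -> RSD exactly 0
  s0 <- simulate_switching_series(6, noise = noise_zero(), seed = 1)
  r0 <- switching_rsd(s0)
  expect_equal(r0$rsd_percent, 0)
  expect_false(r0$off_state_violation)
  # 12 cycles at cv 0.15: RSD near 15% and below the 20% reproducibility
  # bound; strong on/off contrast
  s <- simulate_switching_series(12, seed = 42)
  r <- switching_rsd(s)
  expect_lt(r$rsd_percent, 20)
  expect_gt(r$rsd_percent, 5)
  expect_gt(r$contrast, 5)
  # analyte injected in the off state is flagged as a protocol violation
  bad <- s
  bad$meta$trap_state <- rev(bad$meta$trap_state)
  expect_warning(rb <- switching_rsd(bad), "protocol|trap off")
  expect_true(rb$off_state_violation)
  # guard rails
  no_state <- s; no_state$meta$trap_state <- NA_character_
  expect_error(switching_rsd(no_state), "trap_state")
  one_on <- simulate_switching_series(1, seed = 1)
  expect_error(switching_rsd(one_on), "at least 2")
})
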