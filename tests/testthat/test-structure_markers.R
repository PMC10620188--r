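test_that("amide band centers hit the template positions for every species", {
  cases <- list(HIAPP_helix_coil = 1656, HIAPP_typeI = 1668,
                HIAPP_typeII = c(1655, 1674))
  for (nm in names(cases)) {
    s <- render_spectrum(LIB[[nm]], AX, noise_zero(), 1)
    ab <- amide_band_centers(s)
    got <- ab$centers[ab$centers >= 1640 & ab$centers <= 1700]
    expect_equal(length(got), length(cases[[nm]]))
    expect_true(all(abs(got - cases[[nm]]) <= 2))
  }
  # the type I band is recognizably broad, the predominant band is not
  w_broad <- classify_hiapp(render_spectrum(LIB$HIAPP_typeI, AX,
                                            noise_zero(), 1))
  w_narrow <- classify_hiapp(render_spectrum(LIB$HIAPP_helix_coil, AX,
                                             noise_zero(), 1))
  expect_gte(w_broad$evidence$amide_widths[1], 1.5 * 14)
  expect_lt(w_narrow$evidence$amide_widths[1], 1.5 * 14)
})

test_that("band-center estimates are unbiased within half a grid step", {
  # off-grid symmetric bands; oracle = true center by construction
  for (ctr in c(1655.3, 1661.7, 1668.9)) {
    tp <- species_template("x", list(peak_band(ctr, 14, 5)))
    s <- render_spectrum(tp, AX, noise_zero(), 1)
    ab <- amide_band_centers(s)
    expect_equal(length(ab$centers), 1)
    expect_lte(abs(ab$centers - ctr), AX$step / 2)
  }
})

test_that("doublet ratio recovers encoded areas and is invariant", {
  eq <- species_template("eq", list(peak_band(830, 10, 3),
                                    peak_band(854, 10, 3)))
  s_eq <- render_spectrum(eq, AX, noise_zero(), 1)
  expect_equal(doublet_ratio(s_eq)$ratio, 1, tolerance = 1e-6)
  expect_equal(doublet_ratio(s_eq, "integration")$ratio, 1, tolerance = 0.02)
  # basic-condition tyrosine: 2:1, within 0.1 under noise at the Tyr
  # acquisition settings (10 s integration)
  t13 <- tyr_mixture_template(13)
  s13 <- render_at_snr(t13, 20, seed = 4213, integration_s = 10)
  r13 <- doublet_ratio(s13)
  expect_lt(abs(r13$ratio - 2), 0.1)
  expect_true(is.finite(r13$ratio_se))
  # type II template encodes a ratio > 1
  sII <- render_spectrum(LIB$HIAPP_typeII, AX, noise_zero(), 1)
  expect_gt(doublet_ratio(sII)$ratio, 1.2)
  expect_equal(doublet_ratio(sII)$ratio, 1.5, tolerance = 0.02)
  # invariance under scaling and linear baselines, both methods
  s_tr <- new_spectrum(AX, 7 * s_eq$intensity + 50 - 0.02 * AX$values)
  for (m in c("fit", "integration"))
    expect_equal(doublet_ratio(s_tr, m)$ratio,
                 doublet_ratio(s_eq, m)$ratio, tolerance = 1e-6)
  # degenerate denominator is flagged
  only830 <- render_spectrum(
    species_template("o", list(peak_band(830, 10, 3))), AX, noise_zero(), 1)
  expect_warning(r0 <- doublet_ratio(only830, "integration"), "undefined")
  expect_false(r0$defined)
})

test_that("nu8a position tracks the tyrosine charge state", {
  s_plus <- render_at_snr(LIB$TYR_plus1, 20, seed = 1)
  expect_lte(abs(v8a_position(s_plus) - 1620), 2)
  s_minus <- render_at_snr(LIB$TYR_minus2, 20, seed = 2)
  expect_lte(abs(v8a_position(s_minus) - 1602), 2)
  # 50/50 mixture: reported position falls between the two states
  mid <- tyr_mixture_template(10.2)
  s_mid <- render_at_snr(mid, 20, seed = 3, integration_s = 10)
  p <- v8a_position(s_mid)
  expect_gte(p, 1600)
  expect_lte(p, 1622)
  # flat spectrum: absent
  flat <- render_spectrum(NULL, AX, noise_quiet(), 1, seed = 4)
  expect_true(is.na(v8a_position(flat)))
})

test_that("disulfide marker separates intact and strained conformations", {
  s_mono <- render_spectrum(LIB$HIAPP_helix_coil, AX, noise_zero(), 1)
  expect_identical(disulfide_marker(s_mono)$state, "ggt_tgg_523")
  s_fib <- render_spectrum(LIB$HIAPP_fibril, AX, noise_zero(), 1)
  expect_identical(disulfide_marker(s_fib)$state, "strained_490")
  flat <- render_spectrum(NULL, AX, noise_zero(), 1)
  expect_identical(disulfide_marker(flat)$state, "absent")
  both <- species_template("b", c(LIB$HIAPP_helix_coil$bands,
                                  list(peak_band(490, 14, 1.6))))
  s_both <- render_spectrum(both, AX, noise_zero(), 1)
  expect_identical(disulfide_marker(s_both)$state, "both")
})

test_that("classify_hiapp maps every template to its species, noise-free", {
  for (nm in names(hiapp_truth_map)[1:4]) {
    tpl <- switch(nm, predominant = "HIAPP_helix_coil",
                  typeI = "HIAPP_typeI", typeII = "HIAPP_typeII",
                  fibril = "HIAPP_fibril")
    s <- render_spectrum(LIB[[tpl]], AX, noise_zero(), 1)
    expect_identical(classify_hiapp(s)$call, unname(hiapp_truth_map[nm]))
  }
  flat <- render_spectrum(NULL, AX, noise_zero(), 1)
  expect_identical(suppressWarnings(classify_hiapp(flat)$call),
                   "unclassified")
})

test_that("decision rules are deterministic, total and mutually exclusive", {
  # grid of synthetic single/double band spectra spanning the evidence space
  centers1 <- seq(1644, 1680, 4)
  widths <- c(14, 28)
  for (c1 in centers1) for (w in widths) {
    tp <- species_template("g", list(peak_band(c1, w, 5)))
    s <- render_spectrum(tp, AX, noise_zero(), 1)
    calls <- suppressWarnings(replicate(2, classify_hiapp(s)$call))
    expect_identical(calls[1], calls[2])
    expect_true(calls[1] %in% c("predominant_helix_coil", "typeI_turn",
                                "typeII_beta", "fibril_like",
                                "unclassified"))
  }
  # a 1656 band can never be typeI and a broad 1668 band never predominant
  s56 <- render_spectrum(species_template("a", list(peak_band(1656, 14, 5))),
                         AX, noise_zero(), 1)
  expect_false(suppressWarnings(classify_hiapp(s56)$call) == "typeI_turn")
  s68 <- render_spectrum(species_template("b", list(peak_band(1668, 28, 8))),
                         AX, noise_zero(), 1)
  expect_false(suppressWarnings(classify_hiapp(s68)$call) ==
                 "predominant_helix_coil")
})

test_that("species census recovers simulated fractions and maps all rows", {
  probs <- c(predominant = 0.9, typeI = 0.05, typeII = 0.05)
  set <- simulate_hiapp_set(600, probs, seed = 77, snr = 10)
  cen <- species_census(set)
  expect_equal(nrow(cen$map), 600)
  expect_true(all(cen$map >= 0 & cen$map <= 1))
  truth <- table(factor(set$meta$label_truth, levels = names(probs)))
  for (sp in names(probs)) {
    got <- cen$fractions[[hiapp_truth_map[sp]]]
    se <- sqrt(probs[[sp]] * (1 - probs[[sp]]) / 600)
    # recovered fraction tracks the realized truth fraction
    expect_lt(abs(got - truth[[sp]] / 600), 3 * se + 0.02)
  }
  # degenerate and trivial cases
  all_pred <- simulate_hiapp_set(20, c(predominant = 1), seed = 3, snr = 12)
  cen1 <- species_census(all_pred)
  expect_gte(cen1$fractions$predominant_helix_coil, 0.95)
  expect_error(species_census(structure(list(), class = "sers_set")))
})
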