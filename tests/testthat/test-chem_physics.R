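test_that("hIAPP net charge is +4 at pH 5.5 and +3 at pH 7.4", {
  g <- hiapp_groups()
  q55 <- net_charge(g, 5.5)
  expect_identical(q55$integer_charge, 4L)
  q74 <- net_charge(g, 7.4)
  expect_identical(q74$integer_charge, 3L)
  # the His site is the one that flips
  expect_gt(q55$site_fractions[["His18"]], 0.7)
  expect_lt(q74$site_fractions[["His18"]], 0.05)
  # a single base at pH = pKa is half protonated
  half <- net_charge(list(ionizable_group("b", 7, "base")), 7)
  expect_equal(half$fractional_charge, 0.5)
  expect_error(net_charge(list(), 7), "empty")
})

test_that("net charge is monotone in pH with the correct limits", {
  g <- c(hiapp_groups(), list(ionizable_group("asp", 3.9, "acid")))
  q <- vapply(seq(0, 14, 0.25), function(p) net_charge(g, p)$fractional_charge,
              numeric(1))
  expect_true(all(diff(q) < 0))
  expect_equal(q[1], 4, tolerance = 0.01)      # all bases on, acid protonated
  # pH 14: only the acid charged (Arg pKa 12.5 retains ~3% protonation)
  expect_equal(q[length(q)], -1, tolerance = 0.05)
})

test_that("microstate weights sum to 1 and reproduce HH marginals", {
  g <- tyr_groups()
  for (pH in c(1, 4.5, 9.2, 10.5, 13)) {
    w <- microstate_weights(g, pH)
    expect_equal(sum(w$weight), 1, tolerance = 1e-12)
    # mean charge over microstates equals the fractional net charge
    expect_equal(sum(w$charge * w$weight),
                 net_charge(g, pH)$fractional_charge, tolerance = 1e-12)
    expect_equal(attr(w, "site_fractions"),
                 net_charge(g, pH)$site_fractions, tolerance = 1e-12)
  }
  # the paper's anchoring charge states dominate at the pH extremes
  expect_gt(microstate_weights(g, 1)$weight[
    microstate_weights(g, 1)$charge == 1], 0.9)
  expect_gt(microstate_weights(g, 13)$weight[
    microstate_weights(g, 13)$charge == -2], 0.9)
})

test_that("strong acid-base mixing solves the charge balance", {
  # independent oracle: root of h - Kw/h - (Ca - Cb) = 0
  oracle <- function(v_a, pH_a, v_b, c_b) {
    d <- (10^(-pH_a) * v_a - c_b * v_b) / (v_a + v_b)
    f <- function(h) h - 1e-14 / h - d
    -log10(stats::uniroot(f, c(1e-16, 10), tol = 1e-18)$root)
  }
  cases <- list(c(13, 1, 0.65, 2), c(13, 1, 1.5, 2), c(10, 2, 0.2, 1))
  for (cs in cases)
    expect_equal(mix_strong_acid_base(cs[1], cs[2], cs[3], cs[4]),
                 oracle(cs[1], cs[2], cs[3], cs[4]), tolerance = 1e-6)
  # equal equivalents of strong acid and base neutralize to pH 7
  expect_equal(mix_strong_acid_base(13, 1, 0.65, 2), 7, tolerance = 1e-6)
  # the worked overshoot case lands at pH 13.07 by charge balance
  expect_equal(mix_strong_acid_base(13, 1, 1.5, 2), 13.069, tolerance = 0.001)
  # monotone in base volume; recovers the acid pH with no base
  phs <- vapply(seq(0, 2, 0.1), function(v)
    mix_strong_acid_base(13, 1, v, 2), numeric(1))
  expect_true(all(diff(phs) > 0))
  expect_equal(phs[1], 1, tolerance = 1e-6)
  expect_error(mix_strong_acid_base(-1, 1, 1, 2), "positive")
})

test_that("frequency scaling applies only above the cutoff", {
  expect_equal(apply_freq_scaling(1656), 1617.912)
  expect_equal(apply_freq_scaling(830), 830)
  expect_equal(apply_freq_scaling(c(830, 1656), factor = 1), c(830, 1656))
  expect_error(apply_freq_scaling(1656, factor = 0), "> 0")
  expect_error(apply_freq_scaling(-5), "positive")
})

test_that("fit_scaling_factor equals the brute-force grid minimizer", {
  expect_equal(fit_scaling_factor(c(800, 1200), c(800, 1200)), 1)
  calc <- c(615, 850, 1035, 1180, 1620, 1660)
  expect_equal(fit_scaling_factor(calc, 0.9770 * calc), 0.9770,
               tolerance = 1e-12)
  withr::with_seed(8, {
    obs <- 0.97 * calc + stats::rnorm(length(calc), sd = 5)
  })
  got <- fit_scaling_factor(calc, obs)
  grid <- seq(0.8, 1.1, by = 1e-6)
  rss <- vapply(grid, function(f) sum((obs - f * calc)^2), numeric(1))
  expect_lt(abs(got - grid[which.min(rss)]), 1e-6)
  expect_error(fit_scaling_factor(numeric(0), numeric(0)), "non-empty")
})

test_that("thermal energy matches the room-temperature scale", {
  expect_equal(signif(thermal_energy(293), 1), 4e-21)
  expect_equal(thermal_energy(0.001), 1.380649e-26, tolerance = 1e-9)
  expect_equal(thermal_energy(600), 2 * thermal_energy(300))
  expect_error(thermal_energy(0), "> 0")
})

test_that("Clausius-Mossotti polarizability has the right limits and sign", {
  expect_equal(abs(polarizability_cm(35, 1.77 + 0i, 1.77)), 0)
  # conductor limit
  a_inf <- polarizability_cm(35, 1e9 + 0i, 1.77)
  a_ref <- 4 * pi * 8.8541878128e-12 * 1.77 * (35e-9)^3
  expect_equal(Re(a_inf), a_ref, tolerance = 1e-6)
  # silver at the trapping wavelength polarizes along the field
  expect_gt(Re(polarizability_cm(35, silver_permittivity(1064), 1.77)), 0)
  expect_error(polarizability_cm(35, -3.54 + 0i, 1.77), "singular")
  expect_error(polarizability_cm(0, 1 + 0i), "radius")
})

test_that("trap force and potential satisfy the gradient-force identity", {
  prof <- gaussian_hotspot_profile(n = 4001, width_nm = 50)
  tr <- trap_force_potential(prof)
  # F matches the analytic derivative of the Gaussian intensity profile
  z <- prof$z_nm * 1e-9
  pref <- 0.25 * prof$alpha_re * prof$e0_sq
  f_true <- pref * prof$e2 * (-(z - 0) / (50e-9)^2)
  expect_lt(max(abs(tr$force_pN * 1e-12 - f_true)) / max(abs(f_true)), 1e-6)
  # re-integrating F recovers U up to the far-field constant
  f <- tr$force_pN * 1e-12
  seg <- (f[-1] + f[-length(f)]) / 2 * diff(z)
  u_re <- rev(c(0, cumsum(rev(seg))))
  expect_lt(max(abs(u_re - tr$potential_J)) / tr$well_depth_J, 1e-6)
  # U is proportional to -e2 pointwise
  expect_equal(tr$potential_J,
               -pref * (prof$e2 - prof$e2[length(prof$e2)]),
               tolerance = 1e-12)
  # the potential minimum sits at the force zero crossing
  expect_equal(prof$z_nm[which.min(tr$potential_J)], 0, tolerance = 1)
})

test_that("degenerate and invalid trap profiles are handled", {
  flat <- trap_profile(seq(-100, 100, 1), rep(5, 201))
  tr <- trap_force_potential(flat)
  expect_equal(max(abs(tr$force_pN)), 0, tolerance = 1e-20)
  expect_equal(tr$well_depth_J, 0)
  expect_false(tr$stable)
  expect_error(trap_profile(c(0, 1, 1, 2), rep(1, 4)), "increasing")
  expect_error(trap_profile(1:3, c(1, -1, 1)), ">= 0")
})

test_that("a well calibrated to the headline depth is emphatically stable", {
  prof <- calibrate_trap_profile(gaussian_hotspot_profile(), 3.5e-18)
  tr <- trap_force_potential(prof, T = 293)
  expect_equal(tr$well_depth_J, 3.5e-18, tolerance = 1e-9)
  expect_equal(tr$stability_ratio, 3.5e-18 / thermal_energy(293),
               tolerance = 1e-9)
  expect_gt(tr$stability_ratio, 10)
  expect_true(tr$stable)
})
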