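test_that("closed-form critical GRF matches frozen reference values", {
  expect_equal(critical_grf(90), 1561.274182, tolerance = 1e-8)
  expect_equal(critical_grf(30), 2499.942037, tolerance = 1e-8)
  # removing the quadriceps lowers the threshold to the frozen value
  expect_equal(critical_grf(30, activation = activation_state(
    quad_fraction = 0)), 1713.740241, tolerance = 1e-8)
})

test_that("critical GRF agrees with the scalar root-find oracle", {
  for (a in seq(1, 90, by = 1)) {
    expect_equal(critical_grf(a), oracle_critical_grf(a),
                 tolerance = 1e-6 / critical_grf(a))
  }
  # and with friction
  surf <- surface_state(0.25)
  for (a in c(20, 45, 70, 90)) {
    expect_equal(critical_grf(a, surface = surf),
                 oracle_critical_grf(a, surface = surf),
                 tolerance = 1e-6)
  }
})

test_that("both sides of the printed balance agree at the computed
          critical GRF", {
  for (a in seq(0.5, 90, by = 4.5)) {
    fy <- critical_grf(a)
    expect_equal(balance_lhs(fy, a) / balance_rhs(a), 1,
                 tolerance = 1e-9)
  }
})

test_that("threshold diverges as the abduction lever closes", {
  # monotone increase towards the alpha -> 0 singularity at mu = 0
  small <- c(1, 0.1, 0.01, 0.001)
  vals <- critical_grf(small)
  expect_true(all(diff(vals) > 0))
  expect_gt(critical_grf(0.001), 5e7)
  expect_error(critical_grf(0), "non-positive")
  # with traction the singularity moves to atan(mu)
  surf <- surface_state(0.5)
  expect_error(critical_grf(20, surface = surf), "non-positive")
  expect_equal(critical_grf(20, surface = surf, no_solution = "inf"), Inf)
})

test_that("critical GRF is strictly decreasing in angle at mu = 0", {
  cv <- generate_curve()  # default 0.01-degree grid
  expect_true(all(diff(cv$critical_grf_N) < 0))
})

test_that("angle of damage inverts the threshold relation", {
  # round trip across the open interval, closed-form branch
  for (a in c(0.5, 5, 22.2, 45, 67.9, 89, 90)) {
    expect_equal(angle_of_damage(critical_grf(a)), a, tolerance = 1e-6)
  }
  # bisection branch (mu > 0)
  surf <- surface_state(0.3)
  for (a in c(25, 50, 75, 90)) {
    fy <- critical_grf(a, surface = surf)
    expect_equal(angle_of_damage(fy, surface = surf), a,
                 tolerance = 1e-6)
  }
  # frozen inversions
  expect_equal(angle_of_damage(2499.942037), 30, tolerance = 1e-6)
  expect_equal(angle_of_damage(1561.274182), 90, tolerance = 1e-4)
  # below the 90-degree minimum threshold there is no angle of damage
  expect_true(is.na(angle_of_damage(600)))
  expect_true(is.na(angle_of_damage(1500, surface = surface_state(0.4))))
  expect_error(angle_of_damage(0), "positive")
})

test_that("curve generation samples the closed grid with BW track and
          sentinels", {
  cv <- generate_curve()
  expect_equal(nrow(cv), 9000L)
  expect_equal(cv$angle_deg[1], 0.01)
  expect_equal(cv$angle_deg[9000], 90)
  expect_equal(cv$critical_grf_BW, cv$critical_grf_N / 802)
  expect_false(any(cv$unreachable))
  # sub-grid of a finer curve matches pointwise
  fine <- generate_curve(1, 90, 0.5)
  coarse <- generate_curve(1, 90, 1)
  idx <- match(coarse$angle_deg, fine$angle_deg)
  expect_false(anyNA(idx))
  expect_identical(coarse$critical_grf_N, fine$critical_grf_N[idx])
  # friction curve lies at or above the frictionless one below 90 degrees
  cmu <- generate_curve(1, 90, 1, surface = surface_state(0.3))
  expect_true(all(cmu$critical_grf_N >= coarse$critical_grf_N))
  expect_true(all(cmu$critical_grf_N[cmu$angle_deg < 90] >
                    coarse$critical_grf_N[coarse$angle_deg < 90]))
  # steep-friction cells below atan(mu) carry the Inf sentinel
  cs <- generate_curve(1, 90, 1, surface = surface_state(1))
  expect_true(all(cs$unreachable[cs$angle_deg < 45]))
  expect_true(all(is.infinite(cs$critical_grf_N[cs$unreachable])))
  expect_error(generate_curve(50, 40), "angle_min")
  expect_error(generate_curve(0, 91), "angle_min")
})

test_that("risk classification is strict at the threshold", {
  fy <- critical_grf(30)
  at <- function(f) classify_risk(landing_scenario(30, f, ref_profile()))
  expect_true(at(fy + 1)$at_risk)
  expect_false(at(fy)$at_risk)
  expect_false(at(0)$at_risk)
  expect_equal(at(fy)$margin_Nm, 0, tolerance = 1e-9)
  expect_gt(at(fy + 1)$margin_Nm, 0)
})
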