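test_that("GRF abduction moment arm is L sin(alpha)", {
  p <- ref_profile()
  expect_equal(grf_abduction_moment_arm(p, 90), 0.59486)
  expect_equal(grf_abduction_moment_arm(p, 0), 0)
  expect_equal(grf_abduction_moment_arm(p, 30), 0.29743)
  expect_error(grf_abduction_moment_arm(p, 91), "\\[0, 90\\]")
  expect_error(grf_abduction_moment_arm(p, -1), "\\[0, 90\\]")
})

test_that("COG adduction moment arm is half-biacetabular + T sin(alpha)", {
  p <- ref_profile()
  expect_equal(cog_adduction_moment_arm(p, 0), 0.12378)
  expect_equal(cog_adduction_moment_arm(p, 90), 0.58558)
  zero_thigh <- suppressWarnings(anthropometric_profile(
    0.026, 0.069, 0.058, 0.595, 1e-12, 0.124, 80))
  expect_equal(cog_adduction_moment_arm(zero_thigh, 45), 0.124)
})

test_that("abduction torque matches the slippery-surface expression and
          its friction extension", {
  sc <- function(alpha, fy, mu = 0)
    landing_scenario(alpha, fy, ref_profile(),
                     surface = surface_state(mu))
  expect_equal(abduction_torque(sc(90, 1000)), 594.86)
  expect_equal(abduction_torque(sc(0, 5000)), 0)
  # friction lever exactly cancels at mu = tan(alpha)
  expect_equal(abduction_torque(sc(40, 2000, mu = tan(40 * pi / 180))), 0)
  # clamped at zero when friction overwhelms
  expect_equal(abduction_torque(sc(10, 2000, mu = 2)), 0)
  # linear in Fy at fixed angle
  expect_equal(abduction_torque(sc(35, 4000)),
               4 * abduction_torque(sc(35, 1000)))
  # non-increasing in mu below 90 degrees, independent of mu at 90
  mus <- seq(0, 1, by = 0.1)
  t45 <- vapply(mus, function(m) abduction_torque(sc(45, 3000, m)),
                numeric(1))
  expect_true(all(diff(t45) <= 0))
  t90 <- vapply(mus, function(m) abduction_torque(sc(90, 3000, m)),
                numeric(1))
  expect_true(all(t90 == t90[1]))
})

test_that("adduction torque reproduces the reference sum and scales with
          activation and tissue forces", {
  sc0 <- landing_scenario(0, 0, ref_profile())
  expect_equal(adduction_torque(sc0), 558.37596, tolerance = 1e-12)
  sc90 <- landing_scenario(90, 0, ref_profile())
  expect_equal(adduction_torque(sc90), 928.73956, tolerance = 1e-12)
  # angle dependence is exactly m g T sin(alpha)
  for (a in c(10, 30, 55, 80)) {
    sca <- landing_scenario(a, 0, ref_profile())
    expect_equal(adduction_torque(sca) - adduction_torque(sc0),
                 802 * 0.4618 * sin(a * pi / 180))
  }
  # zero tissue forces and (near-)zero mass give zero torque
  zt <- tissue_parameters(0, 0, 0, 0, 0)
  pm0 <- suppressWarnings(anthropometric_profile(
    0.026, 0.069, 0.058, 0.595, 0.46, 0.124, 1e-12))
  expect_lt(adduction_torque(landing_scenario(30, 0, pm0), zt), 1e-10)
  # non-decreasing in every activation fraction
  for (frac in c("quad_fraction", "semit_fraction", "ligament_fraction")) {
    vals <- vapply(c(0, 0.5, 1), function(v) {
      args <- list(quad_fraction = 1, semit_fraction = 1,
                   gastroc_fraction = 1, ligament_fraction = 1)
      args[[frac]] <- v
      s <- landing_scenario(30, 0, ref_profile(),
                            activation = do.call(activation_state, args))
      adduction_torque(s)
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("adduction torque agrees with the printed-equation transcription
          across angles", {
  for (a in seq(0, 90, by = 7.5)) {
    s <- landing_scenario(a, 0, ref_profile())
    expect_equal(adduction_torque(s), balance_rhs(a), tolerance = 1e-12)
  }
})

test_that("gastrocnemius term is off by default and additive when given", {
  s <- landing_scenario(20, 0, ref_profile())
  base <- adduction_torque(s)
  with_g <- adduction_torque(s, gastroc_arm = 0.05)
  expect_equal(with_g - base, 931 * 0.05)
})

test_that("net abduction torque is abduction minus adduction", {
  s <- landing_scenario(30, 3000, ref_profile())
  expect_equal(net_abduction_torque(s), 148.73224, tolerance = 1e-6)
  s0 <- landing_scenario(45, 0, ref_profile())
  expect_lt(net_abduction_torque(s0), 0)
  # zero at the critical GRF by construction
  fy <- critical_grf(62.5)
  sb <- landing_scenario(62.5, fy, ref_profile())
  expect_equal(net_abduction_torque(sb), 0, tolerance = 1e-9)
})

test_that("scenario and parameter constructors validate their domains", {
  expect_error(landing_scenario(100, 100), "\\[0, 90\\]")
  expect_error(landing_scenario(30, -5), "grf_vertical")
  expect_error(activation_state(quad_fraction = 1.2), "\\[0, 1\\]")
  expect_error(surface_state(-0.1), "mu")
  expect_error(tissue_parameters(acl_max_force = -1), "non-negative")
})
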