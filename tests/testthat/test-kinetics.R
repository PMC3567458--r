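# Rate-law unit tests. Expected values are computed independently: either by
# hand arithmetic from the tabulated constants or by a one-line evaluation of
# the printed formula.

test_that("convective transport follows plasma-fraction flow", {
  expect_equal(convective_transport_rate(1.0, 0.47, 2.0), 1.06)
  expect_equal(convective_transport_rate(1.0, 0.3, 0), 0)
  expect_equal(convective_transport_rate(0, 0.47, 5), 0)
  expect_error(convective_transport_rate(1, 1.0, 1), "hct")
})

test_that("secretion is first order in intracellular concentration", {
  expect_equal(secretion_rate(7.81, 0), 0)
  expect_equal(secretion_rate(7.81, 1e-6), 7.81e-6)
  expect_equal(secretion_rate(7.81, 2e-6), 2 * secretion_rate(7.81, 1e-6))
  expect_error(secretion_rate(7.81, -1), "c_cellular")
})

test_that("prorenin activation matches the competitive-inhibition formula", {
  p <- ref_params()$prorenin
  kinh <- ref_params()$ang2$k_inhibition
  ## independent scalar evaluation of the printed equation
  oracle <- function(cpro, cang2)
    p$vmax_kid * 0.24 * cpro / (cpro + p$km_kid * (1 + cang2 / kinh))
  got <- prorenin_activation_rate(p$vmax_kid, p$km_kid, kinh, 0.24,
                                  1.1e-4, 4.84e-6)
  expect_equal(got, oracle(1.1e-4, 4.84e-6), tolerance = 1e-14)
  expect_equal(got, 3.5172e-6, tolerance = 1e-4)
  ## no inhibitor: plain Michaelis-Menten
  expect_equal(prorenin_activation_rate(p$vmax_kid, p$km_kid, kinh, 0.24,
                                        1.1e-4, 0),
               p$vmax_kid * 0.24 * 1.1e-4 / (1.1e-4 + p$km_kid))
  ## saturation limit VmaxKid * V_Kidney = 0.3888
  expect_equal(prorenin_activation_rate(p$vmax_kid, p$km_kid, kinh, 0.24,
                                        1e9, 4.84e-6),
               1.62 * 0.24, tolerance = 1e-6)
})

test_that("prorenin activation is strictly decreasing in angiotensin 2", {
  p <- ref_params()$prorenin
  kinh <- ref_params()$ang2$k_inhibition
  ang2 <- sort(10^runif(25, -9, -4))
  r <- prorenin_activation_rate(p$vmax_kid, p$km_kid, kinh, 0.24, 1.1e-4, ang2)
  expect_true(all(diff(r) < 0))
})

test_that("degradation follows ln2 over the half-life", {
  expect_equal(degradation_rate(0, 1.54), 0)
  expect_equal(degradation_rate(3.3, log(2)), 3.3)  # unit half-life
  expect_equal(degradation_rate(4.84e-6, 1.54), 2.1785e-6, tolerance = 1e-4)
  expect_error(degradation_rate(1, 0), "half_life")
})

test_that("Michaelis-Menten conversion matches hand arithmetic", {
  ## renin acting on AGT, per litre of plasma
  expect_equal(mm_conversion_rate(3.6, 5.04e-2, 1, 3.62e-7, 0.60),
               1.2022e-6, tolerance = 1e-4)
  expect_equal(mm_conversion_rate(3.6, 5.04e-2, 1, 0, 0.60), 0)
  ## saturation: kcat * V0 * C0
  expect_equal(mm_conversion_rate(3.6, 5.04e-2, 2, 1e-3, 1e9),
               3.6 * 2 * 1e-3, tolerance = 1e-6)
})

test_that("binding kinetics: zero, equilibrium and the Enaat-ACE Kd", {
  expect_equal(binding_rate(35.16, 2.15e-2, 1, 0, 0), 0)
  ## net rate vanishes at the equilibrium complex concentration
  c0 <- 0.3; c2 <- 1e-3
  ceq <- 35.16 * c0 * c2 / 2.15e-2
  expect_equal(binding_rate(35.16, 2.15e-2, c0, c2, ceq), 0, tolerance = 1e-15)
  expect_equal(2.15e-2 / 35.16, 6.1149e-4, tolerance = 1e-4)  # Kd (umol/L)
})

test_that("aldosterone synthesis is affine in the complex concentration", {
  expect_equal(aldosterone_synthesis_rate(7.81, 1.51e-6, 0), 1.51e-6)
  expect_equal(aldosterone_synthesis_rate(7.81, 1.51e-6, 1e-7), 2.291e-6,
               tolerance = 1e-4)
  x <- runif(5)
  expect_equal(diff(aldosterone_synthesis_rate(7.81, 1.51e-6, x))[1:4],
               7.81 * diff(x)[1:4])
})

test_that("all rate laws vanish at zero concentrations except basal synthesis", {
  expect_equal(convective_transport_rate(2, 0.47, 0), 0)
  expect_equal(secretion_rate(5, 0), 0)
  expect_equal(prorenin_activation_rate(1.62, 4.68e-2, 1.87e-8, 0.24, 0, 0), 0)
  expect_equal(degradation_rate(0, 5), 0)
  expect_equal(mm_conversion_rate(3.6, 0.05, 1, 0, 0), 0)
  expect_equal(binding_rate(1, 1, 0, 0, 0), 0)
  expect_equal(aldosterone_synthesis_rate(7.81, 1.51e-6, 0), 1.51e-6)
})
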