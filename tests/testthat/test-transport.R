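test_that("mean velocity follows Q/(w h) and its linearity", {
  v <- mean_velocity(design_setting(), design_geom())
  expect_equal(v, 33e-9 / 3600 / (1250e-6 * 250e-6) * 1e3, tolerance = 1e-12)
  expect_equal(round(v, 2), 0.03)
  expect_equal(mean_velocity(perfusion_setting(0), design_geom()), 0)
  expect_equal(mean_velocity(perfusion_setting(66), design_geom()), 2 * v)
  expect_error(chamber_geometry(-250, 1250, 13000), "positive")
})

test_that("diffusivity scales as MW^(-1/3) from an anchor", {
  expect_equal(estimate_diffusivity(20, 20, 1e-6), 1e-6)
  expect_equal(estimate_diffusivity(160, 20, 1e-6), 5e-7)  # (20/160)^(1/3) = 1/2
  for (anchor in c(1e-7, 3e-7, 1e-6)) {
    d <- estimate_diffusivity(20, 20, anchor)
    expect_true(d >= 1e-7 && d <= 1e-6)
  }
  expect_error(estimate_diffusivity(-1, 20, 1e-6), "positive")
})

test_that("Peclet number reproduces the design anchors", {
  expect_equal(peclet(0.03, design_geom(), design_ligand()), 75, tolerance = 1e-12)
  expect_equal(peclet(0, design_geom(), design_ligand()), 0)
  expect_equal(peclet(0.03, design_geom(), ligand_spec(20, 1e-7)), 750,
               tolerance = 1e-12)
})

test_that("receptor areal density spreads one cell's receptors over its disc", {
  rho <- receptor_areal_density(design_receptor())
  expect_equal(rho, 1e4 / (pi * (10e-6)^2 * 6.02214076e23), tolerance = 1e-12)
  expect_equal(rho, 5.2857e-11, tolerance = 5e-4)
  expect_equal(receptor_areal_density(receptor_spec(1e6, 0, 10)), 0)
  r_half <- receptor_areal_density(receptor_spec(1e6, 1e4, 5))
  expect_equal(r_half, 4 * rho, tolerance = 1e-12)
  expect_equal(receptor_areal_density(design_receptor(), "sphere"), rho / 4,
               tolerance = 1e-12)
})

test_that("Damkohler number reproduces the 0.132 anchor and is linear in N_R", {
  da <- damkohler(design_receptor(), design_geom(), design_ligand())
  expect_equal(da, 0.132, tolerance = 2e-3)
  expect_equal(damkohler(receptor_spec(0, 1e4, 10), design_geom(), design_ligand()), 0)
  da2 <- damkohler(receptor_spec(1e6, 2e4, 10), design_geom(), design_ligand())
  expect_equal(da2, 2 * da, tolerance = 1e-12)
})

test_that("Pe/Da ratio at the design point is of order 500", {
  pe <- peclet(0.03, design_geom(), design_ligand())
  da <- damkohler(design_receptor(), design_geom(), design_ligand())
  expect_equal(pe_over_da(pe, da), pe / da)        # exact identity
  expect_equal(pe_over_da(75, 0.132), 568.18, tolerance = 1e-4)
  expect_true(pe_over_da(pe, da) >= 500)
  expect_equal(pe_over_da(3, 3), 1)
  expect_error(pe_over_da(75, 0), "reaction-free")
})

test_that("wall shear is plane-Poiseuille 6 mu Q / (w h^2)", {
  tau <- wall_shear(design_setting(), design_geom())
  expect_equal(tau, 6 * 1e-3 * (33e-9 / 3600) / (1250e-6 * 250e-6^2) * 10,
               tolerance = 1e-12)
  expect_equal(tau, 7.04e-3, tolerance = 1e-3)
  expect_equal(wall_shear(perfusion_setting(0), design_geom()), 0)
  expect_equal(wall_shear(design_setting(), design_geom(), cell_factor = 0.5),
               tau / 2, tolerance = 1e-12)
  expect_error(wall_shear(design_setting(), design_geom(), cell_factor = 0))
})

test_that("surface-to-volume ratio: 4/mm chamber, ~0.79/mm dish", {
  expect_equal(surface_to_volume(design_geom()), 4)
  expect_equal(surface_to_volume(chamber_geometry(1000, 2000, 10000)), 1)
  expect_equal(surface_to_volume(dish_area_cm2 = 78.5, dish_volume_ml = 10),
               0.785, tolerance = 1e-12)
  expect_error(surface_to_volume(dish_area_cm2 = 78.5, dish_volume_ml = 0))
  expect_error(surface_to_volume(), "provide either")
})

test_that("regime classification covers the threshold truth table", {
  expect_equal(classify_regime(75, 0.132), "convection_dominated")
  expect_equal(classify_regime(0, 0.132), "diffusion_dominated")
  expect_equal(classify_regime(75, 100), "mixed")
  expect_equal(classify_regime(0.5, 100), "reaction_limited")
  expect_equal(classify_regime(0.5, 0.5), "diffusion_dominated")
  expect_equal(classify_regime(75, 0), "convection_dominated")  # no binding at all
  expect_error(classify_regime(-1, 0.1))
})

test_that("Pe, Da and tau are homogeneous degree one in their driving parameter", {
  set.seed(42)
  for (i in 1:20) {
    geom <- chamber_geometry(runif(1, 50, 500), runif(1, 500, 2000), runif(1, 5000, 20000))
    lig <- ligand_spec(runif(1, 5, 100), 10^runif(1, -7, -5))
    v <- runif(1, 0.001, 0.1)
    s <- runif(1, 0.1, 10)
    expect_equal(peclet(s * v, geom, lig), s * peclet(v, geom, lig),
                 tolerance = 1e-12)
    rec <- receptor_spec(10^runif(1, 4, 7), 10^runif(1, 3, 5), runif(1, 3, 20))
    rec2 <- rec; rec2$kon_per_M_s <- s * rec$kon_per_M_s
    expect_equal(damkohler(rec2, geom, lig), s * damkohler(rec, geom, lig),
                 tolerance = 1e-12)
    st <- perfusion_setting(runif(1, 1, 100))
    st2 <- perfusion_setting(s * st$q_ul_per_hr)
    expect_equal(wall_shear(st2, geom), s * wall_shear(st, geom), tolerance = 1e-12)
  }
})

test_that("design summary chains the anchors consistently", {
  s <- design_summary(v_mean_mm_s = 0.03)
  expect_equal(s$pe, 75, tolerance = 1e-12)
  expect_equal(s$da, 0.132, tolerance = 2e-3)
  expect_equal(s$pe_over_da, s$pe / s$da)
  expect_equal(s$sa_v_per_mm, 4)
  expect_equal(s$regime, "convection_dominated")
  s_exact <- design_summary()
  expect_equal(s_exact$v_mean_mm_s, 0.029333, tolerance = 1e-4)
  expect_equal(s_exact$pe, 73.33, tolerance = 1e-3)
})
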