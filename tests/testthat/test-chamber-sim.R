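test_that("Poiseuille profile has no-slip walls, parabolic peak, correct mean", {
  expect_equal(poiseuille_profile(0.03, 250, 125), 1.5 * 0.03)
  expect_equal(poiseuille_profile(0.03, 250, c(0, 250)), c(0, 0))
  z <- seq(0, 250, length.out = 2001)
  u <- poiseuille_profile(0.03, 250, z)
  trapz <- sum((u[-1] + u[-length(u)]) / 2 * diff(z)) / 250
  expect_equal(trapz, 0.03, tolerance = 1e-3)
  expect_error(poiseuille_profile(0.03, 250, 300), "\\[0, h\\]")
})

test_that("no secretion gives an identically zero field", {
  g <- coarse_grid()
  fl <- floor_model(g, qs = 0)
  f <- solve_steady(g, 0.03, design_ligand(), fl)
  expect_true(f$converged)
  expect_equal(max(abs(f$c)), 0)
  summ <- capture_fraction(f)
  expect_true(summ$no_secretion)
  expect_true(is.na(summ$capture_fraction))
})

test_that("sealed no-flow chamber reaches the secretion/binding balance", {
  g <- coarse_grid()
  k <- uptake_velocity(design_receptor())
  fl <- floor_model(g, qs = 1, uptake_m_s = k)
  f <- solve_steady(g, 0, design_ligand(), fl, closed = TRUE)
  expect_true(f$converged)
  summ <- capture_fraction(f)
  expect_equal(summ$capture_fraction, 1, tolerance = 1e-3)
  # converged floor concentration equals qs/uptake everywhere
  expect_equal(max(abs(f$c[, 1] - 1 / k)) / (1 / k), 0, tolerance = 5e-3)
})

test_that("steady solution is exactly linear in the secretion flux", {
  g <- coarse_grid()
  f1 <- solve_steady(g, 0.03, design_ligand(), floor_model(g, qs = 1))
  f10 <- solve_steady(g, 0.03, design_ligand(), floor_model(g, qs = 10))
  expect_equal(f10$c, 10 * f1$c, tolerance = 1e-9)
  expect_equal(capture_fraction(f10)$capture_fraction,
               capture_fraction(f1)$capture_fraction, tolerance = 1e-9)
})

test_that("superposition over disjoint floor sources holds", {
  # with a source-independent operator (zero uptake), fields from disjoint
  # secreting patches add to the field of their union
  g <- coarse_grid()
  left <- seq_len(g$nx) <= g$nx / 2
  f_left <- solve_steady(g, 0.03, design_ligand(),
                         floor_model(g, mask = left, qs = 1, uptake_m_s = 0))
  f_right <- solve_steady(g, 0.03, design_ligand(),
                          floor_model(g, mask = !left, qs = 1, uptake_m_s = 0))
  f_all <- solve_steady(g, 0.03, design_ligand(),
                        floor_model(g, mask = rep(TRUE, g$nx), qs = 1, uptake_m_s = 0))
  expect_equal(f_left$c + f_right$c, f_all$c, tolerance = 1e-9)
})

test_that("design-point capture agrees with the plug-flow closed form", {
  g <- grid2d(design_geom(), 261, 51)
  k <- uptake_velocity(design_receptor())
  v <- mean_velocity(design_setting(), design_geom())
  f <- solve_steady(g, v, design_ligand(), floor_model(g, uptake_m_s = k))
  summ <- capture_fraction(f)
  expect_lt(summ$mass_balance_error, 5e-3)
  pf <- plug_flow_capture(k, 13000, v, 250)
  expect_equal(pf, 0.0894, tolerance = 1e-3)
  expect_lt(abs(summ$capture_fraction - pf) / pf, 0.20)
  # majority of secreted ligand is removed by flow at the design point
  expect_lt(summ$capture_fraction, 0.5)
})

test_that("halving the grid spacing changes design-point capture by <2%", {
  k <- uptake_velocity(design_receptor())
  v <- mean_velocity(design_setting(), design_geom())
  g1 <- grid2d(design_geom(), 131, 26)
  g2 <- grid2d(design_geom(), 261, 51)
  c1 <- capture_fraction(solve_steady(g1, v, design_ligand(),
                                      floor_model(g1, uptake_m_s = k)))$capture_fraction
  c2 <- capture_fraction(solve_steady(g2, v, design_ligand(),
                                      floor_model(g2, uptake_m_s = k)))$capture_fraction
  expect_lt(abs(c2 - c1) / c2, 0.02)
})

test_that("plug-flow closed form limits", {
  expect_equal(plug_flow_capture(1, 13000, 0.03, 250), 1, tolerance = 1e-6)
  expect_equal(plug_flow_capture(5e-8, 0, 0.03, 250), 0)
  expect_error(plug_flow_capture(5e-8, 13000, 0, 250))
})

test_that("capture fraction is monotone non-increasing across a Pe sweep", {
  g <- coarse_grid()
  k <- uptake_velocity(design_receptor())
  sw <- pe_sweep(c(0.1, 1, 10, 75, 750), g, design_ligand(),
                 floor_model(g, uptake_m_s = k))
  expect_true(all(diff(sw$capture_fraction) < 0))
  expect_true(all(diff(sw$mean_floor_conc) < 0))
  expect_error(pe_sweep(c(10, 1), g, design_ligand(), floor_model(g)), "sorted")
})

test_that("low-Pe capture approaches its zero-flow limit; washout there is inlet diffusion", {
  g <- coarse_grid()
  k <- uptake_velocity(design_receptor())
  fl <- floor_model(g, uptake_m_s = k)
  sw <- pe_sweep(c(0.1), g, design_ligand(), fl)
  # genuine zero-flow limit of the perfused (open-inlet) configuration
  f0 <- solve_steady(g, 1e-7, design_ligand(), fl)
  c0 <- capture_fraction(f0)$capture_fraction
  expect_equal(sw$capture_fraction[1], c0, tolerance = 0.01)
  # the remaining washout is the diffusive leak through the fresh-medium inlet,
  # of order sqrt(D h / k) / L relative to secretion
  lam_over_L <- sqrt(1e-10 * 250e-6 / k) / 13e-3
  expect_equal(1 - c0, lam_over_L, tolerance = 0.25)
  expect_gt(sw$capture_fraction[1], 0.9)
})

test_that("flux bookkeeping refuses an unconverged field", {
  g <- coarse_grid()
  f <- solve_steady(g, 0.03, design_ligand(), floor_model(g))
  f$converged <- FALSE
  expect_error(capture_fraction(f), "not converged")
})
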