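#' Discretization grid for the chamber cross-section
#'
#' Node-centred grid on the x-z cross-section of the chamber: x in [0, L]
#' along the flow, z in [0, h] across the height. The chamber is much wider
#' than high, so lateral (y) gradients are neglected and the solver works per
#' unit width. The default 261 x 51 grid gives dx = 50 um, dz = 5 um on the
#' reference 13 mm x 250 um chamber.
#'
#' @param geom a [chamber_geometry()].
#' @param nx,nz node counts along x and z (each >= 8).
#' @return an object of class `grid2d`.
#' @export
grid2d <- function(geom, nx = 261, nz = 51) {
  if (nx < 8 || nz < 8) stop_invalid("grid needs nx, nz >= 8 (got %d x %d)", nx, nz)
  dx <- geom$length_um / (nx - 1)
  dz <- geom$height_um / (nz - 1)
  structure(list(
    nx = nx, nz = nz, dx_um = dx, dz_um = dz,
    x_um = seq(0, geom$length_um, length.out = nx),
    z_um = seq(0, geom$height_um, length.out = nz),
    geom = geom
  ), class = "grid2d")
}

#' Uptake velocity of a receptor-covered floor
#'
#' The linearised binding boundary condition treats the reactive floor as a
#' surface sink with flux k_on rho_R c, so k_on rho_R plays the role of an
#' uptake velocity (m/s). At the reference receptor parameters it is
#' ~5.3e-8 m/s.
#'
#' @inheritParams receptor_areal_density
#' @return uptake velocity (m/s).
#' @export
uptake_velocity <- function(rec, convention = "disc") {
  per_M_s_to_m3_per_mol_s(rec$kon_per_M_s) * receptor_areal_density(rec, convention)
}

#' Reactive-floor model
#'
#' Per-floor-node secretion and uptake. Covered nodes secrete ligand at flux
#' `qs` (mol m^-2 s^-1; the steady problem is linear in qs, so qs = 1
#' arbitrary units is the default and only fractions are meaningful) and
#' recapture it with first-order surface rate `uptake_m_s`. Binding is
#' irreversible and unsaturable: a conservative ceiling on recapture.
#'
#' @param grid a [grid2d()].
#' @param coverage_fraction fraction of the floor covered by cells, laid out
#'   as a contiguous block starting at the inlet; ignored if `mask` given.
#' @param mask optional explicit logical vector of length `nx`.
#' @param qs secretion flux on covered nodes (>= 0).
#' @param uptake_m_s uptake velocity on covered nodes (>= 0), typically
#'   [uptake_velocity()] of a receptor spec.
#' @return an object of class `floor_model`.
#' @export
floor_model <- function(grid, coverage_fraction = 1, mask = NULL, qs = 1,
                        uptake_m_s = uptake_velocity(receptor_spec())) {
  if (is.null(mask)) {
    if (coverage_fraction < 0 || coverage_fraction > 1) {
      stop_invalid("coverage_fraction must lie in [0, 1]")
    }
    n_cov <- round(coverage_fraction * grid$nx)
    mask <- seq_len(grid$nx) <= n_cov
  }
  if (length(mask) != grid$nx) stop_invalid("floor mask length must equal nx")
  if (qs < 0 || uptake_m_s < 0) stop_invalid("qs and uptake velocity must be >= 0")
  structure(list(mask = as.logical(mask), qs = qs, uptake_m_s = uptake_m_s),
            class = "floor_model")
}

#' Plane Poiseuille velocity profile
#'
#' u(z) = 6 v_mean (z/h)(1 - z/h): parabolic with no-slip walls and mean
#' v_mean over the height.
#'
#' @param v_mean_mm_s mean velocity (mm/s).
#' @param height_um chamber height (um).
#' @param z_um height coordinate(s), each in [0, h].
#' @return velocity (mm/s) at each z.
#' @export
poiseuille_profile <- function(v_mean_mm_s, height_um, z_um) {
  if (any(z_um < 0 | z_um > height_um)) {
    stop_invalid("z must lie in [0, h] = [0, %g] um", height_um)
  }
  zeta <- z_um / height_um
  6 * v_mean_mm_s * zeta * (1 - zeta)
}

#' Steady advection-diffusion-reaction solve on the chamber cross-section
#'
#' Solves 0 = -u(z) dc/dx + D laplacian(c) with a reactive floor, by
#' finite-volume discretization: first-order upwind advection, central
#' diffusion, direct sparse LU solve of the resulting linear system
#' (unconditionally stable at the design Pe on coarse grids; the problem is
#' linear and steady so no time stepping is needed).
#'
#' Boundary conditions in perfused mode: inlet (x = 0) fresh medium, c = 0;
#' outlet (x = L) zero diffusive flux (fully developed), advective outflow
#' only; ceiling no-flux; floor Robin flux -D dc/dz = qs - uptake c on
#' covered nodes, no-flux elsewhere. In `closed` mode all walls are no-flux,
#' the velocity is zero and ligand can only leave by floor recapture.
#'
#' @param grid a [grid2d()].
#' @param v_mean_mm_s mean velocity (mm/s); ignored (forced 0) when closed.
#' @param ligand a [ligand_spec()] (supplies D).
#' @param floor a [floor_model()].
#' @param closed logical; sealed no-flow chamber.
#' @param tol relative residual tolerance for the converged flag.
#' @return an object of class `concentration_field`: list with `c` (nx x nz
#'   matrix, mol/m^3 per unit qs), `converged`, `residual`, plus the inputs.
#' @export
solve_steady <- function(grid, v_mean_mm_s, ligand, floor, closed = FALSE,
                         tol = 1e-8) {
  nx <- grid$nx; nz <- grid$nz
  dx <- um_to_m(grid$dx_um); dz <- um_to_m(grid$dz_um)
  D <- cm2_per_s_to_m2_per_s(ligand$d_cm2_s)
  h_um <- grid$geom$height_um
  if (closed) v_mean_mm_s <- 0
  u <- poiseuille_profile(v_mean_mm_s, h_um, grid$z_um) * 1e-3  # m/s per z level
  wx <- rep(dx, nx); wx[c(1, nx)] <- dx / 2   # control-volume widths
  wz <- rep(dz, nz); wz[c(1, nz)] <- dz / 2

  idx <- function(i, j) (j - 1L) * nx + i
  n <- nx * nz
  bvec <- numeric(n)
  dirichlet_inlet <- !closed
  solved_i <- if (dirichlet_inlet) 2:nx else 1:nx

  trip_i <- list(); trip_j <- list(); trip_x <- list(); nt <- 0L
  push <- function(r, c, v) {
    nt <<- nt + 1L
    trip_i[[nt]] <<- r; trip_j[[nt]] <<- c; trip_x[[nt]] <<- v
  }

  # horizontal faces between columns i and i+1 at each z level j;
  # flux p -> q = u_j wz_j c_p + (D wz_j / dx)(c_p - c_q), upwind donor p (u >= 0)
  hf <- expand.grid(i = 1:(nx - 1), j = 1:nz)
  p <- idx(hf$i, hf$j); q <- idx(hf$i + 1L, hf$j)
  dcoef <- D * wz[hf$j] / dx
  acoef <- u[hf$j] * wz[hf$j]
  keep_p <- !dirichlet_inlet | hf$i > 1L   # Dirichlet rows carry no flux terms
  push(p[keep_p], p[keep_p], (acoef + dcoef)[keep_p])
  push(p[keep_p], q[keep_p], -dcoef[keep_p])
  push(q, p, -acoef - dcoef)
  push(q, q, dcoef)

  # vertical faces between rows j and j+1 (pure diffusion)
  vf <- expand.grid(i = solved_i, j = 1:(nz - 1))
  p <- idx(vf$i, vf$j); q <- idx(vf$i, vf$j + 1L)
  dcoef <- D * wx[vf$i] / dz
  push(p, p, dcoef); push(p, q, -dcoef)
  push(q, p, -dcoef); push(q, q, dcoef)

  if (!closed) {  # advective outflow through the outlet face
    p <- idx(nx, 1:nz)
    push(p, p, u * wz)
  }
  # reactive floor (j = 1): uptake to diagonal, secretion to RHS
  cov_i <- solved_i[floor$mask[solved_i]]
  if (length(cov_i)) {
    p <- idx(cov_i, 1L)
    push(p, p, floor$uptake_m_s * wx[cov_i])
    bvec[p] <- bvec[p] + floor$qs * wx[cov_i]
  }
  if (dirichlet_inlet) {
    p <- idx(1L, 1:nz)
    push(p, p, rep(1, nz))
  }

  A <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(n, n))
  sol <- tryCatch(as.numeric(Matrix::solve(A, bvec)),
                  error = function(e) stop_invalid("steady solve failed: %s", conditionMessage(e)))
  scale <- max(abs(bvec), .Machine$double.eps)
  residual <- max(abs(as.numeric(A %*% sol) - bvec)) / scale
  if (min(sol) < -1e-12 * max(abs(sol), 1)) {
    stop_invalid("discretization produced negative concentrations (min %g)", min(sol))
  }
  structure(list(
    c = matrix(sol, nrow = nx, ncol = nz),
    converged = residual <= tol, residual = residual,
    grid = grid, ligand = ligand, floor = floor,
    v_mean_mm_s = v_mean_mm_s, closed = closed,
    u_m_s = u, wx_m = wx, wz_m = wz,
    solved_i = solved_i
  ), class = "concentration_field")
}

#' Capture/washout bookkeeping for a steady field
#'
#' Integrates the steady fluxes: `secreted` (floor secretion), `captured`
#' (floor recapture uptake*c), `outflow` (advective flux through the outlet
#' plus, in perfused mode, the diffusive leak through the inlet), all per
#' unit chamber width (mol/s/m). `capture_fraction` is the fraction of
#' secreted ligand rebound by the floor; `washout_fraction` the fraction
#' carried out of the chamber. Their sum deviates from 1 by
#' `mass_balance_error`.
#'
#' @param field a converged [solve_steady()] result.
#' @return an object of class `capture_summary`.
#' @export
capture_fraction <- function(field) {
  if (!inherits(field, "concentration_field")) stop_invalid("need a concentration_field")
  if (!field$converged) {
    stop_invalid("field not converged (residual %g); refusing flux bookkeeping", field$residual)
  }
  fl <- field$floor; grid <- field$grid
  si <- field$solved_i
  cov <- fl$mask[si]
  secreted <- sum(fl$qs * field$wx_m[si][cov])
  captured <- sum(fl$uptake_m_s * field$c[si, 1][cov] * field$wx_m[si][cov])
  if (field$closed) {
    outflow <- 0
  } else {
    adv_out <- sum(field$u_m_s * field$c[grid$nx, ] * field$wz_m)
    dx <- um_to_m(grid$dx_um)
    D <- cm2_per_s_to_m2_per_s(field$ligand$d_cm2_s)
    inlet_leak <- sum(D * (field$c[2, ] - field$c[1, ]) / dx * field$wz_m)
    outflow <- adv_out + inlet_leak
  }
  if (secreted <= 0) {
    return(structure(list(secreted_total = 0, captured_total = captured,
                          outflow_total = outflow, capture_fraction = NA_real_,
                          washout_fraction = NA_real_, mass_balance_error = NA_real_,
                          no_secretion = TRUE), class = "capture_summary"))
  }
  capf <- captured / secreted
  washf <- outflow / secreted
  structure(list(
    secreted_total = secreted, captured_total = captured, outflow_total = outflow,
    capture_fraction = capf, washout_fraction = washf,
    mass_balance_error = abs(secreted - captured - outflow) / secreted,
    no_secretion = FALSE
  ), class = "capture_summary")
}

#' Plug-flow (well-mixed cross-section) capture closed form
#'
#' In the limit of fast vertical mixing the depth-averaged balance gives
#' capture = 1 - exp(-uptake L / (v_mean h)): an independent closed form the
#' 2D solver is checked against. At the reference design point it is ~0.09,
#' i.e. ~91% of secreted ligand is washed out.
#'
#' @param uptake_m_s floor uptake velocity (m/s).
#' @param length_um chamber length (um).
#' @param v_mean_mm_s mean velocity (mm/s).
#' @param height_um chamber height (um).
#' @return capture fraction in [0, 1].
#' @export
plug_flow_capture <- function(uptake_m_s, length_um, v_mean_mm_s, height_um) {
  if (any(c(uptake_m_s, length_um, height_um) < 0) || v_mean_mm_s <= 0) {
    stop_invalid("plug-flow closed form needs v_mean > 0 and non-negative uptake, L, h")
  }
  1 - exp(-uptake_m_s * um_to_m(length_um) /
            ((v_mean_mm_s * 1e-3) * um_to_m(height_um)))
}

#' Capture fraction across a Peclet sweep
#'
#' Re-solves the steady chamber problem at a series of Peclet numbers
#' (equivalently, mean velocities v = Pe D / h) and tabulates the capture
#' fraction and mean floor concentration. Stronger convection must wash out
#' more ligand, so both columns are non-increasing in Pe.
#'
#' @param pe_values positive, sorted Peclet numbers.
#' @param grid a [grid2d()].
#' @param ligand a [ligand_spec()].
#' @param floor a [floor_model()].
#' @param tol solver tolerance, see [solve_steady()].
#' @return data.frame with columns `pe`, `v_mean_mm_s`, `capture_fraction`,
#'   `mean_floor_conc`.
#' @export
pe_sweep <- function(pe_values, grid, ligand, floor, tol = 1e-8) {
  if (any(pe_values <= 0) || is.unsorted(pe_values)) {
    stop_invalid("pe_values must be positive and sorted increasing")
  }
  D <- cm2_per_s_to_m2_per_s(ligand$d_cm2_s)
  h <- um_to_m(grid$geom$height_um)
  rows <- lapply(pe_values, function(pe) {
    v_mm_s <- pe * D / h * 1e3
    field <- solve_steady(grid, v_mm_s, ligand, floor, tol = tol)
    if (!field$converged) {
      stop_invalid("sweep aborted: Pe = %g did not converge (residual %g)", pe, field$residual)
    }
    summ <- capture_fraction(field)
    data.frame(pe = pe, v_mean_mm_s = v_mm_s,
               capture_fraction = summ$capture_fraction,
               mean_floor_conc = mean(field$c[field$solved_i, 1][floor$mask[field$solved_i]]))
  })
  do.call(rbind, rows)
}
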