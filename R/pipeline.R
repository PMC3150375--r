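#' Read a run configuration
#'
#' YAML parameter file with sections `chamber` (height_um, width_um,
#' length_um), `flow` (q_ul_per_hr, viscosity_pa_s), `ligand` (mw_kda,
#' d_cm2_s), `receptor` (kon_per_M_s, per_cell, cell_radius_um) and optional
#' `sim` (nx, nz, tolerance, coverage_fraction). Missing sections fall back
#' to the reference-design defaults; the parsed config round-trips to file
#' losslessly via [write_config()].
#'
#' @param path YAML file path.
#' @return named list of parameter blocks.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_config()
  for (blk in names(defaults)) {
    if (is.null(cfg[[blk]])) cfg[[blk]] <- defaults[[blk]]
    else for (f in names(defaults[[blk]])) {
      if (is.null(cfg[[blk]][[f]])) cfg[[blk]][[f]] <- defaults[[blk]][[f]]
    }
  }
  cfg
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    chamber = list(height_um = 250, width_um = 1250, length_um = 13000),
    flow = list(q_ul_per_hr = 33, viscosity_pa_s = 1e-3),
    ligand = list(mw_kda = 20, d_cm2_s = 1e-6),
    receptor = list(kon_per_M_s = 1e6, per_cell = 1e4, cell_radius_um = 10),
    sim = list(nx = 261, nz = 51, tolerance = 1e-8, coverage_fraction = 1)
  )
}

config_objects <- function(cfg) {
  list(
    geom = chamber_geometry(cfg$chamber$height_um, cfg$chamber$width_um,
                            cfg$chamber$length_um),
    setting = perfusion_setting(cfg$flow$q_ul_per_hr, cfg$flow$viscosity_pa_s),
    ligand = ligand_spec(cfg$ligand$mw_kda, cfg$ligand$d_cm2_s),
    rec = receptor_spec(cfg$receptor$kon_per_M_s, cfg$receptor$per_cell,
                        cfg$receptor$cell_radius_um)
  )
}

#' Run the chamber design analysis
#'
#' Chains the transport calculations for the configured design point and,
#' optionally, writes the dimensionless summary as a one-row CSV plus a
#' human-readable report. Deterministic: identical configs give identical
#' outputs.
#'
#' @param cfg configuration list from [read_config()] / [default_config()].
#' @param out_dir optional output directory for `design_summary.csv` and
#'   `design_report.txt`.
#' @param cell_factor shear correction factor, see [wall_shear()].
#' @param v_mean_mm_s optional velocity override (e.g. rounded convention).
#' @return the `dimensionless_summary`, invisibly when writing.
#' @export
run_design <- function(cfg = default_config(), out_dir = NULL,
                       cell_factor = 1.0, v_mean_mm_s = NULL) {
  obj <- config_objects(cfg)
  summ <- design_summary(obj$geom, obj$setting, obj$ligand, obj$rec,
                         cell_factor = cell_factor, v_mean_mm_s = v_mean_mm_s)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    df <- data.frame(v_mean_mm_s = summ$v_mean_mm_s, pe = summ$pe, da = summ$da,
                     pe_over_da = summ$pe_over_da, tau_dyn_cm2 = summ$tau_dyn_cm2,
                     sa_v_per_mm = summ$sa_v_per_mm, regime = summ$regime)
    utils::write.csv(df, file.path(out_dir, "design_summary.csv"), row.names = FALSE)
    con <- file(file.path(out_dir, "design_report.txt"), "w")
    sink(con); print(summ); sink(); close(con)
    return(invisible(summ))
  }
  summ
}

#' Measure one synthetic chamber image pair
#'
#' Renders phase (and optionally fluorescence) for a scene and runs the
#' measurement pipeline on the rendered images.
#'
#' @param scene a `colony_scene`.
#' @param truth its [ground_truth()].
#' @param spec a [render_spec()].
#' @param params a [segmentation_params()].
#' @param with_fluorescence also quantify the reporter fraction.
#' @return list with `area_fraction` (measured) and, if requested,
#'   `reporter_fraction` (measured).
#' @export
measure_scene <- function(scene, truth, spec = render_spec(),
                          params = segmentation_params(),
                          with_fluorescence = FALSE) {
  phase <- render_phase(scene, spec)
  mask <- segment_phase(phase, params)
  out <- list(area_fraction = cell_area(mask))
  if (with_fluorescence) {
    fl <- render_fluorescence(scene, truth, spec)
    out$reporter_fraction <- sox1_fraction(mask, fl, params)$fraction
  }
  out
}

#' End-to-end synthetic two-condition comparison
#'
#' Emulates the side-by-side chamber design: for each of `n_experiments`
#' independent experiments, synthetic chambers are seeded at the same
#' coverage for two conditions, grown for `days` at each condition's
#' per-day area fold, imaged, segmented, and summarized as per-experiment
#' fold increases; the condition contrast is then tested with the
#' pooled-variance t-test. All randomness derives from `seed`.
#'
#' @param seed integer master seed.
#' @param fold_per_day_a,fold_per_day_b per-day area growth of the two
#'   conditions (a "healthy vs arrested" contrast is e.g. 1.6 vs 1.05).
#' @param days culture days between the reference and final imaging.
#' @param n_experiments independent experiments (default 3).
#' @param chambers_per_condition chambers per condition per experiment.
#' @param images_per_chamber imaged fields per chamber.
#' @param shape field size in px.
#' @param initial_coverage seeding coverage target (fraction of field).
#' @param spec a [render_spec()].
#' @param params a [segmentation_params()].
#' @param out_dir optional directory for tidy CSV outputs.
#' @return list with `per_image` (tidy data.frame), `summary_a`, `summary_b`
#'   ([aggregate_condition()] of fold increases), and `test` (t-test on the
#'   per-experiment folds).
#' @export
run_end_to_end <- function(seed = 1, fold_per_day_a = 1.6, fold_per_day_b = 1.05,
                           days = 5, n_experiments = 3,
                           chambers_per_condition = 3, images_per_chamber = 2,
                           shape = c(256, 256), initial_coverage = 0.075,
                           spec = render_spec(), params = segmentation_params(),
                           out_dir = NULL) {
  conditions <- list(a = fold_per_day_a, b = fold_per_day_b)
  rows <- list()
  for (e in seq_len(n_experiments)) {
    for (cd in names(conditions)) {
      fold_total <- conditions[[cd]]^days
      for (ch in seq_len(chambers_per_condition)) {
        for (im in seq_len(images_per_chamber)) {
          # fold the master seed so derived seeds stay within integer range
          sseed <- (as.integer(seed) %% 100000L) * 10000L + e * 1000L +
            match(cd, names(conditions)) * 500L + ch * 10L + im
          s0 <- sample_scene(sseed, target_area_fraction = initial_coverage,
                             shape = shape, n_colonies = 8, mean_radius_px = 16)
          m0 <- measure_scene(s0$scene, s0$truth, spec, params)
          s1 <- grow_scene(s0$scene, fold_total)
          m1 <- measure_scene(s1, ground_truth(s1), spec, params)
          rows[[length(rows) + 1]] <- data.frame(
            condition = cd, experiment = e, chamber = ch, image = im,
            area_day0 = m0$area_fraction, area_final = m1$area_fraction,
            value = fold_increase(m1$area_fraction, m0$area_fraction)
          )
        }
      }
    }
  }
  per_image <- do.call(rbind, rows)
  summ <- lapply(names(conditions), function(cd) {
    aggregate_condition(per_image[per_image$condition == cd, ], condition = cd)
  })
  names(summ) <- names(conditions)
  test <- ttest_unpaired_equal_var(summ$a$per_experiment$value,
                                   summ$b$per_experiment$value)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(per_image, file.path(out_dir, "per_image.csv"), row.names = FALSE)
    cond_df <- data.frame(
      condition = names(conditions),
      fold_mean = vapply(summ, function(s) s$mean, numeric(1)),
      fold_sd = vapply(summ, function(s) s$sd, numeric(1)),
      n = vapply(summ, function(s) s$n, numeric(1))
    )
    cond_df$t <- test$t; cond_df$p <- test$p
    utils::write.csv(cond_df, file.path(out_dir, "condition_summary.csv"),
                     row.names = FALSE)
  }
  list(per_image = per_image, summary_a = summ$a, summary_b = summ$b, test = test)
}
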