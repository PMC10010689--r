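#' Default configuration for a synthetic two-condition study
#'
#' Bundles every tunable of the simulate / segment / co-localise / indent /
#' compare stages with the study seeds. All fields are plain scalars or short
#' vectors, so the resolved configuration serialises to JSON alongside the
#' results of every run.
#'
#' @param seed master seed; per-image and per-curve seeds are derived from
#'   it.
#' @param n_images images (animals) per condition.
#' @param k_fragments pieces per object in the fragmented condition.
#' @param gap_um fragmentation gap, um.
#' @param scene a [scene_spec()] for the baseline condition.
#' @param params a [segmentation_params()].
#' @param coloc list: `n_a`, `n_b`, `planted_fraction`, `n_images`.
#' @param afm list: `spec` ([hertz_curve_spec()] fields for the true sample),
#'   `n_curves`, `noise_sd_nN`.
#' @return a `study_config` list.
#' @export
study_config <- function(seed = 1L, n_images = 10L, k_fragments = 3L,
                         gap_um = 0.15,
                         scene = scene_spec(),
                         params = segmentation_params(),
                         coloc = list(n_a = 10L, n_b = 12L,
                                      planted_fraction = 0.3, n_images = 10L),
                         afm = list(E_pa = 150e3, n_curves = 10L,
                                    noise_sd_nN = 9)) {
  structure(list(seed = as.integer(seed), n_images = as.integer(n_images),
                 k_fragments = as.integer(k_fragments), gap_um = gap_um,
                 scene = scene, params = params, coloc = coloc, afm = afm),
            class = "study_config")
}

study_seed <- function(master, stage, i) {
  # distinct, reproducible sub-seeds, kept well below 2^31
  (as.integer(master) * 10007L + stage * 1009L + as.integer(i)) %% 2000000011L
}

#' Run the full synthetic study
#'
#' Generates `n_images` baseline scenes and their fragmented counterparts,
#' runs the segmentation pipeline on every image, compares the three
#' morphometric readouts between conditions with the screened two-group
#' test, runs the object-based co-localisation study on planted channel
#' pairs, and processes a batch of synthetic force curves through the Hertz
#' pipeline. When `out_dir` is given, writes per-image morphometry
#' (`morphometry.csv`), group comparisons (`comparisons.csv`),
#' co-localisation (`coloc.csv`), Hertz fits (`hertz_fits.csv`) and the
#' resolved configuration (`config.json`). Identical configurations and
#' seeds reproduce every output exactly.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory (created if missing).
#' @return a `study_result` list with `morphometry` (per-image data frame),
#'   `comparisons` (per-readout `group_comparison`s), `coloc`
#'   (`coloc_summary`), `hertz` (per-curve fit data frame), and `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  scn <- config$scene
  rows <- list()
  for (i in seq_len(config$n_images)) {
    sp <- scn
    sp$seed <- study_seed(config$seed, 1L, i)
    base <- generate_reticulated_image(sp)
    frag <- fragment_scene(base$ground_truth, config$k_fragments,
                           gap_um = config$gap_um,
                           seed = study_seed(config$seed, 2L, i))
    for (cond in c("baseline", "fragmented")) {
      scene <- if (cond == "baseline") base else frag
      res <- run_pipeline(scene$image, params = config$params)
      s <- res$summary
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, condition = cond, n_objects = s$n_objects,
        mean_area_um2 = s$mean_area_um2, mean_feret_um = s$mean_feret_um,
        density_per_um2 = s$density_per_um2, roi_area_um2 = s$roi_area_um2,
        threshold = res$threshold, background_mean = res$background_mean,
        planted_n = scene$ground_truth$n_objects)
    }
  }
  morpho <- do.call(rbind, rows)
  # the normality screen needs at least 3 images per condition
  cmp <- if (config$n_images >= 3L) {
    out <- lapply(c("mean_area_um2", "mean_feret_um", "density_per_um2"),
                  function(v) {
                    a <- morpho[[v]][morpho$condition == "baseline"]
                    b <- morpho[[v]][morpho$condition == "fragmented"]
                    compare_groups(a, b)
                  })
    names(out) <- c("mean_area_um2", "mean_feret_um", "density_per_um2")
    out
  } else NULL

  coloc_res <- lapply(seq_len(config$coloc$n_images), function(i) {
    pair <- generate_coloc_pair(config$coloc$n_a, config$coloc$n_b,
                                config$coloc$planted_fraction, spec = scn,
                                seed = study_seed(config$seed, 3L, i))
    centroid_in_mask_pct(pair$labels_A, pair$labels_B)
  })
  coloc <- coloc_summary(coloc_res)

  hz <- do.call(rbind, lapply(seq_len(config$afm$n_curves), function(i) {
    spec <- hertz_curve_spec(E_pa = config$afm$E_pa,
                             noise_sd_nN = config$afm$noise_sd_nN,
                             seed = study_seed(config$seed, 4L, i))
    fit <- process_force_curve(generate_force_curve(spec), spec$k_n_per_m,
                               nu = spec$nu, R_um = spec$R_um)
    data.frame(curve = i, E_true_pa = spec$E_pa, E_fit_pa = fit$E_pa,
               z0_true_nm = spec$z0_nm, z0_fit_nm = fit$z0_nm,
               rms_residual_nN = fit$rms_residual_nN,
               converged = fit$converged)
  }))

  result <- structure(list(morphometry = morpho, comparisons = cmp,
                           coloc = coloc, hertz = hz, config = config),
                      class = "study_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(morpho, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    if (!is.null(cmp)) {
      cmp_df <- do.call(rbind, lapply(names(cmp), function(nm) {
        x <- cmp[[nm]]
        data.frame(readout = nm, chosen_test = x$chosen_test,
                   statistic = x$statistic, p_value = x$p_value, star = x$star,
                   normality_p_a = x$normality_p_a,
                   normality_p_b = x$normality_p_b, variance_p = x$variance_p)
      }))
      utils::write.csv(cmp_df, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    }
    utils::write.csv(coloc$per_image, file.path(out_dir, "coloc.csv"),
                     row.names = FALSE)
    utils::write.csv(hz, file.path(out_dir, "hertz_fits.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$scene <- unclass(cfg$scene)
    cfg$params <- unclass(cfg$params)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.study_result <- function(x, ...) {
  agg <- stats::aggregate(cbind(mean_area_um2, mean_feret_um, density_per_um2)
                          ~ condition, data = x$morphometry, FUN = mean)
  cat("<study_result>\n")
  print(agg, row.names = FALSE)
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  %s: %s p = %.3g (%s)\n", nm, cc$chosen_test, cc$p_value, cc$star))
  }
  cat(sprintf("  coloc A-in-B mean %.1f%% over %d images\n",
              x$coloc$A_in_B$mean, x$coloc$A_in_B$n_images))
  cat(sprintf("  Hertz: median E %.1f kPa (true %.1f kPa) over %d curves\n",
              stats::median(x$hertz$E_fit_pa) / 1000,
              x$hertz$E_true_pa[1] / 1000, nrow(x$hertz)))
  invisible(x)
}
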