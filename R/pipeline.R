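# End-to-end pipeline: simulate -> preprocess -> FCD -> group inference,
# driven by a single nested config (JSON on disk), with a run manifest.

#' Default run configuration
#'
#' Nested key-value configuration mirroring the analysis defaults: drop
#' 10 volumes, band 0.01-0.1 Hz, FWHM 6 mm, distance criterion 12 mm,
#' voxel p 0.01, cluster p 0.05, FDR alpha 0.05.
#'
#' @param seed Master seed.
#' @param out_dir Output directory for products and the manifest.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("fcdrun")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohort = list(n_per_group = c(LSS = 25L, RSS = 22L, HC = 39L),
                  dims = c(12L, 12L, 12L), voxel_size_mm = 3,
                  n_volumes = 220L, tr_seconds = 2),
    preprocess = list(drop = 10L, fwhm_mm = 6, band = c(0.01, 0.1),
                      motion_limits = c(2.5, 2.5)),
    fcd = list(criterion_mm = 12, eps = 1e-7),
    inference = list(voxel_p = 0.01, cluster_p = 0.05, fdr_alpha = 0.05,
                     map = "g_z",
                     covariates = c("age", "gender", "education",
                                    "head_motion"),
                     regression_covariates = c("age", "gender", "education",
                                               "head_motion",
                                               "lesion_volume")),
    write_maps = FALSE
  ), class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file with the [default_config()] sections; missing
#'   entries fall back to the defaults.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]))
        merge_in(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  cfg <- merge_in(cfg, user)
  if (cfg$inference$voxel_p <= 0 || cfg$inference$voxel_p >= 1 ||
      cfg$inference$cluster_p <= 0 || cfg$inference$cluster_p >= 1)
    stop("inference thresholds must lie in (0, 1)")
  if (cfg$fcd$criterion_mm <= 0) stop("distance criterion must be positive")
  cfg
}

#' Per-subject FCD maps for a simulated cohort
#'
#' Shared simulate-to-maps path used by the pipeline, the tests and the
#' acceptance script. Each subject's raw series is preprocessed (volume
#' drop, Friston-24 nuisance regression with the simulated motion trace,
#' smoothing, band-pass; or just the volume drop when
#' `preprocess = FALSE`, appropriate for calibration runs whose generator
#' output is already band-limited) and fed to [compute_fcd()].
#'
#' @param sim A [simulate_cohort()] result.
#' @param criterion_mm Distance criterion (mm).
#' @param preprocess Run the full preprocessing chain (default `TRUE`).
#' @param fwhm_mm Smoothing FWHM when preprocessing.
#' @param maps Which maps to return, subset of `g_z, s_z, l_z, g_raw,
#'   s_raw, l_raw`.
#' @return A list: `maps` (named list of `N x V_in` matrices), `mask`
#'   (all-voxel [brain_mask()]), `cohort` (with `excluded` flag column),
#'   `fcd` (per-subject [compute_fcd()] objects).
#' @export
cohort_fcd_maps <- function(sim, criterion_mm = 12, preprocess = TRUE,
                            fwhm_mm = 6, maps = c("g_z", "s_z", "l_z")) {
  spec <- sim$spec
  mask <- brain_mask(rep(TRUE, prod(spec$dims)), spec$grid)
  cfg <- distance_config(criterion_mm)
  n <- length(sim$subjects)
  out <- lapply(maps, function(m) matrix(NA_real_, n, sum(mask$inside)))
  names(out) <- maps
  fcd_objs <- vector("list", n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    subj <- sim$subjects[[i]]
    if (preprocess) {
      pre <- preprocess_subject(subj$series, subj$trace, drop = spec$n_drop,
                                fwhm_mm = fwhm_mm, band = spec$band,
                                mask = mask)
      series <- pre$series
      excluded[i] <- pre$excluded
    } else {
      series <- drop_initial_volumes(subj$series, spec$n_drop)
    }
    fcd <- compute_fcd(series, mask, cfg)
    fcd_objs[[i]] <- fcd
    for (m in maps) out[[m]][i, ] <- fcd[[m]]
  }
  cohort <- sim$cohort
  cohort$excluded <- excluded
  list(maps = out, mask = mask, cohort = cohort, fcd = fcd_objs)
}

#' Run the full pipeline from a configuration
#'
#' Simulates the cohort, preprocesses every subject (screening them
#' against the motion exclusion rule), computes FCD maps at the
#' configured distance criterion, runs the three-group ANCOVA with GRF
#' cluster correction on the configured map, post-hoc pairwise contrasts,
#' and the clinical regression (cluster-mean features vs each clinical
#' score over all patients) with BH-FDR. Products and a manifest (echoed
#' parameters, seed, file checksums) are written under `config$out_dir`.
#'
#' @param config A `run_config` from [default_config()] / [read_config()].
#' @return A list: `sim`, `data` ([cohort_fcd_maps()] result), `stat`,
#'   `smoothness`, `clusters`, `posthoc`, `regression`, `manifest`.
#' @export
run_pipeline <- function(config = default_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(
    n_per_group = config$cohort$n_per_group,
    dims = config$cohort$dims, voxel_size_mm = config$cohort$voxel_size_mm,
    n_volumes = config$cohort$n_volumes, n_drop = config$preprocess$drop,
    tr_seconds = config$cohort$tr_seconds, seed = config$seed)
  sim <- simulate_cohort(spec)
  write_cohort(sim$cohort, file.path(config$out_dir, "cohort.tsv"))

  data <- cohort_fcd_maps(sim, criterion_mm = config$fcd$criterion_mm,
                          preprocess = TRUE,
                          fwhm_mm = config$preprocess$fwhm_mm)
  keep <- !data$cohort$excluded
  cohort <- data$cohort[keep, , drop = FALSE]
  map_name <- config$inference$map
  Y <- data$maps[[map_name]][keep, , drop = FALSE]

  if (isTRUE(config$write_maps)) {
    for (i in which(keep)) {
      write_fcd_maps(data$fcd[[i]],
                     file.path(config$out_dir,
                               paste0("fcd_", data$cohort$id[i])))
    }
  }

  design <- build_design(cohort, config$inference$covariates)
  stat <- ancova_f_map(Y, design)
  smoothness <- estimate_smoothness(stat$residuals, data$mask)
  clusters <- grf_cluster_correct(stat, smoothness, data$mask,
                                  voxel_p = config$inference$voxel_p,
                                  cluster_p = config$inference$cluster_p)
  ct <- cluster_table(clusters)
  utils::write.table(ct, file.path(config$out_dir, "clusters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  posthoc <- list()
  for (pair in list(c("LSS", "HC"), c("RSS", "HC"), c("LSS", "RSS"))) {
    posthoc[[paste(pair, collapse = "_vs_")]] <-
      posthoc_pairwise(Y, cohort, pair, config$inference$covariates)
  }

  regression <- NULL
  if (length(clusters)) {
    pts <- cohort$group != "HC"
    covars <- cohort[pts, setdiff(config$inference$regression_covariates,
                                  character(0)), drop = FALSE]
    rows <- list()
    for (ci in seq_along(clusters)) {
      feature <- vapply(which(pts), function(i)
        extract_cluster_feature(Y[i, ], clusters[[ci]], data$mask), numeric(1))
      for (sc in c("fma_ue", "fma_le", "mbi_c")) {
        fit <- clinical_regression(feature, cohort[[sc]][pts], covars)
        rows[[length(rows) + 1L]] <- data.frame(
          cluster = ci, score = sc, beta = fit$beta, r2 = fit$r2,
          t = fit$t, p = fit$p)
      }
    }
    regression <- do.call(rbind, rows)
    regression$p_adjusted <- bh_fdr(regression$p)
    utils::write.table(regression,
                       file.path(config$out_dir, "regression.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  products <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    n_subjects = nrow(cohort), n_excluded = sum(!keep),
    n_clusters = length(clusters),
    products = as.list(stats::setNames(
      unname(tools::md5sum(products)), basename(products))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(sim = sim, data = data, stat = stat, smoothness = smoothness,
       clusters = clusters, posthoc = posthoc, regression = regression,
       manifest = manifest)
}
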