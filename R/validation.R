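# Leave-one-patient-out reproducibility of the voxelwise ANCOVA.

#' Leave-one-out reproducibility map
#'
#' One fold per patient: the patient is removed, the full ANCOVA + GRF
#' cluster correction is re-run on the remaining cohort, and every voxel
#' inside a surviving cluster is counted. The per-voxel count across
#' folds (0 .. n_folds) measures how reproducible the group difference is
#' under single-patient perturbations.
#'
#' @param maps `N x V_in` matrix of subject maps (cohort row order).
#' @param cohort The matching [cohort_table()].
#' @param mask Analysis [brain_mask()].
#' @param covariates Covariates for [build_design()].
#' @param voxel_p,cluster_p GRF thresholds (defaults 0.01 / 0.05).
#' @return A list of class `reproducibility_map`: `counts` (per in-mask
#'   voxel), `n_folds`, `fold_ids` (patient left out per fold), and
#'   `fold_masks` (`n_folds x V_in` logical matrix of per-fold
#'   significance).
#' @export
loo_reproducibility <- function(maps, cohort, mask,
                                covariates = c("age", "gender", "education",
                                               "head_motion"),
                                voxel_p = 0.01, cluster_p = 0.05) {
  patients <- which(cohort$group != "HC")
  if (length(patients) < 2L) stop("need at least 2 patients")
  inside_idx <- which(mask$inside)
  counts <- integer(length(inside_idx))
  fold_masks <- matrix(FALSE, length(patients), length(inside_idx))
  for (fi in seq_along(patients)) {
    keep <- setdiff(seq_len(nrow(cohort)), patients[fi])
    design <- build_design(cohort[keep, , drop = FALSE], covariates)
    stat <- ancova_f_map(maps[keep, , drop = FALSE], design)
    sm <- estimate_smoothness(stat$residuals, mask)
    clusters <- grf_cluster_correct(stat, sm, mask,
                                    voxel_p = voxel_p, cluster_p = cluster_p)
    sig <- logical(length(inside_idx))
    for (cl in clusters) sig[match(cl$voxels, inside_idx)] <- TRUE
    fold_masks[fi, ] <- sig
    counts <- counts + sig
  }
  structure(list(counts = counts, n_folds = length(patients),
                 fold_ids = cohort$id[patients], fold_masks = fold_masks),
            class = "reproducibility_map")
}

#' @export
print.reproducibility_map <- function(x, ...) {
  cat(sprintf("<reproducibility_map %d folds, max count %d>\n",
              x$n_folds, max(x$counts)))
  invisible(x)
}
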