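# Group-level statistics: voxelwise ANCOVA, post-hoc pairwise effects,
# clinical-score regression with BH-FDR, seed FC, longitudinal
# concordance, summary-statistic demographic tests, and ANOVA power.

#' Build a group + covariate design matrix
#'
#' Columns: intercept, indicators for LSS and RSS (HC is the reference;
#' with only two groups present, the first listed is the indicator), then
#' the requested covariates. Gender is coded 0/1 (male = 1); all
#' covariates enter untransformed.
#'
#' @param cohort A [cohort_table()] (rows define the subject order).
#' @param covariates Character vector of cohort columns to adjust for.
#' @return A list: `X` (full design), `X0` (design without group
#'   columns), `group` (factor), `group_cols` (column indices of the
#'   group indicators).
#' @export
build_design <- function(cohort,
                         covariates = c("age", "gender", "education",
                                        "head_motion")) {
  n <- nrow(cohort)
  present <- intersect(COHORT_GROUPS, unique(cohort$group))
  X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  group_cols <- integer(0)
  if (length(present) > 1) {
    for (g in present[-length(present)]) {
      X <- cbind(X, as.numeric(cohort$group == g))
      colnames(X)[ncol(X)] <- paste0("group_", g)
      group_cols <- c(group_cols, ncol(X))
    }
  }
  for (cv in covariates) {
    if (!cv %in% names(cohort)) stop("covariate not in cohort table: ", cv)
    v <- cohort[[cv]]
    if (cv == "gender") v <- as.numeric(v == "male")
    if (anyNA(v)) stop("covariate ", cv, " has missing values")
    if (stats::var(as.numeric(v)) == 0) {
      warning("covariate ", cv, " is constant; dropped from the design")
      next
    }
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  list(X = X, X0 = X[, -group_cols, drop = FALSE],
       group = factor(cohort$group, levels = present),
       group_cols = group_cols)
}

#' Voxelwise ANCOVA F map
#'
#' Ordinary least squares per voxel; F tests the group indicators
#' (2 numerator df for three groups) adjusted for the covariates, by
#' comparing the full model against the model without group columns.
#'
#' @param maps `N x V` matrix of per-subject maps (rows follow the cohort
#'   order used to build the design).
#' @param design A [build_design()] result.
#' @return A list of class `stat_map`: `kind = "F"`, `values` (length V),
#'   `df = c(df1, df2)`, and `residuals` (`N x V`, full-model residuals
#'   for smoothness estimation).
#' @export
ancova_f_map <- function(maps, design) {
  X <- design$X; X0 <- design$X0
  if (nrow(maps) != nrow(X)) stop("maps rows != design rows")
  qr_full <- qr(X); qr_red <- qr(X0)
  if (qr_full$rank < ncol(X)) stop("design matrix is rank deficient")
  res_full <- qr.resid(qr_full, maps)
  res_red <- qr.resid(qr_red, maps)
  rss1 <- colSums(res_full^2)
  rss0 <- colSums(res_red^2)
  df1 <- qr_full$rank - qr_red$rank
  df2 <- nrow(maps) - qr_full$rank
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  f[!is.finite(f) | f < 0] <- 0
  structure(list(kind = "F", values = f, df = c(df1, df2),
                 residuals = res_full), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map %s, %d voxels, df = (%s), max = %.2f>\n", x$kind,
              length(x$values), paste(x$df, collapse = ", "), max(x$values)))
  invisible(x)
}

#' Covariate-adjusted pairwise contrast with Cohen's d
#'
#' Restricts the cohort to one pair of groups, fits
#' `map ~ group + covariates` per voxel, and returns the t map of the
#' group indicator (sign: first-listed group minus second) and the
#' effect-size map `d = t * sqrt(1/n1 + 1/n2)`.
#'
#' @param maps `N x V` matrix over the full cohort order.
#' @param cohort The matching [cohort_table()].
#' @param pair Character pair, e.g. `c("LSS", "HC")`.
#' @param covariates Covariate columns (see [build_design()]).
#' @return A list of class `stat_map`: `kind = "t"`, `values`, `df`,
#'   `d` (Cohen's d map), `n = c(n1, n2)`, `residuals`.
#' @export
posthoc_pairwise <- function(maps, cohort, pair,
                             covariates = c("age", "gender", "education",
                                            "head_motion")) {
  sel <- cohort$group %in% pair
  sub <- cohort[sel, , drop = FALSE]
  Y <- maps[sel, , drop = FALSE]
  n1 <- sum(sub$group == pair[1]); n2 <- sum(sub$group == pair[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 subjects per group")
  X <- matrix(1, nrow(sub), 1)
  X <- cbind(X, as.numeric(sub$group == pair[1]))
  for (cv in covariates) {
    v <- sub[[cv]]
    if (cv == "gender") v <- as.numeric(v == "male")
    if (stats::var(as.numeric(v)) == 0) {
      warning("covariate ", cv, " is constant in the pair; dropped")
      next
    }
    X <- cbind(X, as.numeric(v))
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  t <- as.vector(beta[2, ]) / se
  t[!is.finite(t)] <- 0
  d <- t * sqrt(1 / n1 + 1 / n2)
  structure(list(kind = "t", values = t, df = df, d = d, n = c(n1, n2),
                 residuals = res), class = "stat_map")
}

#' Mean map value over a cluster
#'
#' @param map Per-subject map: vector over in-mask voxels (with `mask`
#'   supplied) or over the full grid.
#' @param cluster A cluster from [grf_cluster_correct()] (uses its grid
#'   linear `voxels`).
#' @param mask The [brain_mask()] the map is defined on (required for
#'   in-mask vectors).
#' @return Mean value over the cluster's voxels.
#' @export
extract_cluster_feature <- function(map, cluster, mask = NULL) {
  if (length(cluster$voxels) < 1L) stop("empty cluster")
  if (!is.null(mask) && length(map) == sum(mask$inside)) {
    pos <- match(cluster$voxels, which(mask$inside))
    if (anyNA(pos)) stop("cluster voxels outside the mask")
    return(mean(map[pos]))
  }
  mean(map[cluster$voxels])
}

#' Linear regression of a clinical score on an imaging feature
#'
#' Fits `score ~ feature + covariates` over patients and reports the
#' feature coefficient, its t and P, and the R^2 of the full model.
#' FDR adjustment across an analysis family is applied afterwards with
#' [bh_fdr()].
#'
#' @param feature Per-patient numeric feature (e.g. cluster mean FCD z).
#' @param score Per-patient clinical score.
#' @param covariates Optional data frame of per-patient covariates
#'   (gender may be a character column, coded male = 1).
#' @return A list: `beta`, `r2`, `t`, `p`, `df`.
#' @export
clinical_regression <- function(feature, score, covariates = NULL) {
  n <- length(feature)
  if (length(score) != n) stop("feature and score lengths differ")
  X <- cbind(intercept = 1, feature = feature)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (cv in names(covariates)) {
      v <- covariates[[cv]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(v == "male")
      X <- cbind(X, as.numeric(v))
    }
  }
  if (qr(X)$rank < ncol(X)) stop("regression design is rank deficient")
  fit <- stats::lm.fit(X, score)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  tval <- fit$coefficients[["feature"]] / se
  r2 <- 1 - sum(fit$residuals^2) / sum((score - mean(score))^2)
  list(beta = fit$coefficients[["feature"]], r2 = r2, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts ascending, forms `p_(i) * m / i`, enforces monotonicity from the
#' largest rank down, caps at 1, and restores the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  q <- p_values[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Seed-based functional connectivity z map
#'
#' Correlates the mean time series of the seed region with every in-mask
#' voxel and applies the signed Fisher transform (|r| clipped at
#' `1 - eps`).
#'
#' @param series A preprocessed [series_4d()].
#' @param seed_mask [brain_mask()] of the seed region.
#' @param mask Analysis [brain_mask()]; defaults to all voxels.
#' @param eps Clip width for the transform.
#' @return Vector of z values over in-mask voxels.
#' @export
seed_fc <- function(series, seed_mask, mask = NULL, eps = 1e-7) {
  if (!grid_equal(series$grid, seed_mask$grid)) stop("seed grid mismatch")
  seed_ts <- rowMeans(series$data[, seed_mask$inside, drop = FALSE])
  if (stats::sd(seed_ts) == 0) stop("seed mean time series has zero variance")
  cols <- if (is.null(mask)) seq_len(ncol(series$data)) else which(mask$inside)
  r <- suppressWarnings(as.vector(stats::cor(seed_ts, series$data[, cols])))
  r[is.na(r)] <- 0
  fisher_z(r, eps)
}

#' Longitudinal score/feature concordance
#'
#' Fraction of patients whose clinical score improved (increased) while
#' the imaging feature moved in the direction expected from the
#' cross-sectional association (`"decrease"` for a negative association,
#' `"increase"` for a positive one).
#'
#' @param pre_scores,post_scores Paired score vectors.
#' @param pre_features,post_features Paired feature vectors.
#' @param feature_direction `"decrease"` (default) or `"increase"`.
#' @return Fraction in `[0, 1]`.
#' @export
change_concordance <- function(pre_scores, post_scores,
                               pre_features, post_features,
                               feature_direction = c("decrease", "increase")) {
  feature_direction <- match.arg(feature_direction)
  n <- length(pre_scores)
  if (any(c(length(post_scores), length(pre_features),
            length(post_features)) != n))
    stop("pre/post vectors must be paired (equal lengths)")
  score_up <- post_scores > pre_scores
  feat_ok <- if (feature_direction == "decrease") post_features < pre_features
             else post_features > pre_features
  mean(score_up & feat_ok)
}

#' One-way ANOVA from group summary statistics
#'
#' Fixed-effects F from per-group means, SDs and sizes: between-group MS
#' about the weighted grand mean (df `k - 1`), within-group MS from
#' `sum((n_g - 1) sd_g^2)` (df `N - k`).
#'
#' @param means,sds,ns Per-group summaries (`ns` all at least 2).
#' @return A list: `f`, `p`, `df`.
#' @export
summary_anova <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2 || length(sds) != k || length(ns) != k) stop("need >= 2 groups")
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (any(sds < 0)) stop("sds must be non-negative")
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  f <- msb / msw
  list(f = f, p = stats::pf(f, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}

#' Independent two-sample t-test from summary statistics
#'
#' @param m1,sd1,n1,m2,sd2,n2 Group summaries.
#' @param variant `"pooled"` (default; classical equal-variance test) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return A list: `t`, `p`, `df`.
#' @export
summary_ttest <- function(m1, sd1, n1, m2, sd2, n2,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    tval <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the margins, df
#' `(rows - 1)(cols - 1)`, no continuity correction.
#'
#' @param counts Integer matrix of observed counts.
#' @return A list: `chisq`, `p`, `df`.
#' @export
chisq_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column margin")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(E <= 0)) stop("all expected counts must be positive")
  stat <- sum((counts - E)^2 / E)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  list(chisq = stat, p = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Power of a one-way (AN(C)OVA-style) F test
#'
#' `P(F' > F_crit)` with `F_crit` the central-F `1 - alpha` quantile on
#' `(k - 1, N - k)` df and `F'` noncentral F with noncentrality
#' `lambda = f^2 N` (Cohen's effect size f).
#'
#' @param f Cohen's effect size f (>= 0).
#' @param alpha Type-I level in (0, 1).
#' @param n_total Total sample size N.
#' @param k_groups Number of groups.
#' @return Power in `[0, 1]`.
#' @export
power_oneway <- function(f, alpha = 0.05, n_total, k_groups = 3) {
  if (f < 0) stop("f must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  df1 <- k_groups - 1; df2 <- n_total - k_groups
  if (df1 < 1 || df2 < 1) stop("invalid degrees of freedom")
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f^2 * n_total, lower.tail = FALSE)
}
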