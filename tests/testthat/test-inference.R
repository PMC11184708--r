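test_that("build_design codes groups and covariates correctly", {
  cohort <- toy_cohort(12L)
  des <- build_design(cohort)
  expect_equal(ncol(des$X), 1 + 2 + 4)          # intercept, 2 groups, 4 covars
  expect_equal(des$group_cols, c(2L, 3L))
  expect_equal(des$X[, "group_LSS"], as.numeric(cohort$group == "LSS"))
  expect_equal(des$X[, "gender"], as.numeric(cohort$gender == "male"))
  expect_equal(ncol(des$X0), 5)
  co2 <- cohort; co2$age <- 50
  expect_warning(d2 <- build_design(co2), "constant")
  expect_false("age" %in% colnames(d2$X))
})

test_that("ancova_f_map reduces to the one-way ANOVA oracle", {
  set.seed(23)
  cohort <- toy_cohort(18L)
  V <- 40L
  Y <- matrix(rnorm(18 * V), 18, V)
  des <- build_design(cohort, covariates = character(0))
  st <- ancova_f_map(Y, des)
  expect_equal(st$df, c(2, 15))                 # df1 = 2 for three groups
  for (v in c(1L, 17L, 40L)) {
    fit <- stats::aov(Y[, v] ~ factor(cohort$group))
    expect_equal(st$values[v], summary(fit)[[1]]$`F value`[1], tolerance = 1e-10)
  }
  # with covariates: equals the drop-one F from lm/anova
  des2 <- build_design(cohort)
  st2 <- ancova_f_map(Y, des2)
  v <- 5L
  full <- stats::lm(Y[, v] ~ des2$X - 1)
  red <- stats::lm(Y[, v] ~ des2$X0 - 1)
  oracle_f <- stats::anova(red, full)$F[2]
  expect_equal(st2$values[v], oracle_f, tolerance = 1e-10)
  expect_error(ancova_f_map(Y[1:5, ], des), "rows")
})

test_that("voxelwise null p-values are calibrated at the nominal rate", {
  set.seed(24)
  n <- 24L; V <- 400L; reps <- 25L
  hits <- 0L; total <- 0L
  cohort <- toy_cohort(n)
  for (r in seq_len(reps)) {
    cohort$group <- sample(cohort$group)       # permuted labels: pure null
    Y <- matrix(rnorm(n * V), n, V)
    des <- build_design(cohort, covariates = character(0))
    st <- ancova_f_map(Y, des)
    p <- stats::pf(st$values, st$df[1], st$df[2], lower.tail = FALSE)
    hits <- hits + sum(p < 0.01)
    total <- total + V
  }
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(hits / total - 0.01), 3 * se + 1e-12)
})

test_that("posthoc t reduces to the pooled two-sample test and d identity", {
  set.seed(25)
  cohort <- toy_cohort(20L)
  V <- 30L
  Y <- matrix(rnorm(20 * V), 20, V)
  st <- posthoc_pairwise(Y, cohort, c("LSS", "HC"), covariates = character(0))
  sel <- cohort$group %in% c("LSS", "HC")
  g <- cohort$group[sel]
  n1 <- sum(g == "LSS"); n2 <- sum(g == "HC")
  for (v in c(2L, 9L)) {
    tt <- stats::t.test(Y[sel, v][g == "LSS"], Y[sel, v][g == "HC"],
                        var.equal = TRUE)
    expect_equal(st$values[v], unname(tt$statistic), tolerance = 1e-10)
    # d equals the direct pooled-SD standardized mean difference
    y1 <- Y[sel, v][g == "LSS"]; y2 <- Y[sel, v][g == "HC"]
    sp <- sqrt(((n1 - 1) * stats::var(y1) + (n2 - 1) * stats::var(y2)) /
                 (n1 + n2 - 2))
    expect_equal(st$d[v], (mean(y1) - mean(y2)) / sp, tolerance = 1e-10)
  }
  expect_equal(st$df, n1 + n2 - 2)
  # sign convention: first-listed group minus second
  Y2 <- Y; Y2[cohort$group == "LSS", 1] <- Y2[cohort$group == "LSS", 1] + 5
  st2 <- posthoc_pairwise(Y2, cohort, c("LSS", "HC"),
                          covariates = character(0))
  expect_gt(st2$values[1], 0)
  st3 <- posthoc_pairwise(Y2, cohort, c("HC", "LSS"),
                          covariates = character(0))
  expect_lt(st3$values[1], 0)
})

test_that("extract_cluster_feature averages cluster voxels", {
  g <- make_grid(c(4L, 4L, 4L))
  mask <- full_mask(g)
  cl <- list(voxels = c(3L, 10L))
  expect_equal(extract_cluster_feature(rep(1.5, 64), cl, mask), 1.5)
  mp <- numeric(64); mp[c(3, 10)] <- c(0.1, 0.3)
  expect_equal(extract_cluster_feature(mp, cl, mask), 0.2)
  set.seed(26)
  mp <- rnorm(64)
  expect_equal(extract_cluster_feature(mp, cl, mask), mean(mp[c(3, 10)]))
  expect_error(extract_cluster_feature(mp, list(voxels = integer(0)), mask),
               "empty cluster")
})

test_that("clinical_regression recovers coefficients and matches lm", {
  set.seed(27)
  feat <- rnorm(10)
  fit <- clinical_regression(feat, 2 * feat)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # oracle: full normal-equations fit on 10 synthetic patients
  covars <- data.frame(age = rnorm(10, 57, 9),
                       gender = sample(c("male", "female"), 10, TRUE),
                       lesion_volume = runif(10, 1, 5))
  score <- 40 - 3 * feat + 0.1 * covars$age + rnorm(10)
  ours <- clinical_regression(feat, score, covars)
  lmfit <- stats::lm(score ~ feat + covars$age +
                       I(as.numeric(covars$gender == "male")) +
                       covars$lesion_volume)
  sm <- summary(lmfit)
  expect_equal(ours$beta, unname(stats::coef(lmfit)["feat"]), tolerance = 1e-10)
  expect_equal(ours$t, unname(sm$coefficients["feat", "t value"]),
               tolerance = 1e-10)
  expect_equal(ours$p, unname(sm$coefficients["feat", "Pr(>|t|)"]),
               tolerance = 1e-10)
  expect_equal(ours$r2, sm$r.squared, tolerance = 1e-10)
  # null calibration: feature independent of score
  set.seed(28)
  hits <- vapply(1:400, function(i) {
    clinical_regression(rnorm(30), rnorm(30))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_error(clinical_regression(rep(1, 10), rnorm(10)), "rank deficient")
})

test_that("bh_fdr implements the step-up and matches p.adjust", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(29)
  for (i in 1:5) {
    p <- runif(sample(3:40, 1))^2
    expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"))
  }
  p <- runif(25)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in ranks
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("seed_fc equals the per-voxel correlation oracle", {
  g <- make_grid(c(5L, 5L, 5L))
  s <- white_series(g, n_t = 60L, seed = 30L)
  seed_inside <- logical(125); seed_inside[c(1, 2, 6)] <- TRUE
  seed_mask <- brain_mask(seed_inside, g)
  z <- seed_fc(s, seed_mask)
  seed_ts <- rowMeans(s$data[, c(1, 2, 6)])
  oracle <- atanh(pmin(pmax(as.vector(stats::cor(seed_ts, s$data)),
                            -1 + 1e-7), 1 - 1e-7))
  expect_equal(z, oracle, tolerance = 1e-12)
  # a voxel carrying exactly the seed mean goes to the clipped maximum
  s2 <- s; s2$data[, 10] <- seed_ts
  # (recompute: the seed mean changes slightly through voxel 10 only if in seed)
  z2 <- seed_fc(s2, seed_mask)
  expect_equal(z2[10], atanh(1 - 1e-7))
  # uncorrelated voxels stay near zero on average
  expect_lt(abs(mean(z[-c(1, 2, 6)])), 0.05)
  s3 <- s; s3$data[, c(1, 2, 6)] <- 0
  expect_error(seed_fc(s3, seed_mask), "zero variance")
})

test_that("change_concordance counts improving pairs", {
  expect_equal(change_concordance(c(1, 2), c(2, 3), c(5, 5), c(4, 4)), 1)
  expect_equal(change_concordance(c(1, 2), c(2, 3), c(5, 5), c(5, 5)), 0)
  set.seed(31)
  pre_s <- rnorm(50); post_s <- rnorm(50)
  pre_f <- rnorm(50); post_f <- rnorm(50)
  oracle <- mean(post_s > pre_s & post_f < pre_f)
  expect_equal(change_concordance(pre_s, post_s, pre_f, post_f), oracle)
  oracle_up <- mean(post_s > pre_s & post_f > pre_f)
  expect_equal(change_concordance(pre_s, post_s, pre_f, post_f, "increase"),
               oracle_up)
  expect_error(change_concordance(1:3, 1:2, 1:3, 1:3), "paired")
})

test_that("summary statistics tests equal raw-data oracles", {
  set.seed(32)
  groups <- list(rnorm(12, 10, 2), rnorm(9, 11, 2), rnorm(15, 9, 3))
  means <- vapply(groups, mean, 1); sds <- vapply(groups, stats::sd, 1)
  ns <- lengths(groups)
  ours <- summary_anova(means, sds, ns)
  oracle <- summary(stats::aov(unlist(groups) ~
                                 factor(rep(1:3, ns))))[[1]]
  expect_equal(ours$f, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$p, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(summary_anova(c(5, 5, 5), c(1, 2, 3), c(5, 5, 5))$f, 0)
  expect_error(summary_anova(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")

  x <- groups[[1]]; y <- groups[[3]]
  ot <- summary_ttest(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(ot$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ot$p, tt$p.value, tolerance = 1e-10)
  ow <- summary_ttest(mean(x), stats::sd(x), length(x),
                      mean(y), stats::sd(y), length(y), variant = "welch")
  tw <- stats::t.test(x, y)
  expect_equal(ow$t, unname(tw$statistic), tolerance = 1e-10)
  expect_equal(ow$df, unname(tw$parameter), tolerance = 1e-8)
  expect_equal(summary_ttest(3, 1, 10, 3, 2, 12)$t, 0)

  tab <- matrix(c(22, 19, 35, 3, 3, 4), nrow = 2, byrow = TRUE)
  oc <- chisq_counts(tab)
  cc <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(oc$chisq, unname(cc$statistic), tolerance = 1e-10)
  expect_equal(oc$p, cc$p.value, tolerance = 1e-10)
  expect_equal(chisq_counts(rbind(c(10, 20), c(5, 10)))$chisq, 0)
  expect_equal(chisq_counts(rbind(c(10, 0), c(0, 10)))$chisq, 20)
  expect_error(chisq_counts(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("power_oneway matches the noncentral-F definition and simulation", {
  expect_equal(power_oneway(0, 0.05, 30, 3), 0.05, tolerance = 1e-10)
  # monotone in f and N
  expect_gt(power_oneway(0.5, 0.05, 86, 3), power_oneway(0.3, 0.05, 86, 3))
  expect_gt(power_oneway(0.3, 0.05, 120, 3), power_oneway(0.3, 0.05, 60, 3))
  # Monte-Carlo oracle at a small spec: simulate one-way ANOVAs with the
  # stated effect size and compare rejection rates
  f_eff <- 0.4; k <- 3L; n_g <- 12L; N <- k * n_g
  mu <- c(-1, 0, 1)
  mu <- mu * f_eff / sqrt(mean((mu - mean(mu))^2))  # scale so f matches
  set.seed(33)
  rej <- vapply(1:600, function(i) {
    y <- rnorm(N) + rep(mu, each = n_g)
    g <- factor(rep(1:k, each = n_g))
    summary(stats::aov(y ~ g))[[1]]$`Pr(>F)`[1] < 0.05
  }, logical(1))
  analytic <- power_oneway(f_eff, 0.05, N, k)
  se <- sqrt(analytic * (1 - analytic) / 600)
  expect_lt(abs(mean(rej) - analytic), 2 * se + 0.01)
  expect_error(power_oneway(0.5, 0.05, 2, 3), "degrees of freedom")
})
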