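test_that("huber_irls recovers a noiseless line exactly", {
  x <- c(-2, -1, 0, 1, 2, 3)
  fit <- huber_irls(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_true(all(fit$weights == 1))
  expect_true(fit$converged)
})

test_that("huber_irls equals OLS when no residual is clipped", {
  # two-point noise (+-c) keeps max|e|/scale = 0.6745 < k: no clipping
  set.seed(3)
  x <- rnorm(24)
  y <- 1 + 0.5 * x + rep(c(-0.3, 0.3), 12)
  fit <- huber_irls(x, y)
  expect_true(all(fit$weights == 1))
  ols <- coef(lm(y ~ x))
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(ols[2]), tolerance = 1e-10)
})

test_that("huber_irls downweights a gross outlier and matches the IRLS oracle", {
  set.seed(14)
  x <- seq(0, 2, length.out = 11)
  y <- x + rnorm(11, 0, 0.002)
  y[6] <- y[6] + 100 * sd(y)
  fit <- huber_irls(x, y)
  orc <- oracle_irls(x, y)
  expect_equal(fit$slope, orc$slope, tolerance = 1e-8)
  expect_equal(fit$intercept, orc$intercept, tolerance = 1e-8)
  expect_lt(abs(fit$slope - 1), 0.05)
  expect_lt(fit$weights[6], 0.2)
})

test_that("huber_irls error conditions carry typed classes", {
  expect_error(huber_irls(c(1, 2), c(1, 2)), class = "insufficient_data_error")
  expect_error(huber_irls(rep(1, 5), rnorm(5)),
               class = "degenerate_design_error")
})

test_that("breakdown demo: one outlier moves OLS but not Huber", {
  set.seed(77)
  x <- rnorm(20)
  y <- x + rnorm(20, 0, 0.1)
  slope_clean_ols <- unname(coef(lm(y ~ x))[2])
  slope_clean_hub <- huber_irls(x, y)$slope
  y2 <- y
  y2[which.max(x)] <- y2[which.max(x)] - 8
  expect_gt(abs(unname(coef(lm(y2 ~ x))[2]) - slope_clean_ols), 0.3)
  expect_lt(abs(huber_irls(x, y2)$slope - slope_clean_hub), 0.05)
})

test_that("weighted_correlation reduces to Pearson and matches brute force", {
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(weighted_correlation(x, y, rep(1, 40)), cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_correlation(x, y, rep(0.37, 40)), cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_correlation(x, x, runif(40)), 1.0)
  w <- runif(40)
  expect_equal(weighted_correlation(x, y, w), oracle_weighted_cor(x, y, w),
               tolerance = 1e-12)
  expect_error(weighted_correlation(x, rep(2, 40), w), "zero weighted variance")
  expect_error(weighted_correlation(x, y, rep(0, 40)), "not all zero")
})

test_that("Huber weights rescue the correlation of a contaminated line", {
  set.seed(14)
  x <- seq(0, 2, length.out = 11)
  y <- x + rnorm(11, 0, 0.002)
  y[6] <- y[6] + 100 * sd(y)
  fit <- huber_irls(x, y)
  r_w <- weighted_correlation(x, y, fit$weights)
  expect_gte(r_w, 0.95)
  expect_lt(cor(x, y), 0.8)
})

test_that("correlation_pvalue follows the t distribution", {
  expect_equal(correlation_pvalue(0, 15), 1.0)
  # r = 0.9, n = 9: oracle by numerical integration of the t density, df = 7
  t_stat <- 0.9 * sqrt(7 / (1 - 0.81))
  dens <- function(u) dt(u, df = 7)
  p_oracle <- 2 * integrate(dens, t_stat, Inf, rel.tol = 1e-12)$value
  expect_equal(correlation_pvalue(0.9, 9), p_oracle, tolerance = 1e-10)
  expect_equal(correlation_pvalue(0.9, 9), 0.000946, tolerance = 0.01)
  expect_identical(as.numeric(correlation_pvalue(1, 5)), 0)
  expect_true(attr(correlation_pvalue(-1, 5), "exact"))
  # monotone decreasing in |r| at fixed n
  p <- vapply(seq(0, 0.95, by = 0.05), correlation_pvalue,
              numeric(1), n_obs = 12)
  expect_true(all(diff(p) < 0))
})

test_that("huber_slope_pvalue reduces to the OLS t-test without clipping", {
  set.seed(8)
  x <- rnorm(20)
  y <- 0.4 * x + rep(c(-0.3, 0.3), 10)
  fit <- huber_irls(x, y)
  expect_true(all(fit$weights == 1))   # construction guarantees no clipping
  p_pkg <- as.numeric(huber_slope_pvalue(fit, x, y))
  p_ols <- summary(lm(y ~ x))$coefficients[2, 4]
  expect_equal(p_pkg, p_ols, tolerance = 1e-6)
})

test_that("correlate_metabolite produces stable flagged records", {
  cfg <- simulation_config(n_metabolites = 6, seed = 17)
  sp <- sim_paired(cfg)
  rec <- correlate_metabolite(sp$paired, "met001", "controls")
  expect_equal(rec$n_obs, 11)
  expect_true(rec$ok)
  expect_true(abs(rec$r_huber) <= 1 && rec$p_huber > 0 && rec$p_huber <= 1)
  # insufficient data is flagged, not dropped
  p2 <- sp$paired
  keep2 <- which(p2$mask[, 2])
  p2$mask[keep2[-(1:2)], 2] <- FALSE
  rec2 <- correlate_metabolite(p2, "met002", "combined")
  expect_false(rec2$ok)
  expect_match(rec2$flag, "at least 3")
  expect_true(is.na(rec2$r_huber))
})

test_that("planted group difference is detected with the right sign", {
  # sign of (r_pat - r_ctrl) should match planted delta-rho for |delta| >= 0.5
  cfg <- simulation_config(seed = 19)   # default world: 7 + 53 such metabolites
  sp <- sim_paired(cfg)
  rec <- correlate_all(sp$paired, scopes = c("patients", "controls"))
  pat <- rec[rec$scope == "patients", ]
  ctl <- rec[rec$scope == "controls", ]
  dr <- sp$truth$rho$rho_patient - sp$truth$rho$rho_control
  big <- abs(dr) >= 0.5
  sign_match <- sign(pat$r_huber - ctl$r_huber) == sign(dr)
  expect_gte(mean(sign_match[big]), 0.9)
})

test_that("scale_residuals normalizes to unit sum of squares with group shares", {
  fit <- huber_irls(c(0, 1, 2, 3), c(0, 1, 2, 3))
  # force known residuals via a fake zero-slope fit
  fake <- structure(list(slope = 0, intercept = 0, scale = 1,
                         weights = rep(1, 2), n_obs = 2, n_iter = 1,
                         converged = TRUE, used = c(TRUE, TRUE)),
                    class = "RobustFit")
  rp <- scale_residuals(fake, c(0, 0), c(3, 4), c("glioma", "control"))
  expect_equal(rp$scaled_residuals, c(0.6, 0.8))
  expect_equal(sum(rp$scaled_residuals^2), 1, tolerance = 1e-9)
  expect_equal(rp$group_share_patients, 0.36)
  expect_equal(rp$group_share_controls, 0.64)
  # uniform residuals across 31 subjects -> shares are group fractions
  g31 <- rep(c("glioma", "control"), c(20, 11))
  rp31 <- scale_residuals(fake, rep(0, 31), rep(1, 31), g31)
  expect_equal(rp31$group_share_patients, 20 / 31)
  expect_equal(rp31$group_share_controls, 11 / 31)
  # zero residuals: flagged, shares are group fractions
  rp0 <- scale_residuals(fake, c(0, 0, 0), c(0, 0, 0),
                         c("glioma", "glioma", "control"))
  expect_match(rp0$flag, "zero residuals")
  expect_equal(rp0$group_share_patients, 2 / 3)
  # random instance vs independent normalize-then-groupsum oracle
  set.seed(23)
  x <- rnorm(31); y <- 0.7 * x + rnorm(31, 0, 0.4)
  fit <- huber_irls(x, y)
  rp_r <- scale_residuals(fit, x, y, g31)
  e <- y - fit$intercept - fit$slope * x
  s_oracle <- e / sqrt(sum(e^2))
  expect_equal(rp_r$scaled_residuals, s_oracle, tolerance = 1e-12)
  expect_equal(rp_r$group_share_patients, sum(s_oracle[g31 == "glioma"]^2),
               tolerance = 1e-12)
  expect_equal(rp_r$group_share_patients + rp_r$group_share_controls, 1,
               tolerance = 1e-9)
})

test_that("scale_residual_matrix normalizes the chosen margin", {
  e <- matrix(rnorm(12), 3, 4)
  by_m <- scale_residual_matrix(e, "metabolite")
  expect_equal(colSums(by_m^2), rep(1, 4), tolerance = 1e-12)
  by_s <- scale_residual_matrix(e, "subject")
  expect_equal(rowSums(by_s^2), rep(1, 3), tolerance = 1e-12)
})

test_that("mean_profile_correlation is 1 for identical fluids and sane otherwise", {
  cfg <- simulation_config(n_metabolites = 30, seed = 29)
  sp <- sim_paired(cfg)
  p <- sp$paired
  p$s_csf <- p$s_pl
  expect_equal(mean_profile_correlation(p, "combined"), 1.0)
  r <- mean_profile_correlation(sp$paired, "combined")
  expect_true(r > 0.5 && r <= 1)  # plasma and CSF means share mu_pl
})
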