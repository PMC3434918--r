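test_that("cross-product matrices match hand computation on tiny designs", {
  # 2 groups x 2 reps, both traits {0,0 | 2,2}: H = [[4,4],[4,4]], E = 0
  Y <- cbind(c(0, 0, 2, 2), c(0, 0, 2, 2))
  cp <- sscp_matrices(Y, c("a", "a", "b", "b"))
  expect_equal(unname(cp$H), matrix(4, 2, 2))
  expect_equal(unname(cp$E), matrix(0, 2, 2))
  expect_equal(cp$g, 2L)
  expect_equal(cp$k, 2L)

  # all observations identical: H = E = 0
  cp0 <- sscp_matrices(cbind(rep(3, 4), rep(1, 4)), c("a", "a", "b", "b"))
  expect_equal(unname(cp0$H), matrix(0, 2, 2))
  expect_equal(unname(cp0$E), matrix(0, 2, 2))

  # degenerate designs are refused
  expect_error(sscp_matrices(Y, c("a", "a", "a", "a")), "g >= 2")
  expect_error(sscp_matrices(Y[c(1, 3), ], c("a", "b")), "k >= 2")
  expect_error(sscp_matrices(Y, c("a", "a", "a", "b")), "unbalanced")
})

test_that("H + E always equals the total corrected cross-products", {
  set.seed(31)
  for (i in 1:50) {
    g <- sample(3:10, 1); k <- sample(2:6, 1)
    Y <- cbind(stats::rnorm(g * k, 50, 10), stats::rnorm(g * k, 2, 0.5))
    cp <- sscp_matrices(Y, rep(seq_len(g), each = k))
    total <- crossprod(sweep(Y, 2, colMeans(Y)))
    expect_equal(unname(cp$H + cp$E), total, tolerance = 1e-10)
  }
})

test_that("cross-products agree with the stats::manova SSCP decomposition", {
  dat <- simulate_experiment(sim_params(seed = 32))
  carv <- dat[dat$soil_treatment == "carvacrol" & dat$rhizobium_mix != "control", ]
  cp <- crossproducts_manova(carv)
  Y <- cbind(carv$nodule_count, ln_fruit(carv))
  assoc <- factor(paste(carv$medicago_genotype, carv$rhizobium_mix, sep = ":"))
  fit <- summary(stats::manova(Y ~ assoc))
  expect_equal(unname(cp$H), unname(fit$SS$assoc), tolerance = 1e-8)
  expect_equal(unname(cp$E), unname(fit$SS$Residuals), tolerance = 1e-8)
})

test_that("mom_covariances inverts the expected-mean-square identities exactly", {
  g <- 12; k <- 5
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  B <- diag(2)
  cp <- structure(list(H = (g - 1) * (k * A + B), E = g * (k - 1) * B,
                       g = g, k = k,
                       trait_labels = c("nodule_count", "ln_fruit")),
                  class = "crossproducts")
  est <- mom_covariances(cp)
  expect_equal(est$cov_E, B, tolerance = 1e-12)
  expect_equal(est$cov_G, A, tolerance = 1e-12)
  expect_false(any(est$negative_variance_flags))

  # H = 0 forces cov_G = -B/k with both flags set
  cp0 <- structure(list(H = matrix(0, 2, 2), E = g * (k - 1) * B, g = g, k = k,
                        trait_labels = c("nodule_count", "ln_fruit")),
                   class = "crossproducts")
  est0 <- mom_covariances(cp0)
  expect_equal(est0$cov_G, -B / k, tolerance = 1e-12)
  expect_true(all(est0$negative_variance_flags))
})

test_that("cov_to_cor handles defined, zero and undefined cases", {
  expect_equal(cov_to_cor(matrix(c(4, 2, 2, 4), 2)), 0.5)
  expect_equal(cov_to_cor(diag(2)), 0)
  u <- cov_to_cor(matrix(c(-0.1, 0.3, 0.3, 2), 2))
  expect_true(is.na(u))
  expect_match(attr(u, "reason"), "trait 1")
  expect_true(abs(cov_to_cor(matrix(c(1, 2, 2, 1), 2))) > 1)  # reported, not clamped
})

test_that("cov_G off-diagonal equals the brute-force group-means path", {
  dat <- simulate_experiment(sim_params(seed = 33))
  for (env in c("control", "carvacrol")) {
    sub <- dat[dat$soil_treatment == env & dat$rhizobium_mix != "control", ]
    est <- mom_covariances(crossproducts_manova(sub))
    Y <- cbind(sub$nodule_count, ln_fruit(sub))
    groups <- paste(sub$medicago_genotype, sub$rhizobium_mix, sep = ":")
    expect_equal(unname(est$cov_G), unname(oracle_cov_G(Y, groups)),
                 tolerance = 1e-10)
  }
})

test_that("method-of-moments estimates are consistent at large g", {
  p <- sim_params(design = design_spec(n_genotypes = 500, n_mixes = 2,
                                       include_control = FALSE, n_soils = 1),
                  r_G = 0.6, home_effect = 0, seed = 34)
  dat <- simulate_experiment(p, latent = TRUE)
  Y <- cbind(dat$latent_nodule, dat$latent_ln_fruit)
  est <- mom_covariances(sscp_matrices(Y, paste(dat$medicago_genotype,
                                                dat$rhizobium_mix)))
  A <- p$cov_G_by_env$control
  # errors judged per entry against the geometric-mean variance scale
  scale_G <- sqrt(outer(diag(A), diag(A)))
  scale_E <- sqrt(outer(diag(p$cov_E), diag(p$cov_E)))
  expect_lt(max(abs(est$cov_G - A) / scale_G), 0.10)
  expect_lt(max(abs(est$cov_E - p$cov_E) / scale_E), 0.05)
})

test_that("cov_G approaches the sample covariance of genotypic values as k grows", {
  p <- sim_params(design = design_spec(n_genotypes = 6, n_mixes = 2,
                                       include_control = FALSE, n_soils = 1,
                                       k = 2000),
                  home_effect = 0, seed = 35)
  dat <- simulate_experiment(p, latent = TRUE)
  key <- paste(dat$medicago_genotype, dat$rhizobium_mix)
  Y <- cbind(dat$latent_nodule, dat$latent_ln_fruit)
  est <- mom_covariances(sscp_matrices(Y, key))
  # with k huge the association means ARE the genotypic values
  gv <- cbind(tapply(Y[, 1], key, mean), tapply(Y[, 2], key, mean))
  expect_lt(max(abs(est$cov_G - stats::cov(gv)) /
                  pmax(abs(stats::cov(gv)), 0.05)), 0.05)
})

test_that("the jackknife matches a hand-unrolled 3-group computation", {
  set.seed(36)
  Y <- cbind(c(10, 12, 30, 35, 50, 49), c(1.0, 1.2, 2.0, 2.2, 3.1, 2.9))
  grp <- c("a", "a", "b", "b", "c", "c")
  rec <- data.frame(plant_id = sprintf("P%d", 1:6),
                    medicago_genotype = grp, rhizobium_mix = "b",
                    soil_treatment = "control", replicate = rep(1:2, 3),
                    nodule_count = as.integer(Y[, 1]),
                    fruit_count = as.integer(round(exp(Y[, 2]) - 1)))
  jk <- jackknife_se(rec, "r_G")
  # oracle: enumerate the three leave-one-out fits through the cov() path
  Yt <- cbind(rec$nodule_count, log(rec$fruit_count + 1))
  stat <- function(idx) {
    cg <- oracle_cov_G(Yt[idx, ], grp[idx])
    if (any(diag(cg) <= 0)) return(NA_real_)
    cg[1, 2] / sqrt(prod(diag(cg)))
  }
  reps <- c(stat(3:6), stat(c(1, 2, 5, 6)), stat(1:4))
  th <- reps[!is.na(reps)]
  m <- length(th)
  se <- sqrt((m - 1) / m * sum((th - mean(th))^2))
  expect_equal(unname(jk$replicates), reps, tolerance = 1e-10)
  expect_equal(jk$se, se, tolerance = 1e-10)
  expect_equal(jk$n_dropped, sum(is.na(reps)))
})

test_that("jackknife over identical groups yields SE = 0", {
  # 4 identical associations (replicated blocks): every leave-one-out fit
  # sees the same configuration, so all replicates coincide
  base_n <- c(10L, 20L, 30L, 42L)
  base_f <- c(3L, 6L, 9L, 12L)
  rec <- data.frame(plant_id = sprintf("P%02d", 1:16),
                    medicago_genotype = rep(c("A", "B", "C", "D"), each = 4),
                    rhizobium_mix = "b", soil_treatment = "control",
                    replicate = rep(1:4, 4),
                    nodule_count = rep(base_n, 4),
                    fruit_count = rep(base_f, 4))
  jk <- jackknife_se(rec, "r_E")
  expect_equal(stats::sd(jk$replicates), 0, tolerance = 1e-12)
  expect_equal(jk$se, 0, tolerance = 1e-12)
  expect_error(jackknife_se(rec[rec$medicago_genotype %in% c("A", "B"), ]),
               "at least 3")
})

test_that("genotypic means match brute-force recomputation", {
  dat <- simulate_experiment(sim_params(seed = 37))
  carv <- dat[dat$soil_treatment == "carvacrol" & dat$rhizobium_mix != "control", ]
  gm <- genotypic_means(carv)
  expect_equal(nrow(gm), 12L)
  expect_true(all(gm$n == 5L))
  i <- which(gm$association == "A17:b")
  manual <- carv[carv$medicago_genotype == "A17" & carv$rhizobium_mix == "b", ]
  expect_equal(gm$mean_nodules[i], mean(manual$nodule_count))
  expect_equal(gm$mean_ln_fruit[i], mean(log(manual$fruit_count + 1)))

  # single association with k = 1 is just that observation
  one <- carv[1, ]
  gm1 <- genotypic_means(one)
  expect_equal(gm1$mean_nodules, as.numeric(one$nodule_count))
})

test_that("major_axis_fit recovers exact lines and flags degeneracies", {
  pts <- cbind(1:6, 2 * (1:6) + 1)
  fit <- major_axis_fit(pts)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)

  # anisotropic Gaussian cloud: slope approaches the leading eigenvector ratio
  set.seed(38)
  S <- matrix(c(4, 1.2, 1.2, 0.8), 2)
  cloud <- MASS::mvrnorm(4000, c(0, 0), S)
  ei <- eigen(S)
  expect_equal(major_axis_fit(cloud)$slope, ei$vectors[2, 1] / ei$vectors[1, 1],
               tolerance = 0.05)

  expect_error(major_axis_fit(cbind(rep(1, 4), rep(2, 4))), "identical")
  # perfectly isotropic cross: equal eigenvalues, axis not identified
  expect_error(major_axis_fit(cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))),
               "isotropic")
})

test_that("estimate_environment composes a full correlation result per soil", {
  dat <- simulate_experiment(sim_params(seed = 39))
  res <- estimate_environment(dat, "carvacrol")
  expect_s3_class(res, "correlation_result")
  expect_equal(res$n, 12L)
  expect_length(res$jackknife_replicates$r_G, 12L)
  expect_true(abs(res$r_E) <= 1)  # Cauchy-Schwarz on the PSD residual matrix

  tab <- estimate_correlations(dat)
  df <- as.data.frame(tab)
  expect_equal(nrow(df), 2L)
  expect_equal(df$n, c(12L, 12L))
  expect_setequal(df$environment, c("control", "carvacrol"))

  expect_error(estimate_environment(dat), "several environments")
  expect_error(estimate_environment(dat, "seawater"), "no records")
})

test_that("r_E stays within [-1, 1] across random datasets", {
  for (s in 41:60) {
    dat <- simulate_experiment(sim_params(seed = s))
    carv <- dat[dat$soil_treatment == "carvacrol" & dat$rhizobium_mix != "control", ]
    est <- mom_covariances(crossproducts_manova(carv))
    expect_true(abs(cov_to_cor(est$cov_E)) <= 1)
  }
})

test_that("r_G estimates vanish when the generating genetic covariance is zero", {
  p <- sim_params(design = design_spec(n_genotypes = 300, n_mixes = 2,
                                       include_control = FALSE, n_soils = 1),
                  r_G = 0, home_effect = 0, seed = 40)
  dat <- simulate_experiment(p)
  est <- mom_covariances(crossproducts_manova(dat))
  expect_lt(abs(cov_to_cor(est$cov_G)), 0.08)
})
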