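test_that("model spec validates chain settings and implies saved-sample count", {
  expect_error(model_spec("MGG", n_iter = 100, burn_in = 200), "exceed")
  expect_error(model_spec("MGG", thin = 0), "thin")
  # full-length study settings: (100000 - 10000) / 10 saved samples
  expect_equal(n_saved_samples(model_spec("MGG")), 9000L)
  expect_equal(n_saved_samples(model_spec("MHRV", n_iter = 20000,
                                          burn_in = 4000, thin = 10)), 1600L)
})

test_that("coefficient matrix equals hand-assembled Henderson blocks", {
  ped <- validate_and_renumber(
    data.frame(animal = c("S", "D", "O"), sire = c(NA, NA, "S"),
               dam = c(NA, NA, "D")))
  rec <- data.frame(animal = c(1L, 2L, 3L), etr = c(36.1, 36.5, 35.9),
                    grp = c("g1", "g2", "g1"), coat = "bay")
  spec <- model_spec("MGG", fixed_effects = "grp",
                     n_iter = 100, burn_in = 10, thin = 1)
  ai <- a_inverse(ped)
  mme <- build_mme(rec, ai, spec)
  su <- 0.2; se <- 0.7
  cs <- mme_coefficients(mme, su, se)
  X <- cbind(c(1, 0, 1), c(0, 1, 0))
  Z <- diag(3)
  Ainv <- solve(additive_relationship_matrix(ped)$a_matrix)
  C_hand <- rbind(cbind(crossprod(X), crossprod(X, Z)),
                  cbind(crossprod(Z, X), crossprod(Z) + (se / su) * Ainv)) / se
  expect_equal(as.matrix(cs$C), C_hand, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(cs$rhs,
               as.numeric(rbind(crossprod(X, rec$etr),
                                crossprod(Z, rec$etr))) / se,
               tolerance = 1e-12)
  # missing animal is reported
  bad <- rec; bad$animal[1] <- 99L
  expect_error(build_mme(bad, ai, spec), "missing from pedigree")
})

test_that("BLUP limits: huge lambda shrinks breeding values to zero", {
  ped <- random_pedigree(60, n_founders = 20, seed = 3)
  set.seed(4)
  rec <- data.frame(animal = sample(ped$id, 40),
                    grp = rep(c("g1", "g2"), 20), coat = "bay")
  rec$etr <- 36 + 0.5 * (rec$grp == "g2") + rnorm(40, 0, 0.3)
  spec <- model_spec("MGG", fixed_effects = "grp",
                     n_iter = 100, burn_in = 10, thin = 1)
  mme <- build_mme(rec, a_inverse(ped), spec)
  sol <- blup_solve(mme, sigma_u2 = 1e-8, sigma_e2 = 0.09)
  expect_lt(max(abs(sol$u_hat)), 1e-4)
  expect_equal(unname(sol$b_hat),
               as.numeric(tapply(rec$etr, rec$grp, mean)), tolerance = 1e-3)
  expect_lt(sol$relative_residual, 1e-8)
})

test_that("fixed-variance Gibbs posterior means reproduce the BLUP solution", {
  ds <- small_dataset(n_founders = 70, n_per_generation = 70,
                      n_generations = 2, n_phenotyped = 140, seed = 8)
  ai <- a_inverse(ds$pedigree)
  spec <- model_spec("MHRV", n_iter = 3000, burn_in = 500, thin = 1, seed = 21)
  mme <- build_mme(ds$records, ai, spec)
  se_map <- c(chestnut = 0.82, bay = 0.88, black = 0.98, gray = 0.72)
  sol <- blup_solve(mme, 0.186, se_map)
  fit <- gibbs_run(ds$records, ai, spec, start_sigma_u2 = 0.186,
                   start_sigma_e2 = se_map, fix_variances = TRUE)
  # MC error of a posterior mean over ~2500 correlated draws
  expect_lt(max(abs(fit$b_mean - sol$b_hat)), 0.05)
  expect_gt(cor(fit$ebv, sol$u_hat), 0.99)
  expect_lt(mean(abs(fit$ebv - sol$u_hat)), 0.02)
})

test_that("equal class variances make the MHRV system collapse to the pooled one", {
  ds <- small_dataset(seed = 13)
  ai <- a_inverse(ds$pedigree)
  fx <- c("age_class", "sex", "coat", "location", "breed_group")
  spec_h <- model_spec("MHRV", fixed_effects = fx, n_iter = 100, burn_in = 10)
  spec_p <- model_spec("MGG", fixed_effects = fx, n_iter = 100, burn_in = 10)
  se <- 0.85
  sol_h <- blup_solve(build_mme(ds$records, ai, spec_h), 0.2,
                      c(chestnut = se, bay = se, black = se, gray = se))
  sol_p <- blup_solve(build_mme(ds$records, ai, spec_p), 0.2, se)
  expect_equal(sol_h$u_hat, sol_p$u_hat, tolerance = 1e-10)
  expect_equal(sol_h$b_hat, sol_p$b_hat, tolerance = 1e-10)
})

test_that("posterior summaries match their closed-form oracles", {
  s <- posterior_summary(rep(3.5, 200))
  expect_equal(s$mean, 3.5)
  expect_equal(s$sd, 0)
  expect_equal(s$hpd, c(3.5, 3.5))

  grid <- seq(0, 1, length.out = 1001)
  hg <- posterior_summary(grid)
  expect_equal(diff(hg$hpd), 0.95, tolerance = 1.1 / 1000)

  set.seed(31)
  z <- rnorm(10000)
  hz <- posterior_summary(z)
  expect_lt(abs(hz$hpd[1] + 1.96), 0.06)
  expect_lt(abs(hz$hpd[2] - 1.96), 0.06)
  expect_error(posterior_summary(numeric(0)), "empty")
})

test_that("effective sample size tracks the autocorrelation structure", {
  set.seed(41)
  n <- 20000L
  white <- rnorm(n)
  ess_w <- convergence_report(white)$ess
  expect_gt(ess_w, 0.8 * n)
  expect_lte(ess_w, 1.25 * n)

  phi <- 0.9
  ar <- as.numeric(arima.sim(list(ar = phi), n))
  ess_ar <- convergence_report(ar)$ess
  expect_lt(abs(ess_ar / (n * (1 - phi) / (1 + phi)) - 1), 0.5)
})

test_that("the sampler recovers variance components on synthetic data", {
  # moderate-size single run; the scaled-up recovery lives in the
  # acceptance suite
  cfg <- sim_config(n_founders = 150, n_generations = 2,
                    n_per_generation = 200, n_phenotyped = 350,
                    sigma_u2 = 0.186, sigma_e2 = 0.736, seed = 51)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, cfg)
  ag <- a_inverse_with_groups(ped)
  spec <- model_spec("MGG", n_iter = 6000, burn_in = 1500, thin = 5, seed = 52)
  fit <- gibbs_run(rec, ag, spec)
  h2 <- mean(fit$samples$h2_all)
  expect_gt(h2, 0.02)
  expect_lt(h2, 0.45)
  ps <- posterior_summary(fit)
  expect_true(all(ps$hpd_lower <= ps$median & ps$median <= ps$hpd_upper))
  expect_equal(nrow(fit$samples), n_saved_samples(spec))
})

test_that("zero-signal data concentrates the heritability near zero", {
  cfg <- sim_config(n_founders = 150, n_generations = 2,
                    n_per_generation = 200, n_phenotyped = 350,
                    sigma_u2 = 0, sigma_e2 = 0.9, seed = 61)
  ped <- simulate_pedigree(cfg)
  rec <- simulate_phenotypes(ped, cfg)
  spec <- model_spec("MHRV",
                     fixed_effects = c("age_class", "sex", "location"),
                     n_iter = 6000, burn_in = 1500, thin = 5, seed = 62)
  # pooled residual: use the MGG variant's single class without groups
  spec_p <- model_spec("MGG",
                       fixed_effects = c("age_class", "sex", "location"),
                       n_iter = 6000, burn_in = 1500, thin = 5, seed = 62)
  fit <- gibbs_run(rec, a_inverse(ped), spec_p)
  expect_gt(mean(fit$samples$h2_all < 0.10), 0.75)
})

test_that("MHRV orders class residual variances as generated in most seeds", {
  res <- vapply(c(71, 73, 75), function(s) {
    cfg <- sim_config(n_founders = 200, n_generations = 2,
                      n_per_generation = 250, n_phenotyped = 500,
                      sigma_u2 = 0.201,
                      sigma_e2 = c(chestnut = 0.82, bay = 0.88,
                                   black = 0.98, gray = 0.72),
                      seed = s)
    ped <- simulate_pedigree(cfg)
    rec <- simulate_phenotypes(ped, cfg)
    spec <- model_spec("MHRV", n_iter = 6000, burn_in = 1500, thin = 5,
                       seed = s + 1)
    fit <- gibbs_run(rec, a_inverse(ped), spec)
    m <- colMeans(fit$samples)
    c(m[["sigma_e2_gray"]] < m[["sigma_e2_black"]],
      m[["h2_gray"]] > m[["h2_black"]])
  }, logical(2))
  # gray has the smallest, black the largest residual variance by design;
  # with ~80 gray records per dataset an occasional inversion is expected
  expect_gte(sum(res[1, ]), 2L)
  expect_gte(sum(res[2, ]), 2L)
})
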