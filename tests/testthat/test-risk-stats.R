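toy_records <- function() {
  # 3 clusters, 2 sessions each, known values
  tibble::tibble(
    whale_id = rep(c("w1", "w2", "w3"), each = 2),
    group_id = rep(c("g1", "g2", "g3"), each = 2),
    session_type = rep(c("RampUp1", "FullPower"), 3),
    SPL_max_dB = c(170, 173, 168, 175, 171, 174),
    R_min_m = c(420, 250, 500, 210, 380, 300)
  )
}

test_that("the Gaussian independence fit reproduces ordinary least squares", {
  rec <- toy_records()
  fit <- fit_factor_model(rec, SPL_max_dB ~ session_type)
  ols <- lm(SPL_max_dB ~ session_type,
            data = dplyr::mutate(rec, session_type = factor(session_type)))
  expect_equal(fit$coefficients, coef(ols), tolerance = 1e-12)
})

test_that("saturated factor models predict group means for both families", {
  rec <- toy_records()
  for (fam in c("gaussian", "gamma")) {
    fit <- fit_factor_model(rec, R_min_m ~ session_type, family = fam)
    pred <- predict_levels(fit)
    means <- dplyr::summarise(dplyr::group_by(rec, session_type),
                              m = mean(R_min_m), .groups = "drop")
    expect_equal(pred$prediction[order(pred$session_type)],
                 means$m[order(means$session_type)], tolerance = 1e-6)
  }
})

test_that("the jackknife covariance matches the explicit leave-one-out formula", {
  rec <- toy_records()
  fit <- fit_factor_model(rec, SPL_max_dB ~ session_type)
  # independent hand computation with lm refits
  ids <- unique(rec$group_id)
  loo <- t(sapply(ids, function(g) {
    coef(lm(SPL_max_dB ~ factor(session_type), data = rec[rec$group_id != g, ]))
  }))
  centred <- sweep(loo, 2, colMeans(loo))
  expected <- (3 - 1) / 3 * t(centred) %*% centred
  expect_equal(unname(fit$vcov_jack), unname(expected), tolerance = 1e-10)
})

test_that("singleton clusters reduce to the delete-one-observation jackknife", {
  set.seed(1)
  rec <- tibble::tibble(
    whale_id = paste0("w", 1:9), group_id = paste0("g", 1:9),
    session_type = rep(c("FullPower", "RampUp1", "RampUp2"), 3),
    SPL_max_dB = rnorm(9, 172, 3)
  )
  fit <- fit_factor_model(rec, SPL_max_dB ~ session_type)
  loo <- t(sapply(1:9, function(i) {
    coef(lm(SPL_max_dB ~ factor(session_type), data = rec[-i, ]))
  }))
  centred <- sweep(loo, 2, colMeans(loo))
  expect_equal(unname(fit$vcov_jack), unname(8 / 9 * t(centred) %*% centred),
               tolerance = 1e-10)
})

test_that("degenerate model inputs are rejected with informative errors", {
  rec <- toy_records()
  expect_error(fit_factor_model(rec[rec$group_id == "g1", ],
                                SPL_max_dB ~ session_type), "2 clusters")
  rec2 <- dplyr::mutate(rec, session_type = factor(session_type,
                                                   levels = c("RampUp1", "FullPower", "RampUp2")))
  expect_error(fit_factor_model(rec2, SPL_max_dB ~ session_type), "RampUp2")
  expect_error(fit_factor_model(dplyr::rename(rec, grp = group_id),
                                SPL_max_dB ~ session_type), "cluster")
})

test_that("bootstrap contrasts converge to normal-theory intervals", {
  rec <- toy_records()
  fit <- fit_factor_model(rec, SPL_max_dB ~ session_type)
  co <- bootstrap_contrast(fit, list(session_type = "RampUp1"),
                           list(session_type = "FullPower"),
                           n_boot = 20000, seed = 3)
  # saturated Gaussian model: difference of level means; normal-theory CI
  # from the jackknife covariance of (Intercept excluded) the level effect
  d <- co$difference
  v <- fit$vcov_jack["session_typeRampUp1", "session_typeRampUp1"]
  expect_equal(co$conf.low, d - 1.96 * sqrt(v), tolerance = 0.05 * sqrt(v))
  expect_equal(co$conf.high, d + 1.96 * sqrt(v), tolerance = 0.05 * sqrt(v))
  expect_equal(co$boot_mean, d, tolerance = 0.05 * sqrt(v))
  # A = B: difference identically zero
  same <- bootstrap_contrast(fit, list(session_type = "RampUp1"),
                             list(session_type = "RampUp1"),
                             n_boot = 500, seed = 4)
  expect_equal(same$difference, 0)
  expect_true(same$conf.low <= 0 && same$conf.high >= 0)
  expect_false(same$significant)
})

test_that("a zero covariance collapses the bootstrap interval", {
  rec <- toy_records()
  fit <- fit_factor_model(rec, SPL_max_dB ~ session_type)
  fit$vcov_jack[] <- 0
  co <- bootstrap_contrast(fit, list(session_type = "RampUp1"),
                           list(session_type = "FullPower"),
                           n_boot = 200, seed = 1)
  expect_equal(co$conf.low, co$conf.high)
  expect_equal(co$conf.low, co$difference)
})

test_that("Wald tests follow the normal reference distribution", {
  expect_equal(wald_test(0, 1), tibble::tibble(Z = 0, p.value = 1))
  expect_equal(wald_test(1.96, 1)$p.value, 0.05, tolerance = 1e-3)
  w <- wald_test(-3, 1)
  expect_equal(w$Z, -3)
  expect_equal(w$p.value, 0.0027, tolerance = 1e-4)
  expect_error(wald_test(1, 0), "positive")
})

test_that("Barnard's test handles balanced and extreme tables", {
  eq <- barnard_test(2, 4, 2, 4)
  expect_equal(eq$Z, 0)
  expect_equal(eq$p.value, 1)
  ex <- barnard_test(3, 3, 0, 3)
  oracle <- barnard_oracle(3, 3, 0, 3)
  expect_equal(ex$Z, oracle$Z, tolerance = 1e-12)
  expect_equal(ex$p.value, oracle$p, tolerance = 1e-9)
  expect_error(barnard_test(0, 0, 1, 2), "at least one")
})

test_that("Barnard's p matches exhaustive enumeration for small tables", {
  set.seed(9)
  combos <- expand.grid(n1 = 1:6, n2 = 1:6)
  for (i in seq_len(nrow(combos))) {
    n1 <- combos$n1[i]; n2 <- combos$n2[i]
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    got <- barnard_test(x1, n1, x2, n2, grid_size = 201)
    want <- barnard_oracle(x1, n1, x2, n2, grid_size = 201)
    expect_equal(got$Z, want$Z, tolerance = 1e-12)
    expect_equal(got$p.value, want$p, tolerance = 1e-9,
                 label = sprintf("table %d/%d vs %d/%d", x1, n1, x2, n2))
  }
})

test_that("avoidance presence differs between sonar and control arms", {
  # session-level counts observed in the field study: 8 avoiding of 18
  # sonar sessions vs 0 of 11 controls; consistency check of direction and
  # significance, not an exact printed-value target
  res <- barnard_test(8, 18, 0, 11)
  expect_gt(res$Z, 2)
  expect_lt(res$p.value, 0.02)
})

test_that("Pearson correlations match hand computation", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "3 complete")
})

test_that("hearing risk classifies against the TTS and PTS thresholds", {
  h <- hearing_risk(183)
  expect_equal(h$classification, "TTS_range")
  expect_equal(h$margin_to_PTS_dB, 16)
  expect_equal(hearing_risk(178.9)$classification, "below_TTS")
  expect_equal(hearing_risk(199)$classification, "above_PTS")
  expect_equal(hearing_risk(179)$classification, "TTS_range")
  multi <- hearing_risk(c(170, 185, 200))
  expect_equal(multi$classification, c("below_TTS", "TTS_range", "above_PTS"))
})
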