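#' Cluster-robust factor models for risk indicators
#'
#' Fits a factor model for a session risk indicator with an independence
#' working correlation — so point estimates coincide with ordinary least
#' squares (Gaussian family, identity link) or gamma maximum
#' quasi-likelihood (log link) — and estimates the coefficient covariance
#' by the leave-one-cluster-out jackknife, which is preferable to the
#' sandwich estimator at the small cluster counts typical of controlled
#' exposure experiments. Group (not whale) is the clustering unit because
#' the behaviour of associated whales tagged in one group need not be
#' independent.
#'
#' The jackknife covariance is
#' `(m - 1) / m * sum_j (beta_(-j) - beta_bar)(beta_(-j) - beta_bar)'`
#' over the `m` leave-one-cluster-out refits, with `beta_bar` their mean.
#' When every cluster holds one observation this is the ordinary delete-one
#' jackknife.
#'
#' @param records A data frame with one row per whale x session: the
#'   response column, the factor columns, and a cluster column.
#' @param formula Model formula, e.g. `SPL_max_dB ~ session_type` or
#'   `SEL_cum_dB ~ avoided * session_type`.
#' @param family `"gaussian"` (identity link) or `"gamma"` (log link).
#' @param cluster Name of the cluster column (default `"group_id"`).
#' @return An object of class `risk_gee`: list with `fit` (the underlying
#'   `glm`), `coefficients`, `vcov_jack`, `family`, `formula`, `cluster`,
#'   `data`, `n_clusters`.
#' @examples
#' df <- data.frame(
#'   y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b", "c"), each = 2),
#'   f = rep(c("u", "v"), 3)
#' )
#' fit <- fit_factor_model(df, y ~ f, cluster = "g")
#' tidy(fit)
#' @export
fit_factor_model <- function(records, formula,
                             family = c("gaussian", "gamma"),
                             cluster = "group_id") {
  family <- match.arg(family)
  if (!cluster %in% names(records)) {
    abort(sprintf("cluster column `%s` not found", cluster))
  }
  records <- as.data.frame(records)
  fac_vars <- all.vars(formula[[3]])
  for (v in fac_vars) {
    if (!is.factor(records[[v]])) records[[v]] <- factor(records[[v]])
    empty <- levels(records[[v]])[table(records[[v]]) == 0]
    if (length(empty) > 0) {
      abort(sprintf("factor `%s` has empty level(s): %s",
                    v, paste(empty, collapse = ", ")))
    }
  }
  fam <- switch(family,
                gaussian = stats::gaussian(),
                gamma = stats::Gamma(link = "log"))
  fit <- stats::glm(formula, data = records, family = fam)
  clus <- records[[cluster]]
  ids <- unique(clus)
  m <- length(ids)
  if (m < 2) abort("at least 2 clusters are required")
  beta <- stats::coef(fit)
  loo <- matrix(NA_real_, m, length(beta),
                dimnames = list(as.character(ids), names(beta)))
  for (j in seq_len(m)) {
    sub <- records[clus != ids[j], , drop = FALSE]
    for (v in fac_vars) {
      if (any(table(factor(sub[[v]], levels = levels(records[[v]]))) == 0)) {
        abort(sprintf(
          "cluster `%s` carries the only observations of a level of `%s`; jackknife is undefined",
          ids[j], v))
      }
    }
    loo[j, ] <- stats::coef(stats::glm(formula, data = sub, family = fam))
  }
  centred <- sweep(loo, 2, colMeans(loo))
  vcov_jack <- (m - 1) / m * crossprod(centred)
  structure(list(
    fit = fit, coefficients = beta, vcov_jack = vcov_jack,
    loo_coefficients = loo, family = family, formula = formula,
    cluster = cluster, data = records, n_clusters = m
  ), class = "risk_gee")
}

#' @export
print.risk_gee <- function(x, ...) {
  cat(sprintf("<cluster-robust factor model: %s family, %d obs, %d clusters>\n",
              x$family, nrow(x$data), x$n_clusters))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_factor_model
#' @param x,object A `risk_gee` fit.
#' @param ... Unused.
#' @method tidy risk_gee
#' @export
tidy.risk_gee <- function(x, ...) {
  se <- sqrt(diag(x$vcov_jack))
  est <- x$coefficients
  tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
}

#' @rdname fit_factor_model
#' @method glance risk_gee
#' @export
glance.risk_gee <- function(x, ...) {
  tibble(family = x$family, n = nrow(x$data), n_clusters = x$n_clusters,
         df.residual = x$fit$df.residual)
}

#' Response-scale predictions for factor-level combinations
#'
#' @param fit A `risk_gee` fit.
#' @param newdata Data frame of factor-level combinations; defaults to all
#'   combinations observed in the data.
#' @return `newdata` with a `prediction` column (response scale).
#' @export
predict_levels <- function(fit, newdata = NULL) {
  fac_vars <- all.vars(fit$formula[[3]])
  newdata <- newdata %||%
    unique(fit$data[fac_vars]) |> dplyr::arrange(dplyr::across(dplyr::all_of(fac_vars)))
  newdata$prediction <- unname(
    stats::predict(fit$fit, newdata = newdata, type = "response"))
  as_tibble(newdata)
}

#' Parametric-bootstrap contrast between factor-level combinations
#'
#' Draws coefficient vectors from a multivariate normal centred at the
#' fitted coefficients with the jackknife covariance, converts each draw to
#' response-scale predictions for two factor-level combinations, and
#' summarises the per-draw prediction difference (A minus B) by its mean
#' and 2.5/97.5 percentiles. The difference is declared significant when
#' the confidence bounds are exclusively positive or exclusively negative.
#'
#' @param fit A `risk_gee` fit.
#' @param combo_A,combo_B Named lists/one-row data frames giving the factor
#'   levels of the two combinations.
#' @param n_boot Bootstrap draws (default 5000).
#' @param seed Optional integer seed.
#' @return One-row tibble: `difference` (point estimate from the fitted
#'   coefficients), `boot_mean`, `conf.low`, `conf.high`, `significant`.
#' @export
bootstrap_contrast <- function(fit, combo_A, combo_B, n_boot = 5000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- fit$vcov_jack
  ev <- eigen(V, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    abort("jackknife covariance is not positive semi-definite")
  }
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(V))
  beta <- fit$coefficients
  draws <- matrix(stats::rnorm(n_boot * length(beta)), n_boot) %*% t(A)
  draws <- sweep(draws, 2, beta, `+`)
  X <- function(combo) {
    nd <- as.data.frame(combo, stringsAsFactors = FALSE)
    fac_vars <- all.vars(fit$formula[[3]])
    for (v in fac_vars) nd[[v]] <- factor(nd[[v]], levels = levels(fit$data[[v]]))
    stats::model.matrix(stats::delete.response(stats::terms(fit$formula)), nd)
  }
  linkinv <- fit$fit$family$linkinv
  pa <- linkinv(drop(draws %*% t(X(combo_A))))
  pb <- linkinv(drop(draws %*% t(X(combo_B))))
  d <- pa - pb
  ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  point <- unname(linkinv(drop(X(combo_A) %*% beta)) -
                    linkinv(drop(X(combo_B) %*% beta)))
  tibble(
    difference = point, boot_mean = mean(d),
    conf.low = ci[1], conf.high = ci[2],
    significant = ci[1] > 0 | ci[2] < 0
  )
}

#' Two-sided Wald test
#'
#' `Z = estimate / sqrt(variance)` with a two-sided normal p-value.
#'
#' @param estimate Point estimate.
#' @param variance Its variance, > 0.
#' @return One-row tibble: `Z`, `p.value`.
#' @export
wald_test <- function(estimate, variance) {
  if (!is.finite(variance) || variance <= 0) {
    abort("variance must be positive for a Wald test")
  }
  z <- estimate / sqrt(variance)
  tibble(Z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Barnard's unconditional test for a 2x2 table
#'
#' Two-sided unconditional test of equality of two binomial proportions.
#' The test statistic is the pooled-variance score statistic
#' `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled
#' proportion (0 when the pooled variance vanishes). The p-value maximises,
#' over a uniform grid of the nuisance success probability `pi`, the
#' probability under independent binomials of a statistic at least as
#' extreme in absolute value as the observed one.
#'
#' @param x1,n1 Successes (e.g. responders) and trials in arm 1.
#' @param x2,n2 Successes and trials in arm 2.
#' @param grid_size Number of nuisance-probability grid points in (0, 1)
#'   (default 1001).
#' @return One-row tibble: `Z`, `p.value`, `pi_max` (the maximising
#'   nuisance probability).
#' @examples
#' barnard_test(8, 18, 0, 11)
#' @export
barnard_test <- function(x1, n1, x2, n2, grid_size = 1001) {
  if (n1 < 1 || n2 < 1) abort("both arms must contain at least one trial")
  stopifnot(x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  score_z <- function(a, b) {
    p1 <- a / n1; p2 <- b / n2; p <- (a + b) / (n1 + n2)
    v <- p * (1 - p) * (1 / n1 + 1 / n2)
    ifelse(v > 0, (p1 - p2) / sqrt(v), 0)
  }
  z_obs <- score_z(x1, x2)
  tab <- expand.grid(a = 0:n1, b = 0:n2)
  z_all <- score_z(tab$a, tab$b)
  extreme <- abs(z_all) >= abs(z_obs) - 1e-12
  grid <- seq(0, 1, length.out = grid_size + 2)[-c(1, grid_size + 2)]
  log_pa <- outer(0:n1, grid, function(a, p) stats::dbinom(a, n1, p, log = TRUE))
  log_pb <- outer(0:n2, grid, function(b, p) stats::dbinom(b, n2, p, log = TRUE))
  pr <- exp(log_pa[tab$a + 1, ] + log_pb[tab$b + 1, ])
  tail_p <- colSums(pr[extreme, , drop = FALSE])
  tibble(Z = z_obs, p.value = min(1, max(tail_p)),
         pi_max = grid[which.max(tail_p)])
}

#' Pearson correlation between two risk indicators
#'
#' Sample Pearson correlation with the two-sided t-test p-value, as a tidy
#' one-row tibble.
#'
#' @param x,y Numeric vectors, at least 3 complete pairs, non-constant.
#' @return One-row tibble: `r`, `p.value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation is undefined for constant input")
  }
  ct <- stats::cor.test(x, y)
  tibble(r = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Hearing-risk classification of cumulative exposure
#'
#' Classifies frequency-weighted cumulative sound exposure levels against
#' the published onset thresholds for low-frequency hearing specialist
#' cetaceans: temporary threshold shift (TTS) at 179 dB re. 1 uPa^2 s and
#' permanent threshold shift (PTS) risk at 199 dB re. 1 uPa^2 s. (The
#' auditory weighting for these species is 0 dB in the 1.3-2.0 kHz sonar
#' band, so unweighted sonar SEL_cum compares directly.) A value equal to a
#' threshold is classified into the higher-risk category (`>=` convention).
#'
#' @param SEL_cum_dB Weighted cumulative sound exposure level(s), dB re.
#'   1 uPa^2 s.
#' @param tts_dB,pts_dB Onset thresholds (defaults 179 and 199).
#' @return A tibble: `SEL_cum_dB`, `classification` (`below_TTS`,
#'   `TTS_range`, `above_PTS`), `margin_to_TTS_dB`, `margin_to_PTS_dB`
#'   (threshold minus value; positive margins mean headroom).
#' @export
hearing_risk <- function(SEL_cum_dB, tts_dB = 179, pts_dB = 199) {
  cls <- dplyr::case_when(
    SEL_cum_dB >= pts_dB ~ "above_PTS",
    SEL_cum_dB >= tts_dB ~ "TTS_range",
    TRUE ~ "below_TTS"
  )
  tibble(
    SEL_cum_dB = SEL_cum_dB,
    classification = cls,
    margin_to_TTS_dB = tts_dB - SEL_cum_dB,
    margin_to_PTS_dB = pts_dB - SEL_cum_dB
  )
}
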