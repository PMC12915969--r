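#' Covariate-adjusted mediation decomposition
#'
#' Decomposes the effect of sleep quality (X, PSQI total) on safety behavior
#' (Y, NSBQ total) through depressive symptoms (M, PHQ-9 total) with three
#' covariate-adjusted GLM fits on the same design:
#' \itemize{
#'   \item M ~ X + covariates — the `a` path (X to M);
#'   \item Y ~ X + M + covariates — the `b` path (M to Y given X) and the
#'     direct effect `c'` (X to Y given M);
#'   \item Y ~ X + covariates — the total effect `c`, reported from its own
#'     regression.
#' }
#' The indirect effect is the product a*b. With the Gaussian identity family
#' all three fits are ordinary least squares on one design and the identity
#' total = direct + indirect holds to numerical precision; it is checked on
#' every fit. Confidence intervals are percentile bootstrap over participant
#' resamples, refitting all three models per replicate; z statistics are
#' coefficient/SE from the analytic fits.
#'
#' @param x,m,y Numeric vectors: exposure, mediator, outcome totals.
#' @param records Cohort tibble holding the covariates.
#' @param spec A [covariate_spec()].
#' @param family GLM family (default Gaussian identity).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A `mediation_result` with a tibble `paths` (path, estimate,
#'   ci_low, ci_high, z, p), the additivity gap, bootstrap metadata, and the
#'   underlying fits.
#' @export
fit_mediation <- function(x, m, y, records, spec = covariate_spec(),
                          family = gaussian(), n_boot = 1000L, seed = NULL,
                          conf = 0.95) {
  stopifnot(length(x) == length(m), length(m) == length(y),
            length(y) == nrow(records))
  if (anyNA(x) || anyNA(m) || anyNA(y)) stop("fit_mediation: missing values in totals")
  W <- design_matrix(records, spec)
  n <- length(x)
  p_design <- ncol(W) + 2L
  if (n < 10L * p_design) {
    stop(sprintf("n = %d too small for %d design columns (need >= %d)",
                 n, p_design, 10L * p_design))
  }

  est <- mediation_paths(x, m, y, W, family, with_z = TRUE)

  boot <- NULL
  n_failed <- 0L
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    boot <- matrix(NA_real_, n_boot, 5L,
                   dimnames = list(NULL, c("a", "b", "direct", "indirect", "total")))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      eb <- tryCatch(
        mediation_paths(x[idx], m[idx], y[idx], W[idx, , drop = FALSE], family),
        error = function(e) NULL
      )
      if (is.null(eb)) n_failed <- n_failed + 1L else boot[bi, ] <- eb$point
    }
    if (n_failed > 0.01 * n_boot) {
      stop(sprintf("%d/%d bootstrap refits failed", n_failed, n_boot))
    }
  }

  a_ <- (1 - conf) / 2
  ci <- if (!is.null(boot)) {
    apply(boot, 2, quantile, probs = c(a_, 1 - a_), na.rm = TRUE)
  } else {
    matrix(NA_real_, 2, 5, dimnames = list(NULL, names(est$point)))
  }
  paths <- tibble::tibble(
    path = c("a", "b", "direct", "indirect", "total"),
    estimate = unname(est$point),
    ci_low = ci[1, ], ci_high = ci[2, ],
    z = unname(est$z[c("a", "b", "direct", "indirect", "total")]),
    p = unname(est$p[c("a", "b", "direct", "indirect", "total")])
  )
  structure(
    list(paths = paths, additivity_gap = est$additivity_gap,
         n = n, n_boot = as.integer(n_boot), n_failed = n_failed, seed = seed,
         family = family$family, conf = conf, boot = boot, fits = est$fits,
         spec = spec),
    class = "mediation_result"
  )
}

# point estimates for one (possibly resampled) dataset; z statistics only
# when requested (they are skipped inside the bootstrap loop, where sparse
# dummy columns may drop out of a resample and leave aliased coefficients)
mediation_paths <- function(x, m, y, W, family, with_z = FALSE) {
  Xa <- cbind(W, x = x)
  Xb <- cbind(W, x = x, m = m)
  fit_a <- glm.fit(Xa, m, family = family)     # a path
  fit_b <- glm.fit(Xb, y, family = family)     # b and direct
  fit_c <- glm.fit(Xa, y, family = family)     # total
  a <- coef_of(fit_a, "x"); b <- coef_of(fit_b, "m")
  direct <- coef_of(fit_b, "x"); total <- coef_of(fit_c, "x")
  if (anyNA(c(a, b, direct, total))) {
    stop("aliased focal coefficient in mediation fit")
  }
  point <- c(a = a, b = b, direct = direct, indirect = a * b, total = total)
  if (with_z) {
    z <- c(a = glm_z(fit_a, "x"), b = glm_z(fit_b, "m"),
           direct = glm_z(fit_b, "x"), indirect = NA_real_,
           total = glm_z(fit_c, "x"))
  } else {
    z <- rep(NA_real_, 5)
    names(z) <- names(point)
  }
  p <- 2 * pnorm(-abs(z))
  gap <- if (family$family == "gaussian" && family$link == "identity") {
    abs(total - (direct + a * b))
  } else NA_real_
  if (!is.na(gap) && gap > 1e-8) {
    warning(sprintf("Gaussian additivity gap %.3g exceeds tolerance", gap))
  }
  list(point = point, z = z, p = p, additivity_gap = gap,
       fits = list(a = fit_a, b = fit_b, total = fit_c))
}

coef_of <- function(fit, name) unname(fit$coefficients[name])

# Wald z = coef / SE from the weighted least-squares representation
glm_z <- function(fit, name) {
  rank <- fit$qr$rank
  R <- qr.R(fit$qr)[seq_len(rank), seq_len(rank), drop = FALSE]
  # dispersion: Pearson estimate (equals residual MSE for Gaussian)
  disp <- sum(fit$weights * fit$residuals^2) / fit$df.residual
  se <- sqrt(diag(chol2inv(R)) * disp)
  names(se) <- names(fit$coefficients)[fit$qr$pivot[seq_len(rank)]]
  unname(fit$coefficients[name] / se[name])
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation decomposition (family: %s, n = %d, %d bootstrap reps)\n",
              x$family, x$n, x$n_boot))
  df <- as.data.frame(x$paths)
  df$estimate <- round(df$estimate, 3)
  df$ci_low <- round(df$ci_low, 3); df$ci_high <- round(df$ci_high, 3)
  df$z <- round(df$z, 3); df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  if (!is.na(x$additivity_gap)) {
    cat(sprintf("additivity gap |total - (direct + indirect)| = %.2e\n",
                x$additivity_gap))
  }
  invisible(x)
}

#' Full per-predictor effects table
#'
#' Direct, indirect (through the mediator) and total effects of the exposure
#' and of every covariate dummy column on the outcome, with percentile
#' bootstrap confidence intervals: direct effects from the Y ~ X + M +
#' covariates fit, indirect effects as (coefficient in the mediator model) x
#' b, total effects from the Y ~ X + covariates fit.
#'
#' @param x,m,y,records,spec,family,n_boot,seed,conf As in [fit_mediation()].
#' @return A tibble: predictor, effect (direct/indirect/total), estimate,
#'   ci_low, ci_high.
#' @export
export_full_effects <- function(x, m, y, records, spec = covariate_spec(),
                                family = gaussian(), n_boot = 1000L,
                                seed = NULL, conf = 0.95) {
  W <- design_matrix(records, spec)
  preds <- c("x", setdiff(colnames(W), "(Intercept)"))

  one <- function(xi, mi, yi, Wi) {
    Xa <- cbind(Wi, x = xi); Xb <- cbind(Wi, x = xi, m = mi)
    fit_a <- glm.fit(Xa, mi, family = family)
    fit_b <- glm.fit(Xb, yi, family = family)
    fit_c <- glm.fit(Xa, yi, family = family)
    b <- coef_of(fit_b, "m")
    vapply(preds, function(pr) {
      c(direct = coef_of(fit_b, pr),
        indirect = coef_of(fit_a, pr) * b,
        total = coef_of(fit_c, pr))
    }, numeric(3))
  }
  point <- one(x, m, y, W)

  qs <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(x)
    draws <- array(NA_real_, c(n_boot, 3L, length(preds)))
    for (bi in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- tryCatch(one(x[idx], m[idx], y[idx], W[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(db)) draws[bi, , ] <- db
    }
    a_ <- (1 - conf) / 2
    qs <- apply(draws, c(2, 3), quantile, probs = c(a_, 1 - a_), na.rm = TRUE)
  }
  rows <- list()
  for (j in seq_along(preds)) {
    for (ei in 1:3) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        predictor = preds[j],
        effect = c("direct", "indirect", "total")[ei],
        estimate = point[ei, j],
        ci_low = if (is.null(qs)) NA_real_ else qs[1, ei, j],
        ci_high = if (is.null(qs)) NA_real_ else qs[2, ei, j]
      )
    }
  }
  dplyr::bind_rows(rows)
}
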