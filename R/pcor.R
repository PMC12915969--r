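#' Covariate adjustment specification
#'
#' Declares the categorical covariates to adjust for and their dummy coding.
#' Each covariate enters the design matrix through treatment contrasts with a
#' declared reference level (the first listed category by default), so
#' the design is fully reproducible.
#'
#' @param covariates Ordered character vector of covariate names. The default
#'   is the adjustment set used for both the totals analysis and the
#'   item-level network: age band, marital status, work experience,
#'   professional title, number of children, night shifts per month, and off
#'   days after night shifts.
#' @param reference Named character vector of reference levels; defaults to
#'   the first label of each covariate's closed label set.
#' @return A `covariate_spec` object.
#' @export
covariate_spec <- function(covariates = c("age_band", "marital_status",
                                          "work_experience_band",
                                          "professional_title", "children_band",
                                          "night_shift_band", "off_days_band"),
                           reference = NULL) {
  levs <- covariate_levels()
  unknown <- setdiff(covariates, names(levs))
  if (length(unknown) > 0L) stop("unknown covariate(s): ", paste(unknown, collapse = ", "))
  ref <- vapply(covariates, function(cv) levs[[cv]][1], "")
  if (!is.null(reference)) {
    for (cv in names(reference)) {
      if (!reference[[cv]] %in% levs[[cv]])
        stop("invalid reference level for ", cv, ": ", reference[[cv]])
      ref[[cv]] <- reference[[cv]]
    }
  }
  structure(list(covariates = covariates, reference = ref),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("Covariate adjustment spec (dummy coding):\n")
  for (cv in x$covariates) cat(sprintf("  %s (ref: %s)\n", cv, x$reference[[cv]]))
  invisible(x)
}

# treatment-coded design matrix (without intercept column name clashes);
# errors on rank deficiency, naming the aliased columns
design_matrix <- function(records, spec) {
  if (length(spec$covariates) == 0L) {
    return(matrix(1, nrow(records), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(records[, spec$covariates, drop = FALSE])
  for (cv in spec$covariates) {
    f <- droplevels(factor(df[[cv]]))
    if (spec$reference[[cv]] %in% levels(f)) {
      f <- stats::relevel(f, ref = spec$reference[[cv]])
    }
    df[[cv]] <- f
  }
  mm <- model.matrix(~ ., data = df)
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("collinear design: aliased column(s) ", paste(aliased, collapse = ", "))
  }
  mm
}

#' GLM residualization of an outcome on the covariates
#'
#' Regresses the outcome on the dummy-coded covariates with a generalized
#' linear model and returns the deviance residuals, aligned to participant
#' order. Under the Gaussian identity-link family (the default for score
#' totals) the deviance residual equals observed minus fitted exactly.
#'
#' @param outcome Numeric vector.
#' @param records Cohort tibble holding the covariate columns.
#' @param spec A [covariate_spec()].
#' @param family A [stats::family] object; default `gaussian()`.
#' @return Numeric residual vector with attributes `family` and
#'   `design_columns`.
#' @export
residualize <- function(outcome, records, spec = covariate_spec(),
                        family = gaussian()) {
  stopifnot(length(outcome) == nrow(records))
  if (anyNA(outcome)) stop("residualize: outcome contains missing values")
  mm <- design_matrix(records, spec)
  fit <- glm.fit(mm, outcome, family = family)
  r <- residuals.glm_like(fit, outcome, family)
  attr(r, "family") <- family$family
  attr(r, "design_columns") <- colnames(mm)
  r
}

#' @importFrom stats glm.fit
residuals.glm_like <- function(fit, y, family) {
  mu <- fit$fitted.values
  if (family$family == "gaussian" && family$link == "identity") {
    return(as.numeric(y - mu))
  }
  wt <- rep(1, length(y))
  d <- family$dev.resids(y, mu, wt)
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' Spearman correlation between two residual vectors
#'
#' Rank correlation with average ranks for ties; two-sided p-value from the
#' t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of
#' freedom (the naive n is used; no correction for the residualization).
#'
#' @param x,y Equal-length numeric vectors, n >= 10.
#' @return Named vector `c(rho = , p = )`.
#' @export
spearman_partial <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10L) stop("spearman_partial needs n >= 10")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  c(rho = rho, p = p)
}

#' Pairwise Spearman partial-correlation matrix
#'
#' All pairwise Spearman correlations among a set of residualized variables,
#' with two-sided p-values and optional percentile bootstrap confidence
#' intervals from participant (row) resampling.
#'
#' @param residuals Data frame / matrix of residual vectors (columns are the
#'   analysis variables, rows participants).
#' @param n_boot Number of bootstrap replicates; 0 skips CIs.
#' @param seed Integer seed for reproducible resampling.
#' @param conf Confidence level (default 0.95).
#' @return A `pcor_matrix` with elements `nodes`, `rho`, `p`, `ci_low`,
#'   `ci_high`, `n`, `n_boot`, `seed`.
#' @export
pairwise_matrix <- function(residuals, n_boot = 0L, seed = NULL, conf = 0.95) {
  m <- as.matrix(residuals)
  storage.mode(m) <- "double"
  if (ncol(m) < 2L) stop("pairwise_matrix needs at least 2 variables")
  nodes <- colnames(m)
  if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(m)))
  k <- ncol(m); n <- nrow(m)
  if (any(apply(m, 2, sd) == 0)) stop("constant variable: correlation undefined")

  spearman_all <- function(mat) cor(apply(mat, 2, rank))
  rho <- spearman_all(m)
  tval <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df = n - 2)
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- list(nodes, nodes)

  ci_low <- ci_high <- NULL
  if (n_boot > 0L) {
    if (!is.null(seed)) set.seed(seed)
    lower <- lower.tri(rho)
    draws <- matrix(NA_real_, n_boot, sum(lower))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      draws[b, ] <- spearman_all(m[idx, , drop = FALSE])[lower]
    }
    a <- (1 - conf) / 2
    qs <- apply(draws, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    ci_low <- ci_high <- matrix(NA_real_, k, k, dimnames = list(nodes, nodes))
    ci_low[lower] <- qs[1, ]; ci_high[lower] <- qs[2, ]
    ci_low[upper.tri(ci_low)] <- t(ci_low)[upper.tri(ci_low)]
    ci_high[upper.tri(ci_high)] <- t(ci_high)[upper.tri(ci_high)]
    diag(ci_low) <- diag(ci_high) <- 1
  }
  structure(
    list(nodes = nodes, rho = rho, p = p, ci_low = ci_low, ci_high = ci_high,
         n = n, n_boot = as.integer(n_boot), seed = seed),
    class = "pcor_matrix"
  )
}

#' @export
print.pcor_matrix <- function(x, ...) {
  cat(sprintf("Spearman partial-correlation matrix: %d variables, n = %d%s\n",
              length(x$nodes), x$n,
              if (x$n_boot > 0) sprintf(", %d bootstrap reps", x$n_boot) else ""))
  print(round(x$rho, 3))
  invisible(x)
}

#' Long-format pair table of a correlation matrix
#'
#' @param x A `pcor_matrix`.
#' @param ... Unused.
#' @return Tibble with var1, var2, rho, p and (when bootstrapped) ci_low,
#'   ci_high — one row per unordered pair.
#' @export
pcor_pairs <- function(x, ...) {
  stopifnot(inherits(x, "pcor_matrix"))
  idx <- which(lower.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(
    var1 = x$nodes[idx[, 2]], var2 = x$nodes[idx[, 1]],
    rho = x$rho[idx], p = x$p[idx]
  )
  if (!is.null(x$ci_low)) {
    out$ci_low <- x$ci_low[idx]
    out$ci_high <- x$ci_high[idx]
  }
  out
}

#' Residualize the 17 network variables
#'
#' Convenience wrapper: residualizes each PSQI component, each PHQ-9 item and
#' the NSBQ total on the covariate spec, returning a participant x 17 residual
#' data frame in canonical node order.
#'
#' @param records Post-QC cohort tibble (complete items).
#' @param scored Imputed scored tibble aligned with `records`.
#' @param spec A [covariate_spec()].
#' @param family GLM family for the residualization.
#' @return Data frame of residuals, columns [network_nodes()].
#' @export
residualize_network_variables <- function(records, scored,
                                          spec = covariate_spec(),
                                          family = gaussian()) {
  vars <- c(as.list(records[, c(psqi_cols(), phq9_cols())]),
            list(NSBQ_total = scored$nsbq_total))
  res <- lapply(vars, function(v) {
    as.numeric(residualize(as.numeric(v), records, spec, family))
  })
  as.data.frame(res, col.names = network_nodes())
}
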