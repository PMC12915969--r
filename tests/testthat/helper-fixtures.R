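# Small programmatic fixtures shared across test files.

# a tiny hand-written cohort with full schema; items cycle through legal values
make_cohort_df <- function(n = 3, seed = 99) {
  set.seed(seed)
  levs <- covariate_levels()
  df <- tibble::tibble(participant_id = sprintf("T%03d", seq_len(n)))
  for (cv in covariate_cols()) {
    df[[cv]] <- factor(sample(levs[[cv]], n, replace = TRUE), levels = levs[[cv]])
  }
  for (col in psqi_cols()) df[[col]] <- sample(0:3, n, replace = TRUE)
  for (col in phq9_cols()) df[[col]] <- sample(0:3, n, replace = TRUE)
  df[[phq9_reverse_col()]] <- 3L - df[[phq9_cols()[1]]]
  for (col in nsbq_cols()) df[[col]] <- sample(1:5, n, replace = TRUE)
  df$qc_flag <- "none"
  df
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

# independent Cronbach alpha via the covariance-matrix identity:
# alpha = k/(k-1) * (1 - tr(S) / sum(S))
alpha_oracle <- function(m) {
  S <- stats::cov(as.matrix(m))
  k <- ncol(S)
  k / (k - 1) * (1 - sum(diag(S)) / sum(S))
}

# random small adjacency matrix (symmetric 0/1, zero diagonal)
random_adjacency <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  a <- a + t(a)
  dimnames(a) <- list(paste0("n", 1:n), paste0("n", 1:n))
  a
}

# wrap an adjacency matrix as a symptom_network by assigning weight 0.5 to
# every present edge (above the default threshold)
net_from_adjacency <- function(adj, tau = 0.20) {
  w <- adj * 0.5
  diag(w) <- 1
  build_network(w, tau = tau)
}
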