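# Shared fixtures: small graphs and cohorts built in code.

# Two disconnected unit-weight triangles: the canonical graph with a unique
# modularity optimum (the two triangles, Q = 0.5 at gamma = 1).
two_triangles <- function() {
  A <- matrix(0, 6, 6)
  A[1, 2] <- A[2, 3] <- A[1, 3] <- 1
  A[4, 5] <- A[5, 6] <- A[4, 6] <- 1
  A <- A + t(A)
  dimnames(A) <- list(letters[1:6], letters[1:6])
  A
}

# Random symmetric nonnegative weighted adjacency with zero diagonal.
random_weighted_graph <- function(n, seed, density = 0.6) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  w <- stats::runif(sum(up))
  w[stats::runif(sum(up)) > density] <- 0
  A[up] <- w
  A <- A + t(A)
  if (sum(A) == 0) A[1, 2] <- A[2, 1] <- 1  # guarantee m > 0
  A
}

# A small but valid cohort: default structure, few eyes.
small_cohort <- function(seed = 1, n_hc = 8L, n_dwor = 6L) {
  cfg <- default_generator_config()
  cfg$n_eyes <- c(HC = n_hc, DWOR = n_dwor)
  generate_cohort(cfg, seed = seed)$cohort
}

# A fully deterministic 3-eye data frame in the cohort layout (HC only
# would fail the 4-eye rule downstream, so both groups are present when
# n >= 4; used for format-level tests).
tiny_cohort_df <- function(n = 3L) {
  labels <- scn_nodes()$label
  thick <- matrix(seq_len(n * 63) + 10, n, 63, dimnames = list(NULL, labels))
  df <- data.frame(subject_id = paste0("S", seq_len(n)),
                   eye = rep(c("OD", "OS"), length.out = n),
                   group = rep(c("HC", "DWOR"), length.out = n),
                   age = 30 + seq_len(n),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(thick))
}
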