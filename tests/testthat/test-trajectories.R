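test_that("age regression matches the normal equations", {
  cohort <- small_cohort(seed = 41, n_hc = 30L, n_dwor = 10L)
  # noiseless line: thickness = 3 + 0.2 * age
  exact <- cohort
  exact$RNFL_C <- 3 + 0.2 * exact$age
  fit <- fit_age_regression(as_cohort_table(exact), "HC", "RNFL", "C")
  expect_equal(fit$slope, 0.2, tolerance = 1e-12)
  expect_equal(fit$intercept, 3, tolerance = 1e-10)
  expect_equal(fit$r, 1)
  expect_equal(fit$p, 0)

  # closed-form oracle on noisy data: b = cov(x,y)/var(x)
  fit2 <- fit_age_regression(cohort, "HC", "INL", "Avg_I")
  hc <- cohort[cohort$group == "HC", ]
  y <- ring_average(hc, "INL", "inner")
  x <- hc$age
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  expect_equal(fit2$slope, b, tolerance = 1e-10)
  expect_equal(fit2$intercept, a, tolerance = 1e-10)
  expect_equal(fit2$r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(fit2$p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  expect_equal(sign(fit2$slope), sign(fit2$r))

  # degenerate inputs
  flat <- cohort
  flat$age[flat$group == "HC"] <- 50
  expect_error(fit_age_regression(as_cohort_table(flat), "HC", "RNFL", "C"),
               "age variance")
  const <- cohort
  const$RNFL_C[const$group == "HC"] <- 12
  expect_warning(
    fc <- fit_age_regression(as_cohort_table(const), "HC", "RNFL", "C"),
    "zero thickness variance")
  expect_equal(fc$r, 0)
  expect_equal(fc$p, 1)
})

test_that("slope estimates cover the planted truth", {
  cfg <- default_generator_config()
  hits <- 0L
  n_rep <- 25L
  for (s in seq_len(n_rep)) {
    cohort <- generate_cohort(cfg, seed = 7000 + s)$cohort
    fit <- fit_age_regression(cohort, "HC", "INL", "C")
    hc <- cohort[cohort$group == "HC", ]
    se <- sqrt(sum(stats::lm(hc$INL_C ~ hc$age)$residuals^2) /
                 (fit$n - 2) / sum((hc$age - mean(hc$age))^2))
    truth <- cfg$age_slopes$HC[["INL_C"]]
    ci <- fit$slope + c(-1, 1) * stats::qt(0.975, fit$n - 2) * se
    if (truth >= ci[1] && truth <= ci[2]) hits <- hits + 1L
  }
  # nominal 95% coverage; binomial 2.5th percentile at n=25 is 21
  expect_gte(hits, 21L)
})

test_that("Fisher r-to-z matches its closed form and symmetries", {
  expect_equal(fisher_r_to_z(0.4, 50, 0.4, 80)$z, 0)
  expect_equal(fisher_r_to_z(0.4, 50, 0.4, 80)$p, 1)

  hand <- atanh(0.5) / sqrt(2 / 97)
  fz <- fisher_r_to_z(0.5, 100, 0.0, 100)
  expect_equal(fz$z, hand, tolerance = 1e-12)
  expect_equal(hand, 3.8254, tolerance = 1e-4)
  expect_equal(fz$p, 2 * stats::pnorm(-hand), tolerance = 1e-12)

  # antisymmetry and an independent reimplementation on random inputs
  set.seed(3)
  for (i in 1:200) {
    r1 <- stats::runif(1, -0.95, 0.95); r2 <- stats::runif(1, -0.95, 0.95)
    n1 <- sample(5:500, 1); n2 <- sample(5:500, 1)
    a <- fisher_r_to_z(r1, n1, r2, n2)
    b <- fisher_r_to_z(r2, n2, r1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
    z_ind <- (0.5 * log((1 + r1) / (1 - r1)) -
                0.5 * log((1 + r2) / (1 - r2))) /
      sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    expect_equal(a$z, z_ind, tolerance = 1e-12)
  }

  expect_error(fisher_r_to_z(1, 10, 0.5, 10), "infinite")
  expect_error(fisher_r_to_z(0.5, 3, 0.5, 10), "n > 3")
})

test_that("BH adjustment reproduces the step-up and its rejection oracle", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")

  # brute-force oracle: q_i <= alpha iff i rejected by step-up BH at alpha
  bh_reject <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= alpha * seq_len(m) / m)
    rej <- logical(m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(14)
  for (rep in 1:30) {
    p <- stats::runif(sample(1:12, 1))
    q <- fdr_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
    for (alpha in c(0.01, 0.05, 0.1, 0.2, 0.5, 0.8)) {
      expect_identical(q <= alpha, bh_reject(p, alpha))
    }
  }
})

test_that("group-mean comparisons recover planted offsets", {
  cohort <- small_cohort(seed = 2, n_hc = 10L, n_dwor = 10L)
  same <- cohort
  same[same$group == "DWOR", scn_nodes()$label] <-
    same[same$group == "HC", scn_nodes()$label]
  same$age[same$group == "DWOR"] <- same$age[same$group == "HC"]
  cmp0 <- compare_group_means(as_cohort_table(same), "RNFL", "C")
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p, 1)

  # direction and detection of the planted +0.69 um RNFL_C offset; power at
  # this effect size is moderate, so require direction nearly always and
  # detection in a clear majority-of-chance excess
  direction <- 0L; detected <- 0L
  for (s in 1:20) {
    cohort <- generate_cohort(seed = 8000 + s)$cohort
    cmp <- compare_group_means(cohort, "RNFL", "C")
    if (cmp$mean_dwor > cmp$mean_hc) direction <- direction + 1L
    if (cmp$p < 0.05 && cmp$mean_dwor > cmp$mean_hc) detected <- detected + 1L
  }
  expect_gte(direction, 17L)
  expect_gte(detected, 6L)

  # hand data {1,2,3} vs {4,5,6}: textbook Welch t
  hand <- compare_group_means(as_cohort_table(rbind(
    within(tiny_cohort_df(6), {
      group <- rep(c("HC", "DWOR"), each = 3)
      RNFL_C <- c(1, 2, 3, 4, 5, 6)
    }))), "RNFL", "C")
  expect_equal(hand$t, (2 - 5) / sqrt(1 / 3 + 1 / 3), tolerance = 1e-12)
})

test_that("the trajectory report covers the family with FDR over one family", {
  cohort <- small_cohort(seed = 6, n_hc = 20L, n_dwor = 16L)
  rep_tbl <- trajectory_report(cohort)
  fam <- default_trajectory_family()
  expect_equal(nrow(rep_tbl), length(fam$layers) * length(fam$regions))
  expect_true(all(rep_tbl$q >= rep_tbl$p_diff - 1e-15))
  expect_true(all(rep_tbl$q <= 1))
  expect_equal(rep_tbl$q, fdr_adjust(rep_tbl$p_diff))

  # a planted strong HC-only slope attains the family's smallest q
  cfg <- default_generator_config()
  cfg$age_slopes <- lapply(cfg$age_slopes, function(x) x * 0)
  cfg$age_slopes$HC["RNFL_IS"] <- 0.15
  won <- 0L
  for (s in 1:5) {
    cohort <- generate_cohort(cfg, seed = 9000 + s)$cohort
    tr <- trajectory_report(cohort,
                            family = list(layers = primary_layers(),
                                          regions = etdrs_sectors()))
    best <- tr[which.min(tr$q), ]
    if (best$layer == "RNFL" && best$region == "IS") won <- won + 1L
  }
  expect_gte(won, 4L)

  # the optional direct slope-difference test is reported when asked
  tr2 <- trajectory_report(cohort,
                           family = list(layers = "RNFL", regions = "C"),
                           slope_test = TRUE)
  expect_true(all(c("z_slope", "p_slope") %in% names(tr2)))
  expect_equal(nrow(tr2), 1L)
})
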