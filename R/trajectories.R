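# Age-trajectory regressions, Fisher r-to-z group comparison, FDR control,
# and group-mean thickness t-tests.

#' Least-squares age regression of one region's thickness
#'
#' Ordinary least squares of per-eye thickness on age (intercept included)
#' within one group, for one layer and region (a sector, `Avg_I` or
#' `Avg_O`). `r` is the Pearson correlation between age and thickness; its
#' two-sided p-value comes from the t distribution with n - 2 degrees of
#' freedom.
#'
#' @param cohort a `cohort_table`.
#' @param group `"HC"` or `"DWOR"`.
#' @param layer primary or composite layer code.
#' @param region sector code, `"Avg_I"` or `"Avg_O"`.
#' @param scheme composite-layer scheme.
#' @return A one-row data.frame: `group`, `layer`, `region`, `slope`
#'   (um/year), `intercept` (um), `r`, `p`, `n`.
#' @export
fit_age_regression <- function(cohort, group, layer, region,
                               scheme = default_composite_scheme()) {
  cohort <- as_cohort_table(cohort)
  group <- match.arg(group, cohort_groups())
  sub <- cohort[cohort$group == group, , drop = FALSE]
  n <- nrow(sub)
  if (n < 4L) stop("group ", group, " has ", n, " eyes; need at least 4")
  y <- region_values(sub, layer, region, scheme)
  x <- sub$age
  if (stats::var(x) == 0) stop("zero age variance in group ", group)
  if (stats::var(y) == 0) {
    warning("zero thickness variance for ", layer, "_", region,
            " in group ", group, "; r set to 0")
    fit <- stats::lm.fit(cbind(1, x), y)
    return(data.frame(group = group, layer = layer, region = region,
                      slope = 0, intercept = mean(y), r = 0, p = 1, n = n,
                      stringsAsFactors = FALSE))
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  data.frame(group = group, layer = layer, region = region,
             slope = unname(co[2L]), intercept = unname(co[1L]),
             r = r, p = p, n = n, stringsAsFactors = FALSE)
}

#' Fisher r-to-z comparison of two correlations
#'
#' z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3)), with a
#' two-sided p from the standard normal.
#'
#' @param r1,r2 Pearson correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes, each > 3.
#' @return List with `z` and `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  if (any(c(n1, n2) <= 3)) stop("need n > 3 in both samples")
  if (any(abs(c(r1, r2)) >= 1)) {
    stop("|r| = 1: Fisher transform infinite; comparison undefined")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, q_(i) = min_(j >= i) p_(j) m / j capped at 1,
#' returned in input order (delegates to [stats::p.adjust()] with
#' `method = "BH"` after domain checks).
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare group mean thickness in one region
#'
#' Two-sample t-test (Welch default, pooled optional) on per-eye thickness,
#' reporting mean and SD per group.
#'
#' @inheritParams fit_age_regression
#' @param var_equal use pooled variances.
#' @return A one-row data.frame: `layer`, `region`, per-group mean/sd/n,
#'   `t`, `p`.
#' @export
compare_group_means <- function(cohort, layer, region,
                                scheme = default_composite_scheme(),
                                var_equal = FALSE) {
  cohort <- as_cohort_table(cohort)
  y_hc <- region_values(cohort[cohort$group == "HC", , drop = FALSE],
                        layer, region, scheme)
  y_dw <- region_values(cohort[cohort$group == "DWOR", , drop = FALSE],
                        layer, region, scheme)
  if (length(y_hc) < 2L || length(y_dw) < 2L) {
    stop("need at least 2 eyes per group")
  }
  if (stats::var(y_hc) == 0 && stats::var(y_dw) == 0 &&
      mean(y_hc) == mean(y_dw)) {
    t_stat <- 0; p <- 1
  } else {
    tt <- stats::t.test(y_hc, y_dw, var.equal = var_equal)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  }
  data.frame(layer = layer, region = region,
             mean_hc = mean(y_hc), sd_hc = stats::sd(y_hc),
             n_hc = length(y_hc),
             mean_dwor = mean(y_dw), sd_dwor = stats::sd(y_dw),
             n_dwor = length(y_dw),
             t = t_stat, p = p, stringsAsFactors = FALSE)
}

#' Default layer and region families for trajectory reports
#'
#' All seven primary layers plus the three composites, crossed with the
#' nine sectors and the two ring averages.
#'
#' @return List with `layers` and `regions` character vectors.
#' @export
default_trajectory_family <- function() {
  list(layers = c(primary_layers(), composite_layers()),
       regions = c(etdrs_sectors(), "Avg_I", "Avg_O"))
}

#' Full age-trajectory report
#'
#' For every layer x region in the family: the per-group age regression,
#' the between-group Fisher r-to-z comparison of the age correlations
#' (the correlation-based reading of a slope comparison), and the BH
#' q-value over the whole family (one family by default). A normal-theory
#' test on the slope difference itself is available via
#' `slope_test = TRUE` as a sensitivity analysis (columns `z_slope`,
#' `p_slope`).
#'
#' @param cohort a `cohort_table`.
#' @param family list with `layers` and `regions`
#'   (default [default_trajectory_family()]).
#' @param scheme composite-layer scheme.
#' @param slope_test also compute the direct slope-difference z-test.
#' @return A data.frame with one row per layer x region: per-group slope,
#'   r, p and n, plus `z`, `p_diff`, `q`.
#' @export
trajectory_report <- function(cohort, family = default_trajectory_family(),
                              scheme = default_composite_scheme(),
                              slope_test = FALSE) {
  cohort <- as_cohort_table(cohort)
  grid <- expand.grid(region = family$regions, layer = family$layers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hc <- cohort[cohort$group == "HC", , drop = FALSE]
  dw <- cohort[cohort$group == "DWOR", , drop = FALSE]

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    layer <- grid$layer[i]; region <- grid$region[i]
    f_hc <- fit_age_regression(cohort, "HC", layer, region, scheme)
    f_dw <- fit_age_regression(cohort, "DWOR", layer, region, scheme)
    fz <- fisher_r_to_z(f_hc$r, f_hc$n, f_dw$r, f_dw$n)
    out <- data.frame(layer = layer, region = region,
                      slope_hc = f_hc$slope, r_hc = f_hc$r, p_hc = f_hc$p,
                      n_hc = f_hc$n,
                      slope_dwor = f_dw$slope, r_dwor = f_dw$r,
                      p_dwor = f_dw$p, n_dwor = f_dw$n,
                      z = fz$z, p_diff = fz$p, stringsAsFactors = FALSE)
    if (slope_test) {
      se2 <- function(fit, sub) {
        y <- region_values(sub, layer, region, scheme)
        x <- sub$age
        res <- y - fit$intercept - fit$slope * x
        sum(res^2) / (fit$n - 2) / sum((x - mean(x))^2)
      }
      zs <- (f_hc$slope - f_dw$slope) /
        sqrt(se2(f_hc, hc) + se2(f_dw, dw))
      out$z_slope <- zs
      out$p_slope <- 2 * stats::pnorm(-abs(zs))
    }
    out
  })
  report <- do.call(rbind, rows)
  report$q <- fdr_adjust(report$p_diff)
  report
}
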