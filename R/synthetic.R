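# Synthetic cohort generator: planted block covariance, group offsets,
# linear age effects, Gaussian noise.

#' Default generator configuration
#'
#' Returns the documented default configuration for [generate_cohort()]:
#' 156 healthy-control-like (HC) and 78 diabetic-without-retinopathy-like
#' (DWOR) eyes; ages drawn from N(46.06, 13.06^2) for HC and N(50.8, 8.6^2)
#' for DWOR, truncated at 18 years; RNFL central-subfield baseline
#' 10.16 um with a +0.69 um DWOR offset, a +1.0 um DWOR offset on the INL
#' inner ring, and a thinner outer retina (ONL offsets) in DWOR; small linear
#' age slopes concentrated in the central subfield of the HC group; and a
#' planted block-covariance structure with 5 blocks (within-block
#' correlation 0.5) for HC and 4 tighter blocks (0.7) for DWOR over a 0.1
#' background correlation.
#'
#' Baselines outside the handful of regions with published group means are
#' plausible normative values chosen once and documented; they are not
#' claims about any particular device's normative data.
#'
#' @return A list with components `n_eyes`, `age_model`, `baseline`,
#'   `group_offsets`, `age_slopes`, `blocks`, `rho_within`, `rho_between`,
#'   `noise_sd`, `seed`.
#' @export
default_generator_config <- function() {
  labels <- node_labels()
  nodes <- scn_nodes()

  # Per-layer baseline thickness (um) by ring; ring-constant for simplicity.
  base_by_layer <- list(
    RNFL = c(central = 10.16, inner = 21.0, outer = 35.0),
    GCL  = c(central = 14.0,  inner = 48.0, outer = 34.0),
    IPL  = c(central = 19.0,  inner = 40.0, outer = 30.0),
    INL  = c(central = 18.0,  inner = 39.9, outer = 32.0),
    OPL  = c(central = 24.0,  inner = 32.0, outer = 26.0),
    ONL  = c(central = 51.0,  inner = 68.0, outer = 56.0),
    RPE  = c(central = 15.0,  inner = 14.5, outer = 13.5)
  )
  baseline <- stats::setNames(
    mapply(function(l, s) base_by_layer[[l]][[sector_ring(s)]],
           nodes$layer, nodes$sector),
    labels)

  zero <- stats::setNames(numeric(length(labels)), labels)

  # DWOR mean offsets (um): thicker inner retina, thinner outer retina.
  off_dwor <- zero
  off_dwor["RNFL_C"] <- 0.69
  off_dwor[paste0("INL_", ring_sectors("inner"))] <- 1.0
  off_dwor["ONL_C"] <- -1.2
  off_dwor[paste0("ONL_", ring_sectors("inner"))] <- -0.9

  # Age slopes (um/year). HC: central-subfield thickening of most layers,
  # GCL/IPL ring thinning, RPE inner-ring thickening. DWOR: INL_C thickening
  # only, slight RNFL_C thinning, GCL/IPL outer thinning in three sectors.
  sl_hc <- zero
  sl_hc[c("RNFL_C", "GCL_C", "IPL_C", "INL_C", "OPL_C", "ONL_C")] <-
    c(0.030, 0.020, 0.035, 0.070, 0.060, 0.050)
  ring8 <- c(ring_sectors("inner"), ring_sectors("outer"))
  sl_hc[paste0("GCL_", ring8)] <- -0.040
  sl_hc[paste0("IPL_", ring8)] <- -0.040
  sl_hc[paste0("RPE_", ring_sectors("inner"))] <- 0.030

  sl_dwor <- zero
  sl_dwor["RNFL_C"] <- -0.006
  sl_dwor["INL_C"] <- 0.060
  sl_dwor[paste0("GCL_", c("OI", "OT", "ON"))] <- -0.040
  sl_dwor[paste0("IPL_", c("OI", "OT", "ON"))] <- -0.040

  # Planted community blocks: contiguous, near-equal-size groups of nodes in
  # layer-major order, so each block spans anatomically adjacent nodes while
  # keeping block sizes balanced for recoverability.
  blocks <- list(
    HC   = rep(seq_len(5L), times = c(13L, 13L, 13L, 12L, 12L)),
    DWOR = rep(seq_len(4L), times = c(16L, 16L, 16L, 15L))
  )
  blocks <- lapply(blocks, stats::setNames, labels)

  list(
    n_eyes = c(HC = 156L, DWOR = 78L),
    age_model = list(HC = c(mean = 46.06, sd = 13.06),
                     DWOR = c(mean = 50.8, sd = 8.6)),
    age_min = 18,
    baseline = baseline,
    group_offsets = list(HC = zero, DWOR = off_dwor),
    age_slopes = list(HC = sl_hc, DWOR = sl_dwor),
    blocks = blocks,
    rho_within = c(HC = 0.5, DWOR = 0.7),
    rho_between = c(HC = 0.25, DWOR = 0.25),
    noise_sd = 2.4,
    seed = 1L
  )
}

# Internal: validate a generator config, filling nothing in.
validate_generator_config <- function(config) {
  labels <- node_labels()
  for (g in cohort_groups()) {
    if (is.na(config$n_eyes[[g]]) || config$n_eyes[[g]] < 4L) {
      stop("generator config error: need at least 4 eyes per group")
    }
    b <- config$blocks[[g]]
    if (length(b) != length(labels) ||
        !setequal(names(b), labels) || anyNA(b)) {
      stop("generator config error: block partition for group ", g,
           " must assign every one of the 63 nodes exactly once")
    }
    rw <- config$rho_within[[g]]
    rb <- config$rho_between[[g]]
    if (rb < 0 || rb > rw || rw >= 1) {
      stop("generator config error: need 0 <= rho_between <= rho_within < 1")
    }
  }
  if (config$noise_sd < 0) stop("generator config error: noise_sd < 0")
  invisible(config)
}

# Internal: truncated-normal ages via rejection sampling.
draw_ages <- function(n, mean, sd, age_min) {
  out <- numeric(0L)
  while (length(out) < n) {
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= age_min])
  }
  out[seq_len(n)]
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a cohort under a latent-factor model. For eye e and node v in
#' group g:
#' \deqn{t_{ev} = \mu_v + \delta_{gv} + \beta_{gv}(a_e - \bar a_g)
#'   + \sqrt{\rho_b}\,\sigma G_e + \sqrt{\rho_w-\rho_b}\,\sigma F_{e,b(v)}
#'   + \sqrt{1-\rho_w}\,\sigma \varepsilon_{ev}}
#' where \eqn{G_e} is a global factor, \eqn{F_{e,b}} a per-block factor and
#' \eqn{\varepsilon} unit Gaussian noise, all iid standard normal, and
#' \eqn{\sigma} = `noise_sd` is the total age-residual SD. This makes the
#' age-residualised correlation \eqn{\rho_w} within a planted block and
#' \eqn{\rho_b} between blocks, and guarantees a positive semi-definite
#' covariance by construction. Ages are truncated at `age_min` (18 years)
#' by rejection. Thickness is floored at 0.5 um to respect positivity
#' (relevant only in extreme tails).
#'
#' @param config a generator configuration, see [default_generator_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return A list with `cohort` (a `cohort_table`) and `truth` (planted
#'   blocks, slopes, offsets and the seed used).
#' @export
generate_cohort <- function(config = default_generator_config(),
                            seed = NULL) {
  validate_generator_config(config)
  if (!is.null(seed)) config$seed <- seed
  labels <- node_labels()
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  rows <- list()
  eye_i <- 0L
  for (g in cohort_groups()) {
    n <- config$n_eyes[[g]]
    am <- config$age_model[[g]]
    ages <- draw_ages(n, am[["mean"]], am[["sd"]], config$age_min)
    blocks <- config$blocks[[g]][labels]
    rw <- config$rho_within[[g]]
    rb <- config$rho_between[[g]]
    sdv <- config$noise_sd
    k <- max(blocks)

    G <- stats::rnorm(n)
    Fb <- matrix(stats::rnorm(n * k), n, k)
    eps <- matrix(stats::rnorm(n * length(labels)), n, length(labels))

    mu <- config$baseline[labels] + config$group_offsets[[g]][labels]
    beta <- config$age_slopes[[g]][labels]
    centered_age <- ages - am[["mean"]]

    thick <- matrix(mu, n, length(labels), byrow = TRUE) +
      outer(centered_age, beta) +
      sqrt(rb) * sdv * G +
      sqrt(rw - rb) * sdv * Fb[, blocks, drop = FALSE] +
      sqrt(1 - rw) * sdv * eps
    thick <- pmax(thick, 0.5)
    colnames(thick) <- labels

    # Two eyes per subject where the count is even, matching 78+78 / 39+39.
    subj <- paste0(g, "-S", sprintf("%03d", ceiling(seq_len(n) / 2)))
    eye <- rep(c("OD", "OS"), length.out = n)
    rows[[g]] <- data.frame(subject_id = subj, eye = eye, group = g,
                            age = ages, stringsAsFactors = FALSE)
    rows[[g]] <- cbind(rows[[g]], as.data.frame(thick))
    eye_i <- eye_i + n
  }

  cohort <- as_cohort_table(do.call(rbind, c(rows, make.row.names = FALSE)))
  truth <- list(blocks = config$blocks,
                age_slopes = config$age_slopes,
                group_offsets = config$group_offsets,
                rho_within = config$rho_within,
                rho_between = config$rho_between,
                seed = config$seed)
  list(cohort = cohort, truth = truth)
}

# Internal: restore (or clear) the global RNG state.
restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
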