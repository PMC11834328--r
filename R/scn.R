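# Structural covariance network: age-adjusted absolute Pearson correlation.

#' Residualize a vector on age
#'
#' Least-squares residuals of `values` regressed on `ages` with an
#' intercept. With a single shared covariate this is the residualization
#' underlying first-order partial correlation, so correlating two
#' residualized vectors equals their partial correlation given age. If all
#' ages are identical the slope is undefined; the values are mean-centered
#' instead, with a warning.
#'
#' @param values numeric vector.
#' @param ages numeric vector of the same length (>= 3).
#' @return Numeric vector of residuals (sum approximately 0).
#' @export
residualize_on_age <- function(values, ages) {
  if (length(values) != length(ages)) {
    stop("values and ages must have equal length")
  }
  if (length(values) < 3L) stop("need at least 3 observations")
  if (stats::var(ages) == 0) {
    warning("all ages identical; falling back to mean-centering")
    return(values - mean(values))
  }
  stats::lm.fit(cbind(1, ages), values)$residuals
}

#' Build a group's structural covariance network
#'
#' For the requested group, each of the 63 (layer, sector) thickness columns
#' is residualized on age across the group's eyes; the edge weight between
#' nodes i and j is the absolute Pearson correlation of their residuals.
#' Negative correlations are kept in absolute value (not zeroed); their
#' share among off-diagonal pairs is recorded as `negative_fraction` before
#' taking absolute values, and a warning is logged when that share reaches
#' 5%. The diagonal is zero and no thresholding or sparsification is
#' applied.
#'
#' @param cohort a `cohort_table`.
#' @param group `"HC"` or `"DWOR"`.
#' @return An object of class `scn_matrix`: list with `weights` (63x63,
#'   labelled), `nodes` (node table), `group`, `n_samples`,
#'   `negative_fraction`, `full_grid`.
#' @export
build_scn <- function(cohort, group) {
  cohort <- as_cohort_table(cohort)
  group <- match.arg(group, cohort_groups())
  sub <- cohort[cohort$group == group, , drop = FALSE]
  n <- nrow(sub)
  if (n < 4L) stop("group ", group, " has ", n, " eyes; need at least 4")

  M <- as.matrix(sub[, node_labels(), drop = FALSE])
  X <- cbind(1, sub$age)
  if (stats::var(sub$age) == 0) {
    warning("all ages identical in group ", group, "; mean-centering only")
    R <- sweep(M, 2L, colMeans(M))
  } else {
    R <- stats::lm.fit(X, M)$residuals
  }

  sds <- apply(R, 2L, stats::sd)
  degenerate <- sds < 1e-10
  if (any(degenerate)) {
    stop("zero-variance node(s) after age adjustment: ",
         paste(node_labels()[degenerate], collapse = ", "),
         "; correlation undefined")
  }
  C <- stats::cor(R)
  off <- upper.tri(C)
  negative_fraction <- mean(C[off] < 0)
  if (negative_fraction >= 0.05) {
    warning(sprintf(
      "negative correlations in %.1f%% of connections (>= 5%%) in group %s",
      100 * negative_fraction, group))
  }
  W <- abs(C)
  diag(W) <- 0
  dimnames(W) <- list(node_labels(), node_labels())

  structure(list(weights = W, nodes = scn_nodes(), group = group,
                 n_samples = n, negative_fraction = negative_fraction,
                 full_grid = TRUE),
            class = "scn_matrix")
}

# Internal: sanity checks shared by constructors and load_scn.
validate_scn <- function(scn) {
  W <- scn$weights
  n <- nrow(W)
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE))) {
    stop("scn format error: weight matrix is not symmetric")
  }
  if (any(!is.finite(W)) || any(W < 0) || any(W > 1)) {
    stop("scn format error: weights must be finite and in [0, 1]")
  }
  if (any(diag(W) != 0)) stop("scn format error: nonzero diagonal")
  if (length(unique(rownames(W))) != n) {
    stop("scn format error: node labels must be unique and match dimensions")
  }
  if (isTRUE(scn$full_grid) && n != 63L) {
    stop("scn format error: full-grid network must have 63 nodes, found ", n)
  }
  invisible(scn)
}

#' Save a structural covariance network
#'
#' Writes the weight matrix as TSV (node labels as header row and first
#' column) plus a JSON sidecar `<path>.json` carrying `group`, `n_samples`,
#' `negative_fraction` and `full_grid`. The round trip through
#' [load_scn()] is lossless.
#'
#' @param scn an `scn_matrix`.
#' @param path output TSV path.
#' @export
save_scn <- function(scn, path) {
  validate_scn(scn)
  W <- scn$weights
  out <- data.frame(node = rownames(W),
                    formatC(W, format = "g", digits = 17),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("node", colnames(W))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(group = scn$group, n_samples = scn$n_samples,
               negative_fraction = scn$negative_fraction,
               full_grid = isTRUE(scn$full_grid))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a structural covariance network
#'
#' @param path TSV path written by [save_scn()] (sidecar `<path>.json`
#'   optional; without it the network is treated as a generic graph, which
#'   permits reduced node sets for testing).
#' @return An `scn_matrix`.
#' @export
load_scn <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  W <- as.matrix(df[, -1L, drop = FALSE])
  rownames(W) <- labels
  if (!identical(colnames(W), labels)) {
    stop("scn format error: row and column labels differ")
  }
  storage.mode(W) <- "double"
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else {
    list(group = NA_character_, n_samples = NA_integer_,
         negative_fraction = NA_real_, full_grid = FALSE)
  }
  scn <- structure(list(weights = W,
                        nodes = data.frame(label = labels,
                                           stringsAsFactors = FALSE),
                        group = meta$group, n_samples = meta$n_samples,
                        negative_fraction = meta$negative_fraction,
                        full_grid = isTRUE(meta$full_grid)),
                   class = "scn_matrix")
  validate_scn(scn)
  scn
}

#' @export
print.scn_matrix <- function(x, ...) {
  cat(sprintf(
    "Structural covariance network: %d nodes, group %s, n = %s eyes\n",
    nrow(x$weights), x$group, x$n_samples))
  cat(sprintf("  mean weight %.3f, negative fraction before abs %.3f\n",
              mean(x$weights[upper.tri(x$weights)]),
              x$negative_fraction))
  invisible(x)
}
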