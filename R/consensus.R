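# Louvain run ensembles: label alignment, consensus (mode of assignments),
# and the between-group modularity t-test.

#' Align one partition's labels to a reference
#'
#' Community ids are arbitrary per run, so the per-node mode across runs is
#' only well-defined after label alignment. This relabels `other` so that
#' the total node overlap with `reference` is maximal (an optimal
#' assignment on the k x k contingency table; exhaustive over label
#' injections for small k, greedy beyond 8 communities). Ids of `other`
#' left unmatched receive fresh labels above the reference's range. The
#' membership structure of `other` is unchanged; only ids are renamed.
#'
#' @param reference named/unnamed integer vector of community ids.
#' @param other integer vector over the same nodes.
#' @return `other` relabeled.
#' @export
align_partitions <- function(reference, other) {
  if (length(reference) != length(other)) {
    stop("partitions must cover the same node set")
  }
  if (!is.null(names(reference)) && !is.null(names(other)) &&
      !identical(names(reference), names(other))) {
    stop("partitions must cover the same node set (labels differ)")
  }
  tab <- table(other = other, reference = reference)
  ids_o <- as.integer(rownames(tab))
  ids_r <- as.integer(colnames(tab))
  ko <- length(ids_o)
  kr <- length(ids_r)

  assign_best <- function() {
    if (ko <= 8L && kr <= 8L) {
      # exhaustive search over injections other-id -> reference-id
      best_score <- -1L
      best_map <- NULL
      recurse <- function(row, used, map, score) {
        # upper bound prune: remaining rows can add at most their row max
        if (row > ko) {
          if (score > best_score) {
            best_score <<- score
            best_map <<- map
          }
          return(invisible(NULL))
        }
        remaining <- sum(apply(tab[row:ko, , drop = FALSE], 1L, max))
        if (score + remaining <= best_score) return(invisible(NULL))
        for (j in c(which(!used), NA_integer_)) {
          if (is.na(j)) {
            recurse(row + 1L, used, c(map, NA_integer_), score)
          } else {
            used2 <- used; used2[j] <- TRUE
            recurse(row + 1L, used2, c(map, j), score + tab[row, j])
          }
        }
      }
      recurse(1L, logical(kr), integer(0L), 0L)
      best_map
    } else {
      # greedy: repeatedly take the largest remaining contingency cell
      map <- rep(NA_integer_, ko)
      used <- logical(kr)
      work <- tab
      repeat {
        mx <- max(work)
        if (mx < 0) break
        m <- which(work == mx, arr.ind = TRUE)
        r <- m[1L, 1L]; c <- m[1L, 2L]
        map[r] <- c
        used[c] <- TRUE
        work[r, ] <- -1L
        work[, c] <- -1L
        if (all(!is.na(map)) || all(used)) break
      }
      map
    }
  }

  map_idx <- assign_best()
  new_id <- rep(NA_integer_, ko)
  fresh <- max(ids_r) + 1L
  for (r in seq_len(ko)) {
    if (!is.na(map_idx[r])) {
      new_id[r] <- ids_r[map_idx[r]]
    } else {
      new_id[r] <- fresh
      fresh <- fresh + 1L
    }
  }
  out <- new_id[match(other, ids_o)]
  names(out) <- names(other)
  out
}

#' Consensus partition of a run set (mode of assignments)
#'
#' Aligns every partition's labels to the reference partition with
#' [align_partitions()] and assigns each node the most frequent aligned id
#' across the runs. Ties at a node are broken toward the reference's id,
#' and toward the smallest tied id if the reference's is not among the
#' modes. The result is canonicalized (ids 1..k in order of first
#' appearance).
#'
#' @param memberships list of integer membership vectors over the same
#'   node set.
#' @param reference index of the reference run (for [run_ensemble()], the
#'   highest-Q run).
#' @return Integer consensus membership vector.
#' @export
consensus_partition <- function(memberships, reference = 1L) {
  stopifnot(length(memberships) >= 1L)
  n <- length(memberships[[1L]])
  ref <- memberships[[reference]]
  aligned <- vapply(memberships, function(m) {
    unname(align_partitions(ref, m))
  }, integer(n))
  if (n == 1L) aligned <- matrix(aligned, nrow = 1L)
  consensus <- integer(n)
  for (v in seq_len(n)) {
    counts <- table(aligned[v, ])
    top <- as.integer(names(counts)[counts == max(counts)])
    consensus[v] <- if (ref[v] %in% top) ref[v] else min(top)
  }
  canonicalize_partition(consensus)
}

#' Run a Louvain ensemble with consensus
#'
#' Performs `n_runs` independent Louvain runs (per-run seeds drawn from the
#' master `seed`), aligns every run's labels to the highest-Q run, and
#' takes the per-node mode of the aligned assignments as the consensus
#' partition; ties at a node are broken toward the id used by the highest-Q
#' run, and toward the smallest id if that is not among the tied modes. The
#' reported modularity is the arithmetic mean of the run-level Q values.
#'
#' @param model a `modularity_model`.
#' @param n_runs number of runs (default 50).
#' @param seed master seed.
#' @param group optional group tag carried into the result.
#' @return An object of class `scn_ensemble`: list with `runs` (list of
#'   `membership`/`Q`), `Q_values`, `consensus`, `mean_Q`,
#'   `n_communities`, `n_runs`, `seed`, `gamma`, `group`.
#' @export
run_ensemble <- function(model, n_runs = 50L, seed = 1L, group = NA) {
  stopifnot(inherits(model, "modularity_model"), n_runs >= 1L)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)

  runs <- lapply(run_seeds, function(s) louvain_run(model, seed = s))
  qs <- vapply(runs, `[[`, numeric(1L), "Q")
  best <- which.max(qs)
  consensus <- consensus_partition(lapply(runs, `[[`, "membership"),
                                   reference = best)
  names(consensus) <- model$labels

  structure(list(runs = runs, Q_values = qs, consensus = consensus,
                 mean_Q = mean(qs),
                 n_communities = length(unique(consensus)),
                 n_runs = n_runs, seed = seed, gamma = model$gamma,
                 group = group),
            class = "scn_ensemble")
}

#' Compare modularity between two ensembles
#'
#' Two-sample t-test (Welch by default) on the run-level Q values of the
#' two groups' ensembles, two-sided. When both Q lists are constant and
#' equal the comparison degenerates to t = 0, p = 1.
#'
#' @param ensemble_a,ensemble_b `scn_ensemble` objects.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return List with `t_statistic`, `p_value`, `df`, `mean_Q` (named, per
#'   ensemble), `n_runs` (named).
#' @export
compare_modularity <- function(ensemble_a, ensemble_b, var_equal = FALSE) {
  qa <- ensemble_a$Q_values
  qb <- ensemble_b$Q_values
  if (length(qa) < 1L || length(qb) < 1L) stop("empty ensemble")
  if (length(qa) == 1L && length(qb) == 1L) {
    stop("cannot test with a single run per group (no degrees of freedom)")
  }
  ga <- ensemble_a$group
  gb <- ensemble_b$group
  if (is.null(ga) || is.na(ga)) ga <- "a"
  if (is.null(gb) || is.na(gb)) gb <- "b"
  if (stats::var(qa) == 0 && stats::var(qb) == 0) {
    # every run converged to the same Q in both groups: the test degenerates
    if (mean(qa) == mean(qb)) {
      res <- list(t_statistic = 0, p_value = 1, df = NA_real_)
    } else {
      res <- list(t_statistic = sign(mean(qa) - mean(qb)) * Inf,
                  p_value = 0, df = NA_real_)
    }
  } else {
    tt <- stats::t.test(qa, qb, var.equal = var_equal)
    res <- list(t_statistic = unname(tt$statistic),
                p_value = tt$p.value, df = unname(tt$parameter))
  }
  res$mean_Q <- stats::setNames(c(mean(qa), mean(qb)), c(ga, gb))
  res$n_runs <- stats::setNames(c(length(qa), length(qb)), c(ga, gb))
  res
}

#' @export
print.scn_ensemble <- function(x, ...) {
  cat(sprintf(
    "Louvain ensemble (%d runs, gamma %.2f%s): mean Q %.4f, %d consensus communities\n",
    x$n_runs, x$gamma,
    if (is.na(x$group)) "" else paste0(", group ", x$group),
    x$mean_Q, x$n_communities))
  invisible(x)
}
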