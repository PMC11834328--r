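# Weighted Newman-Girvan modularity with resolution parameter, a
# from-scratch Louvain optimiser, and an exhaustive oracle for small graphs.

#' Construct a modularity model
#'
#' Bundles a weighted adjacency matrix with the resolution parameter gamma
#' and the strength-product null model V_ij = k_i k_j / (2m), where k_i is
#' node strength and m the total edge weight. The doubled-sum convention is
#' used throughout: Q = (1/2m) * sum_ij (A_ij - gamma k_i k_j / 2m)
#' delta(c_i, c_j), with both orientations of every edge counted, so Q
#' values are directly comparable across implementations using the same
#' convention.
#'
#' @param A symmetric nonnegative weighted adjacency matrix with zero
#'   diagonal (a plain matrix or an `scn_matrix`).
#' @param gamma resolution parameter, positive (default 1).
#' @return An object of class `modularity_model`.
#' @export
modularity_model <- function(A, gamma = 1) {
  if (inherits(A, "scn_matrix")) A <- A$weights
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (any(!is.finite(A))) stop("adjacency must be finite")
  if (any(A < 0)) stop("adjacency must be nonnegative")
  if (max(abs(A - t(A))) > 1e-12) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar")
  }
  A <- (A + t(A)) / 2  # kill last-bit asymmetry
  k <- rowSums(A)
  two_m <- sum(A)
  structure(list(A = A, gamma = gamma, k = k, two_m = two_m,
                 n = nrow(A),
                 labels = rownames(A) %||% as.character(seq_len(nrow(A)))),
            class = "modularity_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal: canonicalize community ids to 1..k in order of first appearance.
canonicalize_partition <- function(membership) {
  ids <- unique(membership)
  out <- match(membership, ids)
  names(out) <- names(membership)
  out
}

#' Modularity of a partition
#'
#' Evaluates Q = (1/2m) sum_ij (A_ij - gamma k_i k_j / 2m) delta(c_i, c_j)
#' (doubled-sum convention). All nodes in one community gives Q = 0 at
#' gamma = 1; Q always lies in [-1, 1].
#'
#' @param model a `modularity_model`.
#' @param membership integer vector assigning each node a community id.
#' @return Scalar Q.
#' @export
modularity_q <- function(model, membership) {
  stopifnot(inherits(model, "modularity_model"))
  if (model$two_m == 0) {
    stop("modularity undefined: graph has zero total edge weight")
  }
  if (length(membership) != model$n || anyNA(membership)) {
    stop("partition must assign every node exactly one community")
  }
  membership <- as.integer(factor(membership))
  within <- vapply(split(seq_len(model$n), membership), function(idx) {
    sum(model$A[idx, idx])
  }, numeric(1L))
  strength <- vapply(split(model$k, membership), sum, numeric(1L))
  sum(within / model$two_m - model$gamma * (strength / model$two_m)^2)
}

#' One Louvain run
#'
#' Standard two-phase Louvain heuristic: repeated single-node moves to the
#' community with the largest positive modularity gain (gains include the
#' resolution parameter), then aggregation of communities into super-nodes,
#' iterated until no move improves Q. The node sweep order is randomized
#' from `seed`, which fully determines the result; ties among equal-gain
#' moves go to the first candidate encountered in the sweep. Gains below
#' 1e-12 are treated as zero to avoid floating-point livelock.
#'
#' @param model a `modularity_model`.
#' @param seed integer seed for the sweep order.
#' @return List with `membership` (canonical integer vector, named by node
#'   label) and `Q` (recomputed from scratch on the returned partition).
#' @export
louvain_run <- function(model, seed = 1L) {
  stopifnot(inherits(model, "modularity_model"))
  if (model$two_m == 0) {
    stop("modularity undefined: graph has zero total edge weight")
  }
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(seed)

  A <- model$A
  gamma <- model$gamma
  two_m <- model$two_m
  membership <- seq_len(model$n)     # final labels on original nodes
  repeat {
    n <- nrow(A)
    comm <- seq_len(n)
    k <- rowSums(A)                  # self-loops already hold doubled weight
    sigma <- k                       # community total strengths
    tol <- 1e-12
    improved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        ci <- comm[i]
        wi <- A[i, ]
        wi[i] <- 0                   # self-loop moves with i; cancels in gains
        w_to <- rowsum(wi, comm)     # weight from i to each community
        comms <- as.integer(rownames(w_to))
        ki <- k[i]
        # gain of joining community d (relative, x 2/2m): w_id - g ki sigma_d/2m
        sigma_eff <- sigma[comms]
        sigma_eff[comms == ci] <- sigma_eff[comms == ci] - ki
        gain <- w_to[, 1L] - gamma * ki * sigma_eff / two_m
        best <- comms[which.max(gain)]
        if (best != ci && gain[match(best, comms)] >
            gain[match(ci, comms)] + tol) {
          sigma[ci] <- sigma[ci] - ki
          sigma[best] <- sigma[best] + ki
          comm[i] <- best
          moved <- TRUE
          improved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!improved_any) break
    # Aggregate communities into super-nodes (within-community weight
    # becomes a self-loop) and relabel the running membership.
    comm <- as.integer(factor(comm))
    membership <- comm[membership]
    P <- rowsum(A, comm)
    A <- t(rowsum(t(P), comm))
    if (nrow(A) == n) break
  }
  membership <- canonicalize_partition(membership)
  names(membership) <- model$labels
  list(membership = membership, Q = modularity_q(model, membership))
}

# Internal: enumerate all set partitions of n elements as restricted-growth
# strings, applying `fun` to each membership vector.
for_each_partition <- function(n, fun) {
  rgs <- integer(n)
  recurse <- function(pos, maxid) {
    if (pos > n) {
      fun(rgs)
      return(invisible(NULL))
    }
    for (id in seq_len(maxid + 1L)) {
      rgs[pos] <<- id
      recurse(pos + 1L, max(maxid, id))
    }
  }
  recurse(1L, 0L)
  invisible(NULL)
}

#' Exhaustive modularity optimum (test oracle)
#'
#' Enumerates every set partition of the node set (Bell-number many) and
#' returns a global maximizer of Q. Intended as an oracle for small graphs;
#' refuses more than `max_nodes` nodes.
#'
#' @param model a `modularity_model`.
#' @param max_nodes hard size cap (default 10; B(10) = 115975 partitions).
#' @return List with `membership` and `Q` of a global optimum.
#' @export
brute_force_optimal <- function(model, max_nodes = 10L) {
  stopifnot(inherits(model, "modularity_model"))
  if (model$n > max_nodes) {
    stop("brute force limited to ", max_nodes, " nodes; got ", model$n)
  }
  if (model$two_m == 0) {
    stop("modularity undefined: graph has zero total edge weight")
  }
  best_q <- -Inf
  best <- NULL
  for_each_partition(model$n, function(memb) {
    q <- modularity_q(model, memb)
    if (q > best_q) {
      best_q <<- q
      best <<- memb
    }
  })
  best <- canonicalize_partition(best)
  names(best) <- model$labels
  list(membership = best, Q = best_q)
}

#' Read a weighted edge list as an adjacency matrix
#'
#' Reads a TSV with columns `node_i`, `node_j`, `weight` into a symmetric
#' zero-diagonal adjacency matrix suitable for [modularity_model()].
#'
#' @param path TSV file path.
#' @return A labelled numeric matrix.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("node_i", "node_j", "weight") %in% names(df))) {
    stop("edge list must have columns node_i, node_j, weight")
  }
  nodes <- sort(unique(c(df$node_i, df$node_j)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(df))) {
    i <- df$node_i[r]; j <- df$node_j[r]
    if (i == j) stop("self-loops not allowed in input edge lists")
    A[i, j] <- A[i, j] + df$weight[r]
    A[j, i] <- A[j, i] + df$weight[r]
  }
  A
}

#' Write a partition as a two-column TSV
#'
#' @param membership named integer vector (node label -> community id).
#' @param path output path.
#' @export
save_partition <- function(membership, path) {
  utils::write.table(
    data.frame(node_label = names(membership),
               community_id = as.integer(membership)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
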