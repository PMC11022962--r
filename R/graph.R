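#' Pearson correlation between two channel time series
#'
#' @param x,y Numeric vectors of equal length >= 2, each non-constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant channel")
  stats::cor(x, y)
}

#' Pearson-correlation brain network from multichannel data
#'
#' Nodes are channels; the edge weight between channels i and j is the
#' Pearson correlation of their time series, giving a symmetric
#' channels x channels adjacency with unit diagonal.
#'
#' @param data Numeric matrix, channels x samples.
#' @param channel_names Optional channel names (taken from rownames
#'   otherwise).
#' @return A `brain_graph` with fields `adjacency` and `channel_names`.
#' @export
adjacency_from_data <- function(data, channel_names = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop("need at least 2 channels")
  if (ncol(data) < 2L) stop("need at least 2 samples")
  sds <- apply(data, 1, stats::sd)
  if (any(sds == 0)) {
    nm <- if (!is.null(rownames(data))) rownames(data)[sds == 0]
          else which(sds == 0)
    stop("constant channel(s), correlation undefined: ",
         paste(nm, collapse = ", "))
  }
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(rownames(data))) rownames(data)
                     else sprintf("ch%02d", seq_len(nrow(data)))
  }
  a <- stats::cor(t(data))
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(channel_names, channel_names)
  structure(list(adjacency = a, channel_names = channel_names),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  a <- x$adjacency
  off <- a[upper.tri(a)]
  cat(sprintf("<brain_graph> %d nodes, mean |r| = %.3f, range [%.3f, %.3f]\n",
              nrow(a), mean(abs(off)), min(off), max(off)))
  invisible(x)
}

# Apply the signed-edge policy to off-diagonal entries; zero the diagonal.
.policy_adjacency <- function(a, signed_policy = c("abs", "clip_negative")) {
  signed_policy <- match.arg(signed_policy)
  ap <- if (signed_policy == "abs") abs(a) else pmax(a, 0)
  diag(ap) <- 0
  ap
}

#' Symmetric-normalised propagation matrix with self-loops
#'
#' Computes `S = D^{-1/2} (A' + I) D^{-1/2}`, where `A'` is the
#' policy-transformed off-diagonal adjacency (absolute value by default,
#' since negative correlations would break the degree normalisation) and
#' `D` is the degree matrix of `A' + I`.
#'
#' @param g A `brain_graph` or a plain symmetric adjacency matrix.
#' @param signed_policy `"abs"` (default) or `"clip_negative"`.
#' @return Symmetric propagation matrix `S`.
#' @export
propagation_matrix <- function(g, signed_policy = "abs") {
  a <- if (inherits(g, "brain_graph")) g$adjacency else as.matrix(g)
  ap <- .policy_adjacency(a, signed_policy)
  atil <- ap + diag(nrow(ap))
  d <- rowSums(atil)
  stopifnot(all(d > 0))
  s <- atil / sqrt(outer(d, d))
  dimnames(s) <- dimnames(a)
  s
}

#' One 50% graph-coarsening level by greedy heavy-edge matching
#'
#' Pairs the most strongly connected (largest `|weight|`) unmatched nodes
#' first, deterministic tie-break by lowest node index; leftover nodes are
#' paired by ascending index so exactly `ceiling(n/2)` coarse nodes remain
#' (a final odd node forms a singleton). Coarse edge weights are the sums
#' of fine edge weights between groups.
#'
#' @param a Nonnegative symmetric adjacency (policy already applied).
#' @return List with `assignment` (fine index -> coarse index) and
#'   `coarse_adjacency`.
#' @keywords internal
.coarsen_once <- function(a) {
  n <- nrow(a)
  stopifnot(n >= 2L)
  ut <- which(upper.tri(a), arr.ind = TRUE)
  w <- a[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  matched <- rep(FALSE, n)
  pairs <- list()
  for (e in ord) {
    i <- ut[e, 1]; j <- ut[e, 2]
    if (!matched[i] && !matched[j]) {
      matched[i] <- matched[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  left <- which(!matched)
  while (length(left) >= 2L) {
    pairs[[length(pairs) + 1L]] <- left[1:2]
    left <- left[-(1:2)]
  }
  groups <- c(pairs, as.list(left))
  # deterministic coarse numbering: order groups by smallest member
  groups <- groups[order(vapply(groups, min, 0L))]
  assignment <- integer(n)
  for (g in seq_along(groups)) assignment[groups[[g]]] <- g
  m <- length(groups)
  p <- matrix(0, n, m)
  p[cbind(seq_len(n), assignment)] <- 1
  coarse <- t(p) %*% a %*% p
  list(assignment = assignment, coarse_adjacency = coarse)
}

#' Graph-coarsening hierarchy for 50% pooling
#'
#' Builds `levels` successive coarsenings of the brain network, each
#' halving the node count (`ceiling(n / 2^k)` nodes at level k) via greedy
#' heavy-edge matching on the policy-transformed adjacency.
#'
#' @param g A `brain_graph`.
#' @param levels Number of pooling levels (>= 1).
#' @param signed_policy Edge-sign policy, see [propagation_matrix()].
#' @return List of `pooling_level`s, each with `assignment` and
#'   `coarse_adjacency`.
#' @export
build_pooling_hierarchy <- function(g, levels = 2, signed_policy = "abs") {
  stopifnot(inherits(g, "brain_graph"), levels >= 1)
  n <- nrow(g$adjacency)
  if (n < 2^levels)
    stop("graph has ", n, " nodes; too few for ", levels,
         " halving levels (need >= ", 2^levels, ")")
  a <- .policy_adjacency(g$adjacency, signed_policy)
  out <- vector("list", levels)
  for (k in seq_len(levels)) {
    lev <- .coarsen_once(a)
    out[[k]] <- structure(lev, class = "pooling_level")
    a <- lev$coarse_adjacency
  }
  out
}

#' Propagation matrices and pooling assignments for the GCN
#'
#' Packages what the network forward pass needs: the propagation matrix of
#' the full graph, one propagation matrix per coarsened level, and the
#' per-level pooling assignments.
#'
#' @param g A `brain_graph`.
#' @param levels Number of GCN/pooling levels.
#' @param signed_policy Edge-sign policy.
#' @return A `graph_stack`: list with `S` (list of length `levels`,
#'   `S[[l]]` being the propagation matrix fed to GCN layer l) and
#'   `assignment` (list of pooling maps applied after each layer).
#' @export
graph_stack <- function(g, levels = 2, signed_policy = "abs") {
  hier <- build_pooling_hierarchy(g, levels, signed_policy)
  s <- vector("list", levels)
  s[[1]] <- propagation_matrix(g, signed_policy)
  if (levels > 1) {
    for (l in 2:levels)
      s[[l]] <- propagation_matrix(hier[[l - 1]]$coarse_adjacency,
                                   signed_policy)
  }
  structure(list(S = s, assignment = lapply(hier, `[[`, "assignment"),
                 hierarchy = hier, n_nodes = nrow(g$adjacency)),
            class = "graph_stack")
}
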