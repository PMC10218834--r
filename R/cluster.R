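# Pairwise-RMSD clustering of trajectory frames.

#' All-against-all Kabsch RMSD matrix
#'
#' @param traj trajectory (>= 2 frames).
#' @param sel atom indices the RMSD is computed on (superposition uses the
#'   same set).
#' @return symmetric n_frames x n_frames matrix of RMSDs, Angstrom.
#' @export
pairwise_rmsd_matrix <- function(traj, sel = seq_len(n_atoms(traj$topology))) {
  if (!length(sel)) stop("empty selection")
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  coords <- lapply(traj$frames, function(f) f$xyz[sel, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- .fit_rmsd(coords[[i]], coords[[j]])
    }
  }
  m
}

#' Single-linkage clustering at a distance cutoff
#'
#' Two frames belong to the same cluster iff they are connected by a path
#' of pairwise distances strictly below `cutoff` (graph connected
#' components on the thresholded distance matrix).  Cluster ids are
#' assigned by decreasing population, ties broken by the lowest member
#' frame index.
#'
#' @param m square symmetric distance matrix.
#' @param cutoff linkage threshold, Angstrom (strict `<`).
#' @return list of class `"cluster_result"`: `labels` (per-frame id),
#'   `populations` (named count vector), `representatives` (filled by
#'   [representative_frame()] callers; here the lowest member index per
#'   cluster as a placeholder is *not* included), `cutoff`.
#' @export
single_linkage <- function(m, cutoff) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be square")
  if (any(is.na(m))) stop("distance matrix contains NA/NaN")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  n <- nrow(m)
  adj <- (m < cutoff)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # relabel: decreasing population, ties by lowest member frame index
  first <- tapply(seq_len(n), comp, min)
  sizes <- tabulate(comp)
  ord <- order(-sizes, first)
  relab <- integer(max(comp))
  relab[ord] <- seq_along(ord)
  labels <- relab[comp]
  pops <- tabulate(labels)
  names(pops) <- seq_along(pops)
  structure(list(labels = labels, populations = pops, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("single-linkage clustering at cutoff", x$cutoff, "A:",
      length(x$populations), "cluster(s); populations:",
      paste(x$populations, collapse = ", "), "\n")
  invisible(x)
}

#' Medoid representative of a cluster
#'
#' Returns the member frame minimising the summed RMSD to all other
#' members; singleton clusters return their only member; ties are broken
#' by the lowest frame index.
#'
#' @param members integer frame indices of the cluster.
#' @param m pairwise distance matrix over all frames.
#' @return single frame index.
#' @export
representative_frame <- function(members, m) {
  if (!length(members)) stop("cluster has no members")
  if (length(members) == 1) return(members)
  tot <- rowSums(m[members, members, drop = FALSE])
  members[which.min(tot)]   # which.min takes the first (lowest index) on ties
}

#' Cluster a trajectory and summarise
#'
#' Convenience wrapper: pairwise matrix, single-linkage at `cutoff`,
#' medoid representatives.
#'
#' @param traj trajectory.
#' @param sel atom indices clustered on.
#' @param cutoff linkage threshold, Angstrom.
#' @return `"cluster_result"` with `representatives` (named vector
#'   cluster id -> frame index) and the `matrix` attached.
#' @export
cluster_trajectory <- function(traj, sel = seq_len(n_atoms(traj$topology)),
                               cutoff = 2.0) {
  m <- pairwise_rmsd_matrix(traj, sel)
  res <- single_linkage(m, cutoff)
  ids <- sort(unique(res$labels))
  reps <- vapply(ids, function(k)
    representative_frame(which(res$labels == k), m), integer(1))
  names(reps) <- ids
  res$representatives <- reps
  res$matrix <- m
  res
}
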