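# Superposition, RMSD statistics, and aromatic-ring descriptors.

#' Minimum-image displacement vectors
#'
#' @param d numeric matrix (n x 3) of raw displacement vectors, Angstrom.
#' @param box orthorhombic box edges (length 3) or `NULL` for no wrapping.
#' @return matrix of wrapped displacements.
#' @export
min_image <- function(d, box = NULL) {
  d <- rbind(d)
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

.vnorm <- function(v) sqrt(sum(v * v))

#' Kabsch least-squares superposition
#'
#' Rotates and translates `mobile` so that the `fit` atoms best match the
#' reference in the least-squares sense.  The rotation is guaranteed
#' proper (determinant +1).
#'
#' @param mobile frame to move.
#' @param reference frame to match.
#' @param fit integer indices of atoms used for the fit (>= 3,
#'   non-collinear).
#' @return list with `frame` (all atoms transformed), `rotation` (3 x 3),
#'   `translation` (length 3; the transform is `x %*% R + t`), and `rmsd`
#'   of the fit atoms after superposition.
#' @export
kabsch_align <- function(mobile, reference, fit = seq_len(nrow(mobile$xyz))) {
  P <- mobile$xyz[fit, , drop = FALSE]
  Q <- reference$xyz[fit, , drop = FALSE]
  if (nrow(P) < 3) stop("need at least 3 fit atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(crossprod(P0, Q0))
  if (s$d[2] < 1e-10)
    stop("degenerate (collinear) fit set: superposition is ill-defined")
  sgn <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, sgn))
  R <- s$u %*% D %*% t(s$v)
  tr <- cq - drop(cp %*% R)
  new_xyz <- sweep(mobile$xyz %*% R, 2, tr, `+`)
  fitted <- new_xyz[fit, , drop = FALSE]
  rms <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(frame = frame(new_xyz, box = mobile$box, time = mobile$time),
       rotation = R, translation = tr, rmsd = rms)
}

#' Plain (unfitted) RMSD between two coordinate sets
#' @param a,b N x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# RMSD between two frames on `sel` after Kabsch superposition of `fit`,
# via the closed form (no explicit rotation applied when sel == fit).
.fit_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  e0 <- sum(P0^2) + sum(Q0^2)
  s <- svd(crossprod(P0, Q0))
  sgn <- sign(det(s$u %*% t(s$v)))
  d <- s$d; d[3] <- d[3] * sgn
  sqrt(max(0, (e0 - 2 * sum(d)) / nrow(P)))
}

#' Per-frame RMSD time series
#'
#' Each frame is first superposed onto the reference on `fit`, then the
#' RMSD is measured over `measure` (the two selections may differ, e.g.
#' fit on the protein backbone, measure on the ligand).
#'
#' @param traj trajectory.
#' @param reference reference frame (default: first frame).
#' @param fit atom indices used for superposition.
#' @param measure atom indices the RMSD is computed over (default `fit`).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference = traj$frames[[1]],
                        fit = seq_len(n_atoms(traj$topology)),
                        measure = fit) {
  if (!length(measure)) stop("empty measure selection")
  vapply(traj$frames, function(fr) {
    al <- kabsch_align(fr, reference, fit = fit)
    coord_rmsd(al$frame$xyz[measure, , drop = FALSE],
               reference$xyz[measure, , drop = FALSE])
  }, numeric(1))
}

#' Fluctuation (RMSE) of a time series
#'
#' The root-mean-square deviation of a series about its own mean, i.e.
#' the population standard deviation: `sqrt(mean((x - mean(x))^2))`.
#' This is the fluctuation measure reported alongside average RMSD values;
#' set `about` to measure spread about a fixed reference value instead.
#'
#' @param values numeric vector, length >= 2.
#' @param about optional fixed centre; defaults to `mean(values)`.
#' @return scalar RMSE in the units of `values`.
#' @export
series_rmse <- function(values, about = NULL) {
  if (length(values) < 2) stop("need at least 2 values")
  ctr <- if (is.null(about)) mean(values) else about
  sqrt(mean((values - ctr)^2))
}

#' Centroid, best-fit plane normal, and planarity of a ring
#'
#' The centroid is the unweighted mean of the member coordinates.  The
#' normal is the smallest principal axis of the member cloud (robust to
#' ring pucker), sign-normalised into the +z hemisphere.
#'
#' @param fr frame.
#' @param ring [ring_spec()].
#' @return list with `centroid` (3-vector, A), `normal` (unit 3-vector),
#'   `planarity_rms` (A).
#' @export
ring_geometry <- function(fr, ring) {
  X <- fr$xyz[ring$members, , drop = FALSE]
  ctr <- colMeans(X)
  X0 <- sweep(X, 2, ctr)
  s <- svd(X0, nu = 0)
  if (s$d[2] < 1e-8)
    stop("ring '", ring$label, "' members are collinear")
  nrm <- s$v[, 3]
  if (nrm[3] < 0 || (nrm[3] == 0 && (nrm[2] < 0 || (nrm[2] == 0 && nrm[1] < 0))))
    nrm <- -nrm
  list(centroid = ctr, normal = nrm / .vnorm(nrm),
       planarity_rms = sqrt(mean((X0 %*% nrm)^2)))
}

#' Pairwise aromatic-ring descriptor (r_cen, d, theta)
#'
#' `r_cen` is the centroid-centroid distance; `d` the perpendicular
#' distance from ring A's centroid to ring B's plane (asymmetric in
#' general); `theta` the acute angle between the two ring planes, folded
#' into \[0, 90\] degrees.
#'
#' @param fr frame.
#' @param ring_a,ring_b [ring_spec()] objects.
#' @return list with `r_cen`, `d` (Angstrom) and `theta` (degrees).
#' @export
pi_pi_descriptor <- function(fr, ring_a, ring_b) {
  ga <- ring_geometry(fr, ring_a)
  gb <- ring_geometry(fr, ring_b)
  dv <- ga$centroid - gb$centroid
  r_cen <- .vnorm(dv)
  d <- abs(sum(dv * gb$normal))
  ct <- abs(sum(ga$normal * gb$normal))
  theta <- acos(min(1, ct)) * 180 / pi
  list(r_cen = r_cen, d = d, theta = theta)
}

#' Descriptor time series for a ring pair
#'
#' @param traj trajectory.
#' @param ring_a,ring_b [ring_spec()] objects.
#' @param pair_label label written to the output table.
#' @return data.frame: frame, time_ps, pair_label, r_cen_A, d_A, theta_deg.
#' @export
pi_pi_series <- function(traj, ring_a, ring_b,
                         pair_label = paste(ring_a$label, ring_b$label,
                                            sep = "-")) {
  rows <- lapply(seq_along(traj$frames), function(i) {
    p <- pi_pi_descriptor(traj$frames[[i]], ring_a, ring_b)
    data.frame(frame = i, time_ps = traj$frames[[i]]$time,
               pair_label = pair_label, r_cen_A = p$r_cen, d_A = p$d,
               theta_deg = p$theta, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
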