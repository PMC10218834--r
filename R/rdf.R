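# Radial distribution functions between site sets, with ring-centroid
# reference sites and first-peak reporting.

#' Radial distribution function g(r)
#'
#' Standard bulk-density normalisation:
#' `g(r) = hist(r) / (4 pi r^2 dr * rho_target * N_ref * N_frames)` with
#' `rho_target = N_target / V_box`, evaluated with the instantaneous box
#' volume per frame (NPT-compatible).  Reference sites may be atoms or
#' ring centroids (recomputed every frame).  Minimum-image distances are
#' used when `use_pbc`.
#'
#' @param traj trajectory.
#' @param reference_sites list whose elements are atom indices or
#'   [ring_spec()] objects (centroid used).
#' @param target_sites atom indices.
#' @param r_max histogram range, Angstrom; must not exceed half the
#'   smallest box edge under PBC.
#' @param dr bin width, Angstrom.
#' @param use_pbc apply the minimum-image convention.
#' @return list of class `"rdf_result"`: `bin_centers`, `g_of_r`,
#'   `counts`, `reference_count`, `target_density` (mean, A^-3),
#'   `frames_used`, `dr`.
#' @export
compute_rdf <- function(traj, reference_sites, target_sites, r_max = 12,
                        dr = 0.05, use_pbc = TRUE) {
  if (!is.list(reference_sites)) reference_sites <- as.list(reference_sites)
  if (!length(target_sites)) stop("zero target sites")
  nf <- n_frames(traj)
  breaks <- seq(0, r_max, by = dr)
  nb <- length(breaks) - 1
  counts <- numeric(nb)
  denom <- numeric(nb)
  centers <- breaks[-1] - dr / 2
  shell_vol <- 4 * pi * centers^2 * dr
  rho_sum <- 0
  for (i in seq_len(nf)) {
    fr <- traj$frames[[i]]
    box <- if (use_pbc) fr$box else NULL
    if (use_pbc) {
      if (is.null(box)) stop("use_pbc = TRUE but frame ", i, " has no box")
      if (r_max > min(box) / 2 + 1e-9)
        stop("r_max (", r_max, " A) exceeds half the smallest box edge (",
             min(box) / 2, " A)")
    }
    refs <- do.call(rbind, lapply(reference_sites, function(s) {
      if (inherits(s, "ring_spec")) rbind(ring_geometry(fr, s)$centroid)
      else fr$xyz[s, , drop = FALSE]
    }))
    tx <- fr$xyz[target_sites, , drop = FALSE]
    d2 <- matrix(0, nrow(refs), nrow(tx))
    for (k in 1:3) {
      dk <- outer(refs[, k], tx[, k], `-`)
      if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
      d2 <- d2 + dk * dk
    }
    dd <- sqrt(d2)
    dd <- dd[dd > 1e-9 & dd < r_max]   # drop self-pairs and out-of-range
    counts <- counts + graphics::hist(dd, breaks = breaks,
                                      plot = FALSE)$counts
    vol <- if (!is.null(fr$box)) prod(fr$box) else
      stop("RDF normalisation needs a box volume (frame ", i, ")")
    rho <- length(target_sites) / vol
    rho_sum <- rho_sum + rho
    denom <- denom + nrow(refs) * rho * shell_vol
  }
  structure(list(bin_centers = centers, g_of_r = counts / denom,
                 counts = counts, reference_count = length(reference_sites),
                 target_density = rho_sum / nf, frames_used = nf, dr = dr),
            class = "rdf_result")
}

#' Cumulative coordination number n(r)
#'
#' Integrates `4 pi r^2 rho g(r)` over the histogram bins: the mean
#' number of target sites within `r` of a reference site.
#'
#' @param rdf an `"rdf_result"`.
#' @return numeric vector aligned with `rdf$bin_centers`.
#' @export
coordination_number <- function(rdf) {
  cumsum(4 * pi * rdf$bin_centers^2 * rdf$dr * rdf$target_density *
           rdf$g_of_r)
}

#' First peak of a g(r) curve
#'
#' Returns the smallest-r local maximum whose topographic prominence is
#' at least `min_prominence`.
#'
#' @param rdf an `"rdf_result"` (or list with `bin_centers`, `g_of_r`).
#' @param min_prominence required prominence in g units.
#' @return list `r_peak`, `g_peak`, `found`; `found = FALSE` (with `NA`
#'   values) when no qualifying peak exists.
#' @export
first_peak <- function(rdf, min_prominence = 0.5) {
  g <- rdf$g_of_r; r <- rdf$bin_centers
  n <- length(g)
  for (i in 2:(n - 1)) {
    if (!(g[i] > g[i - 1] && g[i] >= g[i + 1])) next
    # prominence: drop to the lowest point before re-reaching g[i] on
    # each side (or the series end)
    left <- g[seq_len(i - 1)]
    hi <- which(left > g[i])
    lidx <- if (length(hi)) seq_len(i - 1)[seq_len(i - 1) > max(hi)] else
      seq_len(i - 1)
    lmin <- if (length(lidx)) min(left[lidx]) else g[i]
    right <- g[(i + 1):n]
    hi <- which(right > g[i])
    ridx <- if (length(hi)) seq_len(min(hi) - 1) else seq_along(right)
    rmin <- if (length(ridx)) min(right[ridx]) else g[i]
    prom <- g[i] - max(lmin, rmin)
    if (prom >= min_prominence)
      return(list(r_peak = r[i], g_peak = g[i], found = TRUE))
  }
  list(r_peak = NA_real_, g_peak = NA_real_, found = FALSE)
}

#' Export an RDF as a data.frame / CSV table
#' @param rdf an `"rdf_result"`.
#' @return data.frame: `r_A`, `g_r`, `cumulative_coordination_number`.
#' @export
rdf_table <- function(rdf) {
  data.frame(r_A = rdf$bin_centers, g_r = rdf$g_of_r,
             cumulative_coordination_number = coordination_number(rdf))
}
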