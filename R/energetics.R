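# Pairwise MM interaction energies, the interaction-entropy estimator,
# solvation surrogates, end-state free-energy bookkeeping, per-residue
# decomposition, and Ki <-> delta-G conversion.

.check_parameterized <- function(top, idx) {
  a <- top$atoms
  bad <- idx[is.na(a$charge[idx]) | is.na(a$sigma[idx]) | is.na(a$epsilon[idx])]
  if (length(bad))
    stop("unparameterized atom(s): ", toString(utils::head(bad, 10)),
         if (length(bad) > 10) " ..." else "")
}

#' Lennard-Jones and Coulomb interaction energy between two selections
#'
#' All-pairs sums (no cutoff, the end-state convention) with
#' Lorentz-Berthelot combining rules and minimum-image distances:
#' `E_vdW = sum 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)`,
#' `E_Coul = sum k_e q_i q_j / r` with
#' `k_e = 138.935458 kJ nm/(mol e^2)`.
#'
#' @param fr frame.
#' @param sel_a,sel_b disjoint atom index sets.
#' @param top parameterized topology.
#' @return list `E_vdW`, `E_Coul` in kJ/mol.
#' @export
lj_coulomb_energy <- function(fr, sel_a, sel_b, top) {
  if (length(intersect(sel_a, sel_b)))
    stop("selections must be disjoint")
  .check_parameterized(top, c(sel_a, sel_b))
  a <- top$atoms
  xa <- fr$xyz[sel_a, , drop = FALSE]
  xb <- fr$xyz[sel_b, , drop = FALSE]
  qa <- a$charge[sel_a]; qb <- a$charge[sel_b]
  sa <- a$sigma[sel_a];  sb <- a$sigma[sel_b]
  ea <- a$epsilon[sel_a]; eb <- a$epsilon[sel_b]
  E_vdW <- 0; E_Coul <- 0
  for (i in seq_along(sel_a)) {
    dv <- min_image(sweep(xb, 2, xa[i, ]), fr$box)
    r <- sqrt(rowSums(dv^2))
    if (any(r < 0.1))
      stop("overlapping atoms (r < 0.1 A) between selections")
    sij <- (sa[i] + sb) / 2
    eij <- sqrt(ea[i] * eb)
    sr6 <- (sij / r)^6
    E_vdW <- E_vdW + sum(4 * eij * (sr6^2 - sr6))
    E_Coul <- E_Coul + sum(.ke_A * qa[i] * qb / r)
  }
  list(E_vdW = E_vdW, E_Coul = E_Coul)
}

#' Per-frame protein-ligand interaction energy series
#'
#' @param traj trajectory.
#' @param sel_a,sel_b disjoint selections (e.g. protein, ligand).
#' @param top parameterized topology.
#' @param temperature ensemble temperature stored with the series, K.
#' @return list of class `"energy_series"`: `E_int` (kJ/mol per frame),
#'   `E_vdW`, `E_Coul`, `temperature`, `times`.
#' @export
interaction_energy_series <- function(traj, sel_a, sel_b, top = traj$topology,
                                      temperature = 298.15) {
  v <- c_ <- numeric(n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    e <- lj_coulomb_energy(traj$frames[[i]], sel_a, sel_b, top)
    v[i] <- e$E_vdW; c_[i] <- e$E_Coul
  }
  structure(list(E_int = v + c_, E_vdW = v, E_Coul = c_,
                 temperature = temperature, times = frame_times(traj)),
            class = "energy_series")
}

#' Interaction-entropy estimate of -T*dS from energy fluctuations
#'
#' `-T dS = k_B T ln < exp(beta dE) >` with
#' `dE_i = E_i - <E>`, evaluated through a log-sum-exp formulation that
#' is stable for beta*dE up to ~700.  The estimate is non-negative for
#' any real series (Jensen's inequality) and exactly 0 for a constant
#' series.  A running per-prefix estimate is returned together with a
#' convergence flag (relative spread of the running estimate over its
#' final 20% below `tol`).
#'
#' @param series numeric vector of interaction energies (kJ/mol) or an
#'   `"energy_series"`.
#' @param temperature K.
#' @param tol relative-spread convergence tolerance.
#' @return list of class `"entropy_estimate"`: `minus_TdS` (kJ/mol),
#'   `running` (per-prefix estimates), `converged`.
#' @export
interaction_entropy <- function(series, temperature = 298.15, tol = 0.05) {
  e <- if (inherits(series, "energy_series")) series$E_int else as.numeric(series)
  if (length(e) < 2) stop("need at least 2 energy values")
  kT <- .kB * temperature
  x <- (e - mean(e)) / kT
  lse <- function(z) { m <- max(z); m + log(mean(exp(z - m))) }
  val <- kT * lse(x)
  if (!is.finite(val))
    stop("interaction entropy did not stabilise; consider block averaging")
  n <- length(e)
  # running estimate on ~100 prefixes (each prefix re-centred on its own mean)
  at <- unique(pmax(2, round(seq(2, n, length.out = min(n - 1, 100)))))
  running <- vapply(at, function(k) {
    xe <- e[seq_len(k)]
    kT * lse((xe - mean(xe)) / kT)
  }, numeric(1))
  tailpart <- running[at >= 0.8 * n]
  spread <- diff(range(tailpart))
  converged <- is.finite(spread) &&
    (spread <= tol * max(abs(val), .Machine$double.eps))
  structure(list(minus_TdS = max(0, val), running = running,
                 running_at = at, converged = converged,
                 temperature = temperature),
            class = "entropy_estimate")
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic sphere sampling with a Fibonacci (golden-angle) point
#' set; a point on atom i's expanded sphere (radius + probe) counts as
#' accessible when it lies outside every other atom's expanded sphere.
#'
#' @param fr frame.
#' @param sel atom indices.
#' @param radii numeric vector of vdW radii for `sel` (Angstrom), or a
#'   named vector keyed by element.
#' @param top topology (needed when `radii` is element-keyed).
#' @param probe probe radius, Angstrom.
#' @param n_points sphere sample points per atom.
#' @return list: `total` (A^2), `per_atom` (named by index in `sel`).
#' @export
sasa <- function(fr, sel, radii, top = NULL, probe = 1.4, n_points = 960) {
  if (!is.null(names(radii))) {
    if (is.null(top)) stop("element-keyed radii need a topology")
    el <- top$atoms$element[sel]
    miss <- setdiff(unique(el), names(radii))
    if (length(miss)) stop("missing radius for element(s): ", toString(miss))
    radii <- unname(radii[el])
  }
  if (length(radii) != length(sel)) stop("one radius per selected atom needed")
  if (any(is.na(radii))) stop("missing radius value")
  # deterministic Fibonacci sphere
  k <- seq_len(n_points) - 0.5
  phi <- acos(1 - 2 * k / n_points)
  theta <- pi * (1 + sqrt(5)) * k
  pts <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  x <- fr$xyz[sel, , drop = FALSE]
  rext <- radii + probe
  per <- numeric(length(sel))
  for (i in seq_along(sel)) {
    sp <- sweep(pts * rext[i], 2, x[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_along(sel)) {
      if (j == i) next
      if (sqrt(sum((x[j, ] - x[i, ])^2)) > rext[i] + rext[j]) next
      d2 <- colSums((t(sp) - x[j, ])^2)
      acc <- acc & (d2 > rext[j]^2)
      if (!any(acc)) break
    }
    per[i] <- 4 * pi * rext[i]^2 * mean(acc)
  }
  names(per) <- sel
  list(total = sum(per), per_atom = per)
}

#' Nonpolar solvation term from buried surface area
#'
#' `ddG_SA = gamma * (SASA_complex - SASA_receptor - SASA_ligand) - b`
#' (the additive constant appears once for each of the three states and
#' so survives as `-b`).
#'
#' @param sasa_complex,sasa_receptor,sasa_ligand total SASA values, A^2.
#' @param gamma surface tension coefficient, kJ/(mol A^2).
#' @param beta_const additive constant b, kJ/mol.
#' @return ddG_SA in kJ/mol.
#' @export
nonpolar_solvation <- function(sasa_complex, sasa_receptor, sasa_ligand,
                               gamma = 0.0227, beta_const = 3.849) {
  stopifnot(sasa_complex >= 0, sasa_receptor >= 0, sasa_ligand >= 0)
  gamma * (sasa_complex - sasa_receptor - sasa_ligand) - beta_const
}

.gb_energy <- function(x, q, R, eps_in, eps_out) {
  pref <- -(.ke_A / 2) * (1 / eps_in - 1 / eps_out)
  n <- length(q)
  g <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    r2 <- sum((x[i, ] - x[j, ])^2)
    fgb <- sqrt(r2 + R[i] * R[j] * exp(-r2 / (4 * R[i] * R[j])))
    g <- g + pref * q[i] * q[j] / fgb
  }
  g
}

#' Generalized-Born polar solvation difference
#'
#' Pairwise GB with the canonical smoothing function
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))` and fixed
#' (user-supplied) Born radii:
#' `ddG = G(complex) - G(receptor) - G(ligand)`.
#' For a single ion this reduces to the Born equation.
#'
#' @param fr frame.
#' @param sel_receptor,sel_ligand atom index sets (the complex is their
#'   union).
#' @param charges full-topology charge vector (e) or `NULL` to use the
#'   topology's.
#' @param born_radii full-topology Born radii (Angstrom), positive.
#' @param top topology.
#' @param eps_in,eps_out interior/solvent dielectric constants.
#' @return list: `ddG_polar`, `G_complex`, `G_receptor`, `G_ligand`
#'   (kJ/mol).
#' @export
gb_polar_surrogate <- function(fr, sel_receptor, sel_ligand, born_radii,
                               top, charges = NULL,
                               eps_in = 1, eps_out = 80) {
  if (is.null(charges)) charges <- top$atoms$charge
  all_sel <- c(sel_receptor, sel_ligand)
  if (any(is.na(charges[all_sel]))) stop("missing charge in GB selection")
  if (any(!is.finite(born_radii[all_sel]) | born_radii[all_sel] <= 0))
    stop("non-positive Born radius")
  gsel <- function(s) .gb_energy(fr$xyz[s, , drop = FALSE], charges[s],
                                 born_radii[s], eps_in, eps_out)
  gc_ <- gsel(all_sel); gr <- gsel(sel_receptor); gl <- gsel(sel_ligand)
  list(ddG_polar = gc_ - gr - gl, G_complex = gc_, G_receptor = gr,
       G_ligand = gl)
}

#' End-state free-energy bookkeeping
#'
#' Assembles the component ledger with the identities
#' `dE_gas = dE_vdW + dE_Coul`,
#' `dG_sol = ddG_PB + ddG_SA`, and
#' `dG_bind = dE_gas - T dS_gas + dG_sol` (the entropy enters as the
#' precomputed `-T dS` term), all held to 1e-9 internally.
#'
#' @param dE_vdW,dE_Coul gas-phase MM components, kJ/mol.
#' @param ddG_PB polar solvation difference, kJ/mol.
#' @param ddG_SA nonpolar solvation difference, kJ/mol.
#' @param minus_TdS entropy term (-T dS), kJ/mol.
#' @param per_residue optional data.frame of per-residue contributions.
#' @return list of class `"free_energy_table"` with all components and
#'   `dG_bind`.
#' @export
mmpbsa_totals <- function(dE_vdW, dE_Coul, ddG_PB, ddG_SA, minus_TdS,
                          per_residue = NULL) {
  dE_gas <- dE_vdW + dE_Coul
  dG_sol <- ddG_PB + ddG_SA
  dG_bind <- dE_gas + minus_TdS + dG_sol
  structure(list(dE_vdW = dE_vdW, dE_Coul = dE_Coul, dE_gas = dE_gas,
                 ddG_PB = ddG_PB, ddG_SA = ddG_SA, dG_sol = dG_sol,
                 minus_TdS = minus_TdS, dG_bind = dG_bind,
                 per_residue = per_residue),
            class = "free_energy_table")
}

#' @export
print.free_energy_table <- function(x, ...) {
  cat(sprintf(
    "dG_bind %10.3f = dE_gas %10.3f (vdW %9.3f + Coul %9.3f)\n",
    x$dG_bind, x$dE_gas, x$dE_vdW, x$dE_Coul))
  cat(sprintf(
    "             + dG_sol %10.3f (PB %10.3f + SA %9.3f) + (-TdS) %8.3f  [kJ/mol]\n",
    x$dG_sol, x$ddG_PB, x$ddG_SA, x$minus_TdS))
  invisible(x)
}

#' Export a free-energy table as a one-row data.frame
#' @param x `"free_energy_table"`.
#' @return data.frame in ledger column order.
#' @export
free_energy_row <- function(x) {
  data.frame(dG_bind = x$dG_bind, dE_vdW = x$dE_vdW, dE_Coul = x$dE_Coul,
             ddG_PB = x$ddG_PB, ddG_SA = x$ddG_SA, minus_TdS = x$minus_TdS)
}

#' Per-residue decomposition of the gas-phase interaction energy
#'
#' For each residue, the pairwise vdW and Coulomb sums against the
#' ligand, averaged over frames.  Summing over all residues reproduces
#' the total ligand-protein interaction energy (conservation).
#'
#' @param traj trajectory.
#' @param ligand_sel ligand atom indices.
#' @param top parameterized topology.
#' @param residue_ids residue ids to decompose over; defaults to every
#'   residue with atoms outside the ligand selection.
#' @return data.frame: `resid`, `resname`, `E_vdW`, `E_Coul`, `E_total`
#'   (kJ/mol, frame-averaged).
#' @export
per_residue_decomposition <- function(traj, ligand_sel, top = traj$topology,
                                      residue_ids = NULL) {
  a <- top$atoms
  if (is.null(residue_ids)) {
    residue_ids <- sort(unique(a$resid[-ligand_sel]))
  }
  nf <- n_frames(traj)
  rows <- lapply(residue_ids, function(rid) {
    sel <- setdiff(which(a$resid == rid), ligand_sel)
    if (!length(sel)) return(NULL)
    vd <- cl <- 0
    for (i in seq_len(nf)) {
      e <- lj_coulomb_energy(traj$frames[[i]], sel, ligand_sel, top)
      vd <- vd + e$E_vdW; cl <- cl + e$E_Coul
    }
    data.frame(resid = rid, resname = a$resname[sel[1]],
               E_vdW = vd / nf, E_Coul = cl / nf,
               E_total = (vd + cl) / nf, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convert an inhibition constant Ki to a binding free energy
#'
#' `dG = R T ln(Ki / 1 M)`.
#'
#' @param Ki inhibition constant, molar; must be positive.
#' @param temperature K.
#' @param R gas constant, J/(mol K).
#' @return dG in kJ/mol.
#' @export
ki_to_delta_g <- function(Ki, temperature = 310, R = 8.314) {
  if (any(Ki <= 0)) stop("Ki must be positive")
  R * temperature * log(Ki) / 1000
}
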