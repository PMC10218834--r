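# Seeded generators for every fixture the analysis stages need.  Each
# generator plants a known ground truth (a bond geometry, a ring-pair
# descriptor, an occupancy, a cluster structure, a fluctuation width)
# that the corresponding stage must recover.

.unit <- function(v) v / sqrt(sum(v * v))

.hexagon <- function(radius = 1.39) {
  ang <- (0:5) * pi / 3
  cbind(radius * cos(ang), radius * sin(ang), 0)
}

# rotate points about the x-axis by `deg` degrees
.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Three-atom donor-H-acceptor fixture with exact geometry
#'
#' Places D-H along +z (bond length 1.0 A), and the acceptor at exactly
#' the requested acceptor...H distance with the requested D-H...A angle.
#'
#' @param distance acceptor...H distance, Angstrom (> 0.5).
#' @param angle D-H...A angle, degrees.
#' @param donor_element,acceptor_element element symbols.
#' @return list `topology` (hydrogens populated), `frame`, and the donor,
#'   hydrogen, acceptor indices (1, 2, 3).
#' @export
make_hbond_fixture <- function(distance, angle, donor_element = "O",
                               acceptor_element = "N") {
  if (distance <= 0.5) stop("acceptor...H distance must exceed 0.5 A")
  if (angle < 0 || angle > 180) stop("angle must lie in [0, 180] degrees")
  a <- angle * pi / 180
  xyz <- rbind(c(0, 0, 1),                                    # donor heavy
               c(0, 0, 0),                                    # hydrogen
               distance * c(sin(a), 0, cos(a)))               # acceptor
  atoms <- data.frame(
    name = c(paste0(donor_element, "D"), "HD",
             paste0(acceptor_element, "A")),
    element = c(donor_element, "H", acceptor_element),
    resname = c("LIG", "LIG", "MET"), resid = c(1L, 1L, 374L),
    stringsAsFactors = FALSE)
  top <- topology(atoms, hydrogens = list(`1` = 2L))
  list(topology = top, frame = frame(xyz), donor = 1L, hydrogen = 2L,
       acceptor = 3L)
}

#' Two labeled hexagonal rings with an exact (theta, d, offset) geometry
#'
#' Ring B lies in the xy-plane at the origin (normal +z); ring A's
#' centroid sits at `(lateral_offset, 0, d)` with its plane tilted by
#' `theta` about the x-axis, so [pi_pi_descriptor()] on (`ring_a`,
#' `ring_b`) returns exactly the requested values.
#'
#' @param theta interplanar angle, degrees in \[0, 90\].
#' @param d perpendicular centroid-to-plane distance, Angstrom.
#' @param lateral_offset in-plane slip, Angstrom.
#' @param labels length-2 ring labels.
#' @return list `topology`, `frame`, `ring_a`, `ring_b`.
#' @export
make_ring_pair <- function(theta, d, lateral_offset = 0,
                           labels = c("alpha", "HEM-porphyrin")) {
  if (theta < 0 || theta > 90) stop("theta must lie in [0, 90] degrees")
  hexB <- .hexagon()
  hexA <- .hexagon() %*% t(.rot_x(theta))
  hexA <- sweep(hexA, 2, c(lateral_offset, 0, d), `+`)
  xyz <- rbind(hexA, hexB)
  atoms <- data.frame(
    name = paste0("C", 1:12), element = "C",
    resname = rep(c("LIG", "HEM"), each = 6),
    resid = rep(c(1L, 600L), each = 6), stringsAsFactors = FALSE)
  ra <- ring_spec(labels[1], 1:6)
  rb <- ring_spec(labels[2], 7:12)
  top <- topology(atoms, rings = stats::setNames(list(ra, rb), labels))
  list(topology = top, frame = frame(xyz), ring_a = ra, ring_b = rb)
}

# static pocket geometry shared by the bridge and toy-complex fixtures:
# ligand hydroxyl at the origin, LEU-372 carbonyl on +x, the water-bridge
# arm along -y towards a MET-374 amide.
.bridge_layout <- function() {
  list(
    O_L  = c(0, 0, 0),          # ligand hydroxyl oxygen (bridge acceptor)
    Sn   = c(-1.9, 0, 0),
    H_on = c(0.97, 0, 0),       # hydroxyl H pointing at LEU-372 O
    H_off = 0.97 * .unit(c(-0.3, 0.75, -0.55)),
    LEU_O = c(2.97, 0, 0), LEU_C = c(4.25, 0, 0), LEU_CA = c(5.6, 0.9, 0),
    W_O  = c(0, -2.85, 0),      # bridging water oxygen
    W_H1 = c(0, -1.89, 0),      # donates to the ligand hydroxyl O
    W_H2 = c(0.90, -3.18, 0),
    MET_N = c(0, -5.86, 0), MET_H = c(0, -4.86, 0),
    MET_CA = c(1.2, -7.0, 0), MET_C = c(0.5, -8.3, 0.4),
    MET_O = c(-0.6, -8.6, 0.4),
    park1 = c(0, -2.85, 9),     # bulk parking spots for the bridge waters
    park2 = c(3.5, -2.85, 9))
}

.water_block <- function(origin) {
  rbind(origin, origin + c(0.96, 0, 0), origin + c(-0.24, 0.93, 0))
}

#' Trajectory with a planted ligand-water-protein bridge
#'
#' A hydroxyl-bearing tin ligand, two waters, and a MET-374-like amide.
#' In a Bernoulli(`p`) subset of frames a water occupies the bridging
#' position (ligand-OH...H2O...HN-MET motif, donor-acceptor distances
#' 2.85 and 3.01 A); otherwise it is parked in the bulk.  At each frame
#' listed in `exchange_frames` the identity of the bridging water swaps
#' with its partner while the geometry persists.
#'
#' @param n_frames number of frames.
#' @param p bridge occupancy probability in \[0, 1\].
#' @param exchange_frames integer frame numbers at which the bridging
#'   water identity swaps.
#' @param seed RNG seed.
#' @param dt sampling interval, ps.
#' @return trajectory with a `"sites"` attribute (`ligand_O`,
#'   `protein_N`, `water_atoms`, `water_resids`).
#' @export
make_bridge_trajectory <- function(n_frames, p = 1, exchange_frames = integer(0),
                                   seed = 1, dt = 10) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  L <- .bridge_layout()
  atoms <- data.frame(
    name =    c("SN", "O1", "HO1", "O", "C", "CA", "N", "H", "CA", "C", "O",
                rep(c("OW", "HW1", "HW2"), 2)),
    element = c("Sn", "O", "H", "O", "C", "C", "N", "H", "C", "C", "O",
                rep(c("O", "H", "H"), 2)),
    resname = c(rep("TBT", 3), rep("LEU", 3), rep("MET", 5),
                rep("HOH", 6)),
    resid = c(rep(1L, 3), rep(372L, 3), rep(374L, 5),
              rep(c(501L, 502L), each = 3)),
    stringsAsFactors = FALSE)
  fixed <- rbind(L$Sn, L$O_L, L$H_off, L$LEU_O, L$LEU_C, L$LEU_CA,
                 L$MET_N, L$MET_H, L$MET_CA, L$MET_C, L$MET_O)
  set.seed(seed)
  present <- stats::runif(n_frames) < p
  frames <- vector("list", n_frames)
  bridging <- 1L   # which of the two waters currently occupies the bridge
  for (i in seq_len(n_frames)) {
    if (i %in% exchange_frames) bridging <- 3L - bridging
    wpos <- vector("list", 2)
    bridge_block <- if (present[i]) rbind(L$W_O, L$W_H1, L$W_H2) else
      .water_block(L$park1 + c(0, 0, 3))
    wpos[[bridging]] <- bridge_block
    wpos[[3L - bridging]] <- .water_block(L$park2)
    xyz <- rbind(fixed, wpos[[1]], wpos[[2]])
    frames[[i]] <- frame(xyz, box = c(40, 40, 40), time = (i - 1) * dt)
  }
  top <- topology(atoms)
  top <- infer_hydrogens(top, frames[[which(present)[1] %||% 1]])
  traj <- trajectory(top, frames)
  attr(traj, "sites") <- list(ligand_O = 2L, protein_N = 7L,
                              water_atoms = 12:17,
                              water_resids = c(501L, 502L),
                              present = present)
  traj
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Ideal-gas trajectory (uniform independent positions)
#'
#' @param natoms number of atoms (>= 2).
#' @param box cubic box edge, Angstrom.
#' @param nframes number of frames.
#' @param seed RNG seed.
#' @return trajectory of non-interacting "AR" atoms.
#' @export
make_ideal_gas <- function(natoms, box = 30, nframes = 100, seed = 1) {
  if (natoms < 2) stop("need at least 2 atoms")
  set.seed(seed)
  atoms <- data.frame(name = "AR", element = "Ar", resname = "GAS",
                      resid = seq_len(natoms), stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nframes), function(i)
    frame(matrix(stats::runif(3 * natoms, 0, box), ncol = 3),
          box = rep(box, 3), time = i - 1))
  trajectory(topology(atoms), frames)
}

#' Ring plus a first solvation shell at an exact radius
#'
#' A hexagonal ring at the centre of the box, `n_shell` target atoms on
#' the hemisphere above the ring at exactly `shell_radius` from its
#' centroid (random directions each frame), and a uniform background of
#' targets at `background_density`.
#'
#' @param shell_radius shell distance, Angstrom (> 0).
#' @param n_shell atoms in the shell.
#' @param background_density bulk target density, A^-3.
#' @param box cubic box edge, Angstrom.
#' @param nframes number of frames.
#' @param seed RNG seed.
#' @return trajectory with a `"ring"` attribute ([ring_spec()]) and a
#'   `"targets"` attribute (target atom indices).
#' @export
make_shell_fixture <- function(shell_radius = 2.3, n_shell = 12,
                               background_density = 0.005, box = 30,
                               nframes = 100, seed = 1) {
  if (shell_radius <= 0) stop("shell_radius must be positive")
  set.seed(seed)
  ctr <- rep(box / 2, 3)
  hex <- sweep(.hexagon(), 2, ctr, `+`)
  n_bg <- max(0L, round(background_density * box^3))
  n_t <- n_shell + n_bg
  atoms <- data.frame(
    name = c(paste0("C", 1:6), rep("OW", n_t)),
    element = c(rep("C", 6), rep("O", n_t)),
    resname = c(rep("RNG", 6), rep("HOH", n_t)),
    resid = c(rep(1L, 6), seq_len(n_t) + 100L), stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nframes), function(i) {
    # hemisphere above the ring (+z), exact radius
    u <- stats::runif(n_shell); v <- stats::runif(n_shell)
    cosphi <- u                       # z >= 0
    sinphi <- sqrt(1 - cosphi^2)
    th <- 2 * pi * v
    shell <- cbind(sinphi * cos(th), sinphi * sin(th), cosphi) * shell_radius
    shell <- sweep(shell, 2, ctr, `+`)
    bg <- matrix(stats::runif(3 * n_bg, 0, box), ncol = 3)
    frame(rbind(hex, shell, bg), box = rep(box, 3), time = i - 1)
  })
  traj <- trajectory(topology(atoms), frames)
  attr(traj, "ring") <- ring_spec("phenyl", 1:6)
  attr(traj, "targets") <- 7L:(6L + n_t)
  traj
}

# scale a displacement field so the Kabsch-aligned RMSD from `base`
# equals `target` (bisection; rmsd is monotone in the scale here)
.scale_to_rmsd <- function(base, disp, target) {
  f <- function(s) .fit_rmsd(base, base + s * disp)
  lo <- 0; hi <- 1
  while (f(hi) < target) hi <- hi * 2
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  base + (lo + hi) / 2 * disp
}

#' Two-state trajectory for clustering tests
#'
#' Frames jitter around conformation A before `switch_frame` and around
#' conformation B from `switch_frame` on; the Kabsch-aligned RMSD
#' between the two reference conformations is exactly `inter_gap`, and
#' within-state jitter is scaled so typical intra-state RMSDs are about
#' `intra_spread`.
#'
#' @param n_frames total frames.
#' @param intra_spread typical within-state pairwise RMSD, Angstrom.
#' @param inter_gap between-state RMSD, Angstrom.
#' @param switch_frame first frame of state B.
#' @param natoms atoms per frame.
#' @param seed RNG seed.
#' @return trajectory with a `"state"` attribute (1/2 per frame).
#' @export
make_two_state_trajectory <- function(n_frames = 40, intra_spread = 0.5,
                                      inter_gap = 3.0, switch_frame = 21,
                                      natoms = 10, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(3 * natoms, sd = 3), ncol = 3)
  disp <- matrix(stats::rnorm(3 * natoms), ncol = 3)
  B <- .scale_to_rmsd(A, disp, inter_gap)
  sd_j <- intra_spread / sqrt(6)   # two jittered copies differ by ~sqrt(6)*sd
  atoms <- data.frame(name = paste0("C", seq_len(natoms)), element = "C",
                      resname = "MOL", resid = 1L, stringsAsFactors = FALSE)
  frames <- lapply(seq_len(n_frames), function(i) {
    base <- if (i < switch_frame) A else B
    frame(base + matrix(stats::rnorm(3 * natoms, sd = sd_j), ncol = 3),
          time = (i - 1) * 10)
  })
  traj <- trajectory(topology(atoms), frames)
  attr(traj, "state") <- ifelse(seq_len(n_frames) < switch_frame, 1L, 2L)
  traj
}

#' Gaussian interaction-energy series
#'
#' i.i.d. normal fluctuations of width `sigma` about zero; the
#' interaction-entropy closed form for such a series is
#' `sigma^2 / (2 kB T)`.
#'
#' @param sigma fluctuation width, kJ/mol.
#' @param n series length.
#' @param seed RNG seed.
#' @param temperature K.
#' @return an `"energy_series"`.
#' @export
make_gaussian_energy_series <- function(sigma, n, seed = 1,
                                        temperature = 298.15) {
  set.seed(seed)
  structure(list(E_int = stats::rnorm(n, 0, sigma), E_vdW = numeric(n),
                 E_Coul = numeric(n), temperature = temperature,
                 times = seq_len(n) - 1),
            class = "energy_series")
}

#' Five-residue pocket plus tin ligand: the end-to-end toy complex
#'
#' A synthetic binding pocket (MET-374 amide, LEU-372 carbonyl, a
#' TRP-224-like aromatic ring, ALA-306 and THR-310 stubs), a tin-centred
#' ligand with a hydroxyl, one phenyl ring and butyl-like chains, and 20
#' waters.  Planted ground truth, independent per feature:
#' a hydroxyl-to-LEU-372 hydrogen bond in a Bernoulli(`hbond_p`) subset
#' of frames; a water bridge (ligand-O...H2O...HN-MET-374) in a
#' Bernoulli(`bridge_p`) subset; a T-shaped phenyl/TRP ring contact
#' (theta ~ 85 deg) in every frame.  All charges/LJ parameters come from
#' the returned synthetic parameter table (ligand net charge 0).
#'
#' @param seed RNG seed.
#' @param n_frames frames in the trajectory.
#' @param hbond_p planted hydrogen-bond occupancy.
#' @param bridge_p planted water-bridge occupancy.
#' @param exchange_frames frames at which the bridging water swaps
#'   identity.
#' @param dt sampling interval, ps.
#' @return list: `topology` (parameterized, hydrogens populated),
#'   `trajectory`, `parameter_table`, `sites` (named indices), `rings`,
#'   and the planted truth in `planted`.
#' @export
make_toy_complex <- function(seed = 1, n_frames = 400, hbond_p = 0.5,
                             bridge_p = 0.7, exchange_frames = integer(0),
                             dt = 10) {
  L <- .bridge_layout()
  set.seed(seed)

  lig_names <- c("SN", "O1", "HO1", paste0("CR", 1:6), paste0("CB", 1:4))
  lig_elem  <- c("Sn", "O", "H", rep("C", 10))
  trp_ring_ctr <- c(-1.9, 0, 7.5)
  lig_ring_ctr <- c(-1.9, 0, 3.0)
  butyl <- rbind(c(-3.0, 1.3, -0.4), c(-4.3, 2.1, 0.1),
                 c(-3.0, -1.3, -0.4), c(-4.3, -2.1, 0.1))

  atoms <- data.frame(
    name = c(lig_names,
             "O", "C", "CA",                  # LEU-372
             "N", "H", "CA", "C", "O",        # MET-374
             paste0("CW", 1:6),               # TRP-224 ring
             "N", "H", "CA",                  # ALA-306
             "OG1", "HG1", "CA",              # THR-310
             rep(c("OW", "HW1", "HW2"), 20)),
    element = c(lig_elem,
                "O", "C", "C",
                "N", "H", "C", "C", "O",
                rep("C", 6),
                "N", "H", "C",
                "O", "H", "C",
                rep(c("O", "H", "H"), 20)),
    resname = c(rep("TPT", 13), rep("LEU", 3), rep("MET", 5),
                rep("TRP", 6), rep("ALA", 3), rep("THR", 3),
                rep("HOH", 60)),
    resid = c(rep(1L, 13), rep(372L, 3), rep(374L, 5), rep(224L, 6),
              rep(306L, 3), rep(310L, 3), rep(501:520, each = 3)),
    stringsAsFactors = FALSE)

  sites <- list(Sn = 1L, ligand_O = 2L, ligand_H = 3L, ligand_ring = 4:9,
                butyl = 10:13, LEU_O = 14L, MET_N = 17L, MET_H = 18L,
                trp_ring = 22:27, ALA_N = 28L, THR_OG1 = 31L,
                water_atoms = 34:93, water_resids = 501:520,
                bridge_waters = c(501L, 502L))
  rings <- list(
    alpha = ring_spec("alpha", sites$ligand_ring),
    `TRP-224-indole` = ring_spec("TRP-224-indole", sites$trp_ring))

  trp_hex <- sweep(.hexagon(), 2, trp_ring_ctr, `+`)
  ala <- rbind(c(-5, -4.5, -3.5), c(-4.2, -3.9, -3.5), c(-6.3, -5.2, -3.6))
  thr <- rbind(c(4.5, -4, 3), c(4.0, -3.2, 3.1), c(5.8, -4.6, 3.2))
  # bulk waters 503..520 on an outer shell, fixed base positions
  nbulk <- 18
  dirs <- matrix(stats::rnorm(3 * nbulk), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  bulk_base <- dirs * stats::runif(nbulk, 9.5, 12)

  hb_on <- stats::runif(n_frames) < hbond_p
  br_on <- stats::runif(n_frames) < bridge_p
  theta_jit <- pmin(90, pmax(75, 85 + stats::rnorm(n_frames, 0, 2)))

  frames <- vector("list", n_frames)
  bridging <- 1L
  for (i in seq_len(n_frames)) {
    if (i %in% exchange_frames) bridging <- 3L - bridging
    lig_ring <- .hexagon() %*% t(.rot_x(theta_jit[i]))
    lig_ring <- sweep(lig_ring, 2, lig_ring_ctr, `+`)
    lig <- rbind(L$Sn, L$O_L, if (hb_on[i]) L$H_on else L$H_off,
                 lig_ring, butyl)
    wpos <- vector("list", 2)
    bridge_block <- if (br_on[i]) rbind(L$W_O, L$W_H1, L$W_H2) else
      .water_block(L$park1)
    wpos[[bridging]] <- bridge_block
    wpos[[3L - bridging]] <- .water_block(L$park2)
    bulk <- bulk_base + matrix(stats::rnorm(3 * nbulk, sd = 0.05), ncol = 3)
    waters <- rbind(wpos[[1]], wpos[[2]],
                    do.call(rbind, lapply(seq_len(nbulk), function(k)
                      .water_block(bulk[k, ]))))
    xyz <- rbind(lig, L$LEU_O, L$LEU_C, L$LEU_CA,
                 L$MET_N, L$MET_H, L$MET_CA, L$MET_C, L$MET_O,
                 trp_hex, ala, thr, waters)
    frames[[i]] <- frame(xyz, box = c(40, 40, 40), time = (i - 1) * dt)
  }

  params <- toy_parameter_table()
  top <- topology(atoms, rings = rings)
  top <- infer_hydrogens(top, frames[[which(hb_on)[1] %||% 1]])
  # hydroxyl H follows the O even in "off" frames; bind it explicitly
  top$hydrogens[["2"]] <- 3L
  top <- assign_parameters(top, params)
  traj <- trajectory(top, frames)
  list(topology = top, trajectory = traj, parameter_table = params,
       sites = sites, rings = rings,
       planted = list(hbond_p = hbond_p, bridge_p = bridge_p,
                      hb_on = hb_on, br_on = br_on,
                      theta = theta_jit, r_cen = 4.5))
}

#' Synthetic parameter table for the toy complex
#'
#' TIP3P-like waters; small fixed charges elsewhere with the ligand
#' summing to net charge 0.  Purely synthetic values (no published
#' force field is reproduced).
#'
#' @return data.frame in [assign_parameters()] layout.
#' @export
toy_parameter_table <- function() {
  row <- function(res, name, q, s, e)
    data.frame(residue_name = res, atom_name = name, charge_e = q,
               sigma_A = s, epsilon_kJmol = e, stringsAsFactors = FALSE)
  rbind(
    row("HOH", "OW", -0.834, 3.1507, 0.6364),
    row("HOH", "HW1", 0.417, 0.40, 0.1923),
    row("HOH", "HW2", 0.417, 0.40, 0.1923),
    row("TPT", "SN", 0.40, 3.98, 2.20),
    row("TPT", "O1", -0.60, 3.00, 0.71),
    row("TPT", "HO1", 0.20, 0.40, 0.19),
    do.call(rbind, lapply(paste0("CR", 1:6), function(n)
      row("TPT", n, 0.0, 3.40, 0.36))),
    do.call(rbind, lapply(paste0("CB", 1:4), function(n)
      row("TPT", n, 0.0, 3.40, 0.46))),
    row("TBT", "SN", 0.40, 3.98, 2.20),
    row("TBT", "O1", -0.60, 3.00, 0.71),
    row("TBT", "HO1", 0.20, 0.40, 0.19),
    row("LEU", "O", -0.57, 2.96, 0.88),
    row("LEU", "C", 0.60, 3.40, 0.36),
    row("LEU", "CA", -0.03, 3.40, 0.46),
    row("MET", "N", -0.42, 3.25, 0.71),
    row("MET", "H", 0.27, 0.60, 0.065),
    row("MET", "CA", 0.02, 3.40, 0.46),
    row("MET", "C", 0.60, 3.40, 0.36),
    row("MET", "O", -0.57, 2.96, 0.88),
    do.call(rbind, lapply(paste0("CW", 1:6), function(n)
      row("TRP", n, -0.01, 3.40, 0.36))),
    row("ALA", "N", -0.42, 3.25, 0.71),
    row("ALA", "H", 0.27, 0.60, 0.065),
    row("ALA", "CA", 0.15, 3.40, 0.46),
    row("THR", "OG1", -0.55, 3.07, 0.88),
    row("THR", "HG1", 0.40, 0.40, 0.19),
    row("THR", "CA", 0.15, 3.40, 0.46))
}

#' Van der Waals radii by element for SASA calculations
#' @return named numeric vector, Angstrom.
#' @export
default_vdw_radii <- function() {
  c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, S = 1.8, Sn = 2.17, Fe = 2.0,
    Ar = 1.88, Cl = 1.75, Na = 2.27)
}
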