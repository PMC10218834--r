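# Hydrogen bonds, X-H...pi contacts, pi-pi classification, and
# water-mediated bridge networks.

#' Default hydrogen-bond criteria
#'
#' Geometric criteria: an event requires an acceptor...H distance strictly
#' below `d_cut` and a donor-H...acceptor angle strictly above
#' `angle_cut`.  The pi-bond variants use an H-to-ring-centroid distance
#' cutoff and an approach cone about the ring normal.
#'
#' @param d_cut acceptor...H distance cutoff, Angstrom.
#' @param angle_cut donor-H...acceptor angle cutoff, degrees.
#' @param d_cut_h_pi H...ring-centroid cutoff for pi acceptors, Angstrom.
#' @param approach_angle_cut maximal angle between the H->centroid vector
#'   and the ring normal, degrees.
#' @return list of criteria passed to the detection functions.
#' @export
hbond_criteria <- function(d_cut = 2.5, angle_cut = 120,
                           d_cut_h_pi = 3.0, approach_angle_cut = 30) {
  list(d_cut = d_cut, angle_cut = angle_cut, d_cut_h_pi = d_cut_h_pi,
       approach_angle_cut = approach_angle_cut)
}

.angle_deg <- function(u, v) {
  c_ <- sum(u * v) / (.vnorm(u) * .vnorm(v))
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' Detect hydrogen bonds in one frame
#'
#' Scans every donor heavy atom (with its bound hydrogens) against every
#' acceptor; an event is recorded when distance(acceptor, H) < `d_cut`
#' and angle(donor, H, acceptor) > `angle_cut`, with minimum-image
#' distances when the frame has a box.  Acceptors are restricted to the
#' elements in `acceptor_elements` (O and N by default).
#'
#' @param fr frame.
#' @param top topology with `hydrogens` populated (see
#'   [infer_hydrogens()]).
#' @param donors atom indices of candidate donor heavy atoms; those
#'   without bound hydrogens are skipped with a warning.
#' @param acceptors atom indices of candidate acceptors.
#' @param criteria [hbond_criteria()].
#' @param acceptor_elements elements allowed as acceptors.
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (possibly 0 rows).
#' @export
detect_hbonds <- function(fr, top, donors, acceptors,
                          criteria = hbond_criteria(),
                          acceptor_elements = c("O", "N")) {
  acceptors <- acceptors[top$atoms$element[acceptors] %in% acceptor_elements]
  out <- list()
  skipped <- 0L
  for (d in donors) {
    hs <- bound_hydrogens(top, d)
    if (!length(hs)) { skipped <- skipped + 1L; next }
    acc <- setdiff(acceptors, c(d, hs))
    if (!length(acc)) next
    for (h in hs) {
      dv <- min_image(sweep(fr$xyz[acc, , drop = FALSE], 2, fr$xyz[h, ]),
                      fr$box)
      dist <- sqrt(rowSums(dv^2))
      cand <- which(dist < criteria$d_cut)
      for (k in cand) {
        hd <- min_image(rbind(fr$xyz[d, ] - fr$xyz[h, ]), fr$box)[1, ]
        ang <- .angle_deg(hd, dv[k, ])
        if (ang > criteria$angle_cut)
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = h, acceptor = acc[k],
            distance = dist[k], angle = ang)
      }
    }
  }
  if (skipped)
    warning(skipped, " donor atom(s) without bound hydrogens skipped")
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  do.call(rbind, out)
}

#' Detect X-H...pi hydrogen bonds against aromatic rings
#'
#' An event is recorded when a donor hydrogen sits within `d_cut_h_pi` of
#' a ring centroid and the H->centroid vector lies within
#' `approach_angle_cut` of the ring normal (acute fold; the normal's sign
#' is arbitrary).
#'
#' @inheritParams detect_hbonds
#' @param rings named list of [ring_spec()] acceptors.
#' @return data.frame `donor`, `hydrogen`, `acceptor` (ring label),
#'   `distance`, `angle` (approach angle).
#' @export
detect_pi_hbonds <- function(fr, top, donors, rings,
                             criteria = hbond_criteria()) {
  out <- list()
  geoms <- lapply(rings, function(r) ring_geometry(fr, r))
  for (d in donors) {
    hs <- bound_hydrogens(top, d)
    for (h in hs) {
      for (ri in seq_along(rings)) {
        g <- geoms[[ri]]
        dv <- min_image(rbind(g$centroid - fr$xyz[h, ]), fr$box)[1, ]
        dist <- .vnorm(dv)
        if (dist >= criteria$d_cut_h_pi) next
        app <- .angle_deg(dv, g$normal)
        app <- min(app, 180 - app)
        if (app < criteria$approach_angle_cut)
          out[[length(out) + 1L]] <- data.frame(
            donor = d, hydrogen = h, acceptor = rings[[ri]]$label,
            distance = dist, angle = app, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Bond-forming probability between a donor and an acceptor site
#'
#' The fraction of trajectory frames containing at least one qualifying
#' hydrogen-bond event between the two sites.  Because a reported mean
#' geometry can be read either way, both conditional means (over
#' qualifying frames) and unconditional means (closest H over all frames)
#' are returned.
#'
#' @param traj trajectory.
#' @param donor_site donor heavy-atom index.
#' @param acceptor_site acceptor atom index.
#' @param criteria [hbond_criteria()].
#' @return list: `probability`, `mean_distance`, `mean_angle` (qualifying
#'   frames; `NaN` when never formed), `mean_distance_all`,
#'   `mean_angle_all` (all frames, closest hydrogen).
#' @export
bond_forming_probability <- function(traj, donor_site, acceptor_site,
                                     criteria = hbond_criteria()) {
  if (!n_frames(traj)) stop("empty trajectory")
  top <- traj$topology
  hits <- logical(n_frames(traj))
  dist_hit <- ang_hit <- dist_all <- ang_all <- numeric(0)
  for (i in seq_len(n_frames(traj))) {
    ev <- detect_hbonds(traj$frames[[i]], top, donor_site, acceptor_site,
                        criteria)
    hits[i] <- nrow(ev) > 0
    if (nrow(ev)) {
      dist_hit <- c(dist_hit, min(ev$distance))
      ang_hit <- c(ang_hit, ev$angle[which.min(ev$distance)])
    }
    # unconditional geometry: closest bound hydrogen, no thresholds
    fr <- traj$frames[[i]]
    hs <- bound_hydrogens(top, donor_site)
    if (length(hs)) {
      dv <- min_image(fr$xyz[rep(acceptor_site, length(hs)), , drop = FALSE] -
                        fr$xyz[hs, , drop = FALSE], fr$box)
      dd <- sqrt(rowSums(dv^2))
      k <- which.min(dd)
      dist_all <- c(dist_all, dd[k])
      hd <- min_image(rbind(fr$xyz[donor_site, ] - fr$xyz[hs[k], ]), fr$box)[1, ]
      ang_all <- c(ang_all, .angle_deg(hd, dv[k, ]))
    }
  }
  list(probability = mean(hits),
       mean_distance = mean(dist_hit), mean_angle = mean(ang_hit),
       mean_distance_all = mean(dist_all), mean_angle_all = mean(ang_all))
}

#' Classify a ring-pair descriptor as T-shaped, stacked, or intermediate
#'
#' Categories partition descriptor space: `NONE` beyond `r_cen_max`;
#' `T_SHAPED` for near-perpendicular planes (`theta >= t_theta_min`);
#' `STACKED` for near-parallel planes within `d_max`; everything else
#' `INTERMEDIATE`.
#'
#' @param desc descriptor from [pi_pi_descriptor()].
#' @param t_theta_min minimal interplanar angle for T-shaped, degrees.
#' @param s_theta_max maximal angle for stacked, degrees.
#' @param r_cen_max maximal centroid distance for any contact, Angstrom.
#' @param d_max maximal perpendicular offset for stacked, Angstrom.
#' @return one of `"T_SHAPED"`, `"STACKED"`, `"INTERMEDIATE"`, `"NONE"`.
#' @export
classify_pipi <- function(desc, t_theta_min = 60, s_theta_max = 30,
                          r_cen_max = 6.0, d_max = 5.0) {
  if (desc$r_cen > r_cen_max) return("NONE")
  if (desc$theta >= t_theta_min) return("T_SHAPED")
  if (desc$theta <= s_theta_max && desc$d <= d_max) return("STACKED")
  "INTERMEDIATE"
}

.water_of <- function(top, idx) {
  # water residue id for each atom index; NA for non-water atoms
  ifelse(top$atoms$resname[idx] %in% .WATER_RES, top$atoms$resid[idx], NA)
}

#' Find ligand-water-protein hydrogen-bond bridges in one frame
#'
#' Builds the frame's hydrogen-bond graph over the given ligand sites,
#' water molecules, and protein sites (rings given as [ring_spec()]
#' entries act as pi acceptors for water hydrogens), then enumerates all
#' simple paths ligand -> (1..`max_waters` waters) -> protein.
#'
#' @param fr frame.
#' @param top topology with hydrogens populated.
#' @param ligand_sites,protein_sites list whose elements are atom indices
#'   or [ring_spec()] objects.
#' @param waters atom indices of the water molecules considered.
#' @param criteria [hbond_criteria()].
#' @param max_waters maximal chain length (1 or 2).
#' @return list of bridges; each a list with `ligand_site`,
#'   `protein_site` (index or ring label), `waters` (ordered residue
#'   ids), and `events` (the supporting H-bond rows).
#' @export
find_water_bridges <- function(fr, top, ligand_sites, protein_sites, waters,
                               criteria = hbond_criteria(), max_waters = 2) {
  if (!is.list(ligand_sites)) ligand_sites <- as.list(ligand_sites)
  if (!is.list(protein_sites)) protein_sites <- as.list(protein_sites)
  site_key <- function(s) if (inherits(s, "ring_spec")) s$label else as.character(s)
  lkeys <- vapply(ligand_sites, site_key, character(1))
  pkeys <- vapply(protein_sites, site_key, character(1))

  site_atoms <- unlist(lapply(c(ligand_sites, protein_sites),
                              function(s) if (is.numeric(s)) s else NULL))
  rings <- Filter(function(s) inherits(s, "ring_spec"),
                  c(ligand_sites, protein_sites))
  names(rings) <- vapply(rings, `[[`, character(1), "label")

  wres <- unique(top$atoms$resid[waters])
  atoms_all <- unique(c(site_atoms, waters))
  ev <- suppressWarnings(
    detect_hbonds(fr, top, donors = atoms_all, acceptors = atoms_all,
                  criteria = criteria))
  pev <- if (length(rings))
    suppressWarnings(detect_pi_hbonds(fr, top, donors = waters,
                                      rings = rings, criteria = criteria))
  else NULL

  # collapse atoms to graph nodes: site keys or water residue ids ("w<id>")
  node_of <- function(a) {
    w <- .water_of(top, a)
    if (!is.na(w) && w %in% wres) return(paste0("w", w))
    if (as.character(a) %in% c(lkeys, pkeys)) return(as.character(a))
    NA_character_
  }
  edges <- list()  # name "n1|n2" -> list of event rows
  add_edge <- function(n1, n2, row) {
    if (is.na(n1) || is.na(n2) || n1 == n2) return()
    key <- paste(sort(c(n1, n2)), collapse = "|")
    edges[[key]] <<- c(edges[[key]], list(row))
  }
  if (nrow(ev)) for (i in seq_len(nrow(ev)))
    add_edge(node_of(ev$donor[i]), node_of(ev$acceptor[i]), ev[i, ])
  if (!is.null(pev) && nrow(pev)) for (i in seq_len(nrow(pev)))
    add_edge(node_of(pev$donor[i]), pev$acceptor[i], pev[i, ])

  has_edge <- function(n1, n2)
    !is.null(edges[[paste(sort(c(n1, n2)), collapse = "|")]])
  get_events <- function(n1, n2)
    edges[[paste(sort(c(n1, n2)), collapse = "|")]]

  bridges <- list()
  wnodes <- paste0("w", wres)
  for (li in seq_along(lkeys)) for (pi_ in seq_along(pkeys)) {
    L <- lkeys[li]; P <- pkeys[pi_]
    for (w1 in wnodes) {
      if (!has_edge(L, w1)) next
      if (has_edge(w1, P))
        bridges[[length(bridges) + 1L]] <- list(
          ligand_site = L, protein_site = P,
          waters = as.integer(sub("^w", "", w1)),
          events = c(get_events(L, w1), get_events(w1, P)))
      if (max_waters >= 2) for (w2 in setdiff(wnodes, w1)) {
        if (has_edge(w1, w2) && has_edge(w2, P))
          bridges[[length(bridges) + 1L]] <- list(
            ligand_site = L, protein_site = P,
            waters = as.integer(sub("^w", "", c(w1, w2))),
            events = c(get_events(L, w1), get_events(w1, w2),
                       get_events(w2, P)))
      }
    }
  }
  bridges
}

#' Occupancy and water-exchange statistics of a bridge pattern
#'
#' A pattern names the ligand site and the protein site; the identity of
#' the mediating water(s) is free.  Occupancy is the fraction of frames
#' with at least one matching bridge.  A water exchange is a transition
#' between consecutive frames where the pattern persists but the set of
#' mediating water residue ids changes.
#'
#' @param traj trajectory.
#' @param ligand_site,protein_site atom index or [ring_spec()].
#' @param waters water atom indices.
#' @param criteria [hbond_criteria()].
#' @param max_waters maximal chain length.
#' @return list: `occupancy`, `exchanges`, `per_frame` (logical vector).
#' @export
bridge_statistics <- function(traj, ligand_site, protein_site, waters,
                              criteria = hbond_criteria(), max_waters = 2) {
  top <- traj$topology
  nf <- n_frames(traj)
  present <- logical(nf)
  wsets <- vector("list", nf)
  for (i in seq_len(nf)) {
    b <- find_water_bridges(traj$frames[[i]], top, list(ligand_site),
                            list(protein_site), waters, criteria, max_waters)
    present[i] <- length(b) > 0
    if (present[i])
      wsets[[i]] <- sort(unique(unlist(lapply(b, `[[`, "waters"))))
  }
  exch <- 0L
  for (i in seq_len(nf - 1)) {
    if (present[i] && present[i + 1] && !identical(wsets[[i]], wsets[[i + 1]]))
      exch <- exch + 1L
  }
  list(occupancy = mean(present), exchanges = exch, per_frame = present)
}
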