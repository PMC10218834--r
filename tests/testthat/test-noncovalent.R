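# Hydrogen-bond and pi-interaction detection, bridges, probabilities.

test_that("geometric criteria are strict on both distance and angle", {
  fx <- make_hbond_fixture(2.04, 160)
  ev <- detect_hbonds(fx$frame, fx$topology, fx$donor, fx$acceptor)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.04, tolerance = 1e-9)
  expect_equal(ev$angle, 160, tolerance = 1e-9)
  cases <- list(c(2.49, 121, 1), c(2.51, 121, 0), c(2.6, 170, 0),
                c(2.0, 110, 0), c(2.0, 119.9, 0), c(2.0, 120.1, 1))
  for (cs in cases) {
    f <- make_hbond_fixture(cs[1], cs[2])
    expect_equal(nrow(detect_hbonds(f$frame, f$topology, 1L, 3L)), cs[3],
                 info = paste(cs, collapse = "/"))
  }
  # donors without hydrogens are skipped with a warning
  expect_warning(detect_hbonds(fx$frame, fx$topology, fx$acceptor, fx$donor),
                 "without bound hydrogens")
})

test_that("detection equals an all-pairs brute-force scan on random systems", {
  for (seed in 1:10) {
    sys <- random_hbond_system(seed, natoms = 50)
    got <- suppressWarnings(detect_hbonds(sys$frame, sys$topology, sys$donors, sys$acceptors))
    want <- oracle_hbond_scan(sys$frame, sys$topology, sys$donors,
                              sys$acceptors)
    key <- function(m) sort(apply(m, 1, paste, collapse = "-"))
    expect_equal(key(as.matrix(got[, 1:3])), key(want))
  }
})

test_that("detections are invariant under rigid motion and periodic shifts", {
  sys <- random_hbond_system(4, natoms = 40)
  base <- suppressWarnings(detect_hbonds(sys$frame, sys$topology, sys$donors, sys$acceptors))
  # rigid motion of a non-periodic copy (a rotation is not compatible
  # with a fixed orthorhombic lattice)
  nopbc <- frame(sys$frame$xyz)
  base_np <- suppressWarnings(detect_hbonds(nopbc, sys$topology, sys$donors,
                                            sys$acceptors))
  a <- 0.7
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  moved <- frame(sweep(nopbc$xyz %*% R, 2, c(2, -1, 3), `+`))
  got <- suppressWarnings(detect_hbonds(moved, sys$topology, sys$donors, sys$acceptors))
  expect_equal(got[, 1:3], base_np[, 1:3])
  expect_equal(got$distance, base_np$distance, tolerance = 1e-9)
  # shift one molecule by a full box vector: minimum image restores it
  shifted <- sys$frame$xyz
  mol <- c(1, sys$topology$hydrogens[["1"]])
  shifted[mol, 1] <- shifted[mol, 1] + sys$frame$box[1]
  got2 <- suppressWarnings(detect_hbonds(frame(shifted, box = sys$frame$box), sys$topology,
                        sys$donors, sys$acceptors))
  expect_equal(got2[, 1:3], base[, 1:3])
})

test_that("bond-forming probability counts qualifying frames", {
  frames <- lapply(1:10, function(i) {
    d <- if (i <= 2) 2.0 else 3.2
    f <- make_hbond_fixture(d, 160)
    f$frame$time <- (i - 1) * 10
    f$frame
  })
  fx <- make_hbond_fixture(2.0, 160)
  traj <- trajectory(fx$topology, frames)
  bp <- bond_forming_probability(traj, fx$donor, fx$acceptor)
  expect_equal(bp$probability, 0.2)
  expect_equal(bp$mean_distance, 2.0, tolerance = 1e-9)
  expect_equal(bp$mean_angle, 160, tolerance = 1e-9)
  # the unconditional mean distance averages over all frames
  expect_equal(bp$mean_distance_all, mean(c(2, 2, rep(3.2, 8))),
               tolerance = 1e-9)
  all_on <- trajectory(fx$topology, lapply(1:5, function(i) {
    f <- make_hbond_fixture(2.1, 150)$frame; f$time <- i; f
  }))
  expect_equal(bond_forming_probability(all_on, 1L, 3L)$probability, 1)
  expect_error(bond_forming_probability(
    trajectory(fx$topology, list()), 1L, 3L))
})

test_that("Bernoulli bond geometry is recovered at the planted rate", {
  set.seed(31)
  p <- 0.3; n <- 2000
  on <- runif(n) < p
  f_on <- make_hbond_fixture(2.0, 160)$frame
  f_off <- make_hbond_fixture(3.4, 160)$frame
  fx <- make_hbond_fixture(2.0, 160)
  frames <- lapply(1:n, function(i) {
    f <- if (on[i]) f_on else f_off; f$time <- i; f
  })
  bp <- bond_forming_probability(trajectory(fx$topology, frames), 1L, 3L)
  expect_equal(bp$probability, mean(on))
  expect_equal(bp$probability, p, tolerance = 0.03 / p)
})

test_that("X-H...pi detection needs both shell distance and approach cone", {
  st <- make_ring_pair(0, 3.5)
  hex_top <- st$topology
  place_h <- function(pos) {
    atoms <- rbind(hex_top$atoms[, c("name", "element", "resname", "resid")],
                   data.frame(name = c("OW", "HW1"), element = c("O", "H"),
                              resname = "HOH", resid = 900L))
    top <- topology(atoms, rings = hex_top$rings,
                    hydrogens = list(`13` = 14L))
    fr <- frame(rbind(st$frame$xyz, pos[1, , drop = FALSE], pos[2, , drop = FALSE]))
    detect_pi_hbonds(fr, top, donors = 13L, rings = list(st$ring_b))
  }
  # H 2.3 A above the centroid along the normal (O further out)
  on_axis <- rbind(c(0, 0, 3.26), c(0, 0, 2.3))
  expect_equal(nrow(place_h(on_axis)), 1)
  expect_equal(place_h(on_axis)$distance, 2.3, tolerance = 1e-9)
  # same distance but in-plane: approach angle 90, rejected
  in_plane <- rbind(c(3.26, 0, 0), c(2.3, 0, 0))
  expect_equal(nrow(place_h(in_plane)), 0)
  # on-axis but beyond the cutoff
  far <- rbind(c(0, 0, 4.46), c(0, 0, 3.5))
  expect_equal(nrow(place_h(far)), 0)
})

test_that("pi-pi categories partition descriptor space", {
  expect_equal(classify_pipi(list(r_cen = 4.72, d = 4.6, theta = 85)),
               "T_SHAPED")
  expect_equal(classify_pipi(list(r_cen = 4.21, d = 4.21, theta = 25)),
               "STACKED")
  expect_equal(classify_pipi(list(r_cen = 5.0, d = 4.0, theta = 45)),
               "INTERMEDIATE")
  expect_equal(classify_pipi(list(r_cen = 6.5, d = 4.0, theta = 85)), "NONE")
  set.seed(17)
  for (k in 1:200) {
    desc <- list(r_cen = runif(1, 0, 8), d = runif(1, 0, 8),
                 theta = runif(1, 0, 90))
    desc$d <- min(desc$d, desc$r_cen)
    cat_ <- classify_pipi(desc)
    expect_true(cat_ %in% c("T_SHAPED", "STACKED", "INTERMEDIATE", "NONE"))
  }
})

test_that("water bridges are found, and vanish without the water", {
  tr <- make_bridge_trajectory(1, p = 1, seed = 1)
  s <- attr(tr, "sites")
  fr <- tr$frames[[1]]
  b <- find_water_bridges(fr, tr$topology, list(s$ligand_O),
                          list(s$protein_N), s$water_atoms)
  expect_equal(length(b), 1)
  expect_equal(b[[1]]$waters, 501L)
  expect_equal(length(b[[1]]$events), 2)
  # removing the water (move it far away) kills the bridge
  gone <- fr$xyz
  gone[12:17, 3] <- gone[12:17, 3] + 15
  b2 <- find_water_bridges(frame(gone, box = fr$box), tr$topology,
                           list(s$ligand_O), list(s$protein_N), s$water_atoms)
  expect_length(b2, 0)
})

test_that("two interlinked waters bridge a ring acceptor to an amide donor", {
  # ring in the xy-plane; water-a H-bonds to the ring face, water-b links
  # water-a to an amide N-H
  hex <- make_ring_pair(0, 3.5)$frame$xyz[7:12, ]
  wa <- rbind(c(0, 0, 3.1), c(0, 0, 2.3), c(0.9, 0, 3.5))      # OW HW1 HW2
  wb <- rbind(c(0, 2.9, 3.4), c(0, 2.0, 3.3), c(0.5, 3.3, 4.2))
  nh <- rbind(c(0, 5.9, 3.5), c(0, 4.9, 3.45))                 # N, H
  atoms <- data.frame(
    name = c(paste0("C", 1:6), "OW", "HW1", "HW2", "OW", "HW1", "HW2",
             "N", "H"),
    element = c(rep("C", 6), "O", "H", "H", "O", "H", "H", "N", "H"),
    resname = c(rep("TPT", 6), rep("HOH", 6), "MET", "MET"),
    resid = c(rep(1L, 6), 501L, 501L, 501L, 502L, 502L, 502L, 374L, 374L))
  ring <- ring_spec("gamma", 1:6)
  top <- topology(atoms, rings = list(gamma = ring),
                  hydrogens = list(`7` = c(8L, 9L), `10` = c(11L, 12L),
                                   `13` = 14L))
  fr <- frame(rbind(hex, wa, wb, nh))
  b <- find_water_bridges(fr, top, list(ring), list(13L), waters = 7:12,
                          max_waters = 2)
  chains <- vapply(b, function(x) paste(x$waters, collapse = ","), "")
  expect_true("501,502" %in% chains)
  # with max_waters = 1 the two-water path disappears
  b1 <- find_water_bridges(fr, top, list(ring), list(13L), waters = 7:12,
                           max_waters = 1)
  expect_length(b1, 0)
})

test_that("bridge enumeration equals brute-force path enumeration", {
  for (seed in 1:10) {
    set.seed(seed)
    # random cluster of one ligand O-H, one protein N-H, 5 waters
    nw <- 5
    pos <- matrix(runif(3 * (2 + nw), 0, 7), ncol = 3)
    atoms <- data.frame(
      name = c("O1", "HO1", "N", "H", rep(c("OW", "HW1", "HW2"), nw)),
      element = c("O", "H", "N", "H", rep(c("O", "H", "H"), nw)),
      resname = c("TBT", "TBT", "MET", "MET", rep("HOH", 3 * nw)),
      resid = c(1L, 1L, 374L, 374L, rep(500L + seq_len(nw), each = 3)))
    xyz <- matrix(0, nrow(atoms), 3)
    xyz[1, ] <- pos[1, ]; xyz[3, ] <- pos[2, ]
    xyz[2, ] <- xyz[1, ] + c(0.97, 0, 0)
    xyz[4, ] <- xyz[3, ] + c(0, 0.99, 0)
    hmap <- list(`1` = 2L, `3` = 4L)
    for (w in seq_len(nw)) {
      o <- 4 + (w - 1) * 3 + 1
      xyz[o, ] <- pos[2 + w, ]
      xyz[o + 1, ] <- xyz[o, ] + c(0.96, 0, 0)
      xyz[o + 2, ] <- xyz[o, ] + c(-0.24, 0.93, 0)
      hmap[[as.character(o)]] <- c(o + 1L, o + 2L)
    }
    top <- topology(atoms, hydrogens = hmap)
    fr <- frame(xyz)
    got <- find_water_bridges(fr, top, list(1L), list(3L), waters = 5:(4 + 3 * nw))
    # oracle: brute-force H-bond scan -> node edges -> path loops
    ev <- oracle_hbond_scan(fr, top, donors = seq_len(nrow(atoms)),
                            acceptors = seq_len(nrow(atoms)))
    node <- function(a) {
      if (atoms$resname[a] == "HOH") paste0("w", atoms$resid[a])
      else as.character(a)
    }
    edges <- if (nrow(ev)) cbind(vapply(ev[, 1], node, ""),
                                 vapply(ev[, 3], node, "")) else
      matrix("", 0, 2)
    want <- oracle_bridge_paths(edges, "1", "3", paste0("w", 501:505))
    key <- function(l) sort(vapply(l, paste, "", collapse = ","))
    expect_equal(key(lapply(got, function(b) paste0("w", b$waters))),
                 key(want), info = paste("seed", seed))
  }
})

test_that("bridge occupancy and exchange statistics match construction", {
  tr <- make_bridge_trajectory(120, p = 1, exchange_frames = c(50, 100),
                               seed = 5)
  s <- attr(tr, "sites")
  bs <- bridge_statistics(tr, s$ligand_O, s$protein_N, s$water_atoms)
  expect_equal(bs$occupancy, 1)
  expect_equal(bs$exchanges, 2L)
  tr0 <- make_bridge_trajectory(30, p = 0, seed = 5)
  bs0 <- bridge_statistics(tr0, attr(tr0, "sites")$ligand_O,
                           attr(tr0, "sites")$protein_N,
                           attr(tr0, "sites")$water_atoms)
  expect_equal(bs0$occupancy, 0)
  expect_equal(bs0$exchanges, 0L)
})
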