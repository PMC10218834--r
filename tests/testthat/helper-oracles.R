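# Independent brute-force oracles, deliberately written without reusing
# the package's internals (plain loops, no minimum-image helper reuse).

oracle_wrap <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}

oracle_dist <- function(x1, x2, box = NULL) {
  d <- x2 - x1
  if (!is.null(box)) for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  sqrt(sum(d^2))
}

oracle_angle <- function(a, b, c, box = NULL) {
  # angle at b, degrees
  u <- a - b; v <- c - b
  if (!is.null(box)) {
    for (k in 1:3) {
      u[k] <- u[k] - box[k] * round(u[k] / box[k])
      v[k] <- v[k] - box[k] * round(v[k] / box[k])
    }
  }
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# all-pairs hydrogen-bond scan: triple loop over donors, their hydrogens,
# and acceptors
oracle_hbond_scan <- function(fr, top, donors, acceptors, d_cut = 2.5,
                              angle_cut = 120,
                              acceptor_elements = c("O", "N")) {
  hits <- list()
  for (d in donors) {
    hs <- top$hydrogens[[as.character(d)]]
    if (is.null(hs)) next
    for (h in hs) {
      for (a in acceptors) {
        if (a == d || a %in% hs) next
        if (!top$atoms$element[a] %in% acceptor_elements) next
        dist <- oracle_dist(fr$xyz[h, ], fr$xyz[a, ], fr$box)
        if (dist >= d_cut) next
        ang <- oracle_angle(fr$xyz[d, ], fr$xyz[h, ], fr$xyz[a, ], fr$box)
        if (ang > angle_cut)
          hits[[length(hits) + 1]] <- c(d, h, a)
      }
    }
  }
  if (!length(hits)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, hits)
}

# connected components by breadth-first search on the strict-< threshold
# graph
oracle_components <- function(m, cutoff) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in seq_len(n)) {
        if (is.na(comp[w]) && m[v, w] < cutoff) {
          comp[w] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# plain double-loop LJ + Coulomb (no combining-rule vectorisation)
oracle_lj_coulomb <- function(fr, sel_a, sel_b, top) {
  ke <- 1389.35458
  a <- top$atoms
  ev <- ec <- 0
  for (i in sel_a) for (j in sel_b) {
    r <- oracle_dist(fr$xyz[i, ], fr$xyz[j, ], fr$box)
    sij <- (a$sigma[i] + a$sigma[j]) / 2
    eij <- sqrt(a$epsilon[i] * a$epsilon[j])
    ev <- ev + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    ec <- ec + ke * a$charge[i] * a$charge[j] / r
  }
  c(E_vdW = ev, E_Coul = ec)
}

# enumerate ligand->water(s)->protein paths by explicit loops over an
# edge list supplied as a character matrix of node pairs
oracle_bridge_paths <- function(edges, lkey, pkey, wnodes, max_waters = 2) {
  has <- function(a, b) {
    any((edges[, 1] == a & edges[, 2] == b) |
          (edges[, 1] == b & edges[, 2] == a))
  }
  paths <- list()
  for (w1 in wnodes) {
    if (!has(lkey, w1)) next
    if (has(w1, pkey)) paths[[length(paths) + 1]] <- w1
    if (max_waters >= 2) for (w2 in setdiff(wnodes, w1)) {
      if (has(w1, w2) && has(w2, pkey))
        paths[[length(paths) + 1]] <- c(w1, w2)
    }
  }
  paths
}

# Kabsch-free minimised RMSD: Nelder-Mead over Euler angles from several
# starting points (translation removed by centring)
oracle_min_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rotmat <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(ang) sqrt(mean(rowSums((P0 %*% rotmat(ang) - Q0)^2)))
  starts <- as.matrix(expand.grid(a = c(0, pi / 2, pi, 3 * pi / 2),
                                  b = c(0, pi / 2, pi),
                                  c = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    o <- stats::optim(starts[s, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# least-squares plane fit by direct optimisation over the normal's
# spherical angles
oracle_plane_rms <- function(X) {
  X0 <- sweep(X, 2, colMeans(X))
  obj <- function(ang) {
    n <- c(sin(ang[1]) * cos(ang[2]), sin(ang[1]) * sin(ang[2]), cos(ang[1]))
    sqrt(mean((X0 %*% n)^2))
  }
  best <- Inf
  for (th in seq(0, pi, length.out = 13)) for (ph in seq(0, 2 * pi, length.out = 13)) {
    o <- stats::optim(c(th, ph), obj, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-12))
    best <- min(best, o$value)
  }
  best
}

# small random topology/frame of O, N, H atoms with hydrogens attached to
# a subset of heavies; used by the randomized-equivalence suites
random_hbond_system <- function(seed, natoms = 40, box = c(15, 15, 15)) {
  set.seed(seed)
  n_heavy <- ceiling(natoms / 2)
  n_h <- natoms - n_heavy
  elem <- c(sample(c("O", "N", "C"), n_heavy, replace = TRUE),
            rep("H", n_h))
  atoms <- data.frame(name = paste0(elem, seq_along(elem)), element = elem,
                      resname = "RND",
                      resid = seq_along(elem), stringsAsFactors = FALSE)
  xyz <- matrix(runif(3 * natoms, 0, box[1]), ncol = 3)
  # park each hydrogen ~1 A from a random heavy atom
  hosts <- sample(n_heavy, n_h, replace = TRUE)
  hmap <- list()
  for (k in seq_len(n_h)) {
    h <- n_heavy + k
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    xyz[h, ] <- xyz[hosts[k], ] + dir * 1.0
    hmap[[as.character(hosts[k])]] <- c(hmap[[as.character(hosts[k])]], h)
  }
  top <- topology(atoms, hydrogens = hmap)
  list(topology = top, frame = frame(xyz, box = box),
       donors = seq_len(n_heavy), acceptors = seq_len(n_heavy))
}
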