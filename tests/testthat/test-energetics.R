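# MM pair energies, interaction entropy, solvation surrogates,
# bookkeeping, decomposition, Ki conversion.

kB <- 0.008314462618

two_atom_system <- function(r, q1 = 0, q2 = 0, sigma = 3.0, eps = 0.5) {
  atoms <- data.frame(name = c("A1", "A2"), element = "C", resname = "XX",
                      resid = 1:2, charge = c(q1, q2), sigma = sigma,
                      epsilon = eps)
  list(top = topology(atoms), fr = frame(rbind(c(0, 0, 0), c(r, 0, 0))))
}

test_that("LJ minimum and Coulomb closed forms are exact", {
  s <- two_atom_system(2^(1 / 6) * 3.0, sigma = 3.0, eps = 0.5)
  e <- lj_coulomb_energy(s$fr, 1L, 2L, s$top)
  expect_equal(e$E_vdW, -0.5, tolerance = 1e-12)
  expect_equal(e$E_Coul, 0)
  s2 <- two_atom_system(13.8935458, q1 = 1, q2 = -1, eps = 0)
  e2 <- lj_coulomb_energy(s2$fr, 1L, 2L, s2$top)
  expect_equal(e2$E_Coul, -100, tolerance = 0.01 / 100)
  expect_error(lj_coulomb_energy(two_atom_system(0.05)$fr, 1L, 2L,
                                 two_atom_system(0.05)$top), "overlap")
})

test_that("pair energies equal a brute-force double loop on random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 10
    atoms <- data.frame(name = paste0("A", 1:n), element = "C",
                        resname = "XX", resid = 1:n,
                        charge = runif(n, -0.8, 0.8),
                        sigma = runif(n, 2.5, 3.5),
                        epsilon = runif(n, 0.1, 1))
    top <- topology(atoms)
    fr <- frame(matrix(runif(3 * n, 0, 10), ncol = 3), box = c(20, 20, 20))
    got <- lj_coulomb_energy(fr, 1:5, 6:10, top)
    want <- oracle_lj_coulomb(fr, 1:5, 6:10, top)
    expect_equal(got$E_vdW, unname(want["E_vdW"]), tolerance = 1e-9)
    expect_equal(got$E_Coul, unname(want["E_Coul"]), tolerance = 1e-9)
    # symmetry in selection order
    rev_ <- lj_coulomb_energy(fr, 6:10, 1:5, top)
    expect_equal(got$E_vdW, rev_$E_vdW, tolerance = 1e-12)
    expect_equal(got$E_Coul, rev_$E_Coul, tolerance = 1e-12)
    # Coulomb scales exactly linearly in q_i q_j
    top2 <- top; top2$atoms$charge <- top$atoms$charge * 2
    expect_equal(lj_coulomb_energy(fr, 1:5, 6:10, top2)$E_Coul,
                 4 * got$E_Coul, tolerance = 1e-9)
  }
})

test_that("energy series match per-frame calls and an analytic trajectory", {
  s <- two_atom_system(3.4, q1 = 0.3, q2 = -0.3)
  static <- trajectory(s$top, lapply(1:5, function(i) {
    f <- s$fr; f$time <- i; f
  }))
  es <- interaction_energy_series(static, 1L, 2L, s$top)
  expect_equal(length(unique(round(es$E_int, 12))), 1)
  # harmonic oscillation: E(t) must equal the closed form at r(t)
  r_t <- 3.4 + 0.3 * sin(2 * pi * (0:19) / 20)
  osc <- trajectory(s$top, lapply(seq_along(r_t), function(i)
    frame(rbind(c(0, 0, 0), c(r_t[i], 0, 0)), time = i)))
  es2 <- interaction_energy_series(osc, 1L, 2L, s$top)
  sig <- 3.0; eps <- 0.5; ke <- 1389.35458
  closed <- 4 * eps * ((sig / r_t)^12 - (sig / r_t)^6) +
    ke * 0.3 * (-0.3) / r_t
  expect_equal(es2$E_int, closed, tolerance = 1e-9)
})

test_that("interaction entropy: exact cases and the Gaussian closed form", {
  expect_equal(interaction_entropy(rep(42, 100))$minus_TdS, 0)
  kT <- kB * 298.15
  expect_equal(interaction_entropy(c(-10, 10))$minus_TdS,
               kT * log(cosh(10 / kT)), tolerance = 1e-9)
  # Gaussian: -TdS -> sigma^2/(2 kB T); modest n, generous MC band
  est <- interaction_entropy(make_gaussian_energy_series(5, 2e5, seed = 2))
  expect_equal(est$minus_TdS, 25 / (2 * kT), tolerance = 0.1)
  # non-negativity (Jensen) on arbitrary real series
  set.seed(19)
  for (k in 1:25) {
    x <- rnorm(50, sd = runif(1, 0.1, 5)) + runif(1, -100, 100)
    expect_gte(interaction_entropy(x)$minus_TdS, 0)
  }
  # log-sum-exp stability: huge fluctuations do not overflow
  expect_true(is.finite(interaction_entropy(c(-2000, 0, 2000))$minus_TdS))
  expect_error(interaction_entropy(1), "at least 2")
})

test_that("SASA matches sphere closed forms", {
  atoms1 <- data.frame(name = "S", element = "S", resname = "XX", resid = 1)
  f1 <- frame(rbind(c(0, 0, 0)))
  a <- sasa(f1, 1L, radii = 1.5)$total
  expect_equal(a, 4 * pi * 2.9^2, tolerance = 0.005)
  # two fully separated atoms: additivity
  f2 <- frame(rbind(c(0, 0, 0), c(50, 0, 0)))
  a2 <- sasa(f2, 1:2, radii = c(1.5, 1.2))$total
  expect_equal(a2, 4 * pi * (2.9^2 + 2.6^2), tolerance = 0.005)
  # atom caged inside a tight shell of large atoms is fully buried
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, 1, -1, -1, 1, 1, -1, -1),
                      c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  cage <- frame(rbind(c(0, 0, 0), dirs * 2.2))
  a3 <- sasa(cage, seq_len(15), radii = c(1.2, rep(2.0, 14)))
  expect_equal(unname(a3$per_atom[1]), 0)
  expect_error(sasa(f1, 1L, radii = NA_real_), "radius")
})

test_that("nonpolar solvation is the linear surface-area form", {
  expect_equal(nonpolar_solvation(100, 60, 40), -3.849)        # zero burial
  expect_equal(nonpolar_solvation(1000, 1500, 500, gamma = 0.0227,
                                  beta_const = 3.849),
               0.0227 * (-1000) - 3.849, tolerance = 1e-12)
  expect_equal(nonpolar_solvation(10, 500, 700, gamma = 0),
               -3.849)                                          # gamma = 0
})

test_that("GB surrogate reproduces the Born equation over radii 1-5 A", {
  topb <- topology(data.frame(name = "NA", element = "Na", resname = "ION",
                              resid = 1))
  f1 <- frame(rbind(c(0, 0, 0)))
  ke <- 1389.35458
  for (R in seq(1, 5, by = 0.5)) {
    got <- gb_polar_surrogate(f1, integer(0), 1L, born_radii = R, topb,
                              charges = 1)$G_ligand
    born <- -(ke / 2) * (1 - 1 / 80) / R
    expect_equal(got, born, tolerance = 1e-3)
  }
  # neutral system -> 0
  expect_equal(gb_polar_surrogate(f1, integer(0), 1L, born_radii = 2, topb,
                                  charges = 0)$G_ligand, 0)
  # two distant ions -> sum of self terms
  top2 <- topology(data.frame(name = c("NA", "CL"), element = c("Na", "Cl"),
                              resname = "ION", resid = 1:2))
  f2 <- frame(rbind(c(0, 0, 0), c(500, 0, 0)))
  got2 <- gb_polar_surrogate(f2, 1L, 2L, born_radii = c(2, 3), top2,
                             charges = c(1, -1))
  selfsum <- -(ke / 2) * (1 - 1 / 80) * (1 / 2 + 1 / 3)
  expect_equal(got2$G_complex, selfsum, tolerance = 1e-3 * abs(selfsum))
  expect_error(gb_polar_surrogate(f1, integer(0), 1L, born_radii = -1, topb,
                                  charges = 1), "Born")
})

test_that("the free-energy ledger identities hold to 1e-9", {
  fe <- mmpbsa_totals(-184.022, -18.402, 115.953, -21.718, 29.804)
  expect_equal(fe$dE_gas, fe$dE_vdW + fe$dE_Coul, tolerance = 1e-12)
  expect_equal(fe$dG_sol, fe$ddG_PB + fe$ddG_SA, tolerance = 1e-12)
  expect_equal(fe$dG_bind, fe$dE_gas + fe$minus_TdS + fe$dG_sol,
               tolerance = 1e-12)
  expect_equal(mmpbsa_totals(0, 0, 0, 0, 0)$dG_bind, 0)
  set.seed(23)
  for (k in 1:20) {
    v <- rnorm(5, sd = 100)
    fe <- mmpbsa_totals(v[1], v[2], v[3], v[4], v[5])
    expect_lt(abs(fe$dG_bind - (v[1] + v[2] + v[3] + v[4] + v[5])), 1e-9)
  }
})

test_that("per-residue decomposition conserves the total gas-phase energy", {
  tc <- make_toy_complex(seed = 6, n_frames = 4)
  top <- tc$topology
  lig <- select_atoms(top, "ligand and not water")
  rest <- setdiff(seq_len(n_atoms(top)), lig)
  dec <- per_residue_decomposition(tc$trajectory, lig, top)
  es <- interaction_energy_series(tc$trajectory, rest, lig, top)
  expect_equal(sum(dec$E_total), mean(es$E_int), tolerance = 1e-6)
  expect_equal(sum(dec$E_vdW) + sum(dec$E_Coul), sum(dec$E_total),
               tolerance = 1e-9)
  # a residue with all-zero charges contributes no Coulomb term
  top0 <- top
  top0$atoms$charge[top0$atoms$resid == 224] <- 0
  dec0 <- per_residue_decomposition(
    trajectory(top0, tc$trajectory$frames[1:2]), lig, top0)
  expect_equal(dec0$E_Coul[dec0$resid == 224], 0)
  # single-residue case: decomposition equals the total
  one <- per_residue_decomposition(tc$trajectory, lig, top,
                                   residue_ids = 372)
  e372 <- interaction_energy_series(tc$trajectory,
                                    which(top$atoms$resid == 372), lig, top)
  expect_equal(one$E_total, mean(e372$E_int), tolerance = 1e-9)
})

test_that("Ki converts to the printed experimental free energies", {
  expect_equal(ki_to_delta_g(50e-6), -25.52, tolerance = 0.005 / 25.52)
  expect_equal(ki_to_delta_g(0.53e-6), -37.24, tolerance = 0.005 / 37.24)
  expect_equal(ki_to_delta_g(1), 0)
  expect_error(ki_to_delta_g(-1), "positive")
})
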