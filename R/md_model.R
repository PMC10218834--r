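#' Construct a molecular topology
#'
#' A topology holds the static description of a system: one row per atom
#' (name, element, residue, chain, partial charge and Lennard-Jones
#' parameters), covalent bonds, aromatic-ring definitions, and the mapping
#' from donor heavy atoms to their bound hydrogens.  Coordinates live in
#' [frame()] objects; a topology plus an ordered list of frames forms a
#' [trajectory()].
#'
#' Atom indices are 1-based row numbers into `atoms`, following R
#' convention.  Partial charges are in elementary charge units, `sigma` in
#' Angstrom, `epsilon` in kJ/mol; unparameterised atoms carry `NA` and are
#' rejected by the energy routines.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid`, and optionally `chain`, `charge`, `sigma`, `epsilon`.
#' @param bonds two-column integer matrix of bonded atom index pairs, or
#'   `NULL`.
#' @param rings named list of [ring_spec()] objects.
#' @param hydrogens list mapping heavy-atom index (as character) to the
#'   integer indices of its covalently bound hydrogens; inferred lazily by
#'   [infer_hydrogens()] when absent.
#' @return object of class `"topology"`.
#' @export
topology <- function(atoms, bonds = NULL, rings = list(), hydrogens = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "resname", "resid")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$chain))   atoms$chain   <- "A"
  if (is.null(atoms$charge))  atoms$charge  <- NA_real_
  if (is.null(atoms$sigma))   atoms$sigma   <- NA_real_
  if (is.null(atoms$epsilon)) atoms$epsilon <- NA_real_
  atoms$index <- seq_len(n)
  bad <- which(!is.na(atoms$sigma) & atoms$sigma < 0)
  if (length(bad)) stop("negative lj sigma for atom(s) ", toString(bad))
  bad <- which(!is.na(atoms$epsilon) & atoms$epsilon < 0)
  if (length(bad)) stop("negative lj epsilon for atom(s) ", toString(bad))
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1L | bonds > n)) stop("bond indices out of range")
  }
  for (r in rings) {
    if (any(r$members < 1L | r$members > n))
      stop("ring '", r$label, "' references atoms outside the topology")
  }
  if (!is.null(hydrogens)) {
    hs <- unlist(hydrogens, use.names = FALSE)
    if (length(hs) && any(hs < 1L | hs > n))
      stop("bound_hydrogens reference atoms outside the topology")
  }
  structure(list(atoms = atoms, bonds = bonds, rings = rings,
                 hydrogens = hydrogens),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      length(x$rings), "ring(s)\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top topology object.
#' @return integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Define an aromatic ring by its member atoms
#'
#' @param label ring label used by the pi-interaction and RDF stages
#'   (e.g. `"alpha"`, `"HEM-porphyrin"`).
#' @param members integer vector (>= 3) of atom indices ordered around the
#'   ring.
#' @return object of class `"ring_spec"`.
#' @export
ring_spec <- function(label, members) {
  members <- as.integer(members)
  if (length(members) < 3) stop("a ring needs at least 3 member atoms")
  structure(list(label = label, members = members), class = "ring_spec")
}

#' Construct a coordinate frame
#'
#' @param xyz N x 3 numeric matrix of coordinates in Angstrom.
#' @param box optional length-3 vector of orthorhombic box edges, Angstrom.
#' @param time frame time in ps.
#' @return object of class `"frame"`.
#' @export
frame <- function(xyz, box = NULL, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an N x 3 matrix")
  storage.mode(xyz) <- "double"
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(box <= 0))
      stop("box must be 3 positive orthorhombic edge lengths (A)")
  }
  structure(list(xyz = xyz, box = box, time = as.numeric(time)),
            class = "frame")
}

#' Construct a trajectory
#'
#' @param top topology shared by every frame.
#' @param frames list of [frame()] objects with matching atom counts and
#'   non-decreasing times.
#' @param dt sampling interval in ps; inferred from frame times when `NULL`.
#' @return object of class `"trajectory"`.
#' @export
trajectory <- function(top, frames, dt = NULL) {
  stopifnot(inherits(top, "topology"), length(frames) >= 1)
  n <- n_atoms(top)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]$xyz) != n)
      stop("frame ", i, " has ", nrow(frames[[i]]$xyz),
           " atoms; topology has ", n)
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  if (is.null(dt)) {
    dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  }
  structure(list(topology = top, frames = frames, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames x", n_atoms(x$topology),
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory object.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Frame times of a trajectory
#' @param traj trajectory object.
#' @return numeric vector of times, ps.
#' @export
frame_times <- function(traj)
  vapply(traj$frames, function(f) f$time, numeric(1))

.infer_element <- function(name) {
  # PDB v3 convention: element is the alphabetic prefix of the atom name;
  # two-letter elements (Sn, Fe, Cl, Na) recognised explicitly.
  nm <- toupper(gsub("[^A-Za-z].*$", "", trimws(name)))
  two <- c(SN = "Sn", FE = "Fe", CL = "Cl", NA_ = "Na", MG = "Mg", ZN = "Zn",
           BR = "Br")
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    key <- substr(nm[i], 1, 2)
    if (key == "NA") key <- "NA_"
    if (key %in% names(two)) out[i] <- two[[key]]
    else out[i] <- paste0(substr(nm[i], 1, 1))
  }
  out
}

.scan_cryst1 <- function(path) {
  ln <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (!length(ln)) return(NULL)
  f <- ln[[1]]
  edges  <- as.numeric(c(substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33)))
  angles <- as.numeric(c(substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54)))
  if (any(is.na(edges))) return(NULL)
  if (any(abs(angles - 90) > 1e-3))
    stop("triclinic boxes are not supported (CRYST1 angles must be 90 deg)")
  edges
}

.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) {
    warning("element column missing for ", sum(blank),
            " atom(s); inferring from atom names")
    elem[blank] <- .infer_element(a$elety[blank])
  }
  data.frame(name = a$elety, element = trimws(elem), resname = a$resid,
             resid = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
             stringsAsFactors = FALSE)
}

#' Read a structure file into a topology and a single frame
#'
#' PDB parsing is delegated to \pkg{bio3d}; single-frame GRO files are read
#' directly (fixed-column format, nm converted to Angstrom on read).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"`, or `"gro"`.
#' @return list with elements `topology` and `frame`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (format == "gro") return(.read_gro(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- .atoms_from_bio3d(pdb)
  xyz <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  box <- .scan_cryst1(path)
  list(topology = topology(atoms), frame = frame(xyz, box = box))
}

.read_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 3) stop("malformed GRO file (fewer than 3 lines): ", path)
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n)) stop("malformed GRO atom count at line 2 of ", path)
  if (length(ln) < 2 + n + 1)
    stop("GRO file truncated: expected ", n, " atom lines")
  rows <- ln[3:(2 + n)]
  parse1 <- function(i) {
    s <- rows[i]
    resid   <- suppressWarnings(as.integer(substr(s, 1, 5)))
    resname <- trimws(substr(s, 6, 10))
    name    <- trimws(substr(s, 11, 15))
    x <- suppressWarnings(as.numeric(substr(s, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(s, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(s, 37, 44)))
    if (any(is.na(c(resid, x, y, z))))
      stop("malformed GRO atom record at line ", i + 2, " of ", path)
    list(resid = resid, resname = resname, name = name, xyz = c(x, y, z))
  }
  recs <- lapply(seq_len(n), parse1)
  boxline <- as.numeric(strsplit(trimws(ln[2 + n + 1]), "\\s+")[[1]])
  if (length(boxline) > 3 && any(abs(boxline[-(1:3)]) > 1e-9))
    stop("triclinic GRO boxes are not supported")
  box <- if (length(boxline) >= 3) boxline[1:3] * 10 else NULL  # nm -> A
  atoms <- data.frame(
    name    = vapply(recs, `[[`, "", "name"),
    element = .infer_element(vapply(recs, `[[`, "", "name")),
    resname = vapply(recs, `[[`, "", "resname"),
    resid   = vapply(recs, `[[`, integer(1), "resid"),
    stringsAsFactors = FALSE)
  xyz <- do.call(rbind, lapply(recs, `[[`, "xyz")) * 10  # nm -> A
  list(topology = topology(atoms), frame = frame(xyz, box = box))
}

.pdb_atom_line <- function(i, name, resname, chain, resid, xyz, element) {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          i %% 100000, nm, substr(resname, 1, 4), chain, resid %% 10000,
          xyz[1], xyz[2], xyz[3], substr(element, 1, 2))
}

.pdb_body <- function(top, fr) {
  a <- top$atoms
  vapply(seq_len(nrow(a)), function(i)
    .pdb_atom_line(i, a$name[i], a$resname[i], a$chain[i], a$resid[i],
                   fr$xyz[i, ], a$element[i]), character(1))
}

#' Write a topology plus one frame as a PDB file
#'
#' @param top topology.
#' @param fr frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, fr, path) {
  out <- character(0)
  if (!is.null(fr$box))
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                   fr$box[1], fr$box[2], fr$box[3])
  out <- c(out, .pdb_body(top, fr), "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj trajectory.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- character(0)
  b <- traj$frames[[1]]$box
  if (!is.null(b))
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                   b[1], b[2], b[3])
  for (i in seq_along(traj$frames)) {
    out <- c(out, sprintf("MODEL %8d", i),
             .pdb_body(traj$topology, traj$frames[[i]]), "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a multi-frame trajectory
#'
#' Multi-model PDB via \pkg{bio3d}.  PDB files carry no time stamps, so
#' frame times are synthesised as `(0:(n-1)) * dt` unless `times` is given.
#'
#' @param path multi-model PDB path.
#' @param top optional topology to validate against; parsed from the file
#'   when `NULL`.
#' @param dt sampling interval in ps (default 1).
#' @param times explicit frame times in ps, overriding `dt`.
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, top = NULL, dt = 1, times = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nf <- nrow(pdb$xyz)
  ftop <- topology(.atoms_from_bio3d(pdb))
  if (!is.null(top)) {
    if (n_atoms(top) != n_atoms(ftop))
      stop("atom-count mismatch: topology has ", n_atoms(top),
           ", file frames have ", n_atoms(ftop))
  } else top <- ftop
  box <- .scan_cryst1(path)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("times must have one entry per frame")
  frames <- lapply(seq_len(nf), function(i)
    frame(matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE), box = box,
          time = times[i]))
  trajectory(top, frames)
}

#' Infer heavy-atom/hydrogen bonding from geometry
#'
#' Attaches each hydrogen to its nearest heavy atom within `cutoff`, and
#' flags O/N heavy atoms as acceptors and, when they carry a hydrogen, as
#' donors.  Operates on a single frame (covalent geometry is assumed
#' static).
#'
#' @param top topology.
#' @param fr frame supplying the geometry.
#' @param cutoff maximum covalent H-X distance, Angstrom.
#' @return topology with `hydrogens` filled in.
#' @export
infer_hydrogens <- function(top, fr, cutoff = 1.25) {
  el <- top$atoms$element
  hs <- which(el == "H")
  heavy <- which(el != "H")
  hmap <- list()
  for (h in hs) {
    d <- sqrt(colSums((t(fr$xyz[heavy, , drop = FALSE]) - fr$xyz[h, ])^2))
    j <- heavy[which.min(d)]
    if (min(d) <= cutoff)
      hmap[[as.character(j)]] <- c(hmap[[as.character(j)]], h)
  }
  top$hydrogens <- hmap
  top
}

#' Hydrogens bound to a heavy atom
#' @param top topology with `hydrogens` populated.
#' @param i heavy-atom index.
#' @return integer vector (possibly empty) of hydrogen indices.
#' @export
bound_hydrogens <- function(top, i) {
  h <- top$hydrogens[[as.character(i)]]
  if (is.null(h)) integer(0) else h
}

#' Attach partial charges and Lennard-Jones parameters
#'
#' The table is keyed by `(residue_name, atom_name)`; a `residue_name` of
#' `"*"` matches any residue.  Atoms without a matching entry keep `NA`
#' parameters and are listed in the `"unparameterized"` attribute of the
#' result (the energy routines refuse to run on them).
#'
#' @param top topology.
#' @param table data.frame with columns `residue_name`, `atom_name`,
#'   `charge_e`, `sigma_A`, `epsilon_kJmol` (a CSV in this layout is the
#'   on-disk form).
#' @return topology with parameter columns filled.
#' @export
assign_parameters <- function(top, table) {
  need <- c("residue_name", "atom_name", "charge_e", "sigma_A", "epsilon_kJmol")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("parameter table missing columns: ", paste(miss, collapse = ", "))
  a <- top$atoms
  key  <- paste(a$resname, a$name, sep = "\r")
  tkey <- paste(table$residue_name, table$atom_name, sep = "\r")
  hit  <- match(key, tkey)
  wild <- match(paste("*", a$name, sep = "\r"), tkey)
  hit[is.na(hit)] <- wild[is.na(hit)]
  ok <- !is.na(hit)
  a$charge[ok]  <- table$charge_e[hit[ok]]
  a$sigma[ok]   <- table$sigma_A[hit[ok]]
  a$epsilon[ok] <- table$epsilon_kJmol[hit[ok]]
  top$atoms <- a
  attr(top, "unparameterized") <- which(!ok)
  top
}

#' Read a parameter table from CSV or YAML
#' @param path file path (`.csv` or `.yml`/`.yaml`).
#' @return data.frame in [assign_parameters()] layout.
#' @export
read_parameter_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    do.call(rbind, lapply(y, as.data.frame))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
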