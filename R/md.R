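# MD trajectory descriptors: density, percentage free volume, radius of
# gyration, Hansen solubility parameters, heat of vaporization and RMS
# displacement, with trailing-window ensemble averaging. Trajectories are an
# extended-XYZ dialect (comment line carries box / time / energy key=value
# pairs); topology is a JSON sidecar with masses, vdW radii and molecule
# membership. Units: Angstrom, ps, u, kcal/mol internally.

.KCAL_PER_MOL_PER_A3_TO_MPA <- 4184 / 6.02214076e-7 / 1e6  # = 6948.03 MPa
.R_KCAL <- 1.98720425864083e-3  # gas constant, kcal/(mol K)
.U_TO_G <- 1.66053906660e-24

# Bondi-type van der Waals radii (Angstrom) keyed by element.
BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
                 I = 1.98, He = 1.40, Ne = 1.54, Ar = 1.88)

#' Read an extended-XYZ trajectory and its JSON topology
#'
#' Frame format: an atom-count line, a comment line with `key=value` pairs
#' (`box="Lx Ly Lz"` in Angstrom, `time=` in ps, optional `energy_total=`,
#' `energy_inter=`, `energy_elst=`, `energy_vdw=` in kcal/mol), then one
#' `element x y z` line per atom. The topology JSON carries `atom_masses`
#' (u), `molecule_membership` (0-based molecule index per atom), and
#' optionally `vdw_radii` (Angstrom; defaults from the bundled Bondi table
#' via `elements`).
#'
#' @param path trajectory file path.
#' @param topology_path topology JSON path.
#' @return list with `trajectory` (a `trajectory`) and `topology` (a
#'   `system_topology`).
#' @export
read_trajectory <- function(path, topology_path) {
  if (!file.exists(path)) stop_ctx("trajectory file not found: %s", path)
  if (!file.exists(topology_path)) {
    stop_ctx("topology file not found: %s", topology_path)
  }
  topo <- jsonlite::read_json(topology_path, simplifyVector = TRUE)
  topology <- system_topology(
    atom_masses = as.numeric(topo$atom_masses),
    molecule_membership = as.integer(topo$molecule_membership),
    vdw_radii = if (!is.null(topo$vdw_radii)) as.numeric(topo$vdw_radii) else NULL,
    elements = if (!is.null(topo$elements)) as.character(topo$elements) else NULL)

  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_ctx("bad atom-count line %d in %s", i, path)
    if (i + 1 + n > length(lines)) stop_ctx("truncated frame at line %d", i)
    meta <- .parse_xyz_comment(lines[i + 1])
    atom_lines <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(atom_lines), "[[:space:]]+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- list(
      coordinates = coords, box_lengths = meta$box, time = meta$time,
      energies = meta$energies)
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop_ctx("no frames in %s", path)
  n_atoms <- vapply(frames, function(f) nrow(f$coordinates), integer(1))
  if (length(unique(n_atoms)) != 1) {
    stop_ctx("atom count varies across frames")
  }
  if (n_atoms[1] != length(topology$atom_masses)) {
    stop_ctx("topology has %d atoms but frames have %d",
             length(topology$atom_masses), n_atoms[1])
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop_ctx("frame times must increase")
  list(trajectory = structure(frames, class = "trajectory"),
       topology = topology)
}

.parse_xyz_comment <- function(line) {
  # key=value tokens; quoted values may contain spaces
  m <- gregexpr('([A-Za-z_]+)=("[^"]*"|[^ ]+)', line)[[1]]
  toks <- regmatches(line, list(m))[[1]]
  kv <- list()
  for (tok in toks) {
    key <- sub("=.*$", "", tok)
    val <- gsub('^"|"$', "", sub("^[^=]*=", "", tok))
    kv[[key]] <- val
  }
  box <- as.numeric(strsplit(trimws(kv$box %||% ""), "[[:space:]]+")[[1]])
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop_ctx("frame comment must carry box=\"Lx Ly Lz\" with positive lengths")
  }
  energies <- NULL
  ekeys <- c(total = "energy_total", inter = "energy_inter",
             elst = "energy_elst", vdw = "energy_vdw")
  if (any(names(kv) %in% ekeys)) {
    energies <- vapply(ekeys, function(k)
      if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else NA_real_, numeric(1))
  }
  list(box = box, time = as.numeric(kv$time %||% "0"), energies = energies)
}

#' Construct a system topology
#'
#' @param atom_masses per-atom masses in u.
#' @param molecule_membership 0-based molecule index per atom (contiguous).
#' @param vdw_radii per-atom van der Waals radii in Angstrom; defaulted from
#'   the bundled Bondi table when `elements` is given instead.
#' @param elements optional element symbols per atom.
#' @return a `system_topology`.
#' @export
system_topology <- function(atom_masses, molecule_membership,
                            vdw_radii = NULL, elements = NULL) {
  n <- length(atom_masses)
  if (any(atom_masses <= 0)) stop_ctx("atom masses must be positive")
  if (length(molecule_membership) != n) stop_ctx("membership length mismatch")
  mols <- sort(unique(as.integer(molecule_membership)))
  if (n > 0 && !identical(mols, seq(0L, length(mols) - 1L))) {
    stop_ctx("molecule membership must be contiguous 0..n_molecules-1")
  }
  if (is.null(vdw_radii)) {
    if (!is.null(elements)) {
      vdw_radii <- unname(BONDI_RADII[elements])
      if (anyNA(vdw_radii)) stop_ctx("no bundled vdW radius for some element")
    } else {
      vdw_radii <- rep(NA_real_, n)
    }
  }
  structure(list(atom_masses = atom_masses, vdw_radii = vdw_radii,
                 molecule_membership = as.integer(molecule_membership),
                 n_molecules = length(mols), elements = elements),
            class = "system_topology")
}

#' Write a trajectory in the extended-XYZ dialect
#'
#' @param trajectory a `trajectory` (list of frames).
#' @param topology matching `system_topology` (for element symbols).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, topology, path) {
  els <- topology$elements %||% rep("X", length(topology$atom_masses))
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in trajectory) {
    writeLines(as.character(nrow(fr$coordinates)), con)
    meta <- sprintf('time=%.6g box="%.8g %.8g %.8g"', fr$time,
                    fr$box_lengths[1], fr$box_lengths[2], fr$box_lengths[3])
    if (!is.null(fr$energies)) {
      e <- fr$energies
      lbl <- c(total = "energy_total", inter = "energy_inter",
               elst = "energy_elst", vdw = "energy_vdw")
      for (k in names(lbl)) {
        if (!is.na(e[[k]])) meta <- paste0(meta, sprintf(" %s=%.10g", lbl[[k]], e[[k]]))
      }
    }
    writeLines(meta, con)
    writeLines(sprintf("%s %.8f %.8f %.8f", els, fr$coordinates[, 1],
                       fr$coordinates[, 2], fr$coordinates[, 3]), con)
  }
  invisible(path)
}

#' Mass density of one frame
#'
#' @param frame a trajectory frame (needs `box_lengths`).
#' @param topology a `system_topology`.
#' @return density in g/cm^3.
#' @export
mass_density <- function(frame, topology) {
  if (length(topology$atom_masses) == 0) stop_ctx("empty topology")
  vol <- prod(frame$box_lengths)  # A^3
  if (vol <= 0) stop_ctx("zero box volume")
  sum(topology$atom_masses) * .U_TO_G / (vol * 1e-24)
}

# Minimum-image displacement of b relative to a under an orthorhombic box.
.min_image <- function(d, box) {
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

#' Mean radius of gyration over molecules in one frame
#'
#' Each molecule is unwrapped across periodic boundaries (atom positions
#' taken by minimum image relative to the molecule's first atom; valid while
#' molecular extent is below half the box), then the mass-weighted radius of
#' gyration about the center of mass is computed; the frame value is the
#' unweighted mean over molecules. Single-atom molecules contribute 0.
#'
#' @param frame a trajectory frame.
#' @param topology a `system_topology`.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, topology) {
  xyz <- frame$coordinates
  box <- frame$box_lengths
  rg <- vapply(seq_len(topology$n_molecules) - 1L, function(m) {
    idx <- which(topology$molecule_membership == m)
    if (length(idx) == 1) return(0)
    anchor <- xyz[idx[1], , drop = FALSE]
    disp <- .min_image(sweep(xyz[idx, , drop = FALSE], 2, anchor, "-"),
                       box)
    mass <- topology$atom_masses[idx]
    com <- colSums(disp * mass) / sum(mass)
    sq <- rowSums(sweep(disp, 2, com, "-")^2)
    sqrt(sum(mass * sq) / sum(mass))
  }, numeric(1))
  mean(rg)
}

#' Per-frame RMS displacement from a reference frame
#'
#' A mobility measure: coordinates are unwrapped along the trajectory
#' (per-atom minimum-image increments accumulated frame to frame) and the
#' root-mean-square displacement of all atoms relative to the reference
#' frame is reported, with no rotational or translational superposition.
#'
#' @param trajectory a `trajectory` with at least 2 frames.
#' @param topology a `system_topology` (atom count check only).
#' @param reference_index 1-based reference frame (default 1).
#' @return numeric vector, one RMS displacement (Angstrom) per frame.
#' @export
rms_displacement <- function(trajectory, topology, reference_index = 1) {
  nf <- length(trajectory)
  if (nf < 2) stop_ctx("need at least 2 frames")
  if (reference_index < 1 || reference_index > nf) {
    stop_ctx("reference index out of range")
  }
  unwrapped <- vector("list", nf)
  unwrapped[[1]] <- trajectory[[1]]$coordinates
  for (t in seq_len(nf - 1)) {
    inc <- .min_image(trajectory[[t + 1]]$coordinates -
                        trajectory[[t]]$coordinates,
                      trajectory[[t + 1]]$box_lengths)
    unwrapped[[t + 1]] <- unwrapped[[t]] + inc
  }
  ref <- unwrapped[[reference_index]]
  vapply(unwrapped, function(u) sqrt(mean(rowSums((u - ref)^2))), numeric(1))
}

#' Percentage free volume of one frame
#'
#' Fraction of box grid points lying farther than (vdW radius + probe
#' radius) from every atom under periodic minimum-image distances, times
#' 100. A grid estimator; accuracy is set by `grid_spacing`.
#'
#' @param frame a trajectory frame.
#' @param topology a `system_topology` with vdW radii.
#' @param probe_radius probe radius in Angstrom (default 0).
#' @param grid_spacing grid spacing in Angstrom (default 0.5).
#' @return percentage free volume in `[0, 100]`.
#' @export
percent_free_volume <- function(frame, topology, probe_radius = 0,
                                grid_spacing = 0.5) {
  if (grid_spacing <= 0) stop_ctx("grid spacing must be positive")
  box <- frame$box_lengths
  dims <- pmax(1L, as.integer(round(box / grid_spacing)))
  xyz <- frame$coordinates
  n <- nrow(xyz)
  if (n == 0) return(100)
  if (anyNA(topology$vdw_radii)) stop_ctx("topology lacks vdW radii")
  # wrap atoms into the box
  xyz <- xyz %% matrix(box, n, 3, byrow = TRUE)
  occupied <- array(FALSE, dim = dims)
  step <- box / dims
  for (a in seq_len(n)) {
    r <- topology$vdw_radii[a] + probe_radius
    if (r <= 0) next
    lo <- floor((xyz[a, ] - r) / step)
    hi <- ceiling((xyz[a, ] + r) / step)
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    # grid point centers (unwrapped), then minimum-image distance to atom
    gx <- (ix + 0.5) * step[1] - xyz[a, 1]
    gy <- (iy + 0.5) * step[2] - xyz[a, 2]
    gz <- (iz + 0.5) * step[3] - xyz[a, 3]
    gx <- gx - round(gx / box[1]) * box[1]
    gy <- gy - round(gy / box[2]) * box[2]
    gz <- gz - round(gz / box[3]) * box[3]
    within <- which(outer(outer(gx^2, gy^2, "+"), gz^2, "+") <= r^2,
                    arr.ind = TRUE)
    if (nrow(within) > 0) {
      occupied[cbind((ix[within[, 1]] %% dims[1]) + 1L,
                     (iy[within[, 2]] %% dims[2]) + 1L,
                     (iz[within[, 3]] %% dims[3]) + 1L)] <- TRUE
    }
  }
  100 * (1 - sum(occupied) / prod(dims))
}

.window_energies <- function(frames, component) {
  e <- vapply(frames, function(f) {
    if (is.null(f$energies)) NA_real_ else f$energies[[component]]
  }, numeric(1))
  if (anyNA(e)) stop_ctx("frames lack '%s' energies", component)
  e
}

#' Cohesive energy density and Hansen solubility parameters
#'
#' `CED = -<E_inter>/<V>` converted from kcal/(mol A^3) to MPa; the total
#' solubility parameter is `sqrt(CED)` and the electrostatic / van der Waals
#' components are the square roots of the corresponding energy shares.
#' Non-cohesive (positive) mean energies clamp the component to 0 with a
#' warning.
#'
#' @param frames list of trajectory frames carrying intermolecular energies.
#' @param topology a `system_topology` (unused; kept for a uniform surface).
#' @return list with `CED` (MPa), `MD_SP`, `MD_SP_E`, `MD_SP_V` (MPa^0.5).
#' @export
cohesive_energy_and_solubility <- function(frames, topology = NULL) {
  vol <- mean(vapply(frames, function(f) prod(f$box_lengths), numeric(1)))
  comp <- function(component) {
    e <- mean(.window_energies(frames, component))
    ced <- -e / vol * .KCAL_PER_MOL_PER_A3_TO_MPA
    if (ced < 0) {
      warning(sprintf("positive mean %s energy; solubility component clamped at 0",
                      component))
      ced <- 0
    }
    ced
  }
  ced <- comp("inter")
  list(CED = ced, MD_SP = sqrt(ced),
       MD_SP_E = sqrt(comp("elst")), MD_SP_V = sqrt(comp("vdw")))
}

#' Heat of vaporization from mean intermolecular energy
#'
#' `HV = -<E_inter>/n_molecules + R*T` with R in kcal/(mol K): the molar
#' cohesive energy plus the ideal-gas expansion term.
#'
#' @param frames list of frames with intermolecular energies.
#' @param topology a `system_topology` (for the molecule count).
#' @param T_K temperature in Kelvin.
#' @return heat of vaporization in kcal/mol.
#' @export
heat_of_vaporization <- function(frames, topology, T_K) {
  if (topology$n_molecules < 1) stop_ctx("need at least one molecule")
  e <- mean(.window_energies(frames, "inter"))
  -e / topology$n_molecules + .R_KCAL * T_K
}

#' Ensemble-averaged MD descriptor set
#'
#' Averages the per-frame descriptors over the trailing window of the
#' trajectory (default: the last half, mirroring analysis of the last 10 ns
#' of a 20 ns production run). RMS displacement is reported as the mean
#' displacement of the window's frames from the window's first frame.
#'
#' @param trajectory a `trajectory`.
#' @param topology a `system_topology`.
#' @param T_K simulation temperature in Kelvin.
#' @param trailing_fraction fraction of trailing frames to average
#'   (default 0.5).
#' @param grid_spacing free-volume grid spacing in Angstrom.
#' @param probe_radius free-volume probe radius in Angstrom.
#' @return an `md_descriptor_set`: named list with `MD_density` (g/cm^3),
#'   `MD_FV` (percent), `MD_Rg` (Angstrom), `MD_SP`, `MD_SP_E`, `MD_SP_V`
#'   (MPa^0.5), `MD_HV` (kcal/mol), `MD_RMSD` (Angstrom).
#' @export
ensemble_descriptors <- function(trajectory, topology, T_K,
                                 trailing_fraction = 0.5,
                                 grid_spacing = 0.5, probe_radius = 0) {
  nf <- length(trajectory)
  n_window <- max(2L, ceiling(trailing_fraction * nf))
  if (n_window > nf) stop_ctx("trailing window larger than trajectory")
  w <- (nf - n_window + 1):nf
  frames <- trajectory[w]

  dens <- mean(vapply(frames, mass_density, numeric(1),
                      topology = topology))
  rg <- mean(vapply(frames, radius_of_gyration, numeric(1),
                    topology = topology))
  fv <- mean(vapply(frames, percent_free_volume, numeric(1),
                    topology = topology, probe_radius = probe_radius,
                    grid_spacing = grid_spacing))
  sol <- cohesive_energy_and_solubility(frames, topology)
  hv <- heat_of_vaporization(frames, topology, T_K)
  rmsd_all <- rms_displacement(trajectory, topology,
                               reference_index = w[1])
  rmsd <- mean(rmsd_all[w[-1]])

  structure(list(MD_density = dens, MD_FV = fv, MD_Rg = rg,
                 MD_SP = sol$MD_SP, MD_SP_E = sol$MD_SP_E,
                 MD_SP_V = sol$MD_SP_V, MD_HV = hv, MD_RMSD = rmsd,
                 T_K = T_K, n_frames_window = n_window),
            class = "md_descriptor_set")
}

#' @method print md_descriptor_set
#' @export
print.md_descriptor_set <- function(x, ...) {
  cat(sprintf(
    "MD descriptors (T = %g K, %d-frame window):\n", x$T_K, x$n_frames_window))
  cat(sprintf("  density %.4f g/cm^3 | FV %.2f%% | Rg %.3f A | RMSD %.3f A\n",
              x$MD_density, x$MD_FV, x$MD_Rg, x$MD_RMSD))
  cat(sprintf("  SP %.3f (E %.3f, V %.3f) MPa^0.5 | HV %.3f kcal/mol\n",
              x$MD_SP, x$MD_SP_E, x$MD_SP_V, x$MD_HV))
  invisible(x)
}
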