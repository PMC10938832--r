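# Structural descriptor blocks: 2D physicochemical/topological descriptors
# and element-composition statistics over a bundled elemental-property table.

# Elemental properties (standard tabulated values): average mass (u), Pauling
# electronegativity, covalent radius (pm), Bondi van der Waals radius (pm),
# dipole polarizability (A^3), first ionization energy (eV), valence
# electrons, period.
ELEMENT_PROPERTIES <- data.frame(
  element = c("H", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I"),
  mass = c(1.008, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974, 32.06,
           35.45, 79.904, 126.904),
  electronegativity = c(2.20, 2.55, 3.04, 3.44, 3.98, 1.90, 2.19, 2.58,
                        3.16, 2.96, 2.66),
  covalent_radius = c(31, 76, 71, 66, 57, 111, 107, 105, 102, 120, 139),
  vdw_radius = c(120, 170, 155, 152, 147, 210, 180, 180, 175, 185, 198),
  polarizability = c(0.667, 1.760, 1.100, 0.802, 0.557, 5.380, 3.630, 2.900,
                     2.180, 3.050, 5.350),
  ionization_energy = c(13.598, 11.260, 14.534, 13.618, 17.423, 8.152,
                        10.487, 10.360, 12.968, 11.814, 10.451),
  valence_electrons = c(1, 4, 5, 6, 7, 4, 5, 6, 7, 7, 7),
  period = c(1, 2, 2, 2, 2, 3, 3, 3, 3, 4, 5),
  stringsAsFactors = FALSE
)

# All-pairs shortest-path distances on the heavy-atom graph (BFS per atom).
.graph_distances <- function(n, bonds) {
  nbr <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      nbr[[bonds$from[k]]] <- c(nbr[[bonds$from[k]]], bonds$to[k])
      nbr[[bonds$to[k]]] <- c(nbr[[bonds$to[k]]], bonds$from[k])
    }
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[[v]]) {
        if (is.infinite(D[s, w])) {
          D[s, w] <- D[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  D
}

# Ring-bond flags: a bond lies on a ring iff removing it leaves its endpoints
# connected. Molecules here are small, so the direct check is fine.
.ring_bonds <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0) return(logical(0))
  flags <- logical(nb)
  for (k in seq_len(nb)) {
    keep <- bonds[-k, , drop = FALSE]
    D <- .graph_distances(n, keep)
    flags[k] <- is.finite(D[bonds$from[k], bonds$to[k]])
  }
  flags
}

#' 2D physicochemical and topological descriptor block
#'
#' Computed from the heavy-atom connectivity graph and OpenBabel bulk
#' properties: size and mass measures, element counts, hydrogen-bonding
#' counts, lipophilicity and polar surface area, ring/rotor counts, and
#' connectivity indices (chi0, chi1, Wiener index, graph diameter).
#' Temperature never enters this block.
#'
#' @param mol parsed molecule (from `parse_molecules()`).
#' @return named numeric vector with `D2_` prefixes.
#' @export
descriptor_block_2d <- function(mol) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  n <- length(atoms)
  deg <- numeric(n)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      deg[bonds$from[k]] <- deg[bonds$from[k]] + 1
      deg[bonds$to[k]] <- deg[bonds$to[k]] + 1
    }
  }
  els <- mol$elements
  count_el <- function(e) if (e %in% names(els)) as.numeric(els[[e]]) else 0
  n_heavy <- sum(els[setdiff(names(els), "H")])
  n_h <- count_el("H")

  props <- mol$props %||% c(MW = NA, logP = NA, TPSA = NA, MR = NA,
                            HBA1 = NA, HBA2 = NA, HBD = NA, nF = NA)
  D <- .graph_distances(n, bonds)
  finite_D <- D[is.finite(D)]
  wiener <- sum(finite_D) / 2
  diameter <- if (length(finite_D) > 0) max(finite_D) else 0

  ring <- .ring_bonds(n, bonds)
  n_ring_bonds <- sum(ring)
  n_rings <- max(0, nrow(bonds) - n + .n_components(n, bonds))
  rotatable <- 0
  if (nrow(bonds) > 0) {
    rotatable <- sum(bonds$order == 1 & !ring &
                       deg[bonds$from] >= 2 & deg[bonds$to] >= 2)
  }
  is_c <- atoms == "C"
  csp3 <- 0
  if (any(is_c)) {
    max_order <- rep(1, n)
    if (nrow(bonds) > 0) {
      for (k in seq_len(nrow(bonds))) {
        max_order[bonds$from[k]] <- max(max_order[bonds$from[k]], bonds$order[k])
        max_order[bonds$to[k]] <- max(max_order[bonds$to[k]], bonds$order[k])
      }
    }
    csp3 <- sum(is_c & max_order == 1) / sum(is_c)
  }
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (nrow(bonds) > 0) {
    sum(1 / sqrt(deg[bonds$from] * deg[bonds$to]))
  } else 0

  v <- c(
    MW = unname(props["MW"]),
    logP = unname(props["logP"]),
    TPSA = unname(props["TPSA"]),
    MR = unname(props["MR"]),
    HBD = unname(props["HBD"]),
    HBA = unname(props["HBA1"]),
    heavy_atoms = n_heavy,
    n_atoms_total = n_heavy + n_h,
    n_H = n_h,
    n_C = count_el("C"), n_N = count_el("N"), n_O = count_el("O"),
    n_F = count_el("F"), n_Si = count_el("Si"), n_P = count_el("P"),
    n_S = count_el("S"), n_Cl = count_el("Cl"), n_Br = count_el("Br"),
    n_I = count_el("I"),
    n_bonds = nrow(bonds),
    n_rings = n_rings,
    n_ring_bonds = n_ring_bonds,
    n_rotatable = rotatable,
    frac_csp3 = csp3,
    heteroatom_frac = if (n_heavy > 0) (n_heavy - count_el("C")) / n_heavy else 0,
    mean_degree = if (n > 0) mean(deg) else 0,
    n_branch_points = sum(deg >= 3),
    chi0 = chi0,
    chi1 = chi1,
    wiener_index = wiener,
    graph_diameter = diameter,
    mw_per_heavy_atom = if (n_heavy > 0) unname(props["MW"]) / n_heavy else 0
  )
  names(v) <- paste0("D2_", names(v))
  v
}

.n_components <- function(n, bonds) {
  if (n == 0) return(0L)
  D <- .graph_distances(n, bonds)
  seen <- logical(n); comp <- 0L
  for (i in seq_len(n)) {
    if (!seen[i]) {
      comp <- comp + 1L
      seen[is.finite(D[i, ])] <- TRUE
    }
  }
  comp
}

#' Element-composition statistics block
#'
#' Composition-weighted statistics (mean, min, max, range, standard
#' deviation) of tabulated elemental properties over the molecular formula
#' (hydrogens included), plus atomic fractions per element — the style of
#' featurization used for composition-based property models.
#'
#' @param mol parsed molecule (from `parse_molecules()`).
#' @return named numeric vector with `CP_` prefixes.
#' @export
descriptor_block_composition <- function(mol) {
  els <- mol$elements
  tab <- ELEMENT_PROPERTIES
  known <- intersect(names(els), tab$element)
  counts <- as.numeric(els[known])
  rows <- match(known, tab$element)
  frac <- if (sum(counts) > 0) counts / sum(counts) else counts

  prop_cols <- setdiff(names(tab), "element")
  out <- c()
  for (pc in prop_cols) {
    p <- tab[[pc]][rows]
    if (length(p) == 0 || sum(counts) == 0) {
      stats_v <- c(mean = 0, min = 0, max = 0, range = 0, sd = 0)
    } else {
      wm <- sum(frac * p)
      stats_v <- c(mean = wm, min = min(p), max = max(p),
                   range = max(p) - min(p),
                   sd = sqrt(sum(frac * (p - wm)^2)))
    }
    names(stats_v) <- paste0(pc, "_", names(stats_v))
    out <- c(out, stats_v)
  }
  fr <- stats::setNames(numeric(nrow(tab)), paste0("frac_", tab$element))
  fr[paste0("frac_", known)] <- frac
  out <- c(out, fr)
  names(out) <- paste0("CP_", names(out))
  out
}

#' Structure feature vector for one molecule
#'
#' Concatenates the enabled blocks — 2D descriptors, hashed circular
#' fingerprint bits, composition statistics — into one named numeric vector.
#' Deterministic per structure; a function of the canonical SMILES only.
#'
#' @param smiles a single SMILES string.
#' @param config a [feature_config()].
#' @param mol optional pre-parsed molecule (skips re-parsing).
#' @return named numeric vector with a `block` attribute tagging each entry
#'   as `"2D"`, `"FP"` or `"COMP"`.
#' @export
compute_structure_features <- function(smiles, config = feature_config(),
                                       mol = NULL) {
  if (is.null(mol)) mol <- parse_molecules(smiles)[[1]]
  if (!isTRUE(mol$ok)) stop_ctx("unparseable SMILES: %s", smiles)
  vals <- numeric(0)
  tags <- character(0)
  if ("2D" %in% config$blocks) {
    b <- descriptor_block_2d(mol)
    vals <- c(vals, b); tags <- c(tags, rep("2D", length(b)))
  }
  if ("FP" %in% config$blocks) {
    b <- morgan_fingerprint(mol, nbits = config$fp_bits,
                            radius = config$fp_radius)
    vals <- c(vals, b); tags <- c(tags, rep("FP", length(b)))
  }
  if ("COMP" %in% config$blocks) {
    b <- descriptor_block_composition(mol)
    vals <- c(vals, b); tags <- c(tags, rep("COMP", length(b)))
  }
  if (anyNA(vals)) {
    bad <- names(vals)[is.na(vals)]
    stop_ctx("descriptor evaluation failed for %s: %s", smiles,
             paste(bad, collapse = ", "))
  }
  attr(vals, "block") <- tags
  vals
}
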