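# Thin cheminformatics layer over ChemmineR/ChemmineOB (OpenBabel).
# All SMILES parsing, canonicalization and bulk physicochemical properties go
# through the toolkit; the package only post-processes atom/bond blocks.

# Default valences used to infer implicit hydrogen counts on neutral atoms.
.default_valence <- c(
  H = 1, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, B = 3
)

# Average atomic masses (IUPAC 2021, rounded) for the elements the curation
# filter admits plus a few common contaminants seen in raw tables.
.atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
  B = 10.81, Na = 22.990, K = 39.098, Li = 6.94, Mg = 24.305, Ca = 40.078,
  Al = 26.982, Sn = 118.71, Ge = 72.63, Se = 78.971, Zn = 65.38
)

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES for each input. Canonical SMILES is
#' the compound identity key used throughout the package: two records refer to
#' the same compound if and only if their canonical SMILES agree.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `NA` where the string could
#'   not be interpreted as a molecule.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    out <- sub("\t.*$", "", sub("\n.*$", "", out))
    out <- trimws(out)
    if (nchar(out) == 0) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Parse a molecular formula string ("C3H6O2") into a named count vector.
parse_formula <- function(formula) {
  if (is.na(formula) || nchar(formula) == 0) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nchar(n) == 0) 1L else as.integer(n)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# Parse a batch of SMILES into molecule descriptions, one list element per
# input. Each element has:
#   ok          parseable as a molecule
#   canonical   canonical SMILES (NA if not ok)
#   n_fragments number of connected components (from canonical SMILES dots)
#   formula     molecular formula string
#   elements    named integer vector of element counts (including H)
#   atoms       heavy-atom element symbols in SDF order
#   bonds       data.frame(from, to, order) over heavy atoms
#   implicit_h  implicit hydrogen count per heavy atom
#   props       named numeric OpenBabel properties (MW, logP, TPSA, HBD, ...)
# Results are deterministic per SMILES and safe to cache by the caller.
parse_molecules <- function(smiles) {
  n <- length(smiles)
  out <- vector("list", n)
  canon <- canonical_smiles(smiles)
  ok <- !is.na(canon)
  if (any(ok)) {
    smi_ok <- smiles[ok]
    names(smi_ok) <- paste0("m", seq_along(smi_ok))
    sdfs <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smi_ok)),
      error = function(e) NULL
    )
    props <- if (!is.null(sdfs)) {
      tryCatch(suppressWarnings(ChemmineR::propOB(sdfs)),
               error = function(e) NULL)
    } else NULL
    idx_ok <- which(ok)
    for (j in seq_along(idx_ok)) {
      i <- idx_ok[j]
      sdf <- if (!is.null(sdfs) && j <= length(sdfs)) sdfs[[j]] else NULL
      out[[i]] <- .describe_molecule(canon[i], sdf,
                                     if (!is.null(props)) props[j, ] else NULL)
    }
  }
  for (i in which(!ok)) {
    out[[i]] <- list(ok = FALSE, canonical = NA_character_,
                     n_fragments = NA_integer_, formula = NA_character_,
                     elements = integer(0), atoms = character(0),
                     bonds = data.frame(from = integer(0), to = integer(0),
                                        order = integer(0)),
                     implicit_h = integer(0), props = NULL)
  }
  out
}

.describe_molecule <- function(canonical, sdf, prop_row) {
  n_frag <- length(gregexpr(".", canonical, fixed = TRUE)[[1]])
  n_frag <- if (grepl(".", canonical, fixed = TRUE)) n_frag + 1L else 1L

  atoms <- character(0)
  bonds <- data.frame(from = integer(0), to = integer(0), order = integer(0))
  if (!is.null(sdf)) {
    ab <- tryCatch(ChemmineR::atomblock(sdf), error = function(e) NULL)
    if (!is.null(ab) && nrow(ab) > 0) {
      atoms <- sub("_.*$", "", rownames(ab))
      bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
      if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
        bonds <- data.frame(from = as.integer(bb[, 1]),
                            to = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
        valid <- bonds$from >= 1 & bonds$from <= length(atoms) &
          bonds$to >= 1 & bonds$to <= length(atoms) & bonds$order >= 1
        bonds <- bonds[valid, , drop = FALSE]
      }
    }
  }
  # bond-order sum per atom, for implicit H inference on neutral atoms
  bsum <- numeric(length(atoms))
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      bsum[bonds$from[k]] <- bsum[bonds$from[k]] + bonds$order[k]
      bsum[bonds$to[k]] <- bsum[bonds$to[k]] + bonds$order[k]
    }
  }
  val <- unname(.default_valence[atoms])
  val[is.na(val)] <- 0
  implicit_h <- pmax(0L, as.integer(round(val - bsum)))

  formula <- if (!is.null(prop_row)) as.character(prop_row$formula) else NA_character_
  elements <- parse_formula(formula)
  if (length(elements) == 0 && length(atoms) > 0) {
    tab <- table(atoms)
    elements <- stats::setNames(as.integer(tab), names(tab))
    nh <- sum(implicit_h)
    if (nh > 0) elements["H"] <- (if ("H" %in% names(elements)) elements[["H"]] else 0L) + nh
  }

  props <- NULL
  if (!is.null(prop_row)) {
    keep <- c("MW", "logP", "TPSA", "MR", "HBA1", "HBA2", "HBD", "nF")
    props <- vapply(keep, function(k) {
      v <- suppressWarnings(as.numeric(prop_row[[k]]))
      if (length(v) == 0 || is.na(v)) 0 else v
    }, numeric(1))
  }

  list(ok = TRUE, canonical = canonical, n_fragments = n_frag,
       formula = formula, elements = elements, atoms = atoms, bonds = bonds,
       implicit_h = implicit_h, props = props)
}

# Dataset-scoped molecule cache: parse each unique SMILES once.
molecule_cache <- function() {
  env <- new.env(parent = emptyenv())
  function(smiles) {
    miss <- unique(smiles[!vapply(smiles, exists, logical(1), envir = env)])
    if (length(miss) > 0) {
      parsed <- parse_molecules(miss)
      for (i in seq_along(miss)) assign(miss[i], parsed[[i]], envir = env)
    }
    lapply(smiles, get, envir = env)
  }
}
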