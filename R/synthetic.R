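# Synthetic data with the statistical structure the pipeline assumes:
# per-compound Vogel viscosity curves log10(mu) = A + B/(T - C) whose
# parameters shift with simple structure summaries (so 2D descriptors carry
# real signal), log-scale measurement noise, right-skewed temperature
# sampling, injected curation violations with ground-truth labels, surrogate
# external descriptors, and analytic toy trajectories for the MD module.

# Alkyl building blocks (SMILES fragments that concatenate head-to-tail).
.alkyl_groups <- function() {
  c(vapply(1:10, function(k) strrep("C", k), character(1)),
    "C(C)C", "CC(C)C", "C(C)CC")
}

# Deterministic enumeration of ester / ether / carbonate / ketone / alcohol /
# alkane candidates from the fragment grammar.
.grammar_candidates <- function() {
  r <- .alkyl_groups()
  pairs <- expand.grid(a = r, b = r, stringsAsFactors = FALSE)
  c(paste0(pairs$a, "C(=O)O", pairs$b),   # esters
    paste0(pairs$a, "O", pairs$b),        # ethers
    paste0(pairs$a, "OC(=O)O", pairs$b),  # carbonates
    paste0(pairs$a, "C(=O)", pairs$b),    # ketones
    paste0(r, "O"),                       # alcohols
    paste0(pairs$a, pairs$b))             # alkanes
}

.library_memo <- new.env(parent = emptyenv())

#' Generate a library of distinct single-fragment organic SMILES
#'
#' Enumerates ester, ether, carbonate, ketone, alcohol and alkane structures
#' from an alkyl fragment grammar, canonicalizes and deduplicates them, and
#' returns `n` distinct structures after a seeded shuffle. The `"battery"`
#' preset returns the six carbonate/ester electrolyte solvents (methyl
#' acetate, ethyl acetate, methyl butyrate, methyl propionate, dimethyl
#' carbonate, ethyl methyl carbonate).
#'
#' The `"homologous_esters"` preset returns a ten-member series of similar
#' medium-chain esters (7-11 heavy atoms) whose viscosity curves stay close
#' together — the standard fixture family for tests that need a narrow,
#' fence-compatible viscosity spread.
#'
#' @param n number of structures.
#' @param seed integer seed for the shuffle.
#' @param preset optional `"battery"` or `"homologous_esters"` preset
#'   (ignores `n` and `seed`).
#' @return character vector of SMILES.
#' @export
generate_compound_library <- function(n, seed = 0, preset = NULL) {
  if (identical(preset, "battery")) {
    return(c(MA = "COC(C)=O", EA = "CCOC(C)=O", MB = "CCCC(=O)OC",
             MP = "CCC(=O)OC", DMC = "COC(=O)OC", EMC = "CCOC(=O)OC"))
  }
  if (identical(preset, "homologous_esters")) {
    return(c("CC(=O)OCCCCC", "CCC(=O)OCCCC", "CCCC(=O)OCCC",
             "CCCCC(=O)OCC", "CCCCCC(=O)OC", "CCC(=O)OCCCCC",
             "CCCC(=O)OCCCC", "CCCCC(=O)OCCC", "CCCCCC(=O)OCC",
             "CCCCCCC(=O)OC"))
  }
  if (identical(preset, "homologous_midsize")) {
    # all grammar structures with exactly 14 heavy atoms and no H-bond
    # donors: size-matched esters/ethers/ketones/carbonates/alkanes whose
    # viscosity curves and temperature ranges stay aligned
    key <- "midsize_pool"
    if (!exists(key, envir = .library_memo)) {
      cand <- unique(.grammar_candidates())
      mols <- parse_molecules(cand)
      keep <- vapply(mols, function(m) {
        if (!isTRUE(m$ok)) return(FALSE)
        nh <- sum(m$elements[setdiff(names(m$elements), "H")])
        hbd <- if (!is.null(m$props)) unname(m$props["HBD"]) else 1
        nh == 14 && hbd == 0
      }, logical(1))
      canon <- vapply(mols[keep], function(m) m$canonical, character(1))
      assign(key, cand[keep][!duplicated(canon)], envir = .library_memo)
    }
    return(get(key, envir = .library_memo))
  }
  if (n < 1) stop_ctx("n must be >= 1")
  key <- "canonical_pool"
  if (!exists(key, envir = .library_memo)) {
    cand <- .grammar_candidates()
    canon <- canonical_smiles(cand)
    keep <- !is.na(canon) & !duplicated(canon)
    assign(key, cand[keep], envir = .library_memo)
  }
  pool <- get(key, envir = .library_memo)
  if (n > length(pool)) {
    stop_ctx("requested %d compounds but the grammar yields %d", n,
             length(pool))
  }
  with_seed(derive_seed(seed, 53), sample(pool))[seq_len(n)]
}

#' Assign Vogel parameters to a structure
#'
#' Draws `(A, B, C)` of `log10(mu) = A + B/(T - C)` from distributions whose
#' means shift with two structure summaries — heavy-atom count and
#' hydrogen-bond-donor count — so that larger and more hydrogen-bonding
#' molecules are systematically more viscous, with a small per-compound
#' random residual. Deterministic per (canonical SMILES, seed).
#'
#' @param smiles a single SMILES string.
#' @param seed integer seed.
#' @param mol optional pre-parsed molecule.
#' @return list with `A` (log10 cP), `B` (K), `C` (K), `n_heavy`, `n_hbd`.
#' @export
assign_vogel_parameters <- function(smiles, seed = 0, mol = NULL) {
  if (is.null(mol)) mol <- parse_molecules(smiles)[[1]]
  if (!isTRUE(mol$ok)) stop_ctx("unparseable SMILES: %s", smiles)
  n_heavy <- sum(mol$elements[setdiff(names(mol$elements), "H")])
  n_hbd <- if (!is.null(mol$props)) unname(mol$props["HBD"]) else 0
  # B grows superlinearly with molecular size (chain entanglement makes
  # viscosity scale faster than linearly in oligomer length), so the
  # structure-viscosity link is genuinely nonlinear; residual scales are
  # small: structure determines the curve up to lab-level reproducibility
  s <- derive_seed(seed, hash_string(mol$canonical))
  draws <- with_seed(s, stats::rnorm(3))
  A <- -1.45 - 0.003 * n_heavy + 0.05 * n_hbd + 0.02 * draws[1]
  B <- max(0, 40 + 3.5 * n_heavy^1.5 + 45 * n_hbd + 3 * draws[2])
  C <- min(190, max(40, 85 + 2.5 * n_heavy + 2 * draws[3]))
  list(A = A, B = B, C = C, n_heavy = n_heavy, n_hbd = n_hbd)
}

#' Synthetic dataset configuration
#'
#' Defaults emulate the curated experimental landscape: repeated compounds
#' at several temperatures, dynamic viscosities clipped to 0.10-26.52 cP,
#' temperatures in 230-400 K with a right-skewed spread, and log-scale
#' multiplicative measurement noise.
#'
#' @param n_compounds number of compounds.
#' @param temperatures_per_compound measurements per compound.
#' @param temperature_range global Kelvin range sampled.
#' @param temperature_window Kelvin width of each compound's own range.
#' @param temperature_spacing `"uniform"` (stratified uniformly in T) or
#'   `"inverse"` (stratified uniformly in 1/(T - C), i.e. evenly spaced
#'   along the viscosity curve).
#' @param viscosity_band optional log10-cP interval `c(lo, hi)`: when set,
#'   each compound's temperatures are chosen so its noiseless log
#'   viscosities stratify this common band (an isoviscous sampling design,
#'   the analogue of measuring every liquid across one instrument range);
#'   overrides `temperature_window`/`temperature_spacing`.
#' @param noise_sd standard deviation of the additive log10-cP noise.
#' @param clip_range_cP viscosities are clipped into this cP range.
#' @param n_element_outliers injected disallowed-element records.
#' @param n_range_outliers injected extreme viscosity/temperature records.
#' @param n_deviation_outliers injected positive-deviation records.
#' @param compounds optional explicit SMILES pool; overrides the library
#'   draw (`n_compounds` then means "use these compounds").
#' @param seed master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 200, temperatures_per_compound = 5,
                             temperature_range = c(230, 400),
                             temperature_window = 120,
                             temperature_spacing = c("uniform", "inverse"),
                             viscosity_band = NULL,
                             noise_sd = 0.02,
                             clip_range_cP = c(0.10, 26.52),
                             n_element_outliers = 0, n_range_outliers = 0,
                             n_deviation_outliers = 0, compounds = NULL,
                             seed = 0) {
  temperature_spacing <- match.arg(temperature_spacing)
  stopifnot(n_compounds >= 1, temperatures_per_compound >= 1,
            diff(temperature_range) > 0, noise_sd >= 0,
            diff(clip_range_cP) > 0, n_element_outliers >= 0,
            n_range_outliers >= 0, n_deviation_outliers >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

.element_violation_smiles <- c("[Na+].[Cl-]", "CC[Sn](CC)CC", "C[Ge](C)C",
                               "B(O)(O)O", "[K+].[Br-]", "C[Se]C")

#' Generate a synthetic viscosity dataset with ground truth
#'
#' For each compound: temperatures are drawn stratified (with spacing) over
#' a right-skewed compound window; viscosities follow the compound's Vogel
#' curve with `Normal(0, noise_sd)` noise added on the log10 scale, then
#' clipping to the configured cP range. Requested numbers of
#' element-violation, range-outlier and positive-deviation records are
#' appended with labels.
#'
#' @param config a [synthetic_config()].
#' @return list with `records` (raw data.frame for [curate()]) and `truth`
#'   (per-row type label, Vogel parameters and noiseless log10 viscosity).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cf <- config
  lib <- cf$compounds %||%
    generate_compound_library(cf$n_compounds, seed = cf$seed)
  mols <- parse_molecules(lib)
  k <- cf$temperatures_per_compound
  rec <- list(); tru <- list()

  for (i in seq_along(lib)) {
    par <- assign_vogel_parameters(lib[i], seed = cf$seed, mol = mols[[i]])
    tw <- with_seed(derive_seed(cf$seed, 61, i), {
      if (!is.null(cf$viscosity_band)) {
        # isoviscous design: stratify the compound's noiseless log viscosity
        # over a common band and solve the curve for the temperatures
        bk <- seq(cf$viscosity_band[1], cf$viscosity_band[2],
                  length.out = k + 1)
        bc <- (bk[-1] + bk[-(k + 1)]) / 2
        m <- bc + stats::runif(k, -0.15, 0.15) * diff(bk[1:2])
        temps <- sort(par$C + par$B / (m - par$A))
      } else {
        lo_max <- cf$temperature_range[2] - cf$temperature_window
        lo <- cf$temperature_range[1] +
          (lo_max - cf$temperature_range[1]) * stats::rbeta(1, 2, 4)
        width <- cf$temperature_window
        # stratified draws, jitter confined to the middle of each stratum;
        # "inverse" spacing stratifies in 1/(T - C), i.e. evenly along the
        # log-viscosity curve
        if (cf$temperature_spacing == "inverse") {
          u <- sort(1 / (c(lo + width, lo) - par$C))
          edges <- seq(u[1], u[2], length.out = k + 1)
        } else {
          edges <- seq(lo, lo + width, length.out = k + 1)
        }
        centers <- (edges[-1] + edges[-(k + 1)]) / 2
        stratum <- diff(edges[1:2])
        pts <- centers + stats::runif(k, -0.15, 0.15) * stratum
        temps <- if (cf$temperature_spacing == "inverse") {
          sort(par$C + 1 / pts)
        } else pts
      }
      list(temps = temps, eps = stats::rnorm(k, 0, cf$noise_sd))
    })
    log_clean <- par$A + par$B / (tw$temps - par$C)
    mu <- 10^(log_clean + tw$eps)
    mu <- pmin(pmax(mu, cf$clip_range_cP[1]), cf$clip_range_cP[2])
    rec[[i]] <- data.frame(
      smiles = lib[i], temperature_K = tw$temps, viscosity_cP = mu,
      source = "synthetic", stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(
      smiles = lib[i], temperature_K = tw$temps, type = "clean",
      A = par$A, B = par$B, C = par$C, n_heavy = par$n_heavy,
      log10_mu_clean = log_clean, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  truth <- do.call(rbind, tru)

  inject <- function(records, truth, df, type) {
    df$source <- paste0("synthetic_outlier_", type)
    t2 <- data.frame(smiles = df$smiles, temperature_K = df$temperature_K,
                     type = type, A = NA, B = NA, C = NA, n_heavy = NA,
                     log10_mu_clean = NA, stringsAsFactors = FALSE)
    list(records = rbind(records, df), truth = rbind(truth, t2))
  }

  if (cf$n_element_outliers > 0) {
    pick <- with_seed(derive_seed(cf$seed, 71), {
      list(smi = sample(.element_violation_smiles, cf$n_element_outliers,
                        replace = TRUE),
           temp = stats::runif(cf$n_element_outliers,
                               cf$temperature_range[1],
                               cf$temperature_range[2]),
           mu = 10^stats::runif(cf$n_element_outliers, -0.5, 0.5))
    })
    out <- inject(records, truth,
                  data.frame(smiles = pick$smi, temperature_K = pick$temp,
                             viscosity_cP = pick$mu,
                             stringsAsFactors = FALSE), "element")
    records <- out$records; truth <- out$truth
  }
  if (cf$n_range_outliers > 0) {
    # each injected record is extreme in exactly one variable and sits in
    # the middle of the clean distribution of the other
    clean_mu <- records$viscosity_cP
    clean_t <- records$temperature_K
    pick <- with_seed(derive_seed(cf$seed, 72), {
      by_temp <- stats::runif(cf$n_range_outliers) < 0.5
      list(smi = sample(lib, cf$n_range_outliers, replace = TRUE),
           temp = ifelse(by_temp,
                         stats::runif(cf$n_range_outliers, 550, 650),
                         stats::quantile(clean_t,
                                         stats::runif(cf$n_range_outliers,
                                                      0.3, 0.7))),
           mu = ifelse(by_temp,
                       stats::quantile(clean_mu,
                                       stats::runif(cf$n_range_outliers,
                                                    0.3, 0.7)),
                       stats::runif(cf$n_range_outliers, 300, 900)))
    })
    out <- inject(records, truth,
                  data.frame(smiles = pick$smi, temperature_K = pick$temp,
                             viscosity_cP = pick$mu,
                             stringsAsFactors = FALSE), "range")
    records <- out$records; truth <- out$truth
  }
  if (cf$n_deviation_outliers > 0) {
    # anchor each injected point on a compound's highest-temperature (lowest
    # viscosity) record: the bumped value stays well inside the range fences
    # and no later clean point follows it in the temperature scan
    clean_idx <- which(truth$type == "clean")
    anchors <- vapply(split(clean_idx, truth$smiles[clean_idx]), function(ix)
      ix[which.max(truth$temperature_K[ix])], integer(1))
    if (cf$n_deviation_outliers > length(anchors)) {
      stop_ctx("at most one deviation outlier per compound (%d available)",
               length(anchors))
    }
    pick_rows <- with_seed(derive_seed(cf$seed, 73),
                           sample(anchors, cf$n_deviation_outliers))
    bumps <- with_seed(derive_seed(cf$seed, 74),
                       stats::runif(cf$n_deviation_outliers, 0.05, 0.5))
    base <- records[pick_rows, , drop = FALSE]
    df <- data.frame(smiles = base$smiles,
                     temperature_K = base$temperature_K + 2.0,
                     viscosity_cP = base$viscosity_cP + bumps,
                     stringsAsFactors = FALSE)
    out <- inject(records, truth, df, "deviation")
    records <- out$records; truth <- out$truth
  }
  rownames(records) <- NULL
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

#' Surrogate external descriptors with tunable informativeness
#'
#' Builds eight columns named like the MD descriptors, each a mixture
#' `informativeness * g + (1 - informativeness) * noise` where `g` is a
#' documented monotone function of the row's noiseless log-viscosity (or a
#' structure-size summary) and the free-volume and RMS-displacement
#' analogues are built *negatively* related to viscosity. All columns are
#' standardized.
#'
#' @param dataset a `curated_dataset` (rows to cover).
#' @param truth ground-truth table from [generate_dataset()].
#' @param informativeness mixing weight in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame with `compound_id`, `temperature_K` and eight
#'   `MD_*` columns, joinable by [assemble_feature_matrix()].
#' @export
generate_surrogate_external_descriptors <- function(dataset, truth,
                                                    informativeness = 0.9,
                                                    seed = 0) {
  if (informativeness < 0 || informativeness > 1) {
    stop_ctx("informativeness must be in [0, 1]")
  }
  key_d <- paste(dataset$smiles, signif(dataset$temperature_K, 10))
  key_t <- paste(truth$smiles, signif(truth$temperature_K, 10))
  idx <- match(key_d, key_t)
  if (anyNA(idx)) stop_ctx("truth table does not cover %d dataset rows",
                           sum(is.na(idx)))
  s <- truth$log10_mu_clean[idx]
  nh <- truth$n_heavy[idx]
  if (anyNA(s)) stop_ctx("surrogate descriptors need clean (labeled) rows")
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  sz <- z(s); nz <- z(nh)
  signals <- list(MD_density = z(tanh(sz)), MD_FV = -sz,
                  MD_Rg = z(0.7 * nz + 0.3 * sz), MD_SP = z(0.9 * sz + 0.1 * nz),
                  MD_SP_E = z(0.8 * sz + 0.2 * nz), MD_SP_V = sz,
                  MD_HV = sz, MD_RMSD = -sz)
  n <- nrow(dataset)
  noise <- with_seed(derive_seed(seed, 81),
                     matrix(stats::rnorm(n * 8), n, 8))
  out <- data.frame(compound_id = dataset$compound_id,
                    temperature_K = dataset$temperature_K,
                    stringsAsFactors = FALSE)
  for (j in seq_along(signals)) {
    col <- informativeness * signals[[j]] + (1 - informativeness) * noise[, j]
    out[[names(signals)[j]]] <- z(col)
  }
  out
}

#' Analytic toy trajectories for the MD descriptor module
#'
#' Fixture catalog with analytically known descriptor values, attached as
#' `expected` metadata:
#' \describe{
#'   \item{single_sphere}{one atom (radius `r`) centered in a cubic box:
#'     free volume `100 (1 - (4/3) pi r^3 / L^3)`, Rg 0.}
#'   \item{dimer}{two equal masses at distance `d`: Rg `d/2`.}
#'   \item{square}{four equal masses at the corners of a square of side `a`:
#'     Rg `a/sqrt(2)`.}
#'   \item{lattice}{a cubic lattice of spheres, spacing `s`, radius `r`:
#'     free volume `100 (1 - (4/3) pi r^3 / s^3)`.}
#'   \item{translate}{all atoms rigidly shifted by `step` Angstrom per
#'     frame: RMS displacement `step * (0, 1, 2, ...)`.}
#'   \item{constant_energy}{static frames with constant intermolecular
#'     energies: analytic CED, solubility parameters and heat of
#'     vaporization.}
#' }
#'
#' @param case fixture name.
#' @param parameters named list of case parameters (see defaults in source).
#' @return list with `trajectory`, `topology` and `expected` (named list of
#'   analytic descriptor values).
#' @export
generate_toy_trajectory <- function(case, parameters = list()) {
  p <- parameters
  frame <- function(xyz, box, time, energies = NULL) {
    list(coordinates = xyz, box_lengths = box, time = time,
         energies = energies)
  }
  traj_of <- function(frames) structure(frames, class = "trajectory")
  if (case == "single_sphere") {
    L <- p$L %||% 10; r <- p$r %||% 1.7; m <- p$m %||% 18
    xyz <- matrix(L / 2, 1, 3)
    topo <- system_topology(m, 0L, vdw_radii = r)
    traj <- traj_of(lapply(0:2, function(t) frame(xyz, rep(L, 3), t)))
    expected <- list(MD_FV = 100 * (1 - (4 / 3) * pi * r^3 / L^3),
                     MD_Rg = 0,
                     MD_density = m * 1.66053906660e-24 / (L^3 * 1e-24),
                     MD_RMSD = 0)
  } else if (case == "dimer") {
    d <- p$d %||% 2; L <- p$L %||% 20; m <- p$m %||% 12
    xyz <- rbind(c(L / 2 - d / 2, L / 2, L / 2),
                 c(L / 2 + d / 2, L / 2, L / 2))
    topo <- system_topology(c(m, m), c(0L, 0L), vdw_radii = c(1.7, 1.7))
    traj <- traj_of(lapply(0:1, function(t) frame(xyz, rep(L, 3), t)))
    expected <- list(MD_Rg = d / 2)
  } else if (case == "square") {
    a <- p$a %||% 2; L <- p$L %||% 20; m <- p$m %||% 12
    c0 <- L / 2
    xyz <- rbind(c(c0, c0, c0), c(c0 + a, c0, c0),
                 c(c0, c0 + a, c0), c(c0 + a, c0 + a, c0))
    topo <- system_topology(rep(m, 4), rep(0L, 4), vdw_radii = rep(1.7, 4))
    traj <- traj_of(lapply(0:1, function(t) frame(xyz, rep(L, 3), t)))
    expected <- list(MD_Rg = a / sqrt(2))
  } else if (case == "lattice") {
    mside <- p$m_side %||% 3; s <- p$s %||% 4; r <- p$r %||% 1.5
    L <- mside * s
    g <- (seq_len(mside) - 0.5) * s
    xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
    colnames(xyz) <- NULL
    n <- nrow(xyz)
    topo <- system_topology(rep(18, n), seq_len(n) - 1L,
                            vdw_radii = rep(r, n))
    traj <- traj_of(lapply(0:1, function(t) frame(xyz, rep(L, 3), t)))
    expected <- list(MD_FV = 100 * (1 - (4 / 3) * pi * r^3 / s^3))
  } else if (case == "translate") {
    step <- p$step %||% 1; nf <- p$n_frames %||% 3; L <- p$L %||% 20
    xyz0 <- rbind(c(5, 5, 5), c(7, 5, 5))
    topo <- system_topology(c(12, 12), c(0L, 1L), vdw_radii = c(1.7, 1.7))
    traj <- traj_of(lapply(seq_len(nf) - 1, function(t) {
      frame(xyz0 + cbind(rep(step * t, 2), 0, 0), rep(L, 3), t)
    }))
    expected <- list(rmsd_per_frame = step * (seq_len(nf) - 1))
  } else if (case == "constant_energy") {
    L <- p$L %||% 46.42; n_mol <- p$n_molecules %||% 100
    e_inter <- p$e_inter %||% -1000
    e_elst <- p$e_elst %||% (0.4 * e_inter)
    e_vdw <- p$e_vdw %||% (0.6 * e_inter)
    T_K <- p$T_K %||% 300
    xyz <- matrix(stats::runif(n_mol * 3, 0, L), n_mol, 3)
    topo <- system_topology(rep(30, n_mol), seq_len(n_mol) - 1L,
                            vdw_radii = rep(1.7, n_mol))
    en <- c(total = e_inter, inter = e_inter, elst = e_elst, vdw = e_vdw)
    traj <- traj_of(lapply(0:2, function(t) frame(xyz, rep(L, 3), t, en)))
    conv <- 4184 / 6.02214076e-7 / 1e6
    ced <- -e_inter / L^3 * conv
    expected <- list(CED = ced, MD_SP = sqrt(ced),
                     MD_SP_E = sqrt(max(0, -e_elst / L^3 * conv)),
                     MD_SP_V = sqrt(max(0, -e_vdw / L^3 * conv)),
                     MD_HV = -e_inter / n_mol + 1.98720425864083e-3 * T_K,
                     T_K = T_K)
  } else {
    stop_ctx("unknown toy-trajectory case: %s", case)
  }
  list(trajectory = traj, topology = topo, expected = expected)
}
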