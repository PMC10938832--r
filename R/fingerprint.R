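# Hashed circular (Morgan/ECFP-style) fingerprints on the heavy-atom graph.
# No installed R package exposes circular fingerprints (OpenBabel's FP2 is
# path-based), so the environment-hashing loop is implemented here: iterated
# neighborhood invariants, every intermediate identifier hashed into a fixed
# number of bits.

# Initial atom invariant: element, heavy degree, implicit hydrogens.
.atom_invariant0 <- function(element, degree, n_h) {
  el_code <- hash_string(element)
  hash_ints(c(el_code, degree, n_h))
}

#' Hashed circular fingerprint of a molecule
#'
#' Computes ECFP-style circular atom environments up to `radius` bond steps
#' and hashes every environment identifier (all radii, 0..radius) into a
#' binary vector of `nbits` positions. Deterministic per canonical structure.
#'
#' @param mol parsed molecule (internal representation from
#'   `parse_molecules()`), with heavy-atom `atoms`, `bonds`, `implicit_h`.
#' @param nbits fingerprint length (default 1000).
#' @param radius maximum environment radius in bonds (default 2).
#' @return integer vector of 0/1 of length `nbits`, named `FP_0001`...
#' @export
morgan_fingerprint <- function(mol, nbits = 1000, radius = 2) {
  n <- length(mol$atoms)
  bits <- integer(nbits)
  names(bits) <- sprintf("FP_%04d", seq_len(nbits))
  if (n == 0) return(bits)

  nbr <- vector("list", n)
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$from[k]; b <- mol$bonds$to[k]; o <- mol$bonds$order[k]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
    }
  }
  degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  inv <- vapply(seq_len(n), function(i) {
    .atom_invariant0(mol$atoms[i], degree[i], mol$implicit_h[i])
  }, integer(1))

  ids <- unique(inv)
  for (r in seq_len(radius)) {
    new_inv <- integer(n)
    for (i in seq_len(n)) {
      if (is.null(nbr[[i]])) {
        new_inv[i] <- hash_ints(c(r, inv[i]))
      } else {
        pairs <- nbr[[i]]
        env <- cbind(pairs[, 2], inv[pairs[, 1]])
        ord <- order(env[, 1], env[, 2])
        new_inv[i] <- hash_ints(c(r, inv[i], t(env[ord, , drop = FALSE])))
      }
    }
    inv <- new_inv
    ids <- unique(c(ids, inv))
  }
  bits[(ids %% nbits) + 1L] <- 1L
  bits
}
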