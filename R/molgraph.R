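# Lightweight molecular graph extracted from a ChemmineR SDF entry: element
# symbols, bond list with orders, implicit hydrogen counts, ring perception
# with aromaticity flags, and topological distances. This is the substrate
# for the 2D descriptor set and the substructure key block.

STANDARD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1,
                      Na = 1, K = 1, Li = 1, Mg = 2, Ca = 2, Al = 3)

# element -> (mass, Pauling electronegativity, covalent radius A,
#             polarizability A^3, valence electrons)
ELEMENT_PROPS <- local({
  m <- rbind(
    H  = c(1.008,  2.20, 0.31, 0.67, 1),
    B  = c(10.81,  2.04, 0.85, 3.03, 3),
    C  = c(12.011, 2.55, 0.76, 1.76, 4),
    N  = c(14.007, 3.04, 0.71, 1.10, 5),
    O  = c(15.999, 3.44, 0.66, 0.80, 6),
    F  = c(18.998, 3.98, 0.57, 0.56, 7),
    Na = c(22.990, 0.93, 1.66, 24.11, 1),
    Mg = c(24.305, 1.31, 1.41, 10.60, 2),
    Al = c(26.982, 1.61, 1.21, 6.80, 3),
    Si = c(28.085, 1.90, 1.11, 5.38, 4),
    P  = c(30.974, 2.19, 1.07, 3.63, 5),
    S  = c(32.06,  2.58, 1.05, 2.90, 6),
    Cl = c(35.45,  3.16, 1.02, 2.18, 7),
    K  = c(39.098, 0.82, 2.03, 43.40, 1),
    Ca = c(40.078, 1.00, 1.76, 22.80, 2),
    Se = c(78.971, 2.55, 1.20, 3.77, 6),
    Br = c(79.904, 2.96, 1.20, 3.05, 7),
    I  = c(126.904, 2.66, 1.39, 5.35, 7))
  colnames(m) <- c("mass", "en", "rcov", "polar", "zval")
  m
})

element_prop <- function(elements, prop) {
  v <- ELEMENT_PROPS[match(elements, rownames(ELEMENT_PROPS)), prop]
  v[is.na(v)] <- ELEMENT_PROPS["C", prop]  # fallback for exotic elements
  v
}

# Parse a V2000 ctab (as produced by OpenBabel) into element symbols and a
# bond table. Done directly from the SDF text because high-level parsers
# mishandle degenerate single-atom / bond-less molecules.
parse_ctab <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(n_atoms) || n_atoms < 1L || is.na(n_bonds)) return(NULL)
  atom_lines <- lines[4L + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32L, 34L))
  if (any(!nzchar(elements))) return(NULL)
  if (n_bonds > 0L) {
    bond_lines <- lines[4L + n_atoms + seq_len(n_bonds)]
    bonds <- data.frame(
      from = as.integer(substr(bond_lines, 1L, 3L)),
      to = as.integer(substr(bond_lines, 4L, 6L)),
      order = as.integer(substr(bond_lines, 7L, 9L)))
  } else {
    bonds <- data.frame(from = integer(0), to = integer(0),
                        order = integer(0))
  }
  list(elements = elements, bonds = bonds)
}

# Parse one SMILES into a molecular graph. Returns NULL when unparseable.
mol_graph <- function(smiles) {
  txt <- try(suppressWarnings(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))),
    silent = TRUE)
  if (inherits(txt, "try-error") || !nzchar(trimws(txt))) return(NULL)
  ctab <- parse_ctab(txt)
  if (is.null(ctab)) return(NULL)
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(c(x = smiles))),
             silent = TRUE)
  if (inherits(sdf, "try-error") || length(sdf) == 0L) return(NULL)
  elements <- ctab$elements
  n <- length(elements)
  bonds <- ctab$bonds
  bonds <- bonds[bonds$from >= 1L & bonds$to >= 1L & bonds$from <= n &
                   bonds$to <= n, , drop = FALSE]
  degree <- integer(n)
  ordersum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    degree[bonds$from[i]] <- degree[bonds$from[i]] + 1L
    degree[bonds$to[i]] <- degree[bonds$to[i]] + 1L
    ordersum[bonds$from[i]] <- ordersum[bonds$from[i]] + bonds$order[i]
    ordersum[bonds$to[i]] <- ordersum[bonds$to[i]] + bonds$order[i]
  }
  val <- STANDARD_VALENCE[elements]
  val[is.na(val)] <- 0
  implicit_h <- pmax(0, val - ordersum)
  rings <- perceive_rings(sdf[[1]], elements, bonds)
  list(smiles = smiles, sdf = sdf, elements = elements, n = n,
       bonds = bonds, degree = degree, ordersum = ordersum,
       implicit_h = implicit_h, rings = rings)
}

# Ring perception: take candidate rings from ChemmineR, then greedily keep a
# minimal cycle basis (smallest rings first, each must cover a new bond) so
# fused systems are counted by their constituent small rings rather than
# their envelope cycles. Each kept ring records size, member atoms, whether
# it is aromatic, saturated (all ring bonds single), and its element content.
perceive_rings <- function(sdf1, elements, bonds) {
  empty <- list(size = integer(0), aromatic = logical(0),
                saturated = logical(0), carbon_only = logical(0),
                has_n = logical(0), has_hetero = logical(0),
                atoms = list())
  if (nrow(bonds) == 0L) return(empty)
  rr <- try(suppressWarnings(
    ChemmineR::rings(sdf1, upper = 10, type = "all", arom = TRUE)),
    silent = TRUE)
  if (inherits(rr, "try-error") || length(rr$RINGS) == 0L) return(empty)
  ring_atoms <- lapply(rr$RINGS, function(r) as.integer(sub("^.*_", "", r)))
  arom <- as.logical(rr$AROMATIC)
  sizes <- lengths(ring_atoms)
  ord <- order(sizes)
  n_cyc <- nrow(bonds) - length(elements) + n_components(length(elements), bonds)
  bond_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  ring_bonds <- function(atoms) {
    k <- length(atoms)
    mapply(bond_key, atoms, atoms[c(2:k, 1)])
  }
  covered <- character(0)
  keep <- integer(0)
  for (i in ord) {
    rb <- ring_bonds(ring_atoms[[i]])
    if (any(!(rb %in% covered))) {
      keep <- c(keep, i)
      covered <- union(covered, rb)
      if (length(keep) >= n_cyc) break
    }
  }
  all_bond_keys <- bond_key(bonds$from, bonds$to)
  orders <- stats::setNames(bonds$order, all_bond_keys)
  atoms_kept <- ring_atoms[keep]
  saturated <- vapply(atoms_kept, function(a) {
    all(orders[ring_bonds(a)] == 1L, na.rm = TRUE)
  }, logical(1))
  elems <- lapply(atoms_kept, function(a) elements[a])
  list(size = lengths(atoms_kept),
       aromatic = arom[keep],
       saturated = saturated,
       carbon_only = vapply(elems, function(e) all(e == "C"), logical(1)),
       has_n = vapply(elems, function(e) any(e == "N"), logical(1)),
       has_hetero = vapply(elems, function(e) any(e != "C"), logical(1)),
       atoms = atoms_kept)
}

n_components <- function(n, bonds) {
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) { comp[x] <<- comp[comp[x]]; x <- comp[x] }; x }
  for (i in seq_len(nrow(bonds))) {
    a <- find(bonds$from[i]); b <- find(bonds$to[i])
    if (a != b) comp[a] <- b
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# All-pairs topological distances by BFS; unreachable pairs are Inf.
topo_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$from[i]]] <- c(adj[[bonds$from[i]]], bonds$to[i])
    adj[[bonds$to[i]]] <- c(adj[[bonds$to[i]]], bonds$from[i])
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}
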