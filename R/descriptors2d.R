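# The continuous descriptor block: a pinned, versioned set of exactly 200
# two-dimensional physicochemical descriptors ("RDKIT2D" block, v1). The set
# combines whole-molecule properties from OpenBabel (logP, TPSA, molar
# refractivity, H-bond counts), composition counts, ring statistics, graph
# topological indices (Wiener, Balaban J, Kier kappa, connectivity chi), a
# topological distance-count profile, and Moreau-Broto / Moran / Geary
# autocorrelations over five atomic properties. The name list ships as a
# data file so the block width is stable across toolkit versions.

descriptor_2d_names <- function() {
  c("MW", "LogP", "MR", "TPSA", "HBA1", "HBA2", "HBD", "NumF",
    "nAtoms", "nHeavy", "nH", "nB", "nC", "nN", "nO", "nSi", "nP", "nS",
    "nCl", "nSe", "nBr", "nI", "nHetero", "nHalogen",
    "nBonds", "nBondsS", "nBondsD", "nBondsT", "nRotatable", "FracCSP3",
    "MeanBondOrder",
    "nRings", "nRingAtoms", "FracRingAtoms", "nAromRings", "nAliphRings",
    "nHeteroRings", "nRing3", "nRing4", "nRing5", "nRing6", "nRing7",
    "nRing8plus", "MaxRingSize",
    "nDeg1", "nDeg2", "nDeg3", "nDeg4", "MeanDegree", "MaxDegree",
    "Zagreb1", "Zagreb2", "GraphDensity", "FracTerminal",
    "Wiener", "MeanDistance", "BalabanJ", "Radius", "Diameter", "MeanEcc",
    "PetitjeanShape", "Kappa1", "Kappa2", "Kappa3", "Chi0", "Chi1", "Chi0v",
    "Chi1v",
    paste0("nPairsD", 1:10), "FracPairsWithin3", "TopoComplexity",
    as.vector(t(outer(c("ATSm", "ATSe", "ATSr", "ATSp", "ATSv"), 0:7,
                      paste0))),
    as.vector(t(outer(c("MoranM", "MoranE", "MoranR", "MoranP", "MoranV"),
                      1:8, paste0))),
    as.vector(t(outer(c("GearyM", "GearyE", "GearyR", "GearyP", "GearyV"),
                      1:8, paste0))))
}

autocorr_props <- c("mass", "en", "rcov", "polar", "zval")

# Moreau-Broto (ATS), Moran (I) and Geary (C) spatial autocorrelation of an
# atomic property over the topological distance matrix.
autocorrelations <- function(p, D) {
  n <- length(p)
  pbar <- mean(p)
  dev <- p - pbar
  ssd <- sum(dev^2)
  ats <- numeric(8); mor <- numeric(8); gea <- numeric(8)
  ats[1] <- sum(p^2)  # lag 0
  for (d in 1:8) {
    pairs <- which(D == d & upper.tri(D), arr.ind = TRUE)
    npairs <- nrow(pairs)
    if (d <= 7 && npairs > 0) {
      ats[d + 1] <- sum(p[pairs[, 1]] * p[pairs[, 2]])
    }
    if (npairs > 0 && ssd > 0 && n > 1) {
      mor[d] <- (sum(dev[pairs[, 1]] * dev[pairs[, 2]]) / npairs) /
        (ssd / n)
      gea[d] <- (sum((p[pairs[, 1]] - p[pairs[, 2]])^2) / (2 * npairs)) /
        (ssd / (n - 1))
    }
  }
  list(ats = ats, moran = mor, geary = gea)
}

compute_descriptors_2d_one <- function(g) {
  el <- g$elements
  n <- g$n
  bonds <- g$bonds
  deg <- g$degree
  prop <- as.data.frame(suppressWarnings(ChemmineR::propOB(g$sdf)))
  nH <- sum(g$implicit_h) + sum(el == "H")
  cnt <- function(e) sum(el == e)
  halogens <- c("F", "Cl", "Br", "I")
  v <- c(MW = prop$MW, LogP = prop$logP, MR = prop$MR, TPSA = prop$TPSA,
         HBA1 = prop$HBA1, HBA2 = prop$HBA2, HBD = prop$HBD, NumF = prop$nF)
  v <- c(v, nAtoms = n, nHeavy = sum(el != "H"), nH = nH,
         nB = cnt("B"), nC = cnt("C"), nN = cnt("N"), nO = cnt("O"),
         nSi = cnt("Si"), nP = cnt("P"), nS = cnt("S"), nCl = cnt("Cl"),
         nSe = cnt("Se"), nBr = cnt("Br"), nI = cnt("I"),
         nHetero = sum(!el %in% c("C", "H")),
         nHalogen = sum(el %in% halogens))
  nb <- nrow(bonds)
  sp3C <- if (cnt("C") > 0) {
    sum(vapply(which(el == "C"), function(i) {
      bi <- bonds$order[bonds$from == i | bonds$to == i]
      length(bi) == 0L || all(bi == 1L)
    }, logical(1))) / cnt("C")
  } else 0
  in_ring_bond <- rep(FALSE, nb)
  if (nb > 0 && length(g$rings$atoms)) {
    ring_pairs <- unlist(lapply(g$rings$atoms, function(a) {
      k <- length(a)
      paste(pmin(a, a[c(2:k, 1)]), pmax(a, a[c(2:k, 1)]))
    }))
    in_ring_bond <- paste(pmin(bonds$from, bonds$to),
                          pmax(bonds$from, bonds$to)) %in% ring_pairs
  }
  rot <- if (nb > 0) {
    sum(bonds$order == 1L & !in_ring_bond &
          deg[bonds$from] >= 2L & deg[bonds$to] >= 2L)
  } else 0
  v <- c(v, nBonds = nb, nBondsS = sum(bonds$order == 1L),
         nBondsD = sum(bonds$order == 2L), nBondsT = sum(bonds$order == 3L),
         nRotatable = rot, FracCSP3 = sp3C,
         MeanBondOrder = if (nb > 0) mean(bonds$order) else 0)
  rg <- g$rings
  nring <- length(rg$size)
  ring_atoms <- unique(unlist(rg$atoms))
  v <- c(v, nRings = nring, nRingAtoms = length(ring_atoms),
         FracRingAtoms = if (n > 0) length(ring_atoms) / n else 0,
         nAromRings = sum(rg$aromatic),
         nAliphRings = sum(!rg$aromatic),
         nHeteroRings = sum(rg$has_hetero),
         nRing3 = sum(rg$size == 3), nRing4 = sum(rg$size == 4),
         nRing5 = sum(rg$size == 5), nRing6 = sum(rg$size == 6),
         nRing7 = sum(rg$size == 7), nRing8plus = sum(rg$size >= 8),
         MaxRingSize = if (nring > 0) max(rg$size) else 0)
  v <- c(v, nDeg1 = sum(deg == 1L), nDeg2 = sum(deg == 2L),
         nDeg3 = sum(deg == 3L), nDeg4 = sum(deg >= 4L),
         MeanDegree = if (n > 0) mean(deg) else 0,
         MaxDegree = if (n > 0) max(deg) else 0,
         Zagreb1 = sum(deg^2),
         Zagreb2 = if (nb > 0) sum(deg[bonds$from] * deg[bonds$to]) else 0,
         GraphDensity = if (n > 1) 2 * nb / (n * (n - 1)) else 0,
         FracTerminal = if (n > 0) sum(deg == 1L) / n else 0)
  D <- topo_distances(n, bonds)
  finD <- D[upper.tri(D) & is.finite(D)]
  ecc <- apply(D, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f)) max(f) else 0
  })
  radius <- if (n > 0) min(ecc) else 0
  diam <- if (n > 0) max(ecc) else 0
  # Balaban J over finite distances; gamma is the cyclomatic number
  balaban <- 0
  if (nb > 0) {
    s <- apply(D, 1, function(r) sum(r[is.finite(r)]))
    gamma <- nb - n + n_components(n, bonds)
    terms <- 1 / sqrt(s[bonds$from] * s[bonds$to])
    terms <- terms[is.finite(terms)]
    balaban <- nb / (gamma + 1) * sum(terms)
  }
  # Kier kappa from path counts
  paths2 <- if (n > 0) sum(deg * (deg - 1) / 2) else 0
  paths3 <- 0
  if (nb > 0) {
    for (i in seq_len(nb)) {
      a <- bonds$from[i]; b <- bonds$to[i]
      paths3 <- paths3 + (deg[a] - 1) * (deg[b] - 1)
    }
    # subtract triangle double-counts
    paths3 <- paths3 - 3 * sum(rg$size == 3)
  }
  kappa1 <- if (nb > 0) n * (n - 1)^2 / nb^2 else 0
  kappa2 <- if (paths2 > 0) (n - 1) * (n - 2)^2 / paths2^2 else 0
  kappa3 <- if (paths3 > 0) {
    if (n %% 2 == 1) (n - 1) * (n - 3)^2 / paths3^2
    else (n - 3) * (n - 2)^2 / paths3^2
  } else 0
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- if (nb > 0) sum(1 / sqrt(deg[bonds$from] * deg[bonds$to])) else 0
  dv <- element_prop(el, "zval") - g$implicit_h
  dv[dv <= 0] <- NA
  chi0v <- sum(1 / sqrt(dv), na.rm = TRUE)
  chi1v <- if (nb > 0) {
    sum(1 / sqrt(dv[bonds$from] * dv[bonds$to]), na.rm = TRUE)
  } else 0
  v <- c(v, Wiener = sum(finD), MeanDistance = if (length(finD)) mean(finD) else 0,
         BalabanJ = balaban, Radius = radius, Diameter = diam,
         MeanEcc = if (n > 0) mean(ecc) else 0,
         PetitjeanShape = if (radius > 0) (diam - radius) / radius else 0,
         Kappa1 = kappa1, Kappa2 = kappa2, Kappa3 = kappa3,
         Chi0 = chi0, Chi1 = chi1, Chi0v = chi0v, Chi1v = chi1v)
  pair_counts <- vapply(1:10, function(d) sum(finD == d), numeric(1))
  names(pair_counts) <- paste0("nPairsD", 1:10)
  v <- c(v, pair_counts,
         FracPairsWithin3 = if (length(finD)) sum(finD <= 3) / length(finD) else 0,
         TopoComplexity = sum(deg[deg > 1] * log2(deg[deg > 1])))
  prop_tag <- c(mass = "m", en = "e", rcov = "r", polar = "p", zval = "v")
  for (pr in autocorr_props) {
    p <- element_prop(el, pr)
    ac <- autocorrelations(p, D)
    tag <- prop_tag[[pr]]
    nm_ats <- paste0("ATS", tag, 0:7)
    nm_mor <- paste0("Moran", toupper(tag), 1:8)
    nm_gea <- paste0("Geary", toupper(tag), 1:8)
    v <- c(v, stats::setNames(ac$ats, nm_ats),
           stats::setNames(ac$moran, nm_mor),
           stats::setNames(ac$geary, nm_gea))
  }
  v
}

#' Pinned 200-descriptor 2D physicochemical block
#'
#' Computes the versioned 200-descriptor set for each molecule. Descriptor
#' values that evaluate to `NaN` or infinity are replaced by 0 with a
#' warning, so downstream matrix operations never see non-finite values.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix, one row per molecule, 200 named columns.
#' @export
fp_rdkit2d <- function(smiles) {
  nms <- descriptor_2d_names()
  stopifnot(length(nms) == 200L)
  out <- matrix(0, length(smiles), 200L, dimnames = list(NULL, nms))
  for (i in seq_along(smiles)) {
    g <- mol_graph(smiles[i])
    if (is.null(g)) stop("RDKIT2D: cannot process SMILES (row ", i, "): ",
                         smiles[i])
    vals <- compute_descriptors_2d_one(g)
    vals <- vals[nms]
    bad <- !is.finite(vals)
    if (any(bad)) {
      rega_warn("RDKIT2D: ", sum(bad), " non-finite descriptor value(s) ",
                "replaced by 0 for SMILES: ", smiles[i])
      vals[bad] <- 0
    }
    out[i, ] <- vals
  }
  out
}
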