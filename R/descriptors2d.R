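# Ertl fragment-contribution table for topological polar surface area.
# Each row is one polar-atom environment, written as a single-atom SMARTS
# (environment constraints via D/X/H/charge/ring primitives and recursive
# $() patterns) so that every match is exactly one atom and the classes are
# mutually exclusive. Contributions in squared angstroms.
tpsa_contribs <- function() {
  data.frame(
    element = c(rep("N", 26), rep("O", 6), rep("S", 7), rep("P", 4)),
    smarts = c(
      # --- neutral aliphatic N ---
      "[N;A;X3;H0;+0;!$([N]=*);!$([N]#*);!r3]",   # N(-*)(-*)-*
      "[N;A;X3;H0;+0;!$([N]=*);!$([N]#*);r3]",    # 3-ring amine N
      "[N;A;X2;H0;+0;$([N](=*)-*)]",              # N(-*)=*
      "[N;A;X1;H0;+0;$([N]#*)]",                  # N#*
      "[N;A;X3;H0;+0;$([N](=*)=*)]",              # N(-*)(=*)=* (uncharged nitro)
      "[N;A;X2;H0;+0;$([N](#*)=*)]",              # N(=*)#*
      "[N;A;X3;H1;+0;!$([N]=*);!r3]",             # NH(-*)-*
      "[N;A;X3;H1;+0;!$([N]=*);r3]",              # 3-ring NH
      "[N;A;X2;H1;+0;$([N]=*)]",                  # NH=*
      "[N;A;X3;H2;+0;!$([N]=*)]",                 # NH2-*
      # --- charged aliphatic N ---
      "[N;A;X4;H0;+1]",                           # N+(-*)(-*)(-*)-*
      "[N;A;X3;H0;+1;$([N]=*);!$([N]#*)]",        # N+(-*)(-*)=*
      "[N;A;X2;H0;+1;$([N]#*)]",                  # N+(-*)#*
      "[N;A;X4;H1;+1]",                           # NH+(-*)(-*)-*
      "[N;A;X3;H1;+1;$([N]=*)]",                  # NH+(-*)=*
      "[N;A;X4;H2;+1]",                           # NH2+(-*)-*
      "[N;A;X3;H2;+1;$([N]=*)]",                  # NH2+=*
      "[N;A;X4;H3;+1]",                           # NH3+-*
      # --- aromatic N ---
      "[n;X2;H0;+0]",                             # n(:*):*
      "[n;X3;H0;+0;!$([n]-*);!$([n]=*)]",         # n(:*)(:*):*
      "[n;X3;H0;+0;$([n]-*)]",                    # n(-*)(:*):*
      "[n;X3;H0;+0;$([n]=*)]",                    # n(=*)(:*):* (aromatic N-oxide form)
      "[n;H1;+0]",                                # nH
      "[n;X3;H0;+1;!$([n]-*)]",                   # n+(:*)(:*):*
      "[n;X3;H0;+1;$([n]-*)]",                    # n+(-*)(:*):*
      "[n;H1;+1]",                                # nH+
      # --- O ---
      "[O;A;X2;H0;+0;!r3]",                       # O(-*)-*
      "[O;A;X2;H0;+0;r3]",                        # 3-ring ether O
      "[O;A;X1;H0;+0]",                           # O=*
      "[O;A;X2;H1;+0]",                           # OH-*
      "[O;A;X1;H0;-1]",                           # O- (-*)
      "[o;+0]",                                   # aromatic o
      # --- S (opt-in) ---
      "[S;A;X2;H0;+0;!$([S]=*)]",                 # S(-*)-*
      "[S;A;X1;H0;+0;$([S]=*)]",                  # S=*
      "[S;A;X3;H0;+0;$([S]=*)]",                  # sulfoxide S
      "[S;A;X4;H0;+0;$([S](=*)=*)]",              # sulfone S
      "[S;A;X2;H1;+0]",                           # SH-*
      "[s;X2;+0]",                                # aromatic s
      "[s;X3;+0;$([s]=*)]",                       # aromatic s with exocyclic =
      # --- P (opt-in) ---
      "[P;A;X3;H0;+0;!$([P]=*)]",                 # P(-*)(-*)-*
      "[P;A;X2;H0;+0;$([P]=*)]",                  # P(-*)=*
      "[P;A;X4;H0;+0;$([P]=*)]",                  # P(-*)(-*)(-*)=*
      "[P;A;X4;H1;+0;$([P]=*)]"                   # PH(-*)(-*)=*
    ),
    contrib = c(
      3.24, 3.01, 12.36, 23.79, 11.68, 13.60, 12.03, 21.94, 23.85, 26.02,
      0.00, 3.01, 4.36, 4.44, 13.97, 16.61, 25.59, 27.64,
      12.89, 4.41, 4.93, 8.39, 15.79, 4.10, 3.88, 14.53,
      9.23, 12.53, 17.07, 20.23, 23.06, 13.14,
      25.30, 32.09, 19.21, 8.38, 38.80, 28.24, 21.70,
      13.59, 34.14, 9.81, 23.47
    ),
    stringsAsFactors = FALSE
  )
}

#' Count carbon atoms
#'
#' Number of carbon atoms in the heavy-atom connection table (nC), one of the
#' three descriptors spanning the PROTAC chemical space.
#'
#' @param structures an \code{SDFset}, a single \code{SDF}, or a character
#'   vector of SMILES.
#' @param ids optional ids when \code{structures} is a SMILES vector.
#' @return named integer vector.
#' @examples
#' count_carbons(c(benzene = "c1ccccc1", water = "O"))
#' @export
count_carbons <- function(structures, ids = NULL) {
  sdf <- as_sdfset(structures, ids)
  out <- vapply(seq_along(sdf), function(i) {
    sum(mol_graph(sdf[i])$elements == "C")
  }, integer(1))
  stats::setNames(out, ChemmineR::cid(sdf))
}

#' Topological polar surface area (Ertl fragment contributions)
#'
#' Sums Ertl's published fragment contributions over the N and O atom
#' environments of a molecule (and S/P environments when
#' \code{include_sp = TRUE}). Atom environments are matched with single-atom
#' SMARTS patterns through OpenBabel, so the value is determined entirely by
#' the connection table and is invariant to atom order and to the input
#' kekulization.
#'
#' The default is the common N,O-only parameterization; several descriptor
#' packages instead include the S and P contributions of the extended table,
#' so thresholds learned on one variant should not be reused with the other.
#'
#' @param structures an \code{SDFset}, a single \code{SDF}, or a character
#'   vector of SMILES.
#' @param include_sp logical; also add S and P contributions.
#' @param ids optional ids when \code{structures} is a SMILES vector.
#' @return named numeric vector, squared angstroms.
#' @examples
#' compute_tpsa(c(benzene = "c1ccccc1", ethanol = "CCO"))
#' @export
compute_tpsa <- function(structures, include_sp = FALSE, ids = NULL) {
  sdf <- as_sdfset(structures, ids)
  tab <- tpsa_contribs()
  if (!include_sp) tab <- tab[tab$element %in% c("N", "O"), ]
  counts <- matrix(0, nrow = length(sdf), ncol = nrow(tab))
  for (j in seq_len(nrow(tab))) {
    counts[, j] <- suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, tab$smarts[j], uniqueMatches = FALSE)
    )
  }
  tpsa <- as.numeric(counts %*% tab$contrib)
  # every polar atom should be classified exactly once; warn if an exotic
  # environment fell outside the table (its contribution is then 0)
  polar_q <- if (include_sp) "[#7,#8,#16,#15]" else "[#7,#8]"
  npolar <- suppressWarnings(
    ChemmineR::smartsSearchOB(sdf, polar_q, uniqueMatches = FALSE)
  )
  nmatched <- rowSums(counts)
  if (any(nmatched != npolar)) {
    off <- ChemmineR::cid(sdf)[nmatched != npolar]
    warning("unclassified or multiply-classified polar atom(s) in: ",
            paste(off, collapse = ", "))
  }
  stats::setNames(round(tpsa, 2), ChemmineR::cid(sdf))
}

# Hall-Kier alpha corrections (covalent-radius ratios relative to sp3 carbon),
# indexed by element and hybridization (sp, sp2, sp3). Halogens are
# hybridization-independent. Unknown environments fall back to 0 with a warning.
kier_alpha_table <- list(
  C  = c(sp = -0.22, sp2 = -0.13, sp3 = 0.00),
  N  = c(sp = -0.29, sp2 = -0.20, sp3 = -0.04),
  O  = c(sp = NA,    sp2 = -0.20, sp3 = -0.04),
  S  = c(sp = NA,    sp2 = 0.22,  sp3 = 0.35),
  P  = c(sp = NA,    sp2 = 0.30,  sp3 = 0.43),
  F  = c(sp = -0.07, sp2 = -0.07, sp3 = -0.07),
  Cl = c(sp = 0.29,  sp2 = 0.29,  sp3 = 0.29),
  Br = c(sp = 0.48,  sp2 = 0.48,  sp3 = 0.48),
  I  = c(sp = 0.73,  sp2 = 0.73,  sp3 = 0.73)
)

# Hybridization from explicit bond orders of the (kekulized) heavy-atom graph:
# a triple bond or two double bonds -> sp; any double or aromatic (order 4)
# bond -> sp2; otherwise sp3. Applied uniformly, so the result does not depend
# on which kekule form the input uses for even-membered aromatic rings.
#' @keywords internal
atom_hybridization <- function(graph) {
  n <- length(graph$elements)
  ndouble <- ntriple <- naromatic <- integer(n)
  b <- graph$bonds
  for (k in seq_len(nrow(b))) {
    for (a in c(b$a1[k], b$a2[k])) {
      if (b$order[k] == 2) ndouble[a] <- ndouble[a] + 1L
      if (b$order[k] == 3) ntriple[a] <- ntriple[a] + 1L
      if (b$order[k] == 4) naromatic[a] <- naromatic[a] + 1L
    }
  }
  ifelse(ntriple > 0 | ndouble >= 2, "sp",
         ifelse(ndouble > 0 | naromatic > 0, "sp2", "sp3"))
}

#' Kier molecular flexibility index (Phi)
#'
#' Computes the alpha-modified kappa shape indices of the hydrogen-suppressed
#' graph and returns \eqn{\Phi = {}^1\kappa_\alpha \, {}^2\kappa_\alpha / A},
#' where \eqn{A} is the heavy-atom count,
#' \eqn{{}^1\kappa_\alpha = (A+\alpha)(A+\alpha-1)^2/({}^1P+\alpha)^2},
#' \eqn{{}^2\kappa_\alpha = (A+\alpha-1)(A+\alpha-2)^2/({}^2P+\alpha)^2},
#' \eqn{{}^1P} is the edge count, \eqn{{}^2P} the number of paths of length
#' two, and \eqn{\alpha} sums Kier's hardness corrections relative to sp3
#' carbon (see \code{kier_alpha_table}; hybridization is perceived from
#' explicit bond orders, so conjugated single-bonded N/O count as sp3).
#'
#' For an unbranched chain of A sp3 carbons the index collapses to
#' \eqn{\Phi = A - 1}.
#'
#' @inheritParams count_carbons
#' @return named numeric vector.
#' @section Errors: molecules with fewer than 3 heavy atoms (no length-2
#'   path exists) raise an error of class \code{protacsol_undefined_index}.
#' @examples
#' compute_kier_phi("CCCCCC") # n-hexane: 5
#' @export
compute_kier_phi <- function(structures, ids = NULL) {
  sdf <- as_sdfset(structures, ids)
  out <- vapply(seq_along(sdf), function(i) {
    g <- mol_graph(sdf[i])
    A <- length(g$elements)
    deg <- tabulate(c(g$bonds$a1, g$bonds$a2), nbins = A)
    P1 <- nrow(g$bonds)
    P2 <- sum(choose(deg, 2))
    if (A < 3 || P2 == 0) {
      stop(structure(
        class = c("protacsol_undefined_index", "error", "condition"),
        list(message = sprintf(
          "Kier flexibility undefined for %s: need >= 3 heavy atoms with a length-2 path",
          ChemmineR::cid(sdf)[i]), call = NULL)
      ))
    }
    hyb <- atom_hybridization(g)
    alpha_i <- mapply(function(el, hy) {
      row <- kier_alpha_table[[el]]
      if (is.null(row) || is.na(row[[hy]])) {
        warning("no Kier alpha for element ", el, " (", hy, "); using 0")
        return(0)
      }
      row[[hy]]
    }, g$elements, hyb)
    alpha <- sum(alpha_i)
    k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
    k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
    k1 * k2 / A
  }, numeric(1))
  stats::setNames(out, ChemmineR::cid(sdf))
}

#' Molecular weight from structure
#'
#' Average-mass molecular weight computed by OpenBabel (implicit hydrogens
#' included).
#'
#' @inheritParams count_carbons
#' @return named numeric vector, g/mol.
#' @export
compute_mw <- function(structures, ids = NULL) {
  sdf <- as_sdfset(structures, ids)
  props <- ChemmineR::propOB(sdf)
  stats::setNames(props$MW, ChemmineR::cid(sdf))
}

#' 2D descriptor profile
#'
#' Convenience wrapper computing the chemical-space descriptors nC, TPSA and
#' Kier Phi (plus molecular weight) for a set of structures.
#'
#' @inheritParams compute_tpsa
#' @return data.frame with columns \code{id}, \code{nc}, \code{tpsa},
#'   \code{phi}, \code{mw}.
#' @examples
#' descriptor_profile(c(caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
#' @export
descriptor_profile <- function(structures, include_sp = FALSE, ids = NULL) {
  sdf <- as_sdfset(structures, ids)
  data.frame(
    id = ChemmineR::cid(sdf),
    nc = unname(count_carbons(sdf)),
    tpsa = unname(compute_tpsa(sdf, include_sp = include_sp)),
    phi = unname(compute_kier_phi(sdf)),
    mw = unname(compute_mw(sdf)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
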