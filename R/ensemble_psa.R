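# Bondi van der Waals radii (angstroms) for the elements that occur in the
# ensembles; polar hydrogens use 1.20.
bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Deterministic quasi-uniform sphere point set
#'
#' Fibonacci-spiral lattice of n points on the unit sphere. Deterministic for
#' a given n, so repeated surface-area evaluations are bit-identical.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n) - 1)
  cbind(r * cos(theta), r * sin(theta), z)
}

# Polar-atom selection: N, O (S optionally) and hydrogens attached to N/O.
# Attachment comes from the bond list when one is available (SDF input);
# otherwise a hydrogen is taken as polar when its nearest heavy atom within
# 1.3 angstroms is N or O.
polar_atom_mask <- function(elements, coords, bonds = NULL,
                            include_sulfur = FALSE) {
  polar_heavy <- c("N", "O", if (include_sulfur) "S")
  mask <- elements %in% polar_heavy
  hs <- which(elements == "H")
  if (length(hs) > 0) {
    for (h in hs) {
      if (!is.null(bonds)) {
        nb <- c(bonds$a2[bonds$a1 == h], bonds$a1[bonds$a2 == h])
      } else {
        d <- sqrt(colSums((t(coords) - coords[h, ])^2))
        d[h] <- Inf
        heavy <- which(elements != "H")
        nb <- heavy[which.min(d[heavy])]
        if (length(nb) == 1 && d[nb] > 1.3) nb <- integer(0)
      }
      if (any(elements[nb] %in% c("N", "O"))) mask[h] <- TRUE
    }
  }
  mask
}

#' 3D polar surface area of one conformer
#'
#' Exposed van der Waals surface area (probe radius 0) summed over the polar
#' atoms: N, O, hydrogens bonded to N or O, and optionally S. Each polar
#' atom's sphere is sampled with a deterministic spiral point set and a point
#' counts as exposed when it lies outside every other atom's sphere; the
#' atom's contribution is (exposed fraction) x 4 pi r^2.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n_atoms x 3), cartesian angstroms.
#' @param bonds optional bond data.frame (\code{a1}, \code{a2}) used to
#'   attribute hydrogens to heavy atoms; distance-based otherwise.
#' @param n_points sphere points per atom (default 960; error well under 1\%
#'   on small test systems and recorded in the result attributes).
#' @param include_sulfur also count S as polar (default FALSE).
#' @return polar surface area, squared angstroms, with attributes
#'   \code{n_points} and \code{include_sulfur}.
#' @section Errors: an element without a tabulated radius raises a
#'   parameterization error.
#' @examples
#' compute_3d_psa("O", matrix(0, 1, 3)) # full sphere: 4*pi*1.52^2
#' @export
compute_3d_psa <- function(elements, coords, bonds = NULL, n_points = 960,
                           include_sulfur = FALSE) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3,
            all(is.finite(coords)))
  unknown <- setdiff(unique(elements), names(bondi_radii))
  if (length(unknown) > 0) {
    stop(structure(class = c("protacsol_parameterization_error", "error", "condition"),
                   list(message = paste0("no van der Waals radius for element(s): ",
                                         paste(unknown, collapse = ", ")), call = NULL)))
  }
  radii <- bondi_radii[elements]
  mask <- polar_atom_mask(elements, coords, bonds, include_sulfur)
  pts <- sphere_points(n_points)
  total <- 0
  for (i in which(mask)) {
    surf <- pts * radii[i] + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    exposed <- rep(TRUE, n_points)
    for (j in seq_along(elements)) {
      if (j == i) next
      d2 <- (surf[, 1] - coords[j, 1])^2 + (surf[, 2] - coords[j, 2])^2 +
        (surf[, 3] - coords[j, 3])^2
      exposed <- exposed & d2 > radii[j]^2
      if (!any(exposed)) break
    }
    total <- total + mean(exposed) * 4 * pi * radii[i]^2
  }
  structure(total, n_points = n_points, include_sulfur = include_sulfur)
}

#' Conformer ensemble container
#'
#' @param compound_id identifier.
#' @param elements character vector shared by all conformers.
#' @param conformers list of coordinate matrices (n_atoms x 3).
#' @param source provenance label, e.g. \code{"CS"} (conformational
#'   sampling), \code{"SMD"} (steered molecular dynamics), \code{"other"}.
#' @param bonds optional bond data.frame.
#' @return object of class \code{protacsol_ensemble}.
#' @export
conformer_ensemble <- function(compound_id, elements, conformers,
                               source = "other", bonds = NULL) {
  stopifnot(length(conformers) >= 1)
  for (cf in conformers) {
    stopifnot(nrow(as.matrix(cf)) == length(elements))
  }
  structure(list(compound_id = compound_id, elements = elements,
                 conformers = lapply(conformers, as.matrix),
                 source = source, bonds = bonds),
            class = "protacsol_ensemble")
}

#' Read a conformer ensemble from a multi-record SDF
#'
#' All records must share one atom list (same elements in the same order).
#'
#' @param path SDF file with one record per conformer.
#' @param compound_id identifier (defaults to the first record's id).
#' @param source provenance label.
#' @return a \code{protacsol_ensemble}.
#' @export
read_ensemble_sdf <- function(path, compound_id = NULL, source = "other") {
  sdf <- ChemmineR::read.SDFset(path)
  graphs <- lapply(seq_along(sdf), function(i) mol_graph(sdf[i]))
  els <- lapply(seq_along(sdf), function(i) {
    ab <- ChemmineR::atomblock(sdf[[i]])
    sub("_.*$", "", rownames(ab))
  })
  for (e in els) {
    if (!identical(e, els[[1]])) stop("conformers do not share one atom list")
  }
  coords <- lapply(seq_along(sdf), function(i) {
    unname(ChemmineR::atomblock(sdf[[i]])[, 1:3, drop = FALSE])
  })
  bb <- ChemmineR::bondblock(sdf[[1]])
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]))
  if (is.null(compound_id)) compound_id <- ChemmineR::cid(sdf)[1]
  conformer_ensemble(compound_id, els[[1]], coords, source, bonds)
}

#' Read a conformer ensemble from a multi-model PDB
#'
#' Models of a multi-model PDB (e.g. frames extracted from a trajectory)
#' become conformers. Hydrogen polarity is assigned by nearest-neighbour
#' distance since PDB files carry no bond orders.
#'
#' @param path PDB file.
#' @param compound_id identifier (defaults to the file name).
#' @param source provenance label.
#' @return a \code{protacsol_ensemble}.
#' @export
read_ensemble_pdb <- function(path, compound_id = NULL, source = "other") {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  elements <- pdb$atom$elesy
  if (all(is.na(elements)) || is.null(elements)) {
    elements <- substr(trimws(pdb$atom$elety), 1, 1)
  }
  nm <- dim(pdb$xyz)[1]
  coords <- lapply(seq_len(nm), function(m) {
    matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
  })
  if (is.null(compound_id)) compound_id <- basename(path)
  conformer_ensemble(compound_id, trimws(elements), coords, source)
}

#' Quartile / adjacent-limit summary of per-conformer PSA values
#'
#' Median and quartiles by linear interpolation between order statistics;
#' Tukey inner fences at Q1 - 1.5 IQR and Q3 + 1.5 IQR; the lower adjacent
#' limit is the smallest data value at or above the lower fence and the upper
#' adjacent limit the largest data value at or below the upper fence (the
#' violin-plot whisker bounds).
#'
#' @param psa numeric vector of per-conformer PSA values (>= 1).
#' @return object of class \code{protacsol_psa_distribution}: list with
#'   \code{per_conformer_psa}, \code{median}, \code{q1}, \code{q3},
#'   \code{lower_adjacent}, \code{upper_adjacent}.
#' @examples
#' summarize_ensemble(c(10, 12, 14, 16, 100))$upper_adjacent # 16
#' @export
summarize_ensemble <- function(psa) {
  if (length(psa) < 1) {
    stop(structure(class = c("protacsol_domain_error", "error", "condition"),
                   list(message = "empty PSA vector", call = NULL)))
  }
  q <- unname(stats::quantile(psa, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lower_fence <- q[1] - 1.5 * iqr
  upper_fence <- q[3] + 1.5 * iqr
  # adjacent limits are data members; in the degenerate case where no data
  # value lies between a quartile and its fence (possible with interpolated
  # quartiles and extreme outliers) they fall back to the quartile itself
  lower_adj <- min(psa[psa >= lower_fence])
  upper_adj <- max(psa[psa <= upper_fence])
  structure(list(per_conformer_psa = psa,
                 median = q[2], q1 = q[1], q3 = q[3],
                 lower_adjacent = min(lower_adj, q[1]),
                 upper_adjacent = max(upper_adj, q[3])),
            class = "protacsol_psa_distribution")
}

#' Per-conformer PSA distribution of an ensemble
#'
#' @param ensemble a \code{protacsol_ensemble}.
#' @param ... passed to \code{\link{compute_3d_psa}}.
#' @return a \code{protacsol_psa_distribution} (see
#'   \code{\link{summarize_ensemble}}) with the compound id attached.
#' @export
ensemble_psa_distribution <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "protacsol_ensemble"))
  psa <- vapply(ensemble$conformers, function(cf) {
    as.numeric(compute_3d_psa(ensemble$elements, cf, bonds = ensemble$bonds, ...))
  }, numeric(1))
  out <- summarize_ensemble(psa)
  out$compound_id <- ensemble$compound_id
  out$source <- ensemble$source
  out
}

#' Regressions of log S on the five representative PSA statistics
#'
#' For each of the five representative statistics of the per-compound PSA
#' distributions (lower adjacent limit, Q1, median, Q3, upper adjacent
#' limit), an OLS fit of log S versus that statistic.
#'
#' @param distributions list of \code{protacsol_psa_distribution} objects
#'   with compound ids.
#' @param log_s named numeric vector of quantitative log S values, names =
#'   compound ids.
#' @return data.frame with columns \code{statistic}, \code{slope},
#'   \code{intercept}, \code{r2}, \code{n}.
#' @export
representative_psa_regressions <- function(distributions, log_s) {
  ids <- vapply(distributions, function(d) d$compound_id, character(1))
  keep <- ids %in% names(log_s)
  if (sum(keep) < 3) {
    stop(structure(class = c("protacsol_insufficient_data_error", "error", "condition"),
                   list(message = "need >= 3 compounds with both a PSA distribution and log S",
                        call = NULL)))
  }
  distributions <- distributions[keep]
  y <- log_s[ids[keep]]
  stats_names <- c("lower_adjacent", "q1", "median", "q3", "upper_adjacent")
  rows <- lapply(stats_names, function(s) {
    x <- vapply(distributions, function(d) d[[s]], numeric(1))
    fit <- fit_linear(x, y, x_name = s, y_name = "log_s")
    data.frame(statistic = s, slope = fit$slope, intercept = fit$intercept,
               r2 = fit$r2, n = fit$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
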