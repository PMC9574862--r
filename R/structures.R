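#' Parse SMILES strings into an SDFset
#'
#' Wraps \code{ChemmineR::smiles2sdf} with per-record error collection so one
#' malformed structure does not abort a whole table. Parsing (including
#' aromaticity handling and kekulization) is delegated to OpenBabel.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional character vector of identifiers (same length); used to
#'   name the returned molecules and to report failures.
#' @return an \code{SDFset} with one molecule per successfully parsed SMILES.
#' @section Errors: if any SMILES fails to parse, an error of class
#'   \code{protacsol_structure_error} is thrown listing the offending ids.
#' @examples
#' sdf <- parse_smiles(c("CCO", "c1ccccc1"), ids = c("ethanol", "benzene"))
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) {
    ids <- if (!is.null(names(smiles))) names(smiles)
           else paste0("CMP", seq_along(smiles))
  }
  stopifnot(length(ids) == length(smiles))
  out <- vector("list", length(smiles))
  bad <- character(0)
  for (i in seq_along(smiles)) {
    res <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], ids[i]))),
      error = function(e) NULL
    )
    if (is.null(res)) bad <- c(bad, ids[i]) else out[[i]] <- res
  }
  if (length(bad) > 0) {
    stop(structure(
      class = c("protacsol_structure_error", "error", "condition"),
      list(message = paste0("unparsable structure for id(s): ",
                            paste(bad, collapse = ", ")),
           call = sys.call(-1), ids = bad)
    ))
  }
  sdfset <- methods::new("SDFset",
                         SDF = lapply(out, function(x) x[[1]]),
                         ID = ids)
  sdfset
}

#' Heavy-atom table of a molecule
#'
#' Returns element symbols, formal charges and the heavy-atom bond list of a
#' single \code{SDF}/\code{SDFset} molecule, with explicit hydrogens stripped
#' from the graph (their count per heavy atom is retained).
#'
#' @param mol an \code{SDF} or a length-one \code{SDFset}.
#' @return list with \code{elements} (character), \code{charge} (integer),
#'   \code{nH_explicit} (integer, explicit H neighbours per heavy atom), and
#'   \code{bonds} (data.frame \code{a1}, \code{a2}, \code{order}; order 4
#'   denotes an aromatic bond as written in the input).
#' @keywords internal
mol_graph <- function(mol) {
  if (is(mol, "SDFset")) {
    stopifnot(length(mol) == 1)
    mol <- mol[[1]]
  }
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_.*$", "", rownames(ab))
  # V2000 atom-line charge code (ChemmineR column "C6"):
  # 0 none, 1:+3, 2:+2, 3:+1, 5:-1, 6:-2, 7:-3
  chgcode <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, nrow(ab))
  charge <- integer(length(chgcode))
  nz <- chgcode %in% c(1:3, 5:7)
  charge[nz] <- 4L - as.integer(chgcode[nz])
  if (is.matrix(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  } else {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  heavy <- which(elements != "H")
  nH <- integer(length(elements))
  for (k in seq_len(nrow(bonds))) {
    if (elements[bonds$a1[k]] == "H") nH[bonds$a2[k]] <- nH[bonds$a2[k]] + 1L
    if (elements[bonds$a2[k]] == "H") nH[bonds$a1[k]] <- nH[bonds$a1[k]] + 1L
  }
  keep <- bonds$a1 %in% heavy & bonds$a2 %in% heavy
  bonds <- bonds[keep, , drop = FALSE]
  remap <- match(seq_along(elements), heavy)
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  list(elements = elements[heavy], charge = charge[heavy],
       nH_explicit = nH[heavy], bonds = bonds)
}

#' @keywords internal
as_sdfset <- function(structures, ids = NULL) {
  if (is(structures, "SDFset")) return(structures)
  if (is(structures, "SDF")) {
    out <- as(structures, "SDFset")
    return(out)
  }
  if (is.character(structures)) return(parse_smiles(structures, ids))
  stop("structures must be an SDFset, an SDF, or a character vector of SMILES")
}
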