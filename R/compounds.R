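#' Read a compound table
#'
#' Reads compound records from a CSV file (columns \code{id}, \code{smiles}
#' required; \code{name}, \code{mw}, \code{role}, \code{charge_note},
#' \code{pair_tags} optional) or from an SDF file (ids from the molecule
#' titles). When \code{mw} is absent it is computed from the structure
#' (average atomic masses). Instrument exports using decimal commas can be
#' normalized with \code{dec = ","}.
#'
#' @param path CSV or SDF file.
#' @param format \code{"csv"} or \code{"sdf"}; guessed from the extension by
#'   default.
#' @param dec decimal separator for CSV numbers.
#' @return data.frame of compound records (order preserved) with columns
#'   \code{id}, \code{name}, \code{smiles}, \code{mw}, \code{role},
#'   \code{charge_note}, \code{pair_tags}.
#' @section Errors: a missing required column raises a schema error naming
#'   the column; an unparsable structure raises a record-level error listing
#'   the offending id(s).
#' @export
read_compounds <- function(path, format = c("auto", "csv", "sdf"), dec = ".") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    ChemmineR::cid(sdf) <- ids
    smiles <- tryCatch(as.character(ChemmineR::sdf2smiles(sdf)),
                       error = function(e) rep(NA_character_, length(sdf)))
    df <- data.frame(id = ids, name = ids, smiles = smiles,
                     mw = unname(ChemmineR::propOB(sdf)$MW),
                     role = NA_character_, charge_note = NA_character_,
                     pair_tags = NA_character_, stringsAsFactors = FALSE)
    return(df)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec,
                        na.strings = c("NA", ""))
  miss <- setdiff(c("id", "smiles"), names(df))
  if (length(miss) > 0) {
    stop(structure(class = c("protacsol_schema_error", "error", "condition"),
                   list(message = paste0("compound table missing required column(s): ",
                                         paste(miss, collapse = ", ")), call = NULL)))
  }
  for (col in c("name", "role", "charge_note", "pair_tags")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  has_structure <- !is.na(df$smiles) & nzchar(df$smiles)
  if (any(has_structure)) {
    # parse all structures up front so malformed records fail loudly, and
    # fill mw from structure where the table does not state it
    sdf <- parse_smiles(df$smiles[has_structure], df$id[has_structure])
    mw_comp <- unname(ChemmineR::propOB(sdf)$MW)
    if (!"mw" %in% names(df)) df$mw <- NA_real_
    fill <- has_structure & is.na(df$mw)
    df$mw[fill] <- mw_comp[match(df$id[fill], df$id[has_structure])]
  }
  if (!"mw" %in% names(df)) df$mw <- NA_real_
  df[, c("id", "name", "smiles", "mw", "role", "charge_note", "pair_tags")]
}

#' Assemble a PROTAC study dataset
#'
#' Bundles the member tables of one study: compound records, raw retention
#' series, solubility measurements and descriptor profiles.
#'
#' @param compounds data.frame with at least \code{id} (unique), optionally
#'   \code{mw}, \code{role}, \code{smiles}, ...
#' @param retention optional retention data.frame (see
#'   \code{\link{chromatographic_descriptors}}).
#' @param solubility optional solubility data.frame (one row per compound,
#'   \code{compound_id}, \code{log_s}, \code{censored}, \code{gsk_class},
#'   ...).
#' @param descriptors optional descriptor data.frame (\code{id} + numeric
#'   descriptor columns).
#' @return object of class \code{protac_dataset}.
#' @export
protac_dataset <- function(compounds, retention = NULL, solubility = NULL,
                           descriptors = NULL) {
  stopifnot(is.data.frame(compounds), "id" %in% names(compounds))
  empty_ret <- data.frame(compound_id = character(), system = character(),
                          percent_organic = numeric(), t_R_min = numeric(),
                          t0_min = numeric(), replicate = integer())
  empty_sol <- data.frame(compound_id = character(), log_s = numeric(),
                          censored = logical())
  structure(list(compounds = compounds,
                 retention = if (is.null(retention)) empty_ret else retention,
                 solubility = if (is.null(solubility)) empty_sol else solubility,
                 descriptors = if (is.null(descriptors))
                   data.frame(id = character()) else descriptors),
            class = "protac_dataset")
}

#' @export
print.protac_dataset <- function(x, ...) {
  cat(sprintf("protac_dataset: %d compounds, %d retention rows, %d solubility rows, %d descriptor rows\n",
              nrow(x$compounds), nrow(x$retention), nrow(x$solubility),
              nrow(x$descriptors)))
  invisible(x)
}

#' Validate a dataset
#'
#' Report-only consistency checks: duplicate compound ids, dangling
#' references from the retention/solubility/descriptor tables, non-positive
#' molecular weights, stated molecular weights that disagree with the
#' structure-computed mass by more than 0.5 g/mol (salts and solvates are
#' reported, not auto-resolved), and retention rows violating t_R >= t0 > 0.
#' The dataset is never modified.
#'
#' @param dataset a \code{protac_dataset}.
#' @return data.frame with columns \code{type}, \code{id}, \code{message};
#'   zero rows when the dataset is consistent.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "protac_dataset"))
  findings <- list()
  add <- function(type, id, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      type = type, id = id, message = message, stringsAsFactors = FALSE)
  }
  ids <- dataset$compounds$id
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("duplicate_id", d, "compound id not unique")
  check_refs <- function(tab, col, what) {
    if (nrow(tab) == 0) return()
    bad <- unique(tab[[col]][!tab[[col]] %in% ids])
    for (b in bad) add("dangling_reference", b,
                      paste0(what, " entry references unknown compound"))
  }
  check_refs(dataset$retention, "compound_id", "retention")
  check_refs(dataset$solubility, "compound_id", "solubility")
  if ("id" %in% names(dataset$descriptors)) {
    check_refs(dataset$descriptors, "id", "descriptor")
  }
  if ("mw" %in% names(dataset$compounds)) {
    bad <- which(!is.na(dataset$compounds$mw) & dataset$compounds$mw <= 0)
    for (b in bad) add("unit_anomaly", ids[b], "molecular weight not positive")
    if ("smiles" %in% names(dataset$compounds)) {
      has <- which(!is.na(dataset$compounds$smiles) &
                     nzchar(dataset$compounds$smiles) &
                     !is.na(dataset$compounds$mw) & dataset$compounds$mw > 0)
      if (length(has) > 0) {
        mw_comp <- tryCatch(
          unname(compute_mw(dataset$compounds$smiles[has],
                            ids = make.unique(dataset$compounds$id[has]))),
          error = function(e) rep(NA_real_, length(has)))
        off <- which(abs(mw_comp - dataset$compounds$mw[has]) > 0.5)
        for (k in off) add("mw_mismatch", ids[has[k]], sprintf(
          "stated mw %.2f differs from structure mw %.2f by > 0.5 g/mol (salt/solvate?)",
          dataset$compounds$mw[has[k]], mw_comp[k]))
      }
    }
  }
  ret <- dataset$retention
  if (nrow(ret) > 0) {
    bad <- which(!(ret$t_R_min >= ret$t0_min & ret$t0_min > 0))
    for (b in bad) add("unit_anomaly", ret$compound_id[b],
                      "retention row violates t_R >= t0 > 0")
  }
  if (length(findings) == 0) {
    return(data.frame(type = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Write / read per-compound profile tables
#'
#' \code{write_profiles} renders one row per compound with its descriptor and
#' solubility fields; censored solubilities are written as the sentinel
#' \code{"ND"} (not detectable). \code{read_profiles} reads such a file back,
#' restoring the censoring flag. Numeric values survive the round trip
#' bit-identically (full precision is written).
#'
#' @param dataset a \code{protac_dataset}.
#' @param path output CSV path.
#' @return \code{write_profiles} invisibly returns the written data.frame;
#'   \code{read_profiles} returns a data.frame with a logical
#'   \code{censored} column.
#' @export
write_profiles <- function(dataset, path) {
  stopifnot(inherits(dataset, "protac_dataset"))
  comp <- dataset$compounds
  out <- data.frame(id = comp$id, stringsAsFactors = FALSE)
  if ("mw" %in% names(comp)) out$mw <- comp$mw
  if ("role" %in% names(comp)) out$role <- comp$role
  d <- dataset$descriptors
  if (nrow(d) > 0) {
    for (col in setdiff(names(d), "id")) {
      out[[col]] <- d[[col]][match(out$id, d$id)]
    }
  }
  sol <- dataset$solubility
  if (nrow(sol) > 0) {
    m <- match(out$id, sol$compound_id)
    cen <- !is.na(m) & sol$censored[m]
    log_s_chr <- ifelse(is.na(m), NA,
                        ifelse(cen, "ND",
                               format(sol$log_s[m], digits = 17)))
    out$log_s <- trimws(log_s_chr)
    if ("gsk_class" %in% names(sol)) {
      out$gsk_class <- as.character(sol$gsk_class[m])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  if ("log_s" %in% names(df)) {
    df$censored <- !is.na(df$log_s) & df$log_s == "ND"
    df$log_s <- suppressWarnings(as.numeric(ifelse(df$censored, NA, df$log_s)))
  }
  df
}

#' Read a dataset from a YAML manifest
#'
#' The manifest names the member files relative to its own directory:
#' \code{compounds} (CSV/SDF), optional \code{retention},
#' \code{solubility}, \code{descriptors} (CSVs).
#'
#' @param path YAML manifest.
#' @return a \code{protac_dataset}.
#' @export
read_dataset <- function(path) {
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (is.null(p)) NULL else file.path(base, p)
  stopifnot(!is.null(man$compounds))
  compounds <- read_compounds(resolve(man$compounds))
  ret <- if (!is.null(man$retention))
    utils::read.csv(resolve(man$retention), stringsAsFactors = FALSE) else NULL
  sol <- if (!is.null(man$solubility))
    read_profiles(resolve(man$solubility)) else NULL
  if (!is.null(sol) && !"compound_id" %in% names(sol) && "id" %in% names(sol)) {
    names(sol)[names(sol) == "id"] <- "compound_id"
  }
  desc <- if (!is.null(man$descriptors))
    utils::read.csv(resolve(man$descriptors), stringsAsFactors = FALSE) else NULL
  protac_dataset(compounds, ret, sol, desc)
}
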