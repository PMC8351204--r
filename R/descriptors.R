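# Molecular property computation, external property tables, and
# standardisation against a reference population.

DESCRIPTOR_NAMES <- c("rotatable_bonds", "molecular_weight", "complexity",
                      "tpsa", "logp", "hbd", "hba", "molar_refractivity")

# Rotatable bond: single, acyclic, both atoms non-terminal, neither in a
# triple bond (standard definition).
ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Compute molecular descriptors
#'
#' Computes physicochemical descriptors from structure for one or more
#' compounds of a library. Supported properties: `rotatable_bonds`,
#' `molecular_weight` (g/mol), `complexity` (unitless, see Details),
#' `tpsa` (topological polar surface area, A^2), `logp` (octanol/water
#' partition coefficient), `hbd`/`hba` (hydrogen-bond donors/acceptors) and
#' `molar_refractivity` (a polarizability surrogate). Values are computed
#' on the largest organic fragment and are deterministic for a fixed
#' toolkit version.
#'
#' `complexity` is a simple graph-complexity index,
#' `bonds * log2(atoms) + 2 * rings + heteroatoms` over the heavy-atom
#' skeleton. Published complexity values from other engines differ in
#' scale; supply those via [attach_property_table()] when reproducing
#' literature tables (the external value then overrides the computed one).
#'
#' @param lib a [compound_library()].
#' @param properties character vector of property names (subset of the
#'   supported set).
#' @param ids compounds to evaluate (default: all). Every requested
#'   compound must have a structure; structureless compounds are an error,
#'   not a silent skip.
#' @return Numeric matrix, rows = compound ids, columns = properties.
#' @examples
#' lib <- compound_library("P1", "propyl paraben", "94-13-3",
#'                         "CCCOC(=O)c1ccc(O)cc1")
#' compute_descriptors(lib, c("molecular_weight", "tpsa", "rotatable_bonds"))
#' @export
compute_descriptors <- function(lib, properties = c("rotatable_bonds",
                                                    "molecular_weight", "tpsa", "logp"),
                                ids = lib$compound_id) {
  stopifnot(inherits(lib, "compound_library"))
  unknown <- setdiff(properties, DESCRIPTOR_NAMES)
  if (length(unknown)) {
    stop("unknown property name(s): ", paste(unknown, collapse = ", "),
         "; supported: ", paste(DESCRIPTOR_NAMES, collapse = ", "))
  }
  sdf <- lib_sdf(lib, ids)  # errors on structureless compounds
  ob <- ChemmineR::propOB(sdf)
  out <- matrix(NA_real_, length(ids), length(properties),
                dimnames = list(ids, properties))
  for (p in properties) {
    out[, p] <- switch(p,
      molecular_weight = ob$MW,
      tpsa = ob$TPSA,
      logp = ob$logP,
      hbd = ob$HBD,
      hba = ob$HBA1,
      molar_refractivity = ob$MR,
      rotatable_bonds = as.numeric(
        ChemmineR::smartsSearchOB(sdf, ROTOR_SMARTS, uniqueMatches = TRUE)),
      complexity = vapply(seq_along(ids), function(i) {
        ab <- ChemmineR::atomblock(sdf[[i]])
        bb <- ChemmineR::bondblock(sdf[[i]])
        el <- sub("_.*$", "", rownames(ab))
        natoms <- nrow(ab); nbonds <- nrow(bb)
        nrings <- max(0L, nbonds - natoms + 1L)
        nhet <- sum(!el %in% c("C", "H"))
        if (natoms < 2) 0 else nbonds * log2(natoms) + 2 * nrings + nhet
      }, numeric(1))
    )
  }
  out
}

#' Attach externally supplied property values
#'
#' Literature descriptor values often come from engines the package does
#' not embed. This attaches per-compound property values from a table;
#' externally supplied values take precedence over computed ones wherever
#' the library's properties are consumed, and each value carries a
#' provenance flag (`"external"`).
#'
#' @param lib a [compound_library()].
#' @param table a data frame (or CSV path) with a `compound_id` column and
#'   one numeric column per property.
#' @param source provenance flag recorded for the attached values.
#' @return The library with the values attached. Rows whose `compound_id`
#'   is not in the library are skipped with a warning; duplicated
#'   `compound_id` rows are resolved last-row-wins with a warning.
#' @export
attach_property_table <- function(lib, table, source = "external") {
  stopifnot(inherits(lib, "compound_library"))
  if (is.character(table) && length(table) == 1) {
    table <- utils::read.csv(table, check.names = FALSE)
  }
  table <- as.data.frame(table)
  if (!"compound_id" %in% names(table)) stop("property table must have a compound_id column")
  if (nrow(table) == 0) return(lib)
  if (anyDuplicated(table$compound_id)) {
    warning("duplicate compound_id rows in property table; last row wins")
    table <- table[!duplicated(table$compound_id, fromLast = TRUE), , drop = FALSE]
  }
  unknown <- setdiff(table$compound_id, lib$compound_id)
  if (length(unknown)) {
    warning("property rows for unknown compound_id skipped: ",
            paste(unknown, collapse = ", "))
    table <- table[!table$compound_id %in% unknown, , drop = FALSE]
  }
  if (nrow(table) == 0) return(lib)
  props <- setdiff(names(table), "compound_id")
  long <- do.call(rbind, lapply(props, function(p) {
    v <- suppressWarnings(as.numeric(table[[p]]))
    keep <- which(!is.na(v))
    if (!length(keep)) return(NULL)
    data.frame(compound_id = table$compound_id[keep], property = p,
               value = v[keep], source = source, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) return(lib)
  existing <- attr(lib, "properties")
  key_old <- paste(existing$compound_id, existing$property)
  key_new <- paste(long$compound_id, long$property)
  attr(lib, "properties") <- rbind(existing[!key_old %in% key_new, , drop = FALSE], long)
  lib
}

#' Property matrix for a set of compounds
#'
#' Assembles the property matrix used by the similarity layer: externally
#' attached values take precedence; remaining values are computed from
#' structure when `compute = TRUE`. Missing values (no external value, no
#' structure, or `compute = FALSE`) are an error listing the gaps.
#'
#' @param lib a [compound_library()].
#' @param properties property names.
#' @param ids compounds (default all).
#' @param compute fill gaps by descriptor computation.
#' @return Numeric matrix rows = ids, cols = properties, with a matching
#'   character matrix of provenance flags in attribute `"source"`.
#' @export
property_matrix <- function(lib, properties, ids = lib$compound_id, compute = TRUE) {
  stopifnot(inherits(lib, "compound_library"))
  out <- matrix(NA_real_, length(ids), length(properties),
                dimnames = list(ids, properties))
  src <- matrix(NA_character_, length(ids), length(properties),
                dimnames = list(ids, properties))
  att <- attr(lib, "properties")
  att <- att[att$compound_id %in% ids & att$property %in% properties, , drop = FALSE]
  for (i in seq_len(nrow(att))) {
    out[att$compound_id[i], att$property[i]] <- att$value[i]
    src[att$compound_id[i], att$property[i]] <- att$source[i]
  }
  if (compute && anyNA(out)) {
    need_row <- rownames(out)[apply(is.na(out), 1, any)]
    computable <- intersect(need_row,
                            lib$compound_id[lib$has_structure])
    need_prop <- intersect(colnames(out)[apply(is.na(out), 2, any)], DESCRIPTOR_NAMES)
    if (length(computable) && length(need_prop)) {
      comp <- compute_descriptors(lib, need_prop, computable)
      fill <- is.na(out[computable, need_prop, drop = FALSE])
      out[computable, need_prop][fill] <- comp[fill]
      src[computable, need_prop][fill] <- "computed"
    }
  }
  if (anyNA(out)) {
    gaps <- which(is.na(out), arr.ind = TRUE)
    stop("missing property values: ",
         paste(sprintf("%s/%s", rownames(out)[gaps[, 1]], colnames(out)[gaps[, 2]]),
               collapse = ", "))
  }
  attr(out, "source") <- src
  out
}

#' Reference statistics for property standardisation
#'
#' Property-based similarity operates on z-scores relative to a large
#' reference population of structures. A reference-statistics object holds,
#' per property, the population mean and standard deviation (and optionally
#' the population size).
#'
#' @param x a data frame with columns `property`, `mean`, `sd` (and
#'   optionally `n`), or a path to a JSON file of the form
#'   `{"property": {"mean": m, "sd": s, "n": n}, ...}`.
#' @return An object of class `reference_statistics`.
#' @seealso [default_reference_statistics()], [standardise_properties()]
#' @export
reference_statistics <- function(x) {
  if (is.character(x) && length(x) == 1) {
    raw <- jsonlite::fromJSON(x)
    x <- data.frame(property = names(raw),
                    mean = vapply(raw, function(e) as.numeric(e$mean), numeric(1)),
                    sd = vapply(raw, function(e) as.numeric(e$sd), numeric(1)),
                    n = vapply(raw, function(e) {
                      if (is.null(e$n)) NA_real_ else as.numeric(e$n)
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  stopifnot(all(c("property", "mean", "sd") %in% names(x)))
  if (any(!is.finite(x$sd) | x$sd <= 0)) {
    stop("reference sd must be positive for every property")
  }
  rownames(x) <- x$property
  class(x) <- c("reference_statistics", "data.frame")
  x
}

#' Bundled example-calibrated reference statistics
#'
#' Reference means and standard deviations for `rotatable_bonds`,
#' `molecular_weight`, `complexity`, `tpsa` and `xlogp`, calibrated so that
#' the bundled paraben example reproduces its published standardised
#' property values. These are an illustration fixture, not population
#' statistics: for real analyses supply your own reference table derived
#' from a relevant structure collection (see [reference_statistics()]).
#'
#' @return A `reference_statistics` object.
#' @export
default_reference_statistics <- function() {
  reference_statistics(system.file("extdata", "reference_stats.json",
                                   package = "toxra", mustWork = TRUE))
}

#' Standardise property values against reference statistics
#'
#' Computes `z = (x - mean) / sd` per property. The reference must cover
#' every property present in `x`.
#'
#' @param x named numeric vector or matrix (columns = properties).
#' @param ref a [reference_statistics()] object.
#' @return z-scores with the same shape and names as `x`.
#' @export
standardise_properties <- function(x, ref) {
  stopifnot(inherits(ref, "reference_statistics"))
  if (is.null(dim(x))) {
    props <- names(x)
    if (is.null(props)) stop("property values must be named")
    miss <- setdiff(props, ref$property)
    if (length(miss)) stop("no reference entry for: ", paste(miss, collapse = ", "))
    (x - ref[props, "mean"]) / ref[props, "sd"]
  } else {
    props <- colnames(x)
    miss <- setdiff(props, ref$property)
    if (length(miss)) stop("no reference entry for: ", paste(miss, collapse = ", "))
    sweep(sweep(x, 2, ref[props, "mean"], "-"), 2, ref[props, "sd"], "/")
  }
}
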