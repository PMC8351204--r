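# Compound data model and structure/tabular I/O. Every workflow starts here.

#' Construct a compound library
#'
#' A compound library is the central container of the package: an ordered
#' table of substances, each identified by an opaque `compound_id`, with an
#' optional CAS Registry Number and an optional structure given as SMILES.
#' Substance-centric sources routinely hold records without structures
#' (UVCBs, polymers, inventory-only entries); such records are retained with
#' `has_structure = FALSE` and every structure-requiring operation rejects
#' them explicitly rather than skipping them silently.
#'
#' SMILES are canonicalised at load time (the original input string is kept
#' in the `smiles` column as provenance; the working form is
#' `canonical_smiles`). Multi-component records (dot-disconnected SMILES,
#' e.g. salts) are accepted; descriptor and fingerprint computations operate
#' on the largest organic fragment, so a sodium salt is processed via its
#' organic component.
#'
#' @param compound_id character vector of unique identifiers.
#' @param name preferred names (recycled to length of `compound_id`).
#' @param cas_rn optional CAS Registry Numbers (`NA` allowed). Values that
#'   fail the CAS checksum trigger a warning but are retained.
#' @param smiles optional SMILES strings (`NA` for structureless records).
#' @param role compound role, one of `"target"`, `"candidate"`,
#'   `"analogue"`, `"similar"`.
#' @param source_label free-text label describing the provenance of the
#'   library.
#' @return An object of class `compound_library`: a data frame with columns
#'   `compound_id`, `name`, `cas_rn`, `smiles`, `canonical_smiles`,
#'   `has_structure`, `role`, plus attached property data (see
#'   [attach_property_table()]).
#' @seealso [read_compounds()], [validate_cas()]
#' @examples
#' lib <- compound_library(
#'   compound_id = c("CMP-1", "CMP-2"),
#'   name = c("ethanol", "no structure"),
#'   smiles = c("CCO", NA)
#' )
#' lib
#' @export
compound_library <- function(compound_id, name = compound_id, cas_rn = NA_character_,
                             smiles = NA_character_, role = "candidate",
                             source_label = "") {
  compound_id <- as.character(compound_id)
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound_id: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "))
  }
  n <- length(compound_id)
  name <- rep_len(as.character(name), n)
  cas_rn <- rep_len(as.character(cas_rn), n)
  smiles <- rep_len(as.character(smiles), n)
  role <- rep_len(as.character(role), n)
  bad_role <- setdiff(unique(role), c("target", "candidate", "analogue", "similar"))
  if (length(bad_role)) stop("unknown role: ", paste(bad_role, collapse = ", "))

  cas_given <- !is.na(cas_rn) & nzchar(cas_rn)
  if (any(cas_given)) {
    ok <- validate_cas(cas_rn[cas_given])
    if (any(!ok)) {
      warning("CAS checksum failure for: ",
              paste(cas_rn[cas_given][!ok], collapse = ", "))
    }
  }

  canon <- canonicalise_smiles(smiles)
  has_structure <- !is.na(canon)
  if (any(!has_structure & !is.na(smiles))) {
    message("records with unparsable structures kept as has_structure = FALSE: ",
            paste(compound_id[!has_structure & !is.na(smiles)], collapse = ", "))
  }

  lib <- data.frame(
    compound_id = compound_id, name = name, cas_rn = cas_rn,
    smiles = smiles, canonical_smiles = canon,
    has_structure = has_structure, role = role,
    stringsAsFactors = FALSE
  )
  attr(lib, "source_label") <- source_label
  attr(lib, "properties") <- empty_property_table()
  class(lib) <- c("compound_library", "data.frame")
  lib
}

empty_property_table <- function() {
  data.frame(compound_id = character(), property = character(),
             value = numeric(), source = character(), stringsAsFactors = FALSE)
}

#' @export
print.compound_library <- function(x, ...) {
  src <- attr(x, "source_label")
  cat("Compound library", if (nzchar(src)) paste0("(", src, ")"), "with",
      nrow(x), "compounds;", sum(x$has_structure), "with structures\n")
  print.data.frame(utils::head(as.data.frame(x)[, c("compound_id", "name", "cas_rn",
                                                    "has_structure", "role")], 10),
                   row.names = FALSE)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  np <- nrow(attr(x, "properties"))
  if (!is.null(np) && np > 0) cat("Attached property values:", np, "\n")
  invisible(x)
}

#' Validate a CAS Registry Number
#'
#' Checks the `d{2,7}-dd-d` format and the CAS check digit (the last digit
#' equals the weighted sum of the preceding digits, weights increasing from
#' right to left, modulo 10). Malformed input returns `FALSE`, never an
#' error.
#'
#' @param cas_rn character vector of candidate CAS numbers.
#' @return Logical vector, `TRUE` where format and checksum are valid.
#' @examples
#' validate_cas(c("94-13-3", "24905-87-1", "94-13-4"))
#' @export
validate_cas <- function(cas_rn) {
  vapply(as.character(cas_rn), function(x) {
    if (is.na(x) || !grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    digits <- as.integer(strsplit(gsub("-", "", x), "")[[1]])
    check <- digits[length(digits)]
    body <- rev(digits[-length(digits)])
    (sum(body * seq_along(body)) %% 10L) == check
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonicalise SMILES strings
#'
#' Converts each SMILES to the toolkit's canonical form. Unparsable strings
#' map to `NA`. Multi-component inputs are canonicalised whole; use
#' [largest_fragment()] to reduce a salt to its organic component.
#'
#' @param smiles character vector of SMILES (`NA` passed through).
#' @return Character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalise_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    sdf <- smiles_to_sdf_one(s)
    if (is.null(sdf)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, " m\n")),
                    error = function(e) NA_character_)
    if (is.na(out)) return(NA_character_)
    out <- strsplit(trimws(out), "[ \t]")[[1]][1]
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# One-molecule SMILES -> SDFset, NULL on parse failure.
smiles_to_sdf_one <- function(s) {
  res <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
                  error = function(e) NULL)
  if (is.null(res) || length(res) < 1) return(NULL)
  ab <- tryCatch(ChemmineR::atomblock(res[[1]]), error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0) return(NULL)
  res
}

# SDFset for a set of library rows (largest organic fragment). Errors if any
# requested compound lacks a structure.
lib_sdf <- function(lib, ids = lib$compound_id) {
  idx <- match(ids, lib$compound_id)
  if (anyNA(idx)) stop("unknown compound_id: ", paste(ids[is.na(idx)], collapse = ", "))
  if (any(!lib$has_structure[idx])) {
    stop("structure required but absent for: ",
         paste(ids[!lib$has_structure[idx]], collapse = ", "))
  }
  smi <- vapply(lib$canonical_smiles[idx], largest_fragment, character(1))
  # canonical SMILES have already parsed once, so batch conversion is safe
  out <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, ids)))
  if (length(out) != length(ids)) {
    stop("internal error: structure conversion dropped records")
  }
  ChemmineR::cid(out) <- ids
  out
}

#' Largest organic fragment of a (possibly multi-component) SMILES
#'
#' Salts and mixtures are written as dot-disconnected SMILES. Descriptor and
#' fingerprint computations use the largest organic fragment: among the
#' carbon-containing fragments (all fragments, if none contains carbon) the
#' one with the most heavy atoms, ties broken by position. A sodium
#' sulfonate salt is therefore processed via its organic anion.
#'
#' @param smiles a single SMILES string.
#' @return SMILES of the selected fragment.
#' @examples
#' largest_fragment("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12")
#' @export
largest_fragment <- function(smiles) {
  stopifnot(length(smiles) == 1, !is.na(smiles))
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1) return(smiles)
  info <- lapply(frags, function(f) {
    sdf <- smiles_to_sdf_one(f)
    if (is.null(sdf)) return(c(n = 0, carbon = 0))
    el <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf[[1]])))
    c(n = length(el), carbon = as.integer("C" %in% el))
  })
  n <- vapply(info, `[`, numeric(1), "n")
  carbon <- vapply(info, `[`, numeric(1), "carbon") > 0
  pool <- if (any(carbon)) which(carbon) else seq_along(frags)
  frags[pool[which.max(n[pool])]]
}

#' Read a compound library from file
#'
#' Supported formats: `"smiles_csv"` (comma-separated, UTF-8, header row
#' `compound_id,name,cas_rn,smiles`), `"sdf"` (V2000; `compound_id`,
#' `name`, `cas_rn` taken from data fields of those names when present,
#' otherwise from the molecule title), and `"json"` (a dump written by
#' [write_compounds()]). Records whose structures fail to parse are kept
#' with `has_structure = FALSE` and reported via [message()].
#'
#' @param path file path.
#' @param format one of `"smiles_csv"`, `"sdf"`, `"json"`.
#' @param source_label provenance label stored on the library (defaults to
#'   the file name).
#' @return A [compound_library()].
#' @export
read_compounds <- function(path, format = c("smiles_csv", "sdf", "json"),
                           source_label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- switch(format,
    smiles_csv = {
      x <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
      names(x) <- tolower(names(x))
      need <- c("compound_id", "name", "cas_rn", "smiles")
      miss <- setdiff(need, names(x))
      if (length(miss)) stop("smiles_csv missing columns: ", paste(miss, collapse = ", "))
      x[need]
    },
    sdf = read_sdf_table(path),
    json = {
      x <- jsonlite::fromJSON(path)
      if (is.null(x$compounds)) stop("json library dump lacks a 'compounds' element")
      as.data.frame(x$compounds, stringsAsFactors = FALSE)
    }
  )
  blank_to_na <- function(v) { v[is.na(v) | !nzchar(v)] <- NA_character_; v }
  lib <- compound_library(
    compound_id = tab$compound_id, name = tab$name,
    cas_rn = blank_to_na(tab$cas_rn), smiles = blank_to_na(tab$smiles),
    role = if (!is.null(tab$role)) tab$role else "candidate",
    source_label = source_label
  )
  if (format == "json") {
    x <- jsonlite::fromJSON(path)
    if (!is.null(x$properties) && length(x$properties)) {
      attr(lib, "properties") <- as.data.frame(x$properties, stringsAsFactors = FALSE)
    }
  }
  lib
}

# Parse an SDF file into an id/name/cas/smiles table, tolerating corrupt
# records: each record block is handled independently and a record that
# fails to parse yields a row with smiles = NA.
read_sdf_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) stop("no records found in SDF: ", path)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  rows <- lapply(seq_along(ends), function(i) {
    block <- lines[starts[i]:ends[i]]
    block <- block[cumsum(nzchar(trimws(block)) | seq_along(block) > 1) > 0]
    title <- trimws(block[1])
    field <- function(tag) {
      j <- grep(paste0("^> *<", tag, ">"), block)
      if (length(j) == 1 && j < length(block)) trimws(block[j + 1]) else NA_character_
    }
    smi <- NA_character_
    parsed <- tryCatch({
      tmp <- tempfile(fileext = ".sdf")
      on.exit(unlink(tmp))
      writeLines(block, tmp)
      sdf <- suppressWarnings(ChemmineR::read.SDFset(tmp))
      if (length(sdf) == 1 && ChemmineR::validSDF(sdf)) {
        as.character(ChemmineR::sdf2smiles(sdf))
      } else NA_character_
    }, error = function(e) NA_character_)
    if (!is.na(parsed) && nzchar(parsed)) smi <- parsed
    id <- field("compound_id")
    data.frame(
      compound_id = if (!is.na(id)) id else if (nzchar(title)) title else sprintf("SDF-%03d", i),
      name = if (!is.na(field("name"))) field("name") else title,
      cas_rn = field("cas_rn"), smiles = smi, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write a compound library to file
#'
#' `"smiles_csv"` writes the four canonical columns; `"json"` writes a full
#' dump including attached property values, readable by [read_compounds()].
#'
#' @param lib a [compound_library()].
#' @param path output file path.
#' @param format `"smiles_csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(lib, path, format = c("smiles_csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(lib, "compound_library"))
  if (format == "smiles_csv") {
    utils::write.csv(as.data.frame(lib)[, c("compound_id", "name", "cas_rn", "smiles")],
                     path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(source_label = attr(lib, "source_label"),
           compounds = as.data.frame(lib),
           properties = attr(lib, "properties")),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

# Subset a library by compound_id, keeping attributes.
lib_subset <- function(lib, ids) {
  idx <- match(ids, lib$compound_id)
  if (anyNA(idx)) stop("unknown compound_id: ", paste(ids[is.na(idx)], collapse = ", "))
  out <- as.data.frame(lib)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "source_label") <- attr(lib, "source_label")
  props <- attr(lib, "properties")
  attr(out, "properties") <- props[props$compound_id %in% ids, , drop = FALSE]
  class(out) <- class(lib)
  out
}
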