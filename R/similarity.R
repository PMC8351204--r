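# Structure- and property-based similarity, Analogue Quality, and
# threshold-governed similarity search.

FP_METHODS <- c(path = "FP2", maccs = "MACCS", fp4 = "FP4")

# Floor below which similarity searching is not meaningful in the source
# data system; searches below it are rejected.
TANIMOTO_FLOOR <- 0.65

#' Compute fingerprints for a compound library
#'
#' Bundled methods: `"path"` (a 1024-bit path-based topological
#' fingerprint), `"maccs"` (the 166 structural keys), `"fp4"` (functional
#' group keys), and `"smarts"` (a chemotype-style fingerprint with one bit
#' per pattern of a supplied [alert_library()]). All requested compounds
#' must carry structures.
#'
#' @param lib a [compound_library()].
#' @param method fingerprint method.
#' @param ids compounds to fingerprint (default all).
#' @param smarts an [alert_library()]; required for `method = "smarts"`.
#' @return An object of class `fp_set`: bit-index sets per compound.
#' @export
fingerprints <- function(lib, method = c("path", "maccs", "fp4", "smarts"),
                         ids = lib$compound_id, smarts = NULL) {
  method <- match.arg(method)
  sdf <- lib_sdf(lib, ids)
  if (method == "smarts") {
    if (is.null(smarts)) stop("method 'smarts' requires a smarts alert library")
    stopifnot(inherits(smarts, "alert_library"))
    hits <- vapply(smarts$smarts, function(pat) {
      as.numeric(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE))
    }, numeric(length(ids)))
    if (is.null(dim(hits))) hits <- matrix(hits, nrow = length(ids))
    bits <- lapply(seq_along(ids), function(i) which(hits[i, ] > 0))
    n_bits <- nrow(smarts)
  } else {
    fp <- ChemmineR::fingerprintOB(sdf, FP_METHODS[[method]])
    m <- fp@fpma
    bits <- lapply(seq_along(ids), function(i) which(m[i, ] == 1))
    n_bits <- ncol(m)
  }
  structure(list(method = method, n_bits = n_bits, ids = ids,
                 bits = stats::setNames(bits, ids)),
            class = "fp_set")
}

#' @export
print.fp_set <- function(x, ...) {
  cat("Fingerprint set:", length(x$ids), "compounds, method", x$method,
      sprintf("(%d bits)\n", x$n_bits))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set-bit indices. Both fingerprints
#' must come from the same method with the same bit length. Two empty
#' bitsets are defined to have similarity 1 (documented convention: two
#' structures in which no feature is present are indistinguishable to the
#' fingerprint).
#'
#' @param a,b either integer vectors of set-bit indices, or `fp_set`
#'   objects together with `id_a`/`id_b` selecting one compound each.
#' @param id_a,id_b compound ids when `a`/`b` are `fp_set` objects.
#' @return Tanimoto coefficient in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4))
#' @export
tanimoto <- function(a, b, id_a = NULL, id_b = NULL) {
  if (inherits(a, "fp_set") || inherits(b, "fp_set")) {
    stopifnot(inherits(a, "fp_set"), inherits(b, "fp_set"))
    if (a$method != b$method || a$n_bits != b$n_bits) {
      stop("fingerprint method/length mismatch: ",
           a$method, "/", a$n_bits, " vs ", b$method, "/", b$n_bits)
    }
    a <- a$bits[[id_a]]
    b <- b$bits[[id_b]]
  }
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Pearson property-based similarity
#'
#' `(1 + r) / 2` where `r` is the sample Pearson correlation between the
#' two (standardised) property vectors. Requires at least three shared
#' properties; a constant (zero-variance) vector makes the correlation
#' undefined and is an explicit error rather than a silent fallback.
#'
#' @param x,y named numeric property vectors over the same property set.
#' @return Similarity in `[0, 1]`.
#' @export
pearson_similarity <- function(x, y) {
  xy <- align_property_vectors(x, y)
  if (length(xy$x) < 3) stop("pearson similarity requires at least 3 properties")
  if (stats::sd(xy$x) == 0 || stats::sd(xy$y) == 0) {
    stop("pearson similarity undefined: zero-variance (constant) property vector")
  }
  (1 + stats::cor(xy$x, xy$y)) / 2
}

#' Euclidean property-based similarity
#'
#' Distance is the Euclidean norm of the difference of the two
#' (standardised) property vectors; similarity is `1 / (1 + distance)`.
#'
#' @param x,y named numeric property vectors over the same property set.
#' @return List with `distance` (>= 0) and `similarity` (in `(0, 1]`).
#' @export
euclidean_similarity <- function(x, y) {
  xy <- align_property_vectors(x, y)
  d <- sqrt(sum((xy$x - xy$y)^2))
  list(distance = d, similarity = 1 / (1 + d))
}

align_property_vectors <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) {
      stop("property-set mismatch: ",
           paste(union(setdiff(names(x), names(y)), setdiff(names(y), names(x))),
                 collapse = ", "))
    }
    y <- y[names(x)]
  } else if (length(x) != length(y)) {
    stop("property vectors differ in length")
  }
  list(x = as.numeric(x), y = as.numeric(y))
}

#' Analogue Quality: geometric mean of similarity measures
#'
#' Combines N similarity measures (each in `[0, 1]`) into a single
#' Analogue Quality score as their geometric mean,
#' `AQ = (prod(s_i))^(1/N)`. The geometric mean is used because each
#' measure is evidence about the same pairing of chemicals, and a single
#' very poor measure should pull the combination down strongly.
#'
#' @param measures numeric vector of similarity values in `[0, 1]`,
#'   length >= 1.
#' @return Analogue Quality in `[0, 1]`.
#' @examples
#' analogue_quality(c(0.91, 0.94, 0.82))
#' @export
analogue_quality <- function(measures) {
  measures <- as.numeric(measures)
  if (length(measures) < 1) stop("analogue_quality needs at least one measure")
  if (anyNA(measures) || any(measures < 0 | measures > 1)) {
    stop("similarity measures must lie in [0, 1]")
  }
  if (any(measures == 0)) return(0)
  exp(mean(log(measures)))
}

#' Threshold-governed similarity search
#'
#' Ranks library compounds by Tanimoto similarity to a query and returns
#' all hits at or above the threshold, sorted by similarity (descending)
#' with ties broken by `compound_id` (ascending), so results are
#' deterministic. Thresholds below the 0.65 search floor are rejected.
#'
#' @param query a compound id present in `lib`, or a SMILES string.
#' @param lib a [compound_library()].
#' @param method fingerprint method (see [fingerprints()]).
#' @param threshold Tanimoto threshold in `[0.65, 1]` (default 0.7, the
#'   recommended setting).
#' @param smarts alert library for `method = "smarts"`.
#' @return Data frame with `compound_id`, `name`, `tanimoto`. Structureless
#'   library compounds are excluded and listed in attribute
#'   `"not_evaluable"`.
#' @export
similarity_search <- function(query, lib, method = "path", threshold = 0.7,
                              smarts = NULL) {
  stopifnot(inherits(lib, "compound_library"))
  if (threshold < TANIMOTO_FLOOR || threshold > 1) {
    stop("similarity threshold must lie in [", TANIMOTO_FLOOR,
         ", 1]: the search floor is a Tanimoto coefficient of ", TANIMOTO_FLOOR)
  }
  if (query %in% lib$compound_id) {
    qlib <- lib
    qid <- query
  } else {
    qlib <- compound_library("..query..", "query", smiles = query)
    if (!qlib$has_structure) stop("query SMILES does not parse")
    qid <- "..query.."
  }
  qfp <- fingerprints(qlib, method, ids = qid, smarts = smarts)
  evaluable <- lib$compound_id[lib$has_structure]
  fps <- fingerprints(lib, method, ids = evaluable, smarts = smarts)
  sims <- vapply(evaluable, function(id) {
    tanimoto(qfp$bits[[qid]], fps$bits[[id]])
  }, numeric(1))
  keep <- sims >= threshold
  out <- data.frame(compound_id = evaluable[keep],
                    name = lib$name[match(evaluable[keep], lib$compound_id)],
                    tanimoto = unname(sims[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$tanimoto, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "not_evaluable") <- lib$compound_id[!lib$has_structure]
  out
}

#' Pairwise similarity profiles against a target
#'
#' Builds one complete similarity profile per candidate: Tanimoto
#' coefficients per fingerprint method, standardised-property Euclidean
#' distance/similarity and Pearson similarity, and both Analogue Quality
#' variants (each AQ is the geometric mean of all fingerprint Tanimotos
#' plus one property-based similarity). All values are kept at full
#' precision; rounding to two decimals happens only in printing/export.
#'
#' When reproducing published tables, the structure- and property-based
#' components can be supplied instead of computed: `tanimoto_values` (a
#' matrix candidates x methods), `zscores` (a matrix of standardised
#' property vectors including the target), or `property_sim` (a data frame
#' with per-candidate `euclidean_distance`, `euclidean_similarity`,
#' `pearson_similarity`).
#'
#' @param lib a [compound_library()].
#' @param target_id compound id of the target.
#' @param candidate_ids candidate compound ids (default: everything else).
#' @param fp_methods fingerprint methods to compute (ignored where
#'   `tanimoto_values` is supplied).
#' @param properties property names for the property-based component.
#' @param ref a [reference_statistics()] object (required when z-scores are
#'   computed from raw properties).
#' @param tanimoto_values optional matrix/data frame of Tanimoto values,
#'   rows named by candidate id, columns by method.
#' @param zscores optional matrix of standardised property vectors, rows
#'   named by compound id (must include the target).
#' @param property_sim optional data frame of precomputed property-based
#'   similarities with a `compound_id` column.
#' @return A data frame of class `similarity_profile`; one row per
#'   candidate with a `status` column (`"ok"` or an error message; failed
#'   candidates carry `NA` values rather than being dropped).
#' @export
pairwise_profile <- function(lib, target_id, candidate_ids = NULL,
                             fp_methods = c("path", "maccs"),
                             properties = c("rotatable_bonds", "molecular_weight",
                                            "complexity", "tpsa", "logp"),
                             ref = NULL, tanimoto_values = NULL, zscores = NULL,
                             property_sim = NULL) {
  stopifnot(inherits(lib, "compound_library"))
  if (!target_id %in% lib$compound_id) stop("target not in library: ", target_id)
  if (is.null(candidate_ids)) candidate_ids <- setdiff(lib$compound_id, target_id)

  if (!is.null(tanimoto_values)) {
    tanimoto_values <- as.matrix(tanimoto_values)
    methods <- colnames(tanimoto_values)
  } else {
    methods <- fp_methods
    fps <- lapply(fp_methods, function(m) {
      fingerprints(lib, m, ids = unique(c(target_id,
        intersect(candidate_ids, lib$compound_id[lib$has_structure]))))
    })
    names(fps) <- fp_methods
  }

  if (is.null(property_sim) && is.null(zscores)) {
    if (is.null(ref)) stop("supply 'ref' reference statistics (or zscores/property_sim)")
    raw <- property_matrix(lib, properties, ids = c(target_id, candidate_ids))
    zscores <- standardise_properties(raw, ref)
  }

  rows <- lapply(candidate_ids, function(cid) {
    res <- tryCatch({
      tv <- vapply(methods, function(m) {
        if (!is.null(tanimoto_values)) {
          v <- tanimoto_values[cid, m]
          if (is.na(v)) stop("missing tanimoto value for ", cid, "/", m)
          as.numeric(v)
        } else {
          tanimoto(fps[[m]]$bits[[target_id]], fps[[m]]$bits[[cid]])
        }
      }, numeric(1))
      if (!is.null(property_sim)) {
        ps <- property_sim[match(cid, property_sim$compound_id), , drop = FALSE]
        if (nrow(ps) != 1 || anyNA(ps$euclidean_similarity)) {
          stop("missing property similarity for ", cid)
        }
        ed <- ps$euclidean_distance; es <- ps$euclidean_similarity
        prs <- ps$pearson_similarity
      } else {
        e <- euclidean_similarity(zscores[target_id, ], zscores[cid, ])
        ed <- e$distance; es <- e$similarity
        prs <- pearson_similarity(zscores[target_id, ], zscores[cid, ])
      }
      c(tv, euclidean_distance = ed, euclidean_similarity = es,
        pearson_similarity = prs,
        aq_euclidean = analogue_quality(c(tv, es)),
        aq_pearson = analogue_quality(c(tv, prs)))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      vals <- rep(NA_real_, length(methods) + 5)
      names(vals) <- c(methods, "euclidean_distance", "euclidean_similarity",
                       "pearson_similarity", "aq_euclidean", "aq_pearson")
      list(vals = vals, status = res)
    } else list(vals = res, status = "ok")
  })

  out <- as.data.frame(do.call(rbind, lapply(rows, `[[`, "vals")))
  names(out)[seq_along(methods)] <- paste0("tanimoto_", methods)
  out <- cbind(data.frame(target_id = target_id, candidate_id = candidate_ids,
                          name = lib$name[match(candidate_ids, lib$compound_id)],
                          stringsAsFactors = FALSE),
               out,
               data.frame(status = vapply(rows, `[[`, character(1), "status"),
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("similarity_profile", "data.frame")
  out
}

#' @export
print.similarity_profile <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  cat("Similarity profile vs target", x$target_id[1], "\n")
  print.data.frame(y[, setdiff(names(y), "target_id")], row.names = FALSE)
  invisible(x)
}

#' Export a similarity profile as CSV
#'
#' Writes the profile with values rounded half-up to two decimals, the
#' precision used in published analogue-quality tables.
#'
#' @param profile a `similarity_profile` from [pairwise_profile()].
#' @param path output CSV path.
#' @param digits decimals for the rounded export.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, digits = 2) {
  y <- as.data.frame(profile)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round_half_up, digits = digits)
  utils::write.csv(y, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Round half away from zero
#'
#' Reported similarity and reliability values are rounded half-up (0.745
#' -> 0.75), matching the convention of the published tables the package
#' reproduces; R's [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon absorbs binary representation error (0.565 * 100 = 56.4999...)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}
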