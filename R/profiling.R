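# Structural-alert (chemotype) matching and endpoint enrichment z-scores.

#' Structural alert library
#'
#' An alert library is a table of SMARTS patterns grouped into categories
#' (e.g. `"liver"`, `"dna_binder"`, `"dart"`). Every pattern is compiled at
#' construction; an invalid SMARTS is an immediate error. The same open
#' format accommodates public chemotype collections: any CSV/JSON with
#' columns `alert_id`, `category`, `label`, `smarts` loads directly.
#'
#' @param x a data frame with columns `alert_id`, `category`, `label`,
#'   `smarts`, or a path to a CSV or JSON file with those fields.
#' @return An object of class `alert_library`.
#' @seealso [default_alert_library()], [match_alerts()]
#' @export
alert_library <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      as.data.frame(jsonlite::fromJSON(x))
    } else {
      utils::read.csv(x, check.names = FALSE, colClasses = "character")
    }
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("alert_id", "category", "label", "smarts")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("alert library missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$alert_id)) stop("duplicate alert_id in alert library")
  probe <- smiles_to_sdf_one("CC")
  for (i in seq_len(nrow(x))) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, x$smarts[i], uniqueMatches = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("SMARTS does not compile for alert ", x$alert_id[i], ": ", x$smarts[i])
  }
  rownames(x) <- NULL
  class(x) <- c("alert_library", "data.frame")
  x
}

#' Bundled structural alert library
#'
#' A small curated SMARTS library covering the chemotype categories used in
#' the worked hair-dye example: pro-quinoid liver alerts
#' (para-amino/alkoxy phenol and phenylenediamine motifs), DNA-binder
#' alerts (aromatic nitro, aromatic amine, aromatic azo), and a
#' developmental/reproductive alert for the nitroaromatic-ether system.
#' It is an executable illustration, not a validated alert set; load a
#' full public chemotype collection via [alert_library()] for real
#' profiling.
#'
#' @return An [alert_library()].
#' @export
default_alert_library <- function() {
  alert_library(system.file("extdata", "alerts_default.csv",
                            package = "toxra", mustWork = TRUE))
}

#' Match a compound against a structural alert library
#'
#' Returns every alert whose SMARTS has at least one substructure match in
#' the compound, with the number of (unique-atom-set) matches. Matching is
#' performed on the largest organic fragment.
#'
#' @param compound a SMILES string, or a [compound_library()] together with
#'   `id` selecting one compound.
#' @param alerts an [alert_library()].
#' @param id compound id when `compound` is a library.
#' @return Data frame `alert_id`, `category`, `label`, `match_count`
#'   (matched alerts only; zero rows when nothing matches).
#' @export
match_alerts <- function(compound, alerts, id = NULL) {
  stopifnot(inherits(alerts, "alert_library"))
  if (inherits(compound, "compound_library")) {
    sdf <- lib_sdf(compound, id)
  } else {
    stopifnot(is.character(compound), length(compound) == 1)
    sdf <- smiles_to_sdf_one(largest_fragment(compound))
    if (is.null(sdf)) stop("compound SMILES does not parse: structure required")
  }
  counts <- vapply(alerts$smarts, function(pat) {
    as.numeric(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE))
  }, numeric(1))
  hit <- counts > 0
  out <- data.frame(alert_id = alerts$alert_id[hit], category = alerts$category[hit],
                    label = alerts$label[hit], match_count = unname(counts[hit]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Screen a compound library against alert categories
#'
#' Produces a per-compound, per-category flag table: `TRUE` when any alert
#' of the category matches. Structureless compounds are flagged
#' not-evaluable (`evaluable = FALSE`, category flags `NA`) rather than
#' silently dropped.
#'
#' @param lib a [compound_library()].
#' @param alerts an [alert_library()].
#' @return Data frame with `compound_id`, `evaluable`, and one logical
#'   column per alert category.
#' @export
screen_library <- function(lib, alerts) {
  stopifnot(inherits(lib, "compound_library"), inherits(alerts, "alert_library"))
  categories <- unique(alerts$category)
  out <- data.frame(compound_id = lib$compound_id, evaluable = lib$has_structure,
                    stringsAsFactors = FALSE)
  for (cat in categories) out[[cat]] <- rep(NA, nrow(out))
  for (i in seq_len(nrow(lib))) {
    if (!lib$has_structure[i]) next
    m <- match_alerts(lib, alerts, id = lib$compound_id[i])
    for (cat in categories) out[i, cat] <- cat %in% m$category
  }
  out
}

#' Endpoint enrichment z-score for a chemotype
#'
#' Two-proportion z statistic comparing the endpoint hit-rate inside a
#' chemotype subset with the hit-rate in its complement, using the pooled
#' proportion for the variance:
#' `z = (p1 - p2) / sqrt(p (1 - p) (1/n1 + 1/n2))`. Positive z means the
#' endpoint is enriched in the subset.
#'
#' @param hits_in_subset endpoint-positive count inside the subset.
#' @param subset_size size of the chemotype subset.
#' @param hits_total endpoint-positive count in the whole collection.
#' @param total size of the whole collection.
#' @return The z statistic; `NaN` (with a warning) when the pooled
#'   proportion is degenerate (0 or 1) or a group is empty.
#' @export
enrichment_z <- function(hits_in_subset, subset_size, hits_total, total) {
  stopifnot(subset_size <= total, hits_in_subset <= subset_size,
            hits_total <= total, hits_in_subset <= hits_total,
            hits_total - hits_in_subset <= total - subset_size)
  n1 <- subset_size
  n2 <- total - subset_size
  if (n1 == 0 || n2 == 0) {
    warning("empty subset or complement: z not defined")
    return(NaN)
  }
  p <- hits_total / total
  if (p <= 0 || p >= 1) {
    warning("degenerate pooled proportion (", p, "): z not defined")
    return(NaN)
  }
  p1 <- hits_in_subset / n1
  p2 <- (hits_total - hits_in_subset) / n2
  (p1 - p2) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

#' Bin an enrichment z-score
#'
#' Bins: `strong_neg` (z <= -2), `neg` (-2 < z <= -1), `neutral`
#' (-1 < z <= 1), `pos` (1 < z < 2), `strong_pos` (z >= 2). The neutral bin
#' owns its closed upper boundary, so z = 1 is neutral. The five intervals
#' partition the real line. Non-finite z yields `NA` (not evaluable).
#'
#' @param z numeric vector of z-scores.
#' @return Ordered factor with levels `strong_neg < neg < neutral < pos <
#'   strong_pos`.
#' @export
bin_z <- function(z) {
  lab <- c("strong_neg", "neg", "neutral", "pos", "strong_pos")
  out <- rep(NA_character_, length(z))
  fin <- is.finite(z)
  out[fin & z <= -2] <- "strong_neg"
  out[fin & z > -2 & z <= -1] <- "neg"
  out[fin & z > -1 & z <= 1] <- "neutral"
  out[fin & z > 1 & z < 2] <- "pos"
  out[fin & z >= 2] <- "strong_pos"
  factor(out, levels = lab, ordered = TRUE)
}
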