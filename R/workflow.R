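# Guided read-across workflow (steps 1-7), fixture generation, report
# export, and the command-line entry point.

#' Generate a packaged example library
#'
#' Three fixture bundles drive the documentation, tests and worked
#' examples:
#'
#' * `"parabens"`: the four alkyl parabens (methyl/ethyl/propyl/butyl
#'   4-hydroxybenzoate), propyl paraben as target, with the published
#'   fingerprint Tanimoto coefficients, raw property values and
#'   standardised property vectors attached as external tables. Because
#'   those similarity components are attached rather than recomputed, the
#'   bundle reproduces the published similarity/Analogue Quality
#'   arithmetic independently of descriptor-toolkit versions.
#' * `"hair_dyes"`: a target hair dye with three candidate dyes, the
#'   published similarity components, and three 90-day oral repeated-dose
#'   study records (NOAELs 17, 50 and 80 mg/kg-bw/day from SCCS/SCC/SCCP
#'   opinions, all grade 4 / Opinion Score 4). The SMILES here are
#'   synthetic surrogate structures chosen to exercise the bundled alert
#'   categories with the same match pattern as the real dyes; the real
#'   structures are not part of the bundle.
#' * `"random_homologues"`: a seed-deterministic synthetic library of
#'   alkyl homologues (parabens, nitro-substituted parabens and
#'   alkylbenzenes) with lognormal NOAELs, for stress-testing similarity
#'   search and nearest-neighbour estimation against brute-force oracles.
#'
#' @param kind fixture kind.
#' @param seed integer seed (used by `"random_homologues"` only; the other
#'   bundles are fully deterministic).
#' @param n library size for `"random_homologues"` (default 20).
#' @return An object of class `fixture_bundle`: a list with elements
#'   `kind`, `library`, `target`, and whichever of `tanimoto`, `zscores`,
#'   `property_sim`, `studies`, `reference` the kind provides.
#' @export
generate_fixture_library <- function(kind = c("parabens", "hair_dyes",
                                              "random_homologues"),
                                     seed = 1, n = 20) {
  kind <- match.arg(kind)
  bundle <- switch(kind,
                   parabens = fixture_parabens(),
                   hair_dyes = fixture_hair_dyes(),
                   random_homologues = fixture_random_homologues(seed, n))
  bundle$kind <- kind
  class(bundle) <- "fixture_bundle"
  bundle
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("Fixture bundle:", x$kind, "- target", x$target, "\n")
  print(x$library)
  invisible(x)
}

fixture_parabens <- function() {
  lib <- compound_library(
    compound_id = c("CMS-2411", "CMS-216", "CMS-2412", "CMS-2413"),
    name = c("Propyl paraben", "Butyl paraben", "Ethyl paraben", "Methyl paraben"),
    cas_rn = c("94-13-3", "94-26-8", "120-47-8", "99-76-3"),
    smiles = c("CCCOC(=O)c1ccc(O)cc1", "CCCCOC(=O)c1ccc(O)cc1",
               "CCOC(=O)c1ccc(O)cc1", "COC(=O)c1ccc(O)cc1"),
    role = c("target", "candidate", "candidate", "candidate"),
    source_label = "paraben example"
  )
  raw <- data.frame(
    compound_id = lib$compound_id,
    rotatable_bonds = c(4, 5, 3, 2),
    molecular_weight = c(180.2, 194.2, 166.2, 152.1),
    complexity = c(159.6, 171.4, 147.9, 136.3),
    tpsa = c(46.5, 46.5, 46.5, 46.5),
    xlogp = c(2.32, 2.87, 1.98, 1.55)
  )
  lib <- attach_property_table(lib, raw, source = "external")
  tanimoto <- matrix(
    c(1.00, 1.00, 1.00, 1.00,
      0.91, 0.94, 0.94, 0.90,
      0.80, 0.92, 0.93, 0.67,
      0.70, 0.82, 0.81, 0.50),
    nrow = 4, byrow = TRUE,
    dimnames = list(lib$compound_id, c("toxprint", "rdkit", "maccs", "liver_biopath")))
  zscores <- matrix(
    c(-0.19, -0.56, -0.51, -0.27, -0.08,
      -0.08, -0.50, -0.49, -0.27,  0.09,
      -0.31, -0.62, -0.53, -0.27, -0.18,
      -0.42, -0.68, -0.56, -0.27, -0.31),
    nrow = 4, byrow = TRUE,
    dimnames = list(lib$compound_id,
                    c("rotatable_bonds", "molecular_weight", "complexity",
                      "tpsa", "xlogp")))
  list(library = lib, target = "CMS-2411", tanimoto = tanimoto,
       zscores = zscores, reference = default_reference_statistics())
}

fixture_hair_dyes <- function() {
  # Surrogate nitroaromatic amine structures: same alert-category match
  # pattern as the documented dyes (all four are pro-quinoid aromatic
  # nitro-amines; only the two "similar" candidates carry the
  # nitroaromatic-ether reproductive alert).
  lib <- compound_library(
    compound_id = c("CMS-23938", "CMS-60520", "CMS-43204", "CMS-72054"),
    name = c("HC Red No. 7", "HC Violet No. 1", "HC Violet No. 2", "HC Blue No. 11"),
    cas_rn = c("24905-87-1", NA, NA, NA),
    smiles = c("Nc1ccc(N)c(c1)[N+](=O)[O-]",
               "OCCNc1ccc(N)c(c1)[N+](=O)[O-]",
               "OCCOc1ccc(N)cc1[N+](=O)[O-]",
               "COc1ccc(NCCO)cc1[N+](=O)[O-]"),
    role = c("target", "candidate", "candidate", "candidate"),
    source_label = "hair dye example (surrogate structures)"
  )
  tanimoto <- matrix(
    c(1.00, 1.00,
      0.85, 0.77,
      0.65, 0.72,
      0.68, 0.75),
    nrow = 4, byrow = TRUE,
    dimnames = list(lib$compound_id, c("toxprint", "rdkit")))
  property_sim <- data.frame(
    compound_id = lib$compound_id,
    euclidean_distance = c(0, 0.13, 1.05, 1.08),
    euclidean_similarity = c(1, 0.88, 0.49, 0.48),
    pearson_similarity = c(1, 0.999, 0.95, 0.90),
    stringsAsFactors = FALSE
  )
  studies <- data.frame(
    study_id = c("S-60520", "S-43204", "S-72054"),
    compound_id = c("CMS-60520", "CMS-43204", "CMS-72054"),
    endpoint = "repeated_dose_90d",
    species = c("SD rat", "SD rat", "Wistar rat"),
    duration = "90d",
    route = "oral gavage/intubation",
    dose_range = c("50-500 mkd", "50-800 mkd", "50-160 mkd"),
    noael = c(17, 50, 80),
    loael = c(50, NA, NA),
    source = c("SCCS", "SCC", "SCCP"),
    minis_rules = "PPPPPPPPPPPPPPFF",
    summary_only = FALSE,
    opinion_score = 4L,
    stringsAsFactors = FALSE
  )
  list(library = lib, target = "CMS-23938", tanimoto = tanimoto,
       property_sim = property_sim, studies = studies)
}

fixture_random_homologues <- function(seed, n) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  scaffold <- sample(c("paraben", "nitroparaben", "alkylbenzene"), n,
                     replace = TRUE, prob = c(0.5, 0.25, 0.25))
  chain <- sample(1:8, n, replace = TRUE)
  smiles <- vapply(seq_len(n), function(i) {
    alkyl <- strrep("C", chain[i])
    switch(scaffold[i],
           paraben = paste0(alkyl, "OC(=O)c1ccc(O)cc1"),
           nitroparaben = paste0(alkyl, "OC(=O)c1ccc(O)c([N+](=O)[O-])c1"),
           alkylbenzene = paste0(alkyl, "c1ccccc1"))
  }, character(1))
  noael <- round(stats::rlnorm(n, log(50), 0.6), 1)
  lib <- compound_library(sprintf("HOM-%03d", seq_len(n)),
                          name = paste0(scaffold, "-C", chain),
                          smiles = smiles,
                          source_label = sprintf("random homologues (seed %d)", seed))
  lib <- attach_property_table(
    lib, data.frame(compound_id = lib$compound_id, noael = noael),
    source = "generator")
  list(library = lib, target = lib$compound_id[1],
       noael = stats::setNames(noael, lib$compound_id))
}

#' Run the guided read-across workflow
#'
#' Executes the seven-step guided workflow against a compound library:
#' (1) similarity search for candidates, (2) property table, (3) pairwise
#' similarity profiles and Analogue Quality, (4) structural-alert
#' screening, (5) study reliability scoring, (6) weight-of-evidence table
#' with read-across reliability (joint probability, full precision, plus a
#' Dempster-Shafer belief/plausibility interval) and analogue
#' qualification, (7) NOAEL bound estimation from the qualified analogues.
#' If a prerequisite is missing (no candidates, no studies, fewer than two
#' analogue NOAELs) the run halts gracefully and returns a partial report
#' with all completed steps intact.
#'
#' `read_across()` is generic: pass a [compound_library()] plus a
#' `target_id`, or a [generate_fixture_library()] bundle, whose attached
#' tables (published Tanimoto coefficients, standardised vectors, property
#' similarities, studies) are used in place of recomputation.
#'
#' @param x a [compound_library()] or `fixture_bundle`.
#' @param ... passed on to methods.
#' @return An object of class `read_across_report`.
#' @export
read_across <- function(x, ...) UseMethod("read_across")

#' @rdname read_across
#' @export
read_across.fixture_bundle <- function(x, ...) {
  args <- list(...)
  bundled <- list(target_id = x$target, studies = x$studies,
                  tanimoto_values = x$tanimoto, zscores = x$zscores,
                  property_sim = x$property_sim, ref = x$reference)
  for (nm in names(bundled)) {
    if (!nm %in% names(args)) args[nm] <- bundled[nm]
  }
  do.call(read_across, c(list(x$library), args))
}

#' @rdname read_across
#' @param target_id compound id of the target in the library.
#' @param studies optional study records (data frame or path; see
#'   [read_study_records()]).
#' @param fp_methods fingerprint methods when Tanimoto values are computed
#'   rather than supplied.
#' @param properties property names for the property-based component.
#' @param ref [reference_statistics()] for standardisation.
#' @param threshold candidate similarity threshold (default 0.7).
#' @param aq_variant which Analogue Quality variant feeds the
#'   weight-of-evidence (`"euclidean"`, the default, or `"pearson"`).
#' @param reliability_table grid for [reliability_likelihood()].
#' @param alerts [alert_library()] for the screening step.
#' @param tanimoto_values,zscores,property_sim optional supplied similarity
#'   components (see [pairwise_profile()]).
#' @param aq_floor,srl_floor,srl_hard_floor qualification floors (see
#'   [qualify_analogue()]).
#' @param dst_discount source discount for the Dempster-Shafer interval.
#' @param noael_level,noael_mode interval settings for [noael_bounds()].
#' @export
read_across.compound_library <- function(x, target_id, studies = NULL,
                                         fp_methods = c("path", "maccs"),
                                         properties = c("rotatable_bonds",
                                                        "molecular_weight",
                                                        "complexity", "tpsa", "logp"),
                                         ref = NULL, threshold = 0.7,
                                         aq_variant = c("euclidean", "pearson"),
                                         reliability_table = default_reliability_table(),
                                         alerts = default_alert_library(),
                                         tanimoto_values = NULL, zscores = NULL,
                                         property_sim = NULL,
                                         aq_floor = 0.7, srl_floor = 0.7,
                                         srl_hard_floor = 0.5, dst_discount = 0.9,
                                         noael_level = 0.95,
                                         noael_mode = "normal_sd", ...) {
  lib <- x
  aq_variant <- match.arg(aq_variant)
  if (!target_id %in% lib$compound_id) stop("target not in library: ", target_id)
  steps <- list()
  messages <- character()
  status <- "complete"
  halt <- function(msg) {
    messages <<- c(messages, msg)
    status <<- "partial"
  }

  # Step 1: similarity searching / candidate selection
  if (!is.null(tanimoto_values)) {
    tv <- as.matrix(tanimoto_values)
    cand <- setdiff(rownames(tv), target_id)
    best <- apply(tv[cand, , drop = FALSE], 1, max)
    hits <- data.frame(compound_id = cand,
                       name = lib$name[match(cand, lib$compound_id)],
                       tanimoto = unname(best), stringsAsFactors = FALSE)
    hits <- hits[hits$tanimoto >= threshold, , drop = FALSE]
    hits <- hits[order(-hits$tanimoto, hits$compound_id), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- similarity_search(target_id, lib, method = fp_methods[1],
                              threshold = threshold)
    hits <- hits[hits$compound_id != target_id, , drop = FALSE]
  }
  steps$hits <- hits
  candidates <- hits$compound_id
  if (!length(candidates)) {
    halt("no candidates above the similarity threshold")
    return(new_report(target_id, steps, status, messages, aq_variant, threshold))
  }

  # Step 2: property table (z-scores, or supplied property similarities)
  steps$properties <- if (!is.null(zscores)) {
    as.data.frame(cbind(compound_id = rownames(zscores), as.data.frame(zscores)))
  } else if (!is.null(property_sim)) {
    property_sim
  } else {
    raw <- property_matrix(lib, properties, ids = c(target_id, candidates))
    z <- standardise_properties(raw, ref)
    zscores <- z
    as.data.frame(cbind(compound_id = rownames(z), as.data.frame(z)))
  }

  # Step 3: similarity profiles and Analogue Quality
  profiles <- pairwise_profile(lib, target_id, candidates,
                               fp_methods = fp_methods, properties = properties,
                               ref = ref, tanimoto_values = tanimoto_values,
                               zscores = zscores, property_sim = property_sim)
  steps$profiles <- profiles

  # Step 4: chemotype / structural alert screening
  steps$alerts <- tryCatch(
    screen_library(lib_subset(lib, c(target_id, candidates)), alerts),
    error = function(e) { halt(paste("alert screening failed:",
                                     conditionMessage(e))); NULL })

  # Step 5: study reliability
  if (is.null(studies)) {
    halt("no study records supplied; stopping after similarity and profiling")
    return(new_report(target_id, steps, status, messages, aq_variant, threshold))
  }
  recs <- read_study_records(studies, table = reliability_table)
  steps$studies <- recs

  # Step 6: weight-of-evidence table
  aq_col <- paste0("aq_", aq_variant)
  ev <- data.frame(compound_id = c(target_id, candidates),
                   name = lib$name[match(c(target_id, candidates), lib$compound_id)],
                   stringsAsFactors = FALSE)
  ev$analogue_quality <- c(1, profiles[[aq_col]][match(candidates,
                                                       profiles$candidate_id)])
  ev$analogue_quality[1] <- NA  # the target is not its own analogue
  best_study <- function(id) {
    r <- recs[recs$compound_id == id & !is.na(recs$study_reliability), , drop = FALSE]
    if (!nrow(r)) return(list(srl = NA_real_, noael = NA_real_, source = NA_character_))
    r <- r[order(-r$study_reliability), , drop = FALSE]
    list(srl = r$study_reliability[1], noael = r$noael[1], source = r$source[1])
  }
  bs <- lapply(ev$compound_id, best_study)
  ev$study_reliability <- vapply(bs, `[[`, numeric(1), "srl")
  ev$noael <- vapply(bs, `[[`, numeric(1), "noael")
  ev$study_source <- vapply(bs, `[[`, character(1), "source")
  ev$read_across_reliability <- NA_real_
  ev$dst_belief <- NA_real_
  ev$dst_plausibility <- NA_real_
  ev$role <- c("target", rep("similar", length(candidates)))
  ev$qualification <- NA_character_
  for (i in seq_len(nrow(ev))[-1]) {
    aq <- ev$analogue_quality[i]; srl <- ev$study_reliability[i]
    if (is.na(aq) || is.na(srl)) next
    ev$read_across_reliability[i] <- joint_reliability(aq, srl)
    q <- qualify_analogue(aq, srl, aq_floor, srl_floor, srl_hard_floor)
    ev$qualification[i] <- as.character(q$status)
    if (q$status == "qualified") ev$role[i] <- "analogue"
    bp <- belief_plausibility(dst_combine(build_mass(aq, dst_discount),
                                          build_mass(srl, dst_discount)))
    ev$dst_belief[i] <- bp["belief"]
    ev$dst_plausibility[i] <- bp["plausibility"]
  }
  if (!is.null(steps$alerts)) {
    flag_cols <- setdiff(names(steps$alerts), c("compound_id", "evaluable"))
    ev <- merge(ev, steps$alerts[, c("compound_id", flag_cols)],
                by = "compound_id", sort = FALSE)
    ev <- ev[match(c(target_id, candidates), ev$compound_id), , drop = FALSE]
    rownames(ev) <- NULL
  }
  steps$evidence <- ev

  # Step 7: NOAEL estimate from qualified analogues
  vals <- ev$noael[ev$role == "analogue" & !is.na(ev$noael)]
  if (length(vals) >= 2) {
    steps$noael <- noael_bounds(vals, level = noael_level, mode = noael_mode)
  } else if (length(vals) == 1) {
    steps$noael <- structure(c(lower = NA_real_, upper = NA_real_),
                             point = vals, n = 1L,
                             note = paste("single qualified analogue:",
                                          "NOAEL reported without an interval"))
    halt("only one qualified analogue NOAEL; no confidence interval estimated")
  } else {
    halt("no qualified analogue NOAELs; endpoint estimation not possible")
  }

  new_report(target_id, steps, status, messages, aq_variant, threshold)
}

new_report <- function(target_id, steps, status, messages, aq_variant, threshold) {
  structure(list(target_id = target_id, steps = steps, status = status,
                 messages = messages,
                 config = list(aq_variant = aq_variant, threshold = threshold)),
            class = "read_across_report")
}

#' @export
print.read_across_report <- function(x, ...) {
  cat("Guided read-across report for target", x$target_id,
      sprintf("[%s]\n", x$status))
  step_names <- c(hits = "1 similarity search", properties = "2 property table",
                  profiles = "3 similarity profiles", alerts = "4 alert screen",
                  studies = "5 study reliability", evidence = "6 weight of evidence",
                  noael = "7 NOAEL estimate")
  for (s in names(step_names)) {
    done <- !is.null(x$steps[[s]])
    cat(sprintf("  step %-22s %s\n", step_names[[s]],
                if (done) "done" else "-"))
  }
  if (!is.null(x$steps$evidence)) {
    ev <- x$steps$evidence
    cat("Evidence (reliability at 2 dp):\n")
    show <- data.frame(compound_id = ev$compound_id, role = ev$role,
                       AQ = round_half_up(ev$analogue_quality),
                       SRL = ev$study_reliability,
                       RAxR = round_half_up(ev$read_across_reliability),
                       DST = ifelse(is.na(ev$dst_belief), NA,
                                    sprintf("%.2f - %.2f", ev$dst_belief,
                                            ev$dst_plausibility)))
    print.data.frame(show, row.names = FALSE)
  }
  if (length(x$messages)) cat("Notes:", paste(x$messages, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.read_across_report <- function(object, ...) {
  object$steps$evidence
}

#' Export a workflow report
#'
#' `"csv_bundle"` writes one file per completed step (`step1_hits.csv` ..
#' `step7_noael.csv`); `"json"` writes a single machine-readable dump that
#' [import_report()] reads back; `"markdown"` writes a human-readable
#' summary with reliabilities at two decimals. Output is deterministic:
#' identical reports produce byte-identical files.
#'
#' @param report a `read_across_report`.
#' @param dir output directory (created if needed).
#' @param format `"csv_bundle"`, `"json"` or `"markdown"`.
#' @return Character vector of the files written.
#' @export
export_report <- function(report, dir, format = c("csv_bundle", "json", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "read_across_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  files <- character()
  if (format == "csv_bundle") {
    step_files <- c(hits = "step1_hits.csv", properties = "step2_properties.csv",
                    profiles = "step3_similarity.csv", alerts = "step4_alerts.csv",
                    studies = "step5_studies.csv", evidence = "step6_evidence.csv",
                    noael = "step7_noael.csv")
    for (s in names(step_files)) {
      obj <- report$steps[[s]]
      if (is.null(obj)) next
      path <- file.path(dir, step_files[[s]])
      if (s == "noael") {
        utils::write.csv(noael_as_df(obj), path, row.names = FALSE, na = "")
      } else {
        utils::write.csv(as.data.frame(obj), path, row.names = FALSE, na = "")
      }
      files <- c(files, path)
    }
  } else if (format == "json") {
    path <- file.path(dir, "report.json")
    payload <- report
    payload$steps <- lapply(report$steps, function(s) {
      if (is.null(dim(s)) && is.numeric(s)) noael_as_df(s) else as.data.frame(s)
    })
    class(payload) <- NULL
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- path
  } else {
    path <- file.path(dir, "report.md")
    lines <- c(paste("# Read-across report:", report$target_id),
               paste("Status:", report$status), "")
    if (!is.null(report$steps$evidence)) {
      ev <- report$steps$evidence
      lines <- c(lines, "## Weight of evidence", "",
                 "| compound | role | AQ | SRL | read-across reliability | DST interval |",
                 "|---|---|---|---|---|---|",
                 vapply(seq_len(nrow(ev)), function(i) {
                   fmt <- function(v) if (is.na(v)) "" else sprintf("%.2f", round_half_up(v))
                   sprintf("| %s | %s | %s | %s | %s | %s |",
                           ev$compound_id[i], ev$role[i],
                           fmt(ev$analogue_quality[i]), fmt(ev$study_reliability[i]),
                           fmt(ev$read_across_reliability[i]),
                           if (is.na(ev$dst_belief[i])) "" else
                             sprintf("%.2f - %.2f", round_half_up(ev$dst_belief[i]),
                                     round_half_up(ev$dst_plausibility[i])))
                 }, character(1)), "")
    }
    if (!is.null(report$steps$noael)) {
      nb <- report$steps$noael
      lines <- c(lines, "## NOAEL estimate", "",
                 if (!is.na(nb["lower"])) {
                   sprintf("%.4g - %.4g mg/kg-bw/day (n = %d, level %.2f, mode %s)",
                           nb["lower"], nb["upper"], attr(nb, "n"),
                           attr(nb, "level"), attr(nb, "mode"))
                 } else {
                   sprintf("single analogue NOAEL %.4g mg/kg-bw/day (no interval)",
                           attr(nb, "point"))
                 }, "")
    }
    if (length(report$messages)) {
      lines <- c(lines, "## Notes", "", paste("-", report$messages), "")
    }
    writeLines(lines, path)
    files <- path
  }
  files
}

noael_as_df <- function(nb) {
  data.frame(lower = unname(nb["lower"]), upper = unname(nb["upper"]),
             mean = if (!is.null(attr(nb, "mean"))) attr(nb, "mean") else NA,
             sd = if (!is.null(attr(nb, "sd"))) attr(nb, "sd") else NA,
             n = attr(nb, "n"),
             point = if (!is.null(attr(nb, "point"))) attr(nb, "point") else NA,
             level = if (!is.null(attr(nb, "level"))) attr(nb, "level") else NA,
             mode = if (!is.null(attr(nb, "mode"))) attr(nb, "mode") else NA)
}

#' Re-import a JSON workflow report
#'
#' @param path a `report.json` written by [export_report()].
#' @return A `read_across_report` whose step tables equal the original's.
#' @export
import_report <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$steps <- lapply(x$steps, as.data.frame)
  structure(list(target_id = x$target_id, steps = x$steps, status = x$status,
                 messages = unlist(x$messages),
                 config = x$config),
            class = "read_across_report")
}

#' Command-line interface
#'
#' Entry point behind the `toxra` command script (see
#' `system.file("cli", "toxra", package = "toxra")`). Subcommands:
#' `ttc`, `search`, `reliability`, `readacross`, `profile`, `fixtures`.
#' Options use `--key value` form, e.g.
#' `toxra ttc --smiles "CCO" --cramer-class III --exposure 0.35
#' --exposure-unit ug_per_kg_bw_day --body-weight 60`.
#'
#' @param args character vector of command-line arguments (defaults to
#'   [commandArgs()] trailing arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
toxra_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: toxra <ttc|search|reliability|readacross|profile|fixtures> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_options(args[-1])
  get <- function(key, default = NULL) {
    if (!is.null(opts[[key]])) opts[[key]] else default
  }
  json <- function(x) cat(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                           na = "null", pretty = TRUE), "\n")
  switch(cmd,
    ttc = {
      v <- ttc_evaluate(get("smiles"),
                        cramer_class = get("cramer-class", "III"),
                        exposure = as.numeric(get("exposure")),
                        exposure_unit = get("exposure-unit", "ug_per_kg_bw_day"),
                        body_weight_kg = as.numeric(get("body-weight", 60)))
      json(unclass(v))
    },
    search = {
      lib <- read_compounds(get("library"), get("format", "smiles_csv"))
      hits <- similarity_search(get("query"), lib,
                                method = get("method", "path"),
                                threshold = as.numeric(get("threshold", 0.7)))
      out <- get("out")
      if (is.null(out)) {
        utils::write.csv(hits, stdout(), row.names = FALSE)
      } else utils::write.csv(hits, out, row.names = FALSE)
    },
    reliability = {
      grade <- if (!is.null(get("rules"))) {
        minis_grade(get("rules"), isTRUE(as.logical(get("summary-only", FALSE))))
      } else as.integer(get("grade"))
      opinion <- as.integer(get("opinion"))
      json(list(grade = grade, opinion = opinion,
                study_reliability = reliability_likelihood(grade, opinion)))
    },
    readacross = {
      report <- if (!is.null(get("fixture"))) {
        read_across(generate_fixture_library(get("fixture"),
                                             seed = as.integer(get("seed", 1))))
      } else {
        lib <- read_compounds(get("library"), get("format", "smiles_csv"))
        read_across(lib, target_id = get("target"), studies = get("studies"),
                    ref = if (!is.null(get("reference")))
                      reference_statistics(get("reference")) else NULL)
      }
      out_dir <- get("out-dir")
      if (!is.null(out_dir)) {
        export_report(report, out_dir, get("export-format", "csv_bundle"))
      }
      print(report)
    },
    profile = {
      lib <- read_compounds(get("library"), get("format", "smiles_csv"))
      alerts <- if (!is.null(get("alerts"))) alert_library(get("alerts"))
                else default_alert_library()
      tab <- screen_library(lib, alerts)
      out <- get("out")
      if (is.null(out)) utils::write.csv(tab, stdout(), row.names = FALSE)
      else utils::write.csv(tab, out, row.names = FALSE)
    },
    fixtures = {
      b <- generate_fixture_library(get("kind", "parabens"),
                                    seed = as.integer(get("seed", 1)))
      out_dir <- get("out-dir", ".")
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_compounds(b$library, file.path(out_dir, paste0(b$kind, "_library.csv")),
                      "smiles_csv")
      if (!is.null(b$studies)) {
        utils::write.csv(b$studies, file.path(out_dir, paste0(b$kind, "_studies.csv")),
                         row.names = FALSE, na = "")
      }
      cat("fixture", b$kind, "written to", out_dir, "\n")
    },
    {
      cat("unknown command:", cmd, "\n")
      return(invisible(1L))
    }
  )
  invisible(0L)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    } else {
      opts[[key]] <- TRUE
      i <- i + 1
    }
  }
  opts
}
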