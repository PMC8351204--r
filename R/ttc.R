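# Non-cancer Threshold of Toxicological Concern decision tree.

# Metals and metalloids flagged by the cohort-of-concern rule when present
# in the assessed (largest organic) fragment.
COC_METALS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb", "Te",
  "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho",
  "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au",
  "Hg", "Tl", "Pb", "Bi", "Po", "Ra", "Th", "U"
)

COC_CORES <- list(
  `polyhalogenated dibenzodioxin` = "c1ccc2c(c1)Oc1ccccc1O2",
  `polyhalogenated dibenzofuran` = "c1ccc2c(c1)oc1ccccc12",
  `polyhalogenated biphenyl` = "c1ccc(-c2ccccc2)cc1"
)
ARYL_HALIDE_SMARTS <- "c[F,Cl,Br,I]"
ORGANOPHOSPHATE_SMARTS <- "[#15X4](=[OX1,SX1])([OX2])[OX2]"

#' Default TTC threshold configuration
#'
#' Human-exposure thresholds for the non-cancer TTC decision tree, in
#' micrograms per person per day: Cramer Class I 1800, Class II 540,
#' Class III 90, and 18 for organophosphates. Class I/II and the
#' organophosphate value are the standard published scheme defaults and
#' are editable configuration. The cohort-of-concern groups (metals and
#' metal-containing compounds, polyhalogenated dibenzo-p-dioxins,
#' dibenzofurans and biphenyls) are encoded as an element rule plus core
#' SMARTS with an aromatic-halogen count.
#'
#' @param cramer named numeric vector of Class I/II/III thresholds
#'   (ug/person/day); must satisfy I >= II >= III > 0.
#' @param organophosphate organophosphate threshold (ug/person/day).
#' @param min_aryl_halogens halogen count on aromatic carbons required for
#'   the "polyhalogenated" cores (default 2).
#' @return An object of class `ttc_thresholds`.
#' @export
ttc_thresholds <- function(cramer = c(I = 1800, II = 540, III = 90),
                           organophosphate = 18, min_aryl_halogens = 2) {
  stopifnot(all(c("I", "II", "III") %in% names(cramer)))
  cramer <- cramer[c("I", "II", "III")]
  if (any(cramer <= 0) || cramer["I"] < cramer["II"] || cramer["II"] < cramer["III"]) {
    stop("Cramer thresholds must satisfy I >= II >= III > 0")
  }
  if (organophosphate <= 0) stop("organophosphate threshold must be positive")
  structure(list(cramer = cramer, organophosphate = organophosphate,
                 min_aryl_halogens = min_aryl_halogens),
            class = "ttc_thresholds")
}

#' Convert exposure per kg body weight to exposure per person
#'
#' @param value exposure in ug/kg-bw/day, positive.
#' @param body_weight_kg body weight in kg (default 60, the conventional
#'   adult value).
#' @return Exposure in ug/person/day.
#' @examples
#' convert_exposure(0.35)  # 21 ug/person/day
#' @export
convert_exposure <- function(value, body_weight_kg = 60) {
  if (any(value <= 0)) stop("exposure must be positive")
  if (any(body_weight_kg <= 0)) stop("body weight must be positive")
  value * body_weight_kg
}

#' Cohort-of-concern check
#'
#' Tests whether a structure belongs to one of the groups excluded from
#' TTC waiving: metals/metal-containing compounds, and polyhalogenated
#' dibenzo-p-dioxins, dibenzofurans and biphenyls. Evaluation uses the
#' largest organic fragment, so simple counterions (e.g. the sodium of a
#' sulfonate salt) do not trigger the metal rule; a metal bound within the
#' main fragment does.
#'
#' @param smiles a SMILES string.
#' @param config a [ttc_thresholds()] configuration.
#' @return List with `is_coc` (logical, `NA` when the structure does not
#'   parse) and `group` (matched group name or `NA`).
#' @export
coc_check <- function(smiles, config = ttc_thresholds()) {
  frag <- largest_fragment(smiles)
  sdf <- smiles_to_sdf_one(frag)
  if (is.null(sdf)) return(list(is_coc = NA, group = NA_character_))
  elements <- sub("_.*$", "", rownames(ChemmineR::atomblock(sdf[[1]])))
  metals <- intersect(elements, COC_METALS)
  if (length(metals)) {
    return(list(is_coc = TRUE,
                group = paste0("metal containing compounds (", metals[1], ")")))
  }
  nhal <- as.numeric(ChemmineR::smartsSearchOB(sdf, ARYL_HALIDE_SMARTS,
                                                uniqueMatches = TRUE))
  if (nhal >= config$min_aryl_halogens) {
    for (grp in names(COC_CORES)) {
      hit <- as.numeric(ChemmineR::smartsSearchOB(sdf, COC_CORES[[grp]],
                                                   uniqueMatches = TRUE))
      if (hit > 0) return(list(is_coc = TRUE, group = grp))
    }
  }
  list(is_coc = FALSE, group = NA_character_)
}

#' Organophosphate check
#'
#' Matches phosphate / phosphorothioate ester cores
#' (`P(=O/S)(O-)(O-)`).
#'
#' @param smiles a SMILES string.
#' @return `TRUE`/`FALSE`, or `NA` when the structure does not parse.
#' @export
is_organophosphate <- function(smiles) {
  sdf <- smiles_to_sdf_one(largest_fragment(smiles))
  if (is.null(sdf)) return(NA)
  as.numeric(ChemmineR::smartsSearchOB(sdf, ORGANOPHOSPHATE_SMARTS,
                                        uniqueMatches = TRUE)) > 0
}

#' Evaluate the non-cancer TTC decision tree
#'
#' Ordered evaluation: (Q1) cohort-of-concern membership fails
#' immediately, independent of exposure; (Q6) organophosphates are
#' compared against the organophosphate threshold; (Q9) otherwise the
#' exposure is compared against the threshold of the supplied Cramer
#' class. Threshold comparisons are strict: an exposure exactly equal to
#' the threshold fails, conservatively. The full question/answer trace is
#' recorded.
#'
#' The Cramer class is an input: it comes from an external classifier
#' (implementations are known to disagree for some compound classes, which
#' is why `cramer_warning` can be set to surface that caveat in the
#' verdict) or from expert assignment.
#'
#' @param smiles SMILES of the query compound (`NA` for a structureless
#'   record: the tree returns `not_applicable`).
#' @param cramer_class `"I"`, `"II"` or `"III"`.
#' @param exposure exposure value, positive.
#' @param exposure_unit `"ug_per_kg_bw_day"` (converted with
#'   `body_weight_kg`) or `"ug_per_person_day"`.
#' @param body_weight_kg body weight for the conversion (default 60 kg).
#' @param config a [ttc_thresholds()] configuration.
#' @param cramer_warning logical flag recorded on the verdict when the
#'   external class assignment is known to be contested.
#' @return An object of class `ttc_verdict`: `outcome` (`"pass"`,
#'   `"fail"`, `"not_applicable"`), `fired_node`, `threshold_applied`
#'   (ug/person/day; `NA` when no threshold comparison occurred),
#'   `exposure_per_person`, `cramer_class`, `cramer_warning`, and `trace`
#'   (ordered data frame of question/answer pairs).
#' @examples
#' ttc_evaluate("[Na+].[O-]S(=O)(=O)c1cccc2ccccc12", "III",
#'              exposure = 0.35, exposure_unit = "ug_per_kg_bw_day")
#' @export
ttc_evaluate <- function(smiles, cramer_class = c("I", "II", "III"),
                         exposure, exposure_unit = c("ug_per_kg_bw_day",
                                                     "ug_per_person_day"),
                         body_weight_kg = 60, config = ttc_thresholds(),
                         cramer_warning = FALSE) {
  cramer_class <- match.arg(as.character(cramer_class), c("I", "II", "III"))
  exposure_unit <- match.arg(exposure_unit)
  if (missing(exposure)) stop("exposure is required")
  epp <- if (exposure_unit == "ug_per_kg_bw_day") {
    convert_exposure(exposure, body_weight_kg)
  } else {
    if (exposure <= 0) stop("exposure must be positive")
    exposure
  }

  trace <- data.frame(question = character(), answer = character(),
                      stringsAsFactors = FALSE)
  note <- function(q, a) {
    trace <<- rbind(trace, data.frame(question = q, answer = a,
                                      stringsAsFactors = FALSE))
  }
  verdict <- function(outcome, node, threshold) {
    structure(list(outcome = outcome, fired_node = node,
                   threshold_applied = threshold, exposure_per_person = epp,
                   cramer_class = cramer_class, cramer_warning = cramer_warning,
                   trace = trace),
              class = "ttc_verdict")
  }

  if (is.na(smiles) || !nzchar(smiles)) {
    note("Q1 cohort of concern", "not evaluable: no structure")
    return(verdict("not_applicable", "Q1 COC", NA_real_))
  }
  coc <- coc_check(smiles, config)
  if (is.na(coc$is_coc)) {
    note("Q1 cohort of concern", "not evaluable: structure does not parse")
    return(verdict("not_applicable", "Q1 COC", NA_real_))
  }
  if (coc$is_coc) {
    note("Q1 cohort of concern", paste0("yes: ", coc$group))
    return(verdict("fail", "Q1 COC", NA_real_))
  }
  note("Q1 cohort of concern", "no")

  op <- is_organophosphate(smiles)
  if (isTRUE(op)) {
    note("Q6 organophosphate", "yes")
    thr <- config$organophosphate
    out <- if (epp < thr) "pass" else "fail"
    note(sprintf("exposure %.4g vs organophosphate threshold %.4g ug/person/day",
                 epp, thr), out)
    return(verdict(out, "Q6 organophosphate", thr))
  }
  note("Q6 organophosphate", "no")

  thr <- config$cramer[[cramer_class]]
  note(paste0("Q9 Cramer class"), cramer_class)
  out <- if (epp < thr) "pass" else "fail"
  note(sprintf("exposure %.4g vs Cramer %s threshold %.4g ug/person/day",
               epp, cramer_class, thr), out)
  verdict(out, paste0("Q9 Cramer ", cramer_class), thr)
}

#' @export
print.ttc_verdict <- function(x, ...) {
  cat("TTC verdict:", toupper(x$outcome), "at node", x$fired_node, "\n")
  cat(sprintf("  exposure: %.4g ug/person/day", x$exposure_per_person))
  if (!is.na(x$threshold_applied)) {
    cat(sprintf("; threshold applied: %.4g ug/person/day", x$threshold_applied))
  }
  cat("\n  Cramer class:", x$cramer_class)
  if (isTRUE(x$cramer_warning)) {
    cat("  [warning: external Cramer assignment contested for this compound type]")
  }
  cat("\n  trace:\n")
  for (i in seq_len(nrow(x$trace))) {
    cat("   ", x$trace$question[i], "->", x$trace$answer[i], "\n")
  }
  invisible(x)
}
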