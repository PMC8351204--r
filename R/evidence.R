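# Weight-of-evidence assembly: joint read-across reliability,
# Dempster-Shafer combination, analogue qualification, NOAEL bounds.

#' Read-across reliability as a joint probability
#'
#' The reliability of reading a study result across from an analogue is
#' the joint probability of two independent pieces of evidence: the
#' Analogue Quality (how good the analogue is) and the study reliability
#' likelihood (how good the study is). Full precision is kept; round only
#' for reporting (see [round_half_up()]).
#'
#' @param analogue_quality value(s) in `[0, 1]`.
#' @param study_reliability value(s) in `[0, 1]`.
#' @return Element-wise product, in `[0, 1]`.
#' @examples
#' joint_reliability(0.83, 0.9)  # ~0.75
#' @export
joint_reliability <- function(analogue_quality, study_reliability) {
  check_unit_interval(analogue_quality, "analogue_quality")
  check_unit_interval(study_reliability, "study_reliability")
  analogue_quality * study_reliability
}

check_unit_interval <- function(x, what) {
  if (anyNA(x) || any(x < 0 | x > 1)) stop(what, " must lie in [0, 1]")
  invisible(x)
}

#' Qualify a candidate as an analogue
#'
#' A candidate qualifies as an analogue when both the Analogue Quality and
#' the study reliability likelihood reach 0.7; below either floor,
#' read-across is unlikely to be feasible or reliable and the candidate
#' remains merely "similar". A study reliability below 0.5 means the data
#' do not warrant read-across at all (`data_unusable`, which takes
#' precedence).
#'
#' @param analogue_quality AQ value(s) in `[0, 1]`.
#' @param study_reliability study reliability value(s) in `[0, 1]`.
#' @param aq_floor,srl_floor qualification floors (default 0.7).
#' @param srl_hard_floor hard floor below which data are unusable
#'   (default 0.5).
#' @return Data frame with `status` (factor: `qualified`, `not_feasible`,
#'   `data_unusable`) and a human-readable `rationale`.
#' @export
qualify_analogue <- function(analogue_quality, study_reliability,
                             aq_floor = 0.7, srl_floor = 0.7,
                             srl_hard_floor = 0.5) {
  check_unit_interval(analogue_quality, "analogue_quality")
  check_unit_interval(study_reliability, "study_reliability")
  n <- max(length(analogue_quality), length(study_reliability))
  aq <- rep_len(analogue_quality, n)
  srl <- rep_len(study_reliability, n)
  status <- character(n)
  rationale <- character(n)
  for (i in seq_len(n)) {
    if (srl[i] < srl_hard_floor) {
      status[i] <- "data_unusable"
      rationale[i] <- sprintf(
        "study reliability %.2f below hard floor %.2f: data do not warrant read-across",
        srl[i], srl_hard_floor)
    } else if (aq[i] >= aq_floor && srl[i] >= srl_floor) {
      status[i] <- "qualified"
      rationale[i] <- sprintf("AQ %.2f >= %.2f and study reliability %.2f >= %.2f",
                              aq[i], aq_floor, srl[i], srl_floor)
    } else {
      status[i] <- "not_feasible"
      low <- c(if (aq[i] < aq_floor) sprintf("AQ %.2f < %.2f", aq[i], aq_floor),
               if (srl[i] < srl_floor) sprintf("study reliability %.2f < %.2f",
                                               srl[i], srl_floor))
      rationale[i] <- paste(low, collapse = "; ")
    }
  }
  data.frame(status = factor(status, levels = c("qualified", "not_feasible",
                                                "data_unusable")),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Mass function over the read-across reliability frame
#'
#' Belief masses over the frame `{reliable, not_reliable}` plus the whole
#' frame (`either`, the residual ignorance). Masses must be non-negative
#' and sum to 1 (within 1e-9).
#'
#' @param reliable,not_reliable,either non-negative masses summing to 1.
#' @return An object of class `mass_function`.
#' @export
mass_function <- function(reliable, not_reliable, either) {
  m <- c(reliable = reliable, not_reliable = not_reliable, either = either)
  if (any(m < -1e-12)) stop("masses must be non-negative")
  if (abs(sum(m) - 1) > 1e-9) stop("masses must sum to 1 (got ", sum(m), ")")
  structure(as.list(pmax(m, 0)), class = "mass_function")
}

#' @export
print.mass_function <- function(x, ...) {
  cat(sprintf("mass function: m(reliable) = %.4f, m(not_reliable) = %.4f, m(either) = %.4f\n",
              x$reliable, x$not_reliable, x$either))
  invisible(x)
}

#' Build a discounted mass function from a reliability score
#'
#' Converts a probability-like score into evidence with an explicit
#' ignorance component: a source of discount `d` commits `d * score` to
#' "reliable", `d * (1 - score)` to "not reliable", and keeps `1 - d` as
#' ignorance. Discount 1 is a fully trusted source; discount 0 yields the
#' vacuous mass.
#'
#' @param score reliability score in `[0, 1]`.
#' @param discount source discount in `[0, 1]` (default 0.9).
#' @return A [mass_function()].
#' @export
build_mass <- function(score, discount = 0.9) {
  check_unit_interval(score, "score")
  check_unit_interval(discount, "discount")
  mass_function(discount * score, discount * (1 - score), 1 - discount)
}

#' Combine two mass functions by Dempster's rule
#'
#' Products of compatible focal elements, renormalised by one minus the
#' conflict `K = m1(R) m2(not R) + m1(not R) m2(R)`. Total conflict
#' (`K = 1`) is an error. The rule is commutative and the vacuous mass
#' (all mass on `either`) is its identity.
#'
#' @param m1,m2 [mass_function()] objects.
#' @return The combined [mass_function()].
#' @export
dst_combine <- function(m1, m2) {
  stopifnot(inherits(m1, "mass_function"), inherits(m2, "mass_function"))
  K <- m1$reliable * m2$not_reliable + m1$not_reliable * m2$reliable
  if (K >= 1 - 1e-12) stop("total conflict between mass functions: cannot combine")
  r <- m1$reliable * m2$reliable + m1$reliable * m2$either + m1$either * m2$reliable
  n <- m1$not_reliable * m2$not_reliable + m1$not_reliable * m2$either +
    m1$either * m2$not_reliable
  e <- m1$either * m2$either
  mass_function(r / (1 - K), n / (1 - K), e / (1 - K))
}

#' Belief and plausibility of "reliable"
#'
#' Belief is the mass committed to "reliable"; plausibility adds the
#' uncommitted mass. The width of the interval is the residual
#' uncertainty.
#'
#' @param m a [mass_function()].
#' @return Named numeric vector `c(belief, plausibility)`.
#' @export
belief_plausibility <- function(m) {
  stopifnot(inherits(m, "mass_function"))
  c(belief = m$reliable, plausibility = m$reliable + m$either)
}

#' Confidence bounds on a set of NOAEL values
#'
#' Interval for the no-observed-adverse-effect level of a target, from the
#' NOAELs of its structural nearest neighbours. Modes:
#' `"normal_sd"` (default) takes the NOAELs as normally distributed and
#' returns `mean +/- z * sd`; `"normal_mean_ci"` returns the confidence
#' interval of the mean, `mean +/- z * sd / sqrt(n)`; `"lognormal_sd"`
#' applies the first form on the log scale and exponentiates. Lower bounds
#' are clipped at 0. A single value carries no spread: the caller should
#' fall back to reporting that NOAEL with no interval.
#'
#' @param values NOAELs in mg/kg-bw/day, length >= 2, all positive.
#' @param level two-sided confidence level (default 0.95).
#' @param mode interval convention, see above.
#' @return Named vector `c(lower, upper)` with attributes `mean`, `sd`,
#'   `n`, `level`, `mode`.
#' @export
noael_bounds <- function(values, level = 0.95,
                         mode = c("normal_sd", "normal_mean_ci", "lognormal_sd")) {
  mode <- match.arg(mode)
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("at least 2 NOAEL values are required; with a single value, ",
         "report the analogue's NOAEL directly with no confidence interval")
  }
  if (anyNA(values) || any(values <= 0)) stop("NOAEL values must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (mode == "lognormal_sd") {
    lv <- log(values)
    lo <- exp(mean(lv) - z * stats::sd(lv))
    hi <- exp(mean(lv) + z * stats::sd(lv))
    m <- exp(mean(lv)); s <- stats::sd(lv)
  } else {
    m <- mean(values); s <- stats::sd(values)
    half <- if (mode == "normal_sd") z * s else z * s / sqrt(length(values))
    lo <- max(0, m - half)
    hi <- m + half
  }
  structure(c(lower = lo, upper = hi), mean = m, sd = s,
            n = length(values), level = level, mode = mode)
}

#' NOAELs of structural nearest neighbours
#'
#' Finds the dataset compounds within a Tanimoto threshold of the target
#' and returns their NOAELs, optionally excluding neighbours that match a
#' structural alert (e.g. removing compounds hitting a reproductive
#' toxicant profile before estimating bounds for a target without that
#' alert).
#'
#' @param target a compound id in `dataset`, or a SMILES string.
#' @param dataset a [compound_library()] whose compounds carry a `noael`
#'   property ([attach_property_table()]), or a data frame with columns
#'   `compound_id`, `smiles`, `noael`.
#' @param method fingerprint method (see [fingerprints()]).
#' @param threshold Tanimoto threshold (default 0.7).
#' @param exclusion_alerts optional [alert_library()]; neighbours matching
#'   any of its alerts are removed.
#' @return Named numeric vector of NOAELs (names = compound ids), possibly
#'   empty with attribute `status = "empty"` and a message.
#' @export
nearest_neighbor_noaels <- function(target, dataset, method = "path",
                                    threshold = 0.7, exclusion_alerts = NULL) {
  if (!inherits(dataset, "compound_library")) {
    df <- as.data.frame(dataset)
    stopifnot(all(c("compound_id", "smiles", "noael") %in% names(df)))
    lib <- compound_library(df$compound_id, df$compound_id, smiles = df$smiles)
    dataset <- attach_property_table(lib, df[, c("compound_id", "noael")],
                                     source = "dataset")
  }
  props <- attr(dataset, "properties")
  noaels <- props[props$property == "noael", , drop = FALSE]
  hits <- similarity_search(target, dataset, method = method, threshold = threshold)
  ids <- setdiff(hits$compound_id, character(0))
  if (!is.null(exclusion_alerts)) {
    excluded <- vapply(ids, function(id) {
      nrow(match_alerts(dataset, exclusion_alerts, id = id)) > 0
    }, logical(1))
    ids <- ids[!excluded]
  }
  ids <- ids[ids %in% noaels$compound_id]
  out <- stats::setNames(noaels$value[match(ids, noaels$compound_id)], ids)
  if (!length(out)) {
    attr(out, "status") <- "empty"
    attr(out, "message") <- paste0("no neighbours with NOAELs at Tanimoto >= ",
                                   threshold)
  }
  out
}
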