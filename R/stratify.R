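#' Cohort fractions from prevalence, sensitivity and negative predictive value
#'
#' Solves the 2x2 diagnostic table for the cohort proportions of true
#' positives, false positives, true negatives and false negatives given the
#' occult-metastasis prevalence and the test's sensitivity and NPV:
#' `tp = p*se`, `fn = p*(1-se)`, `tn = npv*fn/(1-npv)` (or `1-p` when
#' `npv = 1`), `fp = 1 - tp - fn - tn`.
#'
#' Not every (prevalence, sensitivity, NPV) triple is jointly feasible: the
#' implied `tn` may exceed the disease-negative fraction `1-p`, in which case
#' the strict mode raises an error. With `clamp = TRUE` (used when the triple
#' comes from random probabilistic-sensitivity draws) `tn` is capped at
#' `1-p`, which sets `fp = 0` and corresponds to capping the NPV at its
#' feasible maximum; the clamping is flagged on the result.
#'
#' @param prevalence occult-metastasis prevalence, in (0,1]
#' @param sensitivity test sensitivity, in (0,1]
#' @param npv negative predictive value, in (0,1]
#' @param clamp cap infeasible `tn` at `1-p` instead of raising
#' @return named list `tp`, `fp`, `tn`, `fn` (summing to 1) with attribute
#'   `clamped` (logical)
#' @examples
#' stratify_from_sens_npv(0.23, 0.81, 0.93)
#' @export
stratify_from_sens_npv <- function(prevalence, sensitivity, npv, clamp = FALSE) {
  stopifnot(prevalence > 0, prevalence <= 1,
            sensitivity > 0, sensitivity <= 1,
            npv > 0, npv <= 1)
  tp <- prevalence * sensitivity
  fn <- prevalence * (1 - sensitivity)
  tn <- if (npv < 1) npv * fn / (1 - npv) else 1 - prevalence
  clamped <- FALSE
  if (tn > 1 - prevalence + 1e-12) {
    if (!clamp)
      stop("infeasible diagnostic inputs: implied true-negative fraction ",
           signif(tn, 6), " exceeds the disease-negative fraction ",
           signif(1 - prevalence, 6),
           " (prevalence, sensitivity and NPV are mutually inconsistent)",
           call. = FALSE)
    tn <- 1 - prevalence
    clamped <- TRUE
  }
  fp <- 1 - tp - fn - tn
  if (fp < -1e-12)
    stop("infeasible diagnostic inputs: negative false-positive fraction",
         call. = FALSE)
  fp <- max(fp, 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn), clamped = clamped)
}

#' Specificity implied by prevalence, sensitivity and NPV
#'
#' `tn / (1 - p)` from the stratification above. Used by the
#' occult-metastasis threshold analysis, which holds sensitivity and this
#' implied specificity constant while the prevalence is swept (NPV is
#' prevalence-dependent and cannot be held fixed across a wide sweep).
#'
#' @inheritParams stratify_from_sens_npv
#' @return specificity in [0,1]
#' @export
implied_specificity <- function(prevalence, sensitivity, npv) {
  f <- stratify_from_sens_npv(prevalence, sensitivity, npv)
  f$tn / (1 - prevalence)
}

#' NPV implied by prevalence, sensitivity and specificity
#' @inheritParams stratify_from_sens_npv
#' @param specificity test specificity, in [0,1]
#' @return negative predictive value in (0,1]
#' @export
npv_from_spec <- function(prevalence, sensitivity, specificity) {
  tn <- (1 - prevalence) * specificity
  fn <- prevalence * (1 - sensitivity)
  if (tn + fn == 0) return(1)
  tn / (tn + fn)
}

#' Radiotherapy +/- chemotherapy adjuvant bundle cost
#'
#' Modality-weighted radiotherapy package rate plus the expected
#' chemotherapy cost (`adjuvant_chemo_fraction` x weekly cisplatin x number
#' of weekly cycles). Used both for upfront adjuvant therapy of
#' histopathologically node-positive patients and as the non-surgical arm of
#' recurrence treatment.
#'
#' @param params slnb_params object
#' @return cost in INR
#' @export
adjuvant_bundle_cost <- function(params) {
  co <- params$costs
  rt <- sum(co$rt_modality_weights * c(co$rt_2d, co$rt_3dcrt, co$rt_imrt))
  rt + co$adjuvant_chemo_fraction * co$cisplatin_weekly * co$chemo_cycles
}

#' Expected treatment cost charged on entry to the recurrence state
#'
#' A fraction `lrr_salvage_fraction` of recurrences is managed with salvage
#' surgery, the remainder with the radiotherapy +/- chemotherapy bundle.
#'
#' @param params slnb_params object
#' @return cost in INR
#' @export
lrr_entry_cost <- function(params) {
  f <- params$costs$lrr_salvage_fraction
  f * params$costs$salvage_surgery + (1 - f) * adjuvant_bundle_cost(params)
}

#' Upfront pathway profiles for a treatment group
#'
#' Expands a strategy into its diagnostic strata with cohort weights and,
#' per stratum, the upfront hospital cost, the neck dissection performed,
#' adjuvant eligibility (final histopathology node-positive only),
#' readmission status, the utility track and the recurrence-risk class
#' (driven by final histopathology, not by the test result).
#'
#' Stratification uses the clamped mode of [stratify_from_sens_npv()]:
#' at the base-case inputs the 2x2 is exactly feasible and clamping is a
#' no-op, but sensitivity analyses that push the NPV or prevalence to an
#' interval bound can make the triple jointly infeasible, in which case the
#' NPV is capped at its feasible maximum (false positives = 0).
#'
#' Group I (SLNB-guided): all strata pay the SLNB package; SLNB-positive
#' (TP/FP) receive MND in the same admission; FN are readmitted within a
#' month for MND (MND package only, no repeat SLNB); TN have no neck
#' dissection and keep the primary-resection utility track with undissected
#' recurrence dynamics. Group II (END alone): everyone receives SND; the
#' occult-metastasis fraction is node-positive. Group III (END + frozen
#' section): everyone pays the frozen-section rate; FS-positive (TP/FP)
#' receive MND, FS-negative (TN/FN) receive SND; by default FN keep their
#' SND and receive adjuvant therapy only (toggle
#' `costs$group3_fn_readmission_mnd` converts them to an MND readmission).
#'
#' @param group `"I"`, `"II"` or `"III"`
#' @param params slnb_params object
#' @return data.frame with one row per stratum: `group`, `stratum`,
#'   `weight`, `upfront_cost`, `neck_dissection`, `receives_adjuvant`,
#'   `readmission`, `utility_track`, `risk_class`, `dissected`
#' @export
pathway_profiles <- function(group, params) {
  group <- as.character(group)
  if (!group %in% c("I", "II", "III"))
    stop("unknown treatment group: '", group, "' (expected I, II or III)",
         call. = FALSE)
  co <- params$costs
  p <- params$config$occult_metastasis_rate
  adj <- adjuvant_bundle_cost(params)

  row <- function(stratum, weight, cost, nd, adjuvant, readm, track, risk, diss)
    data.frame(group = group, stratum = stratum, weight = weight,
               upfront_cost = cost + if (adjuvant) adj else 0,
               neck_dissection = nd, receives_adjuvant = adjuvant,
               readmission = readm, utility_track = track, risk_class = risk,
               dissected = diss, stringsAsFactors = FALSE)

  out <- switch(group,
    "I" = {
      a <- params$accuracy$slnb
      f <- stratify_from_sens_npv(p, a$sensitivity, a$npv, clamp = TRUE)
      rbind(
        row("TP", f$tp, co$slnb + co$mnd, "MND", TRUE,  FALSE, "mnd", "node_pos", TRUE),
        row("FP", f$fp, co$slnb + co$mnd, "MND", FALSE, FALSE, "mnd", "node_neg", TRUE),
        row("TN", f$tn, co$slnb,          "none", FALSE, FALSE,
            "primary_resection_only", "node_neg", FALSE),
        row("FN", f$fn, co$slnb + co$mnd, "MND", TRUE,  TRUE,  "mnd", "node_pos", TRUE)
      )
    },
    "II" = rbind(
      row("node_pos", p,     co$snd, "SND", TRUE,  FALSE, "snd", "node_pos", TRUE),
      row("node_neg", 1 - p, co$snd, "SND", FALSE, FALSE, "snd", "node_neg", TRUE)
    ),
    "III" = {
      a <- params$accuracy$endfs
      f <- stratify_from_sens_npv(p, a$sensitivity, a$npv, clamp = TRUE)
      fn_mnd <- isTRUE(co$group3_fn_readmission_mnd)
      rbind(
        row("TP", f$tp, co$frozen_section + co$mnd, "MND", TRUE,  FALSE, "mnd", "node_pos", TRUE),
        row("FP", f$fp, co$frozen_section + co$mnd, "MND", FALSE, FALSE, "mnd", "node_neg", TRUE),
        row("TN", f$tn, co$frozen_section + co$snd, "SND", FALSE, FALSE, "snd", "node_neg", TRUE),
        row("FN", f$fn,
            co$frozen_section + co$snd + if (fn_mnd) co$mnd else 0,
            if (fn_mnd) "MND" else "SND", TRUE, fn_mnd,
            if (fn_mnd) "mnd" else "snd", "node_pos", TRUE)
      )
    }
  )
  rownames(out) <- NULL
  out
}
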