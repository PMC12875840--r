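#' Fit a sampling distribution to a base estimate and 95% interval
#'
#' Method-of-moments fit with `sd = (high - low) / 3.92` (normal-theory 95%
#' interval). Families: `beta` (alpha/beta from mean and sd), `gamma`
#' (shape/scale), `normal`, `fixed` (degenerate point mass). Dirichlet rows
#' are fitted jointly at the block level by [sample_parameter_set()], not
#' here.
#'
#' @param family one of `"beta"`, `"gamma"`, `"normal"`, `"fixed"`
#' @param mean base estimate
#' @param low,high 95% interval bounds (ignored for `fixed`)
#' @return function of `n` returning `n` draws; carries the fitted
#'   parameters as attribute `fit`
#' @examples
#' s <- fit_distribution("beta", 0.23, 0.2, 0.3)
#' attr(s, "fit")  # alpha ~ 62.4
#' @export
fit_distribution <- function(family, mean, low = NA, high = NA) {
  if (family == "fixed") {
    f <- function(n) rep(mean, n)
    attr(f, "fit") <- list(family = "fixed", value = mean)
    return(f)
  }
  sdv <- (high - low) / 3.92
  if (is.na(sdv) || sdv <= 0)
    stop("non-positive sd implied by bounds (", low, ", ", high, ")",
         call. = FALSE)
  f <- switch(family,
    beta = {
      if (mean <= 0 || mean >= 1)
        stop("beta mean must lie in (0,1), got ", mean, call. = FALSE)
      k <- mean * (1 - mean) / sdv^2 - 1
      if (k <= 0)
        stop("beta variance too large for mean ", mean, call. = FALSE)
      a <- mean * k; b <- (1 - mean) * k
      g <- function(n) stats::rbeta(n, a, b)
      attr(g, "fit") <- list(family = "beta", alpha = a, beta = b, sd = sdv)
      g
    },
    gamma = {
      if (mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
      shape <- mean^2 / sdv^2; scale <- sdv^2 / mean
      g <- function(n) stats::rgamma(n, shape = shape, scale = scale)
      attr(g, "fit") <- list(family = "gamma", shape = shape, scale = scale,
                             sd = sdv)
      g
    },
    normal = {
      g <- function(n) stats::rnorm(n, mean, sdv)
      attr(g, "fit") <- list(family = "normal", mean = mean, sd = sdv)
      g
    },
    stop("unknown distribution family: ", family, call. = FALSE))
  f
}

#' Jointly sample a Dirichlet transition block
#'
#' Components of a block share a source health state and together with the
#' implicit "stay" remainder form a probability simplex. The common
#' concentration is chosen so that the marginal standard deviations match
#' the CI-implied standard deviations on average:
#' `alpha0 = mean_i[p_i (1-p_i) / sd_i^2] - 1`, `alpha_i = p_i alpha0`.
#'
#' @param means component means (exit probabilities; sum < 1)
#' @param sds CI-implied standard deviations per component
#' @return one draw of the named exit components (stay remainder dropped)
#' @keywords internal
sample_dirichlet_block <- function(means, sds) {
  stay <- 1 - sum(means)
  stopifnot(stay >= 0)
  a0 <- mean(means * (1 - means) / sds^2) - 1
  a0 <- max(a0, 1)
  alpha <- c(means, stay) * a0
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  draw <- g / sum(g)
  draw[seq_along(means)]
}

#' Draw one random parameter set for probabilistic sensitivity analysis
#'
#' Every parameter with a non-fixed distribution is drawn independently
#' (Dirichlet blocks jointly). Draws are post-processed so that all
#' parameter-set invariants still hold: probabilities are clipped to [0,1],
#' with-morbidity utilities are capped at their without-morbidity
#' counterparts, and jointly infeasible diagnostic draws are resolved by
#' capping the NPV at its feasible maximum (see
#' [stratify_from_sens_npv()]). The number of adjusted draws is recorded in
#' attribute `n_clipped`.
#'
#' @param params slnb_params object (base means and bounds)
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first so the draw is reproducible. When `NULL` the current RNG stream
#'   is used (as in [run_psa()] loops).
#' @return slnb_params object with sampled values, attribute `n_clipped`
#' @export
sample_parameter_set <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dd <- params$distributions
  out <- params
  n_clipped <- 0L

  plain <- dd[!dd$family %in% c("fixed", "dirichlet"), , drop = FALSE]
  for (i in seq_len(nrow(plain))) {
    s <- fit_distribution(plain$family[i], plain$mean[i], plain$low[i],
                          plain$high[i])
    val <- s(1)
    if (plain$family[i] == "beta" || grepl("fraction|rate|npv|sensitivity",
                                           plain$param[i])) {
      if (val < 0 || val > 1) { val <- min(max(val, 0), 1); n_clipped <- n_clipped + 1L }
    }
    if (val < 0 && grepl("^costs\\.", plain$param[i])) {
      val <- 0; n_clipped <- n_clipped + 1L
    }
    out <- set_param(out, plain$param[i], val)
  }

  diri <- dd[dd$family == "dirichlet", , drop = FALSE]
  for (b in unique(diri$block)) {
    rows <- diri[diri$block == b, , drop = FALSE]
    sds <- (rows$high - rows$low) / 3.92
    draw <- sample_dirichlet_block(rows$mean, sds)
    for (i in seq_len(nrow(rows))) out <- set_param(out, rows$param[i], draw[i])
  }

  # utility ordering invariant: with-morbidity <= without-morbidity
  u <- out$utilities
  for (proc in c("snd", "mnd")) {
    wfield <- paste0(proc, "_with_morbidity")
    wofield <- paste0(proc, "_without_morbidity")
    if (u[[wfield]] > u[[wofield]]) {
      out$utilities[[wfield]] <- u[[wofield]]
      n_clipped <- n_clipped + 1L
    }
  }

  # joint feasibility of (prevalence, sensitivity, NPV) per diagnostic test
  p <- out$config$occult_metastasis_rate
  for (test in c("slnb", "endfs")) {
    a <- out$accuracy[[test]]
    f <- stratify_from_sens_npv(p, a$sensitivity, a$npv, clamp = TRUE)
    if (isTRUE(attr(f, "clamped"))) {
      out$accuracy[[test]]$npv <- npv_from_spec(p, a$sensitivity, 1)
      n_clipped <- n_clipped + 1L
    }
  }

  attr(out, "n_clipped") <- n_clipped
  out
}

#' Probabilistic sensitivity analysis (Monte Carlo over the parameter space)
#'
#' Runs `n_iterations` model evaluations, each on an independent parameter
#' draw, and records the incremental cost and incremental QALYs of each
#' requested comparison (comparator minus reference).
#'
#' @param params slnb_params object
#' @param comparisons list of 2-vectors `c(comparator, reference)`, e.g.
#'   `list(c("I","II"))`; default compares I vs II, I vs III, II vs III
#' @param n_iterations number of Monte Carlo iterations (>= 1)
#' @param seed integer seed for reproducibility
#' @param horizon_years optional horizon override
#' @return data.frame of CE-plane points: `iteration`, `comparison`,
#'   `delta_cost`, `delta_qaly`; attribute `n_clipped` totals the clipped
#'   draws
#' @export
run_psa <- function(params, comparisons = list(c("I", "II"), c("I", "III"),
                                               c("II", "III")),
                    n_iterations = params$config$psa_iterations,
                    seed = params$config$rng_seed, horizon_years = NULL) {
  stopifnot(n_iterations >= 1)
  set.seed(seed)
  groups <- unique(unlist(comparisons))
  labels <- vapply(comparisons, function(cp) paste(cp[1], "vs", cp[2]),
                   character(1))
  out <- vector("list", n_iterations)
  n_clipped <- 0L
  for (it in seq_len(n_iterations)) {
    ps <- tryCatch(sample_parameter_set(params),
                   error = function(e)
                     stop("PSA draw ", it, " failed: ", conditionMessage(e),
                          call. = FALSE))
    n_clipped <- n_clipped + attr(ps, "n_clipped")
    res <- lapply(stats::setNames(groups, groups), run_group, params = ps,
                  horizon_years = horizon_years)
    out[[it]] <- data.frame(
      iteration = it, comparison = labels,
      delta_cost = vapply(comparisons, function(cp)
        res[[cp[1]]]$total_cost - res[[cp[2]]]$total_cost, numeric(1)),
      delta_qaly = vapply(comparisons, function(cp)
        res[[cp[1]]]$total_qaly - res[[cp[2]]]$total_qaly, numeric(1)),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "n_clipped") <- n_clipped
  res
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of CE-plane points with positive incremental net monetary
#' benefit (`wtp * dQ - dC > 0`) -- robust to draws with negative
#' incremental QALYs, unlike the ICUR-quadrant rule.
#'
#' @param points CE-plane data.frame from [run_psa()] (a single comparison)
#' @param wtp_grid vector of willingness-to-pay values (non-empty)
#' @return data.frame `wtp`, `probability_cost_effective`
#' @export
ceac <- function(points, wtp_grid) {
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid", call. = FALSE)
  if (nrow(points) == 0) stop("no CE points supplied", call. = FALSE)
  prob <- vapply(wtp_grid, function(w)
    mean(w * points$delta_qaly - points$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter with interval bounds is set to its lower and upper bound
#' in turn (all other parameters at base) and the ICUR of the requested
#' comparison recomputed, re-stratifying the diagnostic cohort where
#' accuracy or prevalence parameters are varied. Entries are sorted by
#' spread (|high - low| ICUR) descending. The raw cost/QALY ratio is
#' reported even when an extreme makes the comparison dominant/dominated,
#' so tornado bars remain numeric.
#'
#' @param params slnb_params object
#' @param comparison 2-vector `c(comparator, reference)`, default I vs II
#' @param horizon_years optional horizon override
#' @return data.frame `parameter`, `low_value`, `high_value`, `low_icur`,
#'   `high_icur`, `spread`, sorted by spread descending
#' @export
one_way_dsa <- function(params, comparison = c("I", "II"),
                        horizon_years = NULL) {
  dd <- params$distributions
  dd <- dd[!is.na(dd$low) & !is.na(dd$high) & dd$family != "fixed", ,
           drop = FALSE]
  raw_icur <- function(ps) {
    a <- run_group(comparison[1], ps, horizon_years)
    b <- run_group(comparison[2], ps, horizon_years)
    (a$total_cost - b$total_cost) / (a$total_qaly - b$total_qaly)
  }
  rows <- lapply(seq_len(nrow(dd)), function(i) {
    lo <- raw_icur(set_param(params, dd$param[i], dd$low[i]))
    hi <- raw_icur(set_param(params, dd$param[i], dd$high[i]))
    data.frame(parameter = dd$param[i], low_value = dd$low[i],
               high_value = dd$high[i], low_icur = lo, high_icur = hi,
               spread = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

#' Threshold analysis on a swept parameter
#'
#' Re-runs the deterministic model over a grid of values of one parameter
#' and reports the largest grid value at which the comparison remains
#' cost-effective at the given willingness-to-pay (positive INMB,
#' equivalent to ICUR <= WTP when incremental QALYs are positive).
#'
#' When the swept parameter is the occult-metastasis rate
#' (`"config.occult_metastasis_rate"`), the cohort is re-stratified at each
#' grid value holding each test's sensitivity and base-implied specificity
#' fixed; the NPV is recomputed from the swept prevalence, since a fixed
#' NPV is infeasible once the prevalence grows beyond the base region.
#'
#' @param params slnb_params object
#' @param parameter_name dotted parameter name to sweep
#' @param grid ascending vector of values within the parameter's valid range
#' @param comparison 2-vector `c(comparator, reference)`; the default
#'   compares SLNB against END alone, its predecessor in the base-case
#'   dominance ladder
#' @param wtp willingness-to-pay (INR/QALY)
#' @param horizon_years optional horizon override
#' @return list: `breakpoint` (largest cost-effective grid value, or `NA`
#'   with message `"none on grid"`), `resolution` (grid step), `grid`
#'   (data.frame `value`, `delta_cost`, `delta_qaly`, `icur`, `inmb`,
#'   `cost_effective`)
#' @export
threshold_sweep <- function(params, parameter_name = "config.occult_metastasis_rate",
                            grid = seq(0.05, 0.95, by = 0.01),
                            comparison = c("I", "II"),
                            wtp = params$config$wtp_threshold,
                            horizon_years = NULL) {
  stopifnot(length(grid) >= 1, !is.unsorted(grid))
  sweep_occult <- identical(parameter_name, "config.occult_metastasis_rate")
  if (sweep_occult) {
    sp <- lapply(params$accuracy, function(a) {
      p0 <- params$config$occult_metastasis_rate
      implied_specificity(p0, a$sensitivity, a$npv)
    })
  }
  rows <- lapply(grid, function(v) {
    ps <- set_param(params, parameter_name, v)
    if (sweep_occult) {
      for (test in names(ps$accuracy)) {
        se <- ps$accuracy[[test]]$sensitivity
        ps$accuracy[[test]]$npv <- npv_from_spec(v, se, sp[[test]])
      }
    }
    a <- run_group(comparison[1], ps, horizon_years)
    b <- run_group(comparison[2], ps, horizon_years)
    dc <- a$total_cost - b$total_cost
    dq <- a$total_qaly - b$total_qaly
    data.frame(value = v, delta_cost = dc, delta_qaly = dq,
               icur = if (dq != 0) dc / dq else NA_real_,
               inmb = inmb(dc, dq, wtp),
               cost_effective = inmb(dc, dq, wtp) >= 0)
  })
  g <- do.call(rbind, rows)
  ce <- g$value[g$cost_effective]
  list(
    breakpoint = if (length(ce)) max(ce) else NA_real_,
    message = if (length(ce)) NULL else "none on grid",
    resolution = if (length(grid) > 1) stats::median(diff(grid)) else NA_real_,
    grid = g)
}
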