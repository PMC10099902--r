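#' Factor grouping of the model parameters
#'
#' Partition of all anatomical and metabolic parameters into the nine
#' factor groups used by the substitution analysis: F1 leaf-scale
#' structure, F2 mesophyll-cell size and shape, F3 porosity, F4
#' bundle-sheath properties, F5 mesophyll plastid fraction, F6 wall
#' thickness, F7 exposed mesophyll surface, F8 chlorophyll content, F9
#' the metabolic parameter block.
#'
#' @return Named list mapping `F1`...`F9` to parameter-field names;
#'   `"kinetics"` denotes the whole [kinetic_params] block.
#' @export
factor_grouping <- function() {
  list(F1 = c("mesophyll_thickness_vein", "mesophyll_thickness_bulliform",
              "interveinal_distance", "epidermis_thickness",
              "bulliform_width"),
       F2 = c("mc_length", "mc_width", "mc_depth", "lobe_number",
              "lobe_amplitude"),
       F3 = "porosity",
       F4 = c("bs_cell_area", "bs_thickness", "bs_plastid_fraction"),
       F5 = "mc_plastid_fraction",
       F6 = "wall_thickness",
       F7 = "smes_fraction",
       F8 = "chlorophyll_per_area",
       F9 = "kinetics")
}

## check that a grouping partitions the full parameter set exactly once
validate_grouping <- function(grouping) {
  fields <- unlist(grouping, use.names = FALSE)
  expected <- c(names(anatomy_params()), "kinetics")
  if (anyDuplicated(fields)) {
    stop_eleaf("experiments", "grouping assigns a field twice: ",
               paste(fields[duplicated(fields)], collapse = ", "))
  }
  missing <- setdiff(expected, fields)
  extra <- setdiff(fields, expected)
  if (length(missing) || length(extra)) {
    stop_eleaf("experiments", "grouping is not a partition; missing: ",
               paste(missing, collapse = ", "), "; unknown: ",
               paste(extra, collapse = ", "))
  }
  invisible(grouping)
}

#' Substitute factor groups between two parameterisations
#'
#' Builds the intermediate model in which the named groups take their
#' values from the alternative (e.g. elevated-CO2) parameter set while all
#' other groups keep the base values.
#'
#' @param base_anatomy,alt_anatomy [anatomy_params] of the base and
#'   alternative condition.
#' @param base_kinetics,alt_kinetics Matching [kinetic_params].
#' @param groups Character vector of group ids (`"F1"`...`"F9"`).
#' @param grouping A grouping as from [factor_grouping()].
#' @return List with elements `anatomy` and `kinetics`.
#' @export
substitute_groups <- function(base_anatomy, alt_anatomy, base_kinetics,
                              alt_kinetics, groups,
                              grouping = factor_grouping()) {
  validate_grouping(grouping)
  bad <- setdiff(groups, names(grouping))
  if (length(bad)) {
    stop_eleaf("experiments", "unknown group id: ", paste(bad, collapse = ", "))
  }
  an <- unclass(base_anatomy)
  kn <- base_kinetics
  for (g in groups) {
    for (f in grouping[[g]]) {
      if (f == "kinetics") kn <- alt_kinetics else an[[f]] <- alt_anatomy[[f]]
    }
  }
  an <- validate_anatomy_params(structure(an, class = "anatomy_params"))
  list(anatomy = an, kinetics = kn)
}

## shallow copy of a light field at a different incident PPFD (the
## absorbed fraction field is exactly linear in the incident flux)
with_ppfd <- function(field, q) {
  d <- field$dims; h <- field$voxel_size
  field$absorbed <- field$absorbed_frac * q * d[1] * d[2] / h * 1e6
  field$incident_ppfd <- q
  field
}

## run one parameterisation over replicates x conditions; the sparse
## factorisation and the traced light field are reused within a replicate
run_condition_grid <- function(aparams, kp, conditions, n_replicates, seed,
                               voxel_size = 2, n_rays = 20000,
                               optics = optical_props(),
                               tp = transport_params(),
                               solver_cfg = list(), strict = FALSE,
                               hold_smes = TRUE) {
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    gseed <- seed + r - 1L
    vol <- pack_mesophyll(aparams, gseed, voxel_size, strict = strict,
                          hold_smes = hold_smes)
    f1 <- trace_light(vol, optics, light_source(incident_ppfd = 1),
                      n_rays = n_rays, seed = seed + 1000L + r)
    sys <- solver_cfg$system; fac <- solver_cfg$factor
    rows <- vector("list", nrow(conditions))
    for (k in seq_len(nrow(conditions))) {
      ci <- conditions$ci[k]; q <- conditions$q[k]
      tpk <- tp; tpk$ci_boundary <- ci
      cfg <- solver_cfg
      cfg$system <- sys; cfg$factor <- fac
      st <- tryCatch(solve_coupled(vol, tpk, with_ppfd(f1, q), kp, cfg),
                     error = function(e) e)
      if (inherits(st, "error")) {
        rows[[k]] <- data.frame(ci = ci, q = q, replicate = r,
                                a_n = NA_real_, phi_psii = NA_real_,
                                error = conditionMessage(st))
      } else {
        if (is.null(sys)) { sys <- st$system; fac <- st$factor }
        rows[[k]] <- data.frame(ci = ci, q = q, replicate = r,
                                a_n = st$a_net_leaf,
                                phi_psii = st$phi_psii_leaf,
                                error = NA_character_)
      }
    }
    out[[r]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Light x CO2 response surface with replicate ensemble
#'
#' One steady-state solve per (C_i, Q) grid point and replicate geometry;
#' solver failures at single grid points are recorded in the `error`
#' column rather than aborting the surface.
#'
#' @param aparams An [anatomy_params] object.
#' @param kparams A [kinetic_params] object.
#' @param ci_grid,q_grid Grid values (ubar; umol m-2 s-1).
#' @param n_replicates Replicate geometries (default 5).
#' @param seed Base seed.
#' @param ... Passed to the model runner (`voxel_size`, `n_rays`,
#'   `optics`, `tp`, `solver_cfg`).
#' @return A `response_surface` data frame (long format: ci, q, replicate,
#'   a_n, phi_psii, error) with a `summary` attribute holding per-point
#'   mean and SD.
#' @export
response_surface <- function(aparams, kparams, ci_grid, q_grid,
                             n_replicates = 5L, seed = 1L, ...) {
  if (!length(ci_grid) || !length(q_grid)) {
    stop_eleaf("experiments", "grids must be non-empty")
  }
  if (n_replicates < 1L) stop_eleaf("experiments", "n_replicates must be >= 1")
  conditions <- expand.grid(ci = ci_grid, q = q_grid)
  df <- run_condition_grid(aparams, kparams, conditions, n_replicates, seed,
                           ...)
  agg_m <- stats::aggregate(cbind(a_n, phi_psii) ~ ci + q, df, mean,
                            na.action = stats::na.omit)
  agg_s <- stats::aggregate(cbind(a_n, phi_psii) ~ ci + q, df, sd,
                            na.action = stats::na.omit)
  names(agg_s)[3:4] <- c("a_n_sd", "phi_psii_sd")
  attr(df, "summary") <- merge(agg_m, agg_s, by = c("ci", "q"))
  class(df) <- c("response_surface", "data.frame")
  df
}

#' Contribution of one factor group to the assimilation change
#'
#' Runs the base model and the model with the named group substituted from
#' the alternative condition, with matched geometry and tracer seeds, and
#' reports the assimilation change per condition.
#'
#' @param base_anatomy,alt_anatomy,base_kinetics,alt_kinetics The two
#'   parameterisations.
#' @param group Group id (`"F1"`...`"F9"`), or `"all"` for the full
#'   alternative model.
#' @param conditions Data frame with columns `ci` and `q`.
#' @param n_replicates Replicates (matched seeds in both runs).
#' @param seed Base seed.
#' @param grouping A grouping as from [factor_grouping()].
#' @param base_df Optional precomputed base run (the output of
#'   `run_condition_grid` for the base parameterisation with identical
#'   seeds), to avoid re-running the control.
#' @param ... Passed to the model runner.
#' @return A `factor_substitution` data frame: per condition and replicate
#'   `a_base`, `a_subst`, `delta_a`, with the group id attached.
#' @export
factor_substitution <- function(base_anatomy, alt_anatomy, base_kinetics,
                                alt_kinetics, group, conditions,
                                n_replicates = 5L, seed = 1L,
                                grouping = factor_grouping(),
                                base_df = NULL, ...) {
  validate_grouping(grouping)
  groups <- if (identical(group, "all")) names(grouping) else group
  sub <- substitute_groups(base_anatomy, alt_anatomy, base_kinetics,
                           alt_kinetics, groups, grouping)
  if (is.null(base_df)) {
    base_df <- run_condition_grid(base_anatomy, base_kinetics, conditions,
                                  n_replicates, seed, ...)
  }
  sub_df <- run_condition_grid(sub$anatomy, sub$kinetics, conditions,
                               n_replicates, seed, ...)
  out <- data.frame(group = paste(groups, collapse = "+"),
                    ci = base_df$ci, q = base_df$q,
                    replicate = base_df$replicate,
                    a_base = base_df$a_n, a_subst = sub_df$a_n,
                    delta_a = sub_df$a_n - base_df$a_n)
  class(out) <- c("factor_substitution", "data.frame")
  out
}

#' One-way ANOVA significance between two replicate ensembles
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F test) comparing a
#' control and a treatment ensemble of replicate model outputs; the flag
#' marks P < 0.05.  Two ensembles with zero variance and equal means are
#' reported as not significant.
#'
#' @param control,treatment Numeric vectors (>= 2 replicates each).
#' @return List with `statistic` (F), `p_value` and `significant`.
#' @export
anova_significance <- function(control, treatment) {
  control <- control[is.finite(control)]
  treatment <- treatment[is.finite(treatment)]
  if (length(control) < 2L || length(treatment) < 2L) {
    stop_eleaf("experiments", "need >= 2 replicates per arm")
  }
  if (var(control) == 0 && var(treatment) == 0) {
    same <- isTRUE(all.equal(mean(control), mean(treatment)))
    return(list(statistic = if (same) 0 else Inf,
                p_value = if (same) 1 else 0,
                significant = !same))
  }
  ht <- stats::oneway.test(y ~ g,
                           data = data.frame(y = c(control, treatment),
                                             g = rep(c("c", "t"),
                                                     c(length(control),
                                                       length(treatment)))),
                           var.equal = TRUE)
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       significant = is.finite(ht$p.value) && ht$p.value < 0.05)
}

#' Anatomy parameter sweep with significance testing
#'
#' Re-packs the leaf for a range of values of one anatomical parameter
#' (porosity, S_mes fraction or lobe number), keeping the other targets as
#' constant as the packing constraints allow, and reports the assimilation
#' change against the unmodified control per condition, with a one-way
#' ANOVA flag across replicates.  Values for which the packing targets are
#' infeasible are reported as such, not dropped.
#'
#' For lobe-number sweeps, a `marked` flag records a drop of more than
#' 10 % in mean assimilation relative to the largest lobe number at that
#' condition.
#'
#' @param base_params An [anatomy_params] control parameterisation.
#' @param kp A [kinetic_params] object.
#' @param field One of `"porosity"`, `"smes_fraction"`, `"lobe_number"`.
#' @param values Values to impose.
#' @param conditions Data frame with columns `ci`, `q`.
#' @param n_replicates Replicates per value (matched seeds).
#' @param seed Base seed.
#' @param ... Passed to the model runner.
#' @return A `sweep_result` data frame: per (value, condition) the mean
#'   `delta_a`, its replicate SD, the ANOVA `p_value` and `significant`
#'   flag, and `feasible`.
#' @export
sweep_anatomy <- function(base_params, kp, field, values, conditions,
                          n_replicates = 5L, seed = 1L, ...) {
  field <- match.arg(field, c("porosity", "smes_fraction", "lobe_number"))
  if (!length(values)) stop_eleaf("experiments", "`values` is empty")
  ## for lobe sweeps the exposed-surface change is the mechanism under
  ## study, so S_mes floats (control included, for comparability)
  hold_smes <- field != "lobe_number"
  base_df <- run_condition_grid(base_params, kp, conditions, n_replicates,
                                seed, hold_smes = hold_smes, ...)
  rows <- list()
  any_feasible <- FALSE
  for (v in values) {
    p <- unclass(base_params)
    p[[field]] <- if (field == "lobe_number") as.integer(v) else v
    p <- structure(p, class = "anatomy_params")
    df <- tryCatch({
      validate_anatomy_params(p)
      run_condition_grid(p, kp, conditions, n_replicates, seed,
                         hold_smes = hold_smes, ...)
    }, error = function(e) conditionMessage(e))
    if (is.character(df)) {
      rows[[length(rows) + 1L]] <-
        data.frame(field = field, value = v, ci = conditions$ci,
                   q = conditions$q, delta_a = NA_real_, sd = NA_real_,
                   p_value = NA_real_, significant = NA, feasible = FALSE,
                   reason = df)
      next
    }
    any_feasible <- TRUE
    for (k in seq_len(nrow(conditions))) {
      ci <- conditions$ci[k]; q <- conditions$q[k]
      a0 <- base_df$a_n[base_df$ci == ci & base_df$q == q]
      a1 <- df$a_n[df$ci == ci & df$q == q]
      same_value <- isTRUE(all.equal(v, base_params[[field]]))
      if (same_value) {
        ## identical parameters + matched seeds: exact control
        delta <- 0; sdv <- 0; pv <- 1; sig <- FALSE
      } else if (n_replicates >= 2L && sum(is.finite(a0)) >= 2L &&
                 sum(is.finite(a1)) >= 2L) {
        tst <- anova_significance(a0, a1)
        delta <- mean(a1, na.rm = TRUE) - mean(a0, na.rm = TRUE)
        sdv <- sd(a1 - a0, na.rm = TRUE)
        pv <- tst$p_value; sig <- tst$significant
      } else {
        delta <- mean(a1, na.rm = TRUE) - mean(a0, na.rm = TRUE)
        sdv <- NA_real_; pv <- NA_real_; sig <- NA
      }
      rows[[length(rows) + 1L]] <-
        data.frame(field = field, value = v, ci = ci, q = q,
                   delta_a = delta, sd = sdv, p_value = pv,
                   significant = sig, feasible = TRUE, reason = NA_character_)
    }
  }
  if (!any_feasible) {
    stop_eleaf("experiments", "all sweep values infeasible for packing")
  }
  out <- do.call(rbind, rows)
  if (field == "lobe_number") {
    ref_v <- max(values[vapply(values, function(v) {
      any(out$feasible[out$value == v])
    }, logical(1))])
    out$marked <- FALSE
    for (k in seq_len(nrow(out))) {
      if (!isTRUE(out$feasible[k])) next
      ref_rows <- out$value == ref_v & out$ci == out$ci[k] & out$q == out$q[k]
      base_a <- mean(base_df$a_n[base_df$ci == out$ci[k] &
                                   base_df$q == out$q[k]], na.rm = TRUE)
      a_ref <- base_a + out$delta_a[ref_rows][1]
      a_here <- base_a + out$delta_a[k]
      out$marked[k] <- is.finite(a_ref) && is.finite(a_here) &&
        (a_here < a_ref * 0.9)
    }
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}
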