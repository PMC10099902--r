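#' Default gas-exchange measurement protocol
#'
#' The C_i ladder of an A/C_i curve at saturating PPFD (2000 umol m-2 s-1)
#' and the PPFD ladder of an AQ curve at ambient CO2, following the usual
#' combined fluorescence / infrared gas-analysis protocol for rice leaf 5.
#'
#' @param aci_ci C_i set points for the A/C_i curve (ubar).
#' @param aci_ppfd PPFD held during the A/C_i curve (umol m-2 s-1).
#' @param aq_q PPFD set points for the AQ curve (umol m-2 s-1).
#' @param aq_ci C_i held during the AQ curve (ubar).
#' @param temperature Leaf temperature (degC, fixed at 28).
#' @return A `measurement_protocol` list.
#' @export
measurement_protocol <- function(aci_ci = c(400, 300, 250, 200, 150, 100, 50,
                                            400, 500, 700, 800, 900, 1000,
                                            1200, 1500),
                                 aci_ppfd = 2000,
                                 aq_q = c(2000, 1800, 1600, 1500, 1200, 1000,
                                          900, 700, 500, 400, 300, 200, 150,
                                          100, 75, 50, 25),
                                 aq_ci = 280,
                                 temperature = 28) {
  if (any(aci_ci <= 0) || any(aq_q <= 0)) {
    stop_eleaf("fitting", "C_i and Q set points must be strictly positive")
  }
  structure(list(aci_ci = aci_ci, aci_ppfd = aci_ppfd, aq_q = aq_q,
                 aq_ci = aq_ci, temperature = temperature),
            class = "measurement_protocol")
}

## big-leaf surrogate: A and PhiPSII at (ci, q) for one parameter set;
## vectorised over points.  Cc = Ci (the surrogate has no explicit
## mesophyll resistance; the 3D model supplies it when needed).
bigleaf_point <- function(ci, q, kp) {
  n <- max(length(ci), length(q))
  ci <- rep_len(ci, n); q <- rep_len(q, n)
  i_abs <- kp$absorptance * q
  j <- electron_transport(i_abs, kp)
  a <- net_rate(ci, j, kp)
  ## realised electron flux: Rubisco-limited points run below potential J
  kco <- kp$kc * (1 + kp$o2 / kp$ko)
  wc <- kp$vcmax * ci / (ci + kco)
  wj <- j * ci / (4 * ci + 8 * kp$gamma_star)
  w <- pmin(wc, wj)
  j_real <- ifelse(ci > 0, w * (4 * ci + 8 * kp$gamma_star) / ci, 0)
  phi <- clamp(j_real / (kp$s_factor * kp$absorptance * q), 0, 1)
  list(a_n = a, phi_psii = phi)
}

#' Noise-free gas-exchange curves from the big-leaf surrogate
#'
#' Evaluates the same FvCB equations as the metabolism module on a
#' homogeneous leaf (`Cc = Ci`, fixed absorptance), producing the A/C_i
#' and AQ curves with PhiPSII that the genetic-algorithm fit inverts.
#'
#' @param kp A [kinetic_params] object.
#' @param protocol A [measurement_protocol].
#' @return A `gas_exchange_dataset`: data frame with columns `curve`
#'   ("aci"/"aq"), `x` (the varied quantity), `ci`, `q`, `a_n`,
#'   `phi_psii`, with the protocol attached as attribute.
#' @export
forward_curves <- function(kp, protocol = measurement_protocol()) {
  stopifnot(inherits(kp, "kinetic_params"),
            inherits(protocol, "measurement_protocol"))
  aci <- bigleaf_point(protocol$aci_ci, protocol$aci_ppfd, kp)
  aq <- bigleaf_point(protocol$aq_ci, protocol$aq_q, kp)
  ds <- rbind(
    data.frame(curve = "aci", x = protocol$aci_ci, ci = protocol$aci_ci,
               q = protocol$aci_ppfd, a_n = aci$a_n, phi_psii = aci$phi_psii),
    data.frame(curve = "aq", x = protocol$aq_q, ci = protocol$aq_ci,
               q = protocol$aq_q, a_n = aq$a_n, phi_psii = aq$phi_psii))
  attr(ds, "protocol") <- protocol
  class(ds) <- c("gas_exchange_dataset", "data.frame")
  ds
}

#' Synthetic noisy gas-exchange dataset
#'
#' [forward_curves()] plus iid Gaussian measurement noise, emulating
#' combined gas-exchange/fluorescence measurements.
#'
#' @param kp A [kinetic_params] object.
#' @param protocol A [measurement_protocol].
#' @param noise_sd Length-2 vector `c(sd_A, sd_phi)`: noise on A_N
#'   (umol m-2 s-1) and on PhiPSII.
#' @param seed RNG seed.
#' @return A `gas_exchange_dataset`.
#' @export
synth_dataset <- function(kp, protocol = measurement_protocol(),
                          noise_sd = c(0.5, 0.01), seed = 1L) {
  if (length(noise_sd) != 2L || any(noise_sd < 0)) {
    stop_eleaf("fitting", "`noise_sd` must be two non-negative numbers")
  }
  ds <- forward_curves(kp, protocol)
  with_seed(seed, {
    ds$a_n <- ds$a_n + rnorm(nrow(ds), 0, noise_sd[1])
    ds$phi_psii <- clamp(ds$phi_psii + rnorm(nrow(ds), 0, noise_sd[2]), 0, 1)
  })
  ds
}

#' Read / write gas-exchange datasets as CSV
#'
#' @param ds A `gas_exchange_dataset`.
#' @param path File path.
#' @return `read_gas_exchange` returns a `gas_exchange_dataset`.
#' @export
write_gas_exchange <- function(ds, path) {
  utils::write.csv(as.data.frame(ds)[, c("curve", "x", "ci", "q", "a_n",
                                         "phi_psii")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gas_exchange
#' @export
read_gas_exchange <- function(path) {
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve", "x", "ci", "q", "a_n", "phi_psii")
  if (!all(need %in% names(ds))) {
    stop_eleaf("fitting", "gas-exchange CSV must have columns: ",
               paste(need, collapse = ", "))
  }
  class(ds) <- c("gas_exchange_dataset", "data.frame")
  ds
}

#' Genetic-algorithm configuration
#'
#' Elitist generational GA with tournament selection, simulated-binary
#' crossover (SBX) and polynomial mutation, followed by a derivative-free
#' simplex polish.
#'
#' @param population Population size (>= 10).
#' @param generations Number of generations.
#' @param crossover_rate,mutation_rate Per-individual SBX probability and
#'   per-gene polynomial-mutation probability.
#' @param eta_c,eta_m SBX and mutation distribution indices.
#' @param elitism Number of elites copied unchanged each generation.
#' @param tournament_k Tournament size.
#' @param bounds Named list of `c(lo, hi)` per fitted parameter
#'   (`vcmax`, `jmax`, `rd`, `y2ll`, `s_factor`).
#' @param objective_weights `c(w_A, w_phi)`; `NA` for `w_phi` scales the
#'   PhiPSII term by the variance ratio of the data so both terms are
#'   comparable.
#' @param seed RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 100L, generations = 200L,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      eta_c = 15, eta_m = 20, elitism = 2L,
                      tournament_k = 3L,
                      bounds = list(vcmax = c(20, 400),
                                    jmax = c(20, 500),
                                    rd = c(0.05, 8),
                                    y2ll = c(0.4, 0.85),
                                    s_factor = c(0.3, 2)),
                      objective_weights = c(1, NA),
                      seed = 1L) {
  if (population < 10L) stop_eleaf("fitting", "population must be >= 10")
  for (nm in names(bounds)) {
    if (bounds[[nm]][1] >= bounds[[nm]][2]) {
      stop_eleaf("fitting", "bounds for ", nm, " must satisfy lo < hi")
    }
  }
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 eta_c = eta_c, eta_m = eta_m, elitism = as.integer(elitism),
                 tournament_k = as.integer(tournament_k), bounds = bounds,
                 objective_weights = objective_weights,
                 seed = as.integer(seed)),
            class = "ga_config")
}

## objective over a population matrix (rows = individuals, columns =
## vcmax, jmax, rd, y2ll, s_factor); vectorised over the population
fit_objective <- function(pop, ds, base_kp, w_a, w_phi) {
  kco <- base_kp$kc * (1 + base_kp$o2 / base_kp$ko)
  gst <- base_kp$gamma_star
  th <- base_kp$theta
  alpha <- base_kp$absorptance
  sse <- numeric(nrow(pop))
  ci <- ds$ci; q <- ds$q
  for (k in seq_len(nrow(pop))) {
    vc <- pop[k, 1]; jm <- pop[k, 2]; rd <- pop[k, 3]
    y2 <- pop[k, 4]; sf <- pop[k, 5]
    x <- sf * y2 * alpha * q
    bq <- x + jm
    j <- if (th < 1e-10) x * jm / pmax(bq, 1e-300) else
      (bq - sqrt(pmax(0, bq^2 - 4 * th * x * jm))) / (2 * th)
    wc <- vc * ci / (ci + kco)
    wj <- j * ci / (4 * ci + 8 * gst)
    w <- pmin(wc, wj)
    a <- (1 - gst / ci) * w - rd
    j_real <- w * (4 * ci + 8 * gst) / ci
    phi <- clamp(j_real / (sf * alpha * q), 0, 1)
    sse[k] <- w_a * sum((a - ds$a_n)^2) + w_phi * sum((phi - ds$phi_psii)^2)
  }
  sse
}

#' Estimate photosynthetic parameters from gas-exchange curves
#'
#' Joint genetic-algorithm estimation of `vcmax`, `jmax`, `rd`, `y2ll` and
#' `s_factor` from combined A/C_i + AQ curves with PhiPSII, minimising
#' `w_A * SSE(A) + w_phi * SSE(PhiPSII)` over both curves, followed by a
#' Nelder-Mead polish of the best individual.  Deterministic for a given
#' `cfg$seed`.
#'
#' @param ds A `gas_exchange_dataset`.
#' @param cfg A [ga_config].
#' @param base_kp Kinetic constants held fixed during fitting
#'   (`gamma_star`, `kc`, `ko`, `o2`, `theta`, `absorptance`).
#' @return A `fitted_params` list: `estimates` (named vector), `objective`
#'   value, per-generation best-objective `trace`, the polished flag and
#'   any identifiability `warnings`.
#' @export
fit_parameters <- function(ds, cfg = ga_config(),
                           base_kp = kinetic_params()) {
  stopifnot(inherits(ds, "gas_exchange_dataset"), inherits(cfg, "ga_config"))
  if (nrow(ds) < 10L) {
    stop_eleaf("fitting", "need at least 10 curve points to fit")
  }
  warnings <- character()
  aci_ci <- if (any(ds$curve == "aci")) ds$ci[ds$curve == "aci"] else ds$ci
  if (min(aci_ci) > 300) {
    warnings <- c(warnings,
                  paste("dataset lacks C_i points below 300 ubar;",
                        "vcmax and rd are weakly identified"))
  }
  w_a <- cfg$objective_weights[1]
  w_phi <- cfg$objective_weights[2]
  if (is.na(w_phi)) {
    w_phi <- w_a * var(ds$a_n) / max(var(ds$phi_psii), 1e-12)
  }
  bounds <- cfg$bounds
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  npar <- length(lo)

  obj <- function(pop) fit_objective(pop, ds, base_kp, w_a, w_phi)

  res <- with_seed(cfg$seed, {
    np <- cfg$population
    pop <- matrix(runif(np * npar), np, npar)
    pop <- sweep(sweep(pop, 2, hi - lo, `*`), 2, lo, `+`)
    fit <- obj(pop)
    trace <- numeric(cfg$generations)
    for (g in seq_len(cfg$generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(cfg$elitism)], , drop = FALSE]
      ## tournament selection
      pick <- function(n) {
        cand <- matrix(sample.int(np, n * cfg$tournament_k, replace = TRUE),
                       n, cfg$tournament_k)
        idx <- apply(cand, 1, function(r) r[which.min(fit[r])])
        pop[idx, , drop = FALSE]
      }
      n_off <- np - cfg$elitism
      pa <- pick(n_off); pb <- pick(n_off)
      ## SBX crossover
      u <- matrix(runif(n_off * npar), n_off, npar)
      beta <- ifelse(u <= 0.5, (2 * u)^(1 / (cfg$eta_c + 1)),
                     (1 / (2 * (1 - u)))^(1 / (cfg$eta_c + 1)))
      do_cx <- runif(n_off) < cfg$crossover_rate
      beta[!do_cx, ] <- 1
      child <- 0.5 * ((1 + beta) * pa + (1 - beta) * pb)
      ## polynomial mutation
      um <- matrix(runif(n_off * npar), n_off, npar)
      do_mu <- matrix(runif(n_off * npar), n_off, npar) < cfg$mutation_rate
      span <- matrix(hi - lo, n_off, npar, byrow = TRUE)
      delta <- ifelse(um < 0.5,
                      (2 * um)^(1 / (cfg$eta_m + 1)) - 1,
                      1 - (2 * (1 - um))^(1 / (cfg$eta_m + 1)))
      child <- child + do_mu * delta * span
      child <- sweep(child, 2, lo, pmax)
      child <- sweep(child, 2, hi, pmin)
      pop <- rbind(elite, child)
      fit <- obj(pop)
      trace[g] <- min(fit)
    }
    best <- pop[which.min(fit), ]
    ## derivative-free simplex polish inside the bounds
    pen_obj <- function(th) {
      if (any(th < lo) || any(th > hi)) return(1e12)
      obj(matrix(th, 1))
    }
    pol <- optim(best, pen_obj, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-12))
    if (pol$value < min(fit)) {
      list(estimates = pol$par, objective = pol$value, trace = trace)
    } else {
      list(estimates = best, objective = min(fit), trace = trace)
    }
  })
  names(res$estimates) <- names(bounds)
  structure(list(estimates = res$estimates, objective = res$objective,
                 trace = res$trace, warnings = warnings,
                 weights = c(w_a = w_a, w_phi = w_phi), config = cfg),
            class = "fitted_params")
}

#' @export
print.fitted_params <- function(x, ...) {
  cat("<fitted_params> objective", signif(x$objective, 5), "\n")
  print(signif(x$estimates, 5))
  if (length(x$warnings)) cat("warning:", x$warnings, "\n")
  invisible(x)
}
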