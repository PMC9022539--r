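#' Fit a polynomial response curve between primary and secondary levels
#'
#' Least-squares polynomial describing how the abundance of a secondary
#' miRNA responds to the abundance of the primary miRNA driving its
#' biogenesis. Degree 2 is the default: the smallest nonlinearity able to
#' capture a saturating dose response. With exactly `degree + 1` distinct
#' primary levels the fit interpolates the points exactly.
#'
#' @param primary_levels Numeric vector of primary miRNA abundances
#'   (linear scale).
#' @param secondary_levels Numeric vector of matching secondary
#'   abundances.
#' @param degree Polynomial degree (default 2).
#' @return Object of class `cb_response_curve`: `degree`,
#'   `coefficients` (ascending power order, intercept first), and
#'   `r_squared`.
#' @export
fit_response_curve <- function(primary_levels, secondary_levels, degree = 2L) {
  if (length(primary_levels) != length(secondary_levels))
    stop("primary and secondary level series must have equal length")
  if (any(!is.finite(primary_levels)) || any(!is.finite(secondary_levels)))
    stop("levels must be finite")
  n_distinct <- length(unique(primary_levels))
  if (n_distinct < degree + 1)
    stop(sprintf("need at least %d distinct primary levels for a degree-%d fit; got %d",
                 degree + 1, degree, n_distinct))
  fit <- stats::lm(secondary_levels ~ stats::poly(primary_levels, degree, raw = TRUE))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((secondary_levels - mean(secondary_levels))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(degree = as.integer(degree), coefficients = coefs,
                 r_squared = r2),
            class = "cb_response_curve")
}

#' Evaluate a fitted response curve
#'
#' @param object A `cb_response_curve`.
#' @param newdata Numeric vector of primary levels.
#' @param ... Unused.
#' @return Predicted secondary levels.
#' @export
predict.cb_response_curve <- function(object, newdata, ...) {
  powers <- outer(newdata, 0:object$degree, `^`)
  drop(powers %*% object$coefficients)
}

#' Define a layered miRNA regulatory network
#'
#' Layer 0 holds the primary miRNA; each subsequent layer holds miRNAs
#' whose biogenesis is coordinated by the layer above through shared
#' target mRNAs. `coupling[n]` (in \[0, 1\]) is the strength with which
#' layer `n-1` abundance propagates into layer `n`.
#'
#' @param coupling Numeric vector of per-layer coupling coefficients for
#'   layers 1..L.
#' @param mirnas Optional list of miRNA id vectors per layer (length
#'   `length(coupling) + 1`).
#' @param targets Optional list of target mRNA ids per layer.
#' @return Object of class `cb_layer_network`.
#' @export
layer_network <- function(coupling, mirnas = NULL, targets = NULL) {
  coupling <- as.numeric(coupling)
  if (any(coupling < 0 | coupling > 1))
    stop("coupling coefficients must lie in [0, 1]")
  L <- length(coupling)
  if (is.null(mirnas)) mirnas <- as.list(paste0("miRNA_L", 0:L))
  if (is.null(targets)) targets <- as.list(paste0("target_L", 0:L))
  if (length(mirnas) != L + 1 || length(targets) != L + 1)
    stop("mirnas and targets must list one entry per layer (layers 0..L)")
  structure(list(coupling = coupling, mirnas = mirnas, targets = targets,
                 n_layers = L),
            class = "cb_layer_network")
}

#' Dampening model parameters
#'
#' @param w Attenuation base in (0, 1): the per-layer-distance decay of
#'   repressive influence (`w^x` at layer distance `x`).
#' @param beta Non-negative repression strength at distance 0.
#' @param baseline Positive baseline (unrepressed) mRNA level.
#' @return Object of class `cb_dampening_params`.
#' @export
dampening_params <- function(w = 0.5, beta = 1, baseline = 1) {
  if (w <= 0 || w >= 1) stop("attenuation base w must lie strictly inside (0, 1)")
  if (beta < 0) stop("repression strength beta must be non-negative")
  if (baseline <= 0) stop("baseline mRNA level must be positive")
  structure(list(w = w, beta = beta, baseline = baseline),
            class = "cb_dampening_params")
}

#' Propagate a primary miRNA level through network layers
#'
#' Multiplicative coupling: `level(0) = primary_level`,
#' `level(n) = coupling[n] * level(n - 1)`. With all coupling
#' coefficients below 1 the abundance is non-increasing across layers;
#' coupling 1 is the conservation limit.
#'
#' @param network A `cb_layer_network`.
#' @param primary_level Non-negative abundance of the layer-0 miRNA.
#' @return Named numeric vector of levels for layers 0..L.
#' @export
propagate_layers <- function(network, primary_level) {
  stopifnot(inherits(network, "cb_layer_network"))
  if (primary_level < 0) stop("primary_level must be non-negative")
  levels <- cumprod(c(primary_level, network$coupling))
  names(levels) <- paste0("layer", 0:network$n_layers)
  levels
}

#' Predict an mRNA level under cross-layer dampened repression
#'
#' The target mRNA in layer `t` is repressed by every miRNA layer `m <= t`,
#' with influence attenuated exponentially in the layer distance:
#'
#' `level = baseline * exp(-sum_m beta * w^(t - m) * miRNA_level(m))`
#'
#' so the repressive effect of a distant layer shrinks geometrically while
#' a same-layer miRNA acts at full strength. The prediction is strictly
#' positive and equals the baseline when all miRNA levels are zero.
#'
#' @param levels_by_layer Numeric vector of miRNA levels for layers 0..L
#'   (as from [propagate_layers()]).
#' @param target_layer Integer layer index of the target mRNA (0-based).
#' @param params A `cb_dampening_params`.
#' @return Predicted mRNA abundance in (0, baseline].
#' @export
predict_target_level <- function(levels_by_layer, target_layer, params) {
  stopifnot(inherits(params, "cb_dampening_params"))
  L <- length(levels_by_layer) - 1L
  if (target_layer < 0 || target_layer > L)
    stop("target_layer must lie within the network depth (0..", L, ")")
  m <- 0:target_layer
  exponent <- sum(params$beta * params$w^(target_layer - m) * levels_by_layer[m + 1])
  params$baseline * exp(-exponent)
}

#' Simulate a dose-response concentration series
#'
#' Forward-simulates the layered dampening model over a vector of primary
#' miRNA doses: each dose is propagated through the network and the
#' target mRNA level predicted for every layer. Optional multiplicative
#' log-normal noise perturbs the target levels (abundances stay
#' positive). Deterministic for a fixed seed.
#'
#' @param params A `cb_dampening_params`.
#' @param network A `cb_layer_network`.
#' @param doses Non-negative numeric vector of primary levels.
#' @param noise_sigma Standard deviation of the log-normal noise on
#'   target levels (0 = exact forward model).
#' @param seed Integer RNG seed.
#' @return data.frame with columns `dose`, `layer`, `mirna_level`,
#'   `target_level`.
#' @export
generate_concentration_series <- function(params, network, doses,
                                          noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(params, "cb_dampening_params"),
            inherits(network, "cb_layer_network"))
  if (any(doses < 0)) stop("doses must be non-negative")
  set.seed(seed)
  rows <- lapply(doses, function(d) {
    lv <- propagate_layers(network, d)
    data.frame(dose = d, layer = 0:network$n_layers,
               mirna_level = unname(lv),
               target_level = vapply(0:network$n_layers, function(t)
                 predict_target_level(lv, t, params), numeric(1)))
  })
  out <- do.call(rbind, rows)
  if (noise_sigma > 0)
    out$target_level <- out$target_level * exp(stats::rnorm(nrow(out), 0, noise_sigma))
  rownames(out) <- NULL
  out
}

#' Recover dampening parameters from a simulated series
#'
#' Estimates the attenuation base `w` and repression strength `beta` from
#' a dose-response table (as produced by
#' [generate_concentration_series()]) with a known baseline, and fits the
#' primary-to-secondary response curve. For a fixed `w` the model is
#' linear in `beta` through the transformed response
#' `-log(target / baseline)`, so `beta` is profiled out in closed form
#' and `w` found by one-dimensional minimization. A single-layer series
#' carries no information about distance attenuation and is refused.
#'
#' @param series data.frame with columns `dose`, `layer`, `mirna_level`,
#'   `target_level`.
#' @param baseline The (known) unrepressed mRNA level used in simulation.
#' @param degree Degree for the response-curve fit (default 2).
#' @return List with `curve` (a `cb_response_curve` for layer 1 vs layer
#'   0 levels), `w`, `beta`, and `rss` of the dampening fit.
#' @export
recover_params <- function(series, baseline = 1, degree = 2L) {
  need <- c("dose", "layer", "mirna_level", "target_level")
  stopifnot(all(need %in% names(series)))
  layers <- sort(unique(series$layer))
  if (length(layers) < 2)
    stop("non-identifiable: attenuation base w cannot be estimated from a single layer")

  # per-row transformed response and per-layer miRNA level matrix
  y <- -log(pmax(series$target_level, .Machine$double.xmin) / baseline)
  lv_wide <- stats::reshape(series[, c("dose", "layer", "mirna_level")],
                            idvar = "dose", timevar = "layer", direction = "wide")
  lv_mat <- as.matrix(lv_wide[, -1, drop = FALSE])  # doses x layers
  dose_of_row <- match(series$dose, lv_wide$dose)

  design_for <- function(w) {
    vapply(seq_len(nrow(series)), function(i) {
      t <- series$layer[i]
      m <- 0:t
      sum(w^(t - m) * lv_mat[dose_of_row[i], m + 1])
    }, numeric(1))
  }
  rss_for <- function(w) {
    x <- design_for(w)
    sxx <- sum(x * x)
    if (sxx == 0) return(sum(y^2))
    beta <- sum(x * y) / sxx
    sum((y - beta * x)^2)
  }
  opt <- stats::optimize(rss_for, interval = c(1e-8, 1 - 1e-8),
                         tol = .Machine$double.eps^0.6)
  # polish around the optimum: golden-section accuracy is ~sqrt(tol)
  fine <- stats::optimize(rss_for, tol = .Machine$double.eps^0.8,
                          interval = c(max(1e-8, opt$minimum - 1e-4),
                                       min(1 - 1e-8, opt$minimum + 1e-4)))
  w_hat <- fine$minimum
  x <- design_for(w_hat)
  beta_hat <- sum(x * y) / sum(x * x)

  l0 <- series$mirna_level[series$layer == 0]
  l1 <- series$mirna_level[series$layer == 1]
  curve <- fit_response_curve(l0, l1, degree = min(degree, length(unique(l0)) - 1L))
  list(curve = curve, w = w_hat, beta = beta_hat, rss = fine$objective)
}
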