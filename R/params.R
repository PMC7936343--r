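#' Within-patch microbial growth parameters
#'
#' Bundles the parameters of the stochastic within-patch growth process: the
#' fitness cost of the slow-growing type, the patch carrying capacity, and the
#' growth kernel.
#'
#' @param c Dimensionless fitness cost of the slow type; its per-event birth
#'   weight is \code{1 - c}. Must lie in \code{[0, 1]}.
#' @param K Carrying capacity of a patch (cells); microbial growth stops once
#'   the patch holds \code{K} cells. Must be at least 1.
#' @param kernel Growth kernel: \code{"pure_birth"} (one birth per time step
#'   until capacity) or \code{"logistic"} (the birth additionally occurs only
#'   with acceptance probability \code{1 - N/K}, a density-dependent
#'   slowdown).
#' @return An object of class \code{"growth_params"}.
#' @examples
#' growth_params(c = 0.15, K = 1e4)
#' @export
growth_params <- function(c = 0.15, K = 1e4, kernel = c("pure_birth", "logistic")) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(c), length(c) == 1L, c >= 0, c <= 1)
  stopifnot(is.numeric(K), length(K) == 1L, K >= 1, K == floor(K))
  structure(list(c = c, K = as.integer(min(K, .Machine$integer.max)), kernel = kernel),
            class = "growth_params")
}

#' Host decay (patch quality) parameters
#'
#' Parameters of the per-time-step host mortality probability
#' \eqn{\delta = \delta_K (N_f + \delta_s N_s) / K}: the maximal decay
#' probability when a patch is fully occupied by the fast type, and the
#' relative impact of the slow type.
#'
#' @param delta_K Maximal per-step host decay probability (patch fully
#'   occupied by the fast type); in \code{[0, 1]}.
#' @param delta_s Relative impact of the slow type on decay; in \code{[0, 1]}.
#' @return An object of class \code{"decay_params"}.
#' @examples
#' decay_params(delta_K = 0.1, delta_s = 0.1)
#' @export
decay_params <- function(delta_K = 0.1, delta_s = 0.1) {
  stopifnot(is.numeric(delta_K), length(delta_K) == 1L, delta_K >= 0, delta_K <= 1)
  stopifnot(is.numeric(delta_s), length(delta_s) == 1L, delta_s >= 0, delta_s <= 1)
  structure(list(delta_K = delta_K, delta_s = delta_s), class = "decay_params")
}

#' Full simulation parameter set
#'
#' All parameters of the metapopulation simulation.  The defaults are the
#' reference parameter set used throughout: \code{M = 50}, \code{K = 1e4},
#' \code{D = 100}, \code{c = 0.15}, \code{H0 = 100}, \code{b = 5},
#' \code{tau = 1e3}, \code{delta_K = 0.1}, \code{delta_s = 0.1},
#' \code{N0 = 5}.
#'
#' @param M Number of habitat patches.
#' @param K Carrying capacity of each patch (cells).
#' @param c Fitness cost of the slow microbial type, in \code{[0, 1]}.
#' @param delta_K Maximal per-step host decay probability.
#' @param delta_s Relative impact of the slow type on patch decay.
#' @param b Dispersal bottleneck: microbial cells carried by each dispersing
#'   host.
#' @param D Maximum size of the host dispersal pool.
#' @param H0 Eggs laid per colonising host (developing hosts per clutch).
#' @param tau Host development time (time steps per growth cycle).
#' @param N0 Founder microbial cells per initially colonised patch.
#' @param m Host-independent microbial migrants per dispersal event.
#' @param colonized_fraction Fraction of patches initially carrying microbes.
#' @param tau_d Half-width of the development-time jitter (asynchronous
#'   engine); development times are uniform on \code{[tau - tau_d, tau + tau_d]}.
#'   Must be strictly less than \code{tau}.
#' @param M0 Patches replaced per renewal event (asynchronous engine).
#' @param renewal_mean Mean number of time steps between renewal events
#'   (asynchronous engine, geometric inter-event times).
#' @param max_cycles Cap on dispersal cycles for fixation runs; runs hitting
#'   the cap are reported as censored.
#' @param kernel Within-patch growth kernel, \code{"pure_birth"} or
#'   \code{"logistic"}.
#' @param seed Optional RNG seed recorded with the parameter set; engines use
#'   it when no explicit seed is given.
#' @return An object of class \code{"sim_params"}: a validated list of all
#'   fields plus derived \code{growth_params} / \code{decay_params} accessors
#'   via [as_growth_params()] and [as_decay_params()].
#' @examples
#' p <- sim_params(M = 10, K = 1000, tau = 200)
#' p$b
#' @export
sim_params <- function(M = 50, K = 1e4, c = 0.15, delta_K = 0.1, delta_s = 0.1,
                       b = 5, D = 100, H0 = 100, tau = 1e3, N0 = 5, m = 0,
                       colonized_fraction = 1, tau_d = 0, M0 = M,
                       renewal_mean = tau, max_cycles = 1000,
                       kernel = c("pure_birth", "logistic"), seed = NA_integer_) {
  kernel <- match.arg(kernel)
  p <- list(M = M, K = K, c = c, delta_K = delta_K, delta_s = delta_s, b = b,
            D = D, H0 = H0, tau = tau, N0 = N0, m = m,
            colonized_fraction = colonized_fraction, tau_d = tau_d, M0 = M0,
            renewal_mean = renewal_mean, max_cycles = max_cycles,
            kernel = kernel, seed = seed)
  validate_sim_params(p)
  counts <- c("M", "K", "b", "D", "H0", "tau", "N0", "m", "tau_d", "M0",
              "max_cycles")
  p[counts] <- lapply(p[counts], function(x) as.integer(x))
  structure(p, class = "sim_params")
}

# Field-by-field bound checks; errors name the offending field and bound.
validate_sim_params <- function(p) {
  chk <- function(field, ok, bound) {
    if (!isTRUE(ok)) {
      stop(sprintf("invalid value for '%s' (%s): must satisfy %s",
                   field, format(p[[field]]), bound), call. = FALSE)
    }
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  cnt <- function(x) num1(x) && x >= 0 && x == floor(x)
  chk("M", cnt(p$M) && p$M >= 1, "integer >= 1")
  chk("K", cnt(p$K) && p$K >= 1, "integer >= 1")
  chk("c", num1(p$c) && p$c >= 0 && p$c <= 1, "0 <= c <= 1")
  chk("delta_K", num1(p$delta_K) && p$delta_K >= 0 && p$delta_K <= 1,
      "0 <= delta_K <= 1")
  chk("delta_s", num1(p$delta_s) && p$delta_s >= 0 && p$delta_s <= 1,
      "0 <= delta_s <= 1")
  chk("b", cnt(p$b), "integer >= 0")
  chk("D", cnt(p$D), "integer >= 0")
  chk("H0", cnt(p$H0), "integer >= 0")
  chk("tau", cnt(p$tau), "integer >= 0")
  chk("N0", cnt(p$N0) && p$N0 <= p$K, "integer >= 0 and <= K")
  chk("m", cnt(p$m), "integer >= 0")
  chk("colonized_fraction",
      num1(p$colonized_fraction) && p$colonized_fraction >= 0 &&
        p$colonized_fraction <= 1, "0 <= colonized_fraction <= 1")
  chk("tau_d", cnt(p$tau_d) && p$tau_d < max(p$tau, 1), "integer >= 0 and < tau")
  chk("M0", cnt(p$M0) && p$M0 <= p$M, "integer >= 0 and <= M")
  chk("renewal_mean", num1(p$renewal_mean) && p$renewal_mean > 0,
      "positive number")
  chk("max_cycles", cnt(p$max_cycles) && p$max_cycles >= 1, "integer >= 1")
  invisible(p)
}

#' @rdname sim_params
#' @param params A \code{sim_params} object.
#' @export
as_growth_params <- function(params) {
  growth_params(c = params$c, K = params$K, kernel = params$kernel)
}

#' @rdname sim_params
#' @export
as_decay_params <- function(params) {
  decay_params(delta_K = params$delta_K, delta_s = params$delta_s)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Host-microbe metapopulation parameters\n")
  cat(sprintf("  landscape:  M = %d patches, K = %d cells/patch\n", x$M, x$K))
  cat(sprintf("  microbes:   c = %g, kernel = %s, N0 = %d, m = %d migrants\n",
              x$c, x$kernel, x$N0, x$m))
  cat(sprintf("  decay:      delta_K = %g, delta_s = %g\n", x$delta_K, x$delta_s))
  cat(sprintf("  hosts:      H0 = %d eggs, b = %d cells/host, D = %d pool cap, tau = %d steps\n",
              x$H0, x$b, x$D, x$tau))
  cat(sprintf("  init/async: colonized_fraction = %g, tau_d = %d, M0 = %d, renewal_mean = %g\n",
              x$colonized_fraction, x$tau_d, x$M0, x$renewal_mean))
  cat(sprintf("  run:        max_cycles = %d, seed = %s\n", x$max_cycles,
              ifelse(is.na(x$seed), "unset", format(x$seed))))
  invisible(x)
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("growth_params: c = %g, K = %d, kernel = %s\n", x$c, x$K, x$kernel))
  invisible(x)
}

#' @export
print.decay_params <- function(x, ...) {
  cat(sprintf("decay_params: delta_K = %g, delta_s = %g\n", x$delta_K, x$delta_s))
  invisible(x)
}
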