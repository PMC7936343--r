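#' Patch state
#'
#' A snapshot of one habitat patch: counts of the fast- and slow-growing
#' microbial types, the number of live developing hosts, and the time steps
#' elapsed in the current growth cycle.  Within a cycle microbial counts never
#' decrease and the host count never increases.
#'
#' @param Nf Fast-type cell count.
#' @param Ns Slow-type cell count.
#' @param H Live developing hosts.
#' @param t Time steps elapsed in the current cycle.
#' @return An object of class \code{"patch_state"}.
#' @examples
#' s <- patch_state(Nf = 4, Ns = 1, H = 100)
#' slow_fraction(s)
#' @export
patch_state <- function(Nf, Ns, H = 0L, t = 0L) {
  stopifnot(Nf >= 0, Ns >= 0, H >= 0, t >= 0)
  structure(list(Nf = as.numeric(Nf), Ns = as.numeric(Ns),
                 H = as.numeric(H), t = as.numeric(t)),
            class = "patch_state")
}

#' @export
print.patch_state <- function(x, ...) {
  f <- slow_fraction(x)
  cat(sprintf("patch_state: Nf = %g, Ns = %g (f = %s), H = %g hosts, t = %g\n",
              x$Nf, x$Ns, ifelse(is.na(f), "no microbes", sprintf("%.4f", f)),
              x$H, x$t))
  invisible(x)
}

#' Relative abundance of the slow type
#'
#' \code{Ns / (Nf + Ns)}.  Sterile patches (no microbes) return \code{NA}
#' rather than 0, so that averages over patches are not biased toward the
#' fast type; callers exclude the sentinel from means.
#'
#' @param Nf Fast-type count, or a \code{patch_state}.
#' @param Ns Slow-type count (ignored when \code{Nf} is a \code{patch_state}).
#' @return Slow-type fraction in \code{[0, 1]}, or \code{NA_real_} when the
#'   patch holds no microbes.  Vectorised over counts.
#' @export
slow_fraction <- function(Nf, Ns = NULL) {
  if (inherits(Nf, "patch_state")) {
    Ns <- Nf$Ns
    Nf <- Nf$Nf
  }
  tot <- Nf + Ns
  ifelse(tot > 0, Ns / tot, NA_real_)
}

#' Per-event birth probabilities of the two microbial types
#'
#' In each time step below carrying capacity, one cell is chosen to reproduce
#' with probability proportional to its growth rate: the fast type has weight
#' \code{Nf} and the slow type weight \code{(1 - c) * Ns}, so
#' \deqn{P_f = N_f / (N_f + (1-c) N_s), \quad P_s = (1-c) N_s / (N_f + (1-c) N_s).}
#' At or above capacity, and in an empty patch, both probabilities are zero
#' (a pure birth process without death that halts at \code{K}).
#'
#' @param Nf,Ns Current cell counts (non-negative).
#' @param params A [growth_params()] object.
#' @return Named numeric vector \code{c(Pf, Ps)}; sums to 1 whenever
#'   \code{0 < Nf + Ns < K} (and the total birth weight is positive).
#' @examples
#' birth_probabilities(4, 1, growth_params(c = 0.15, K = 100))
#' @export
birth_probabilities <- function(Nf, Ns, params) {
  stopifnot(inherits(params, "growth_params"))
  if (Nf < 0 || Ns < 0) stop("cell counts must be non-negative", call. = FALSE)
  tot <- Nf + Ns
  if (tot == 0 || tot >= params$K) return(c(Pf = 0, Ps = 0))
  w <- Nf + (1 - params$c) * Ns
  if (w == 0) return(c(Pf = 0, Ps = 0)) # c = 1 with only slow cells: no births
  c(Pf = Nf / w, Ps = (1 - params$c) * Ns / w)
}

#' One stochastic growth step within a patch
#'
#' Applies a single time step of the within-patch birth process to a
#' \code{patch_state}: with the pure-birth kernel exactly one of \code{Nf},
#' \code{Ns} is incremented (probabilities from [birth_probabilities()])
#' unless the patch is empty or at capacity; with the logistic kernel the
#' birth additionally occurs only with acceptance probability
#' \code{1 - (Nf + Ns)/K}.  The step counter \code{t} is incremented either
#' way.
#'
#' @param state A [patch_state()].
#' @param params A [growth_params()].
#' @return The updated \code{patch_state}.
#' @export
growth_step <- function(state, params) {
  stopifnot(inherits(state, "patch_state"), inherits(params, "growth_params"))
  pr <- birth_probabilities(state$Nf, state$Ns, params)
  state$t <- state$t + 1
  if (pr[["Pf"]] + pr[["Ps"]] == 0) return(state)
  if (params$kernel == "logistic" &&
      stats::runif(1) >= 1 - (state$Nf + state$Ns) / params$K) {
    return(state) # birth attempt rejected by density dependence
  }
  if (stats::runif(1) < pr[["Ps"]]) state$Ns <- state$Ns + 1 else state$Nf <- state$Nf + 1
  state
}

#' Per-step host decay probability (patch load)
#'
#' The probability that each developing host dies in the current time step,
#' \deqn{\delta = \delta_K (N_f + \delta_s N_s) / K,}
#' rising linearly with microbial load; the slow type's contribution is
#' discounted by \code{delta_s}.  Bounded by \code{delta_K}, attained when the
#' patch is fully occupied by the fast type.
#'
#' @param Nf,Ns Cell counts with \code{Nf + Ns <= K}.
#' @param d A [decay_params()] object.
#' @param K Patch carrying capacity.
#' @return Decay probability in \code{[0, delta_K]}.  Vectorised over counts.
#' @examples
#' host_decay_probability(1e4, 0, decay_params(0.1, 0.1), K = 1e4) # 0.1
#' @export
host_decay_probability <- function(Nf, Ns, d, K) {
  stopifnot(inherits(d, "decay_params"), K >= 1)
  if (any(Nf + Ns > K)) stop("microbial load exceeds carrying capacity K", call. = FALSE)
  d$delta_K * (Nf + d$delta_s * Ns) / K
}

#' Patch quality
#'
#' Rescales the decay probability to a quality index
#' \eqn{\rho = 1 - \delta / \delta_K}: empty patches have maximal quality
#' \eqn{\rho = 1}; a patch fully occupied by the fast type has \eqn{\rho = 0};
#' full occupancy in general gives the minimal quality
#' \eqn{(1 - \delta_s) N_s / K}.  When \code{delta_K = 0} hosts never decay
#' and the quality is defined as 1.
#'
#' @param delta Host decay probability, \code{0 <= delta <= delta_K}.
#' @param d A [decay_params()] object.
#' @return Quality in \code{[0, 1]}. Vectorised over \code{delta}.
#' @export
patch_quality <- function(delta, d) {
  stopifnot(inherits(d, "decay_params"))
  if (d$delta_K == 0) {
    if (any(delta > 0)) stop("delta exceeds delta_K", call. = FALSE)
    return(rep(1, length(delta)))
  }
  if (any(delta < 0 | delta > d$delta_K)) {
    stop("delta must lie in [0, delta_K]", call. = FALSE)
  }
  1 - delta / d$delta_K
}

#' One binomial host-mortality draw
#'
#' The number of hosts dying in one time step, drawn from
#' \code{Binomial(H, delta)} (mean \code{H * delta}).
#'
#' @param H Live hosts (non-negative integer).
#' @param delta Per-host death probability for this step.
#' @return Number of deaths, between 0 and \code{H}.
#' @export
host_decay_step <- function(H, delta) {
  stopifnot(H >= 0, delta >= 0, delta <= 1)
  stats::rbinom(1L, as.integer(H), delta)
}

# Simulate the post-birth microbial trajectory over tau steps.
# Returns numeric vectors Nf, Ns of length tau (abundances after the birth
# attempt of steps 1..tau).  Pure single-type patches take a closed-form
# fast path; mixed patches loop over the urn draws.
simulate_trajectory <- function(Nf0, Ns0, tau, params) {
  K <- params$K
  w <- 1 - params$c
  tot0 <- Nf0 + Ns0
  if (tau == 0L) return(list(Nf = numeric(0), Ns = numeric(0)))
  steps <- seq_len(tau)
  if (params$kernel == "pure_birth") {
    if (tot0 == 0 || (Nf0 == 0 && w == 0)) { # empty, or slow-only with zero rate
      return(list(Nf = rep(Nf0, tau), Ns = rep(Ns0, tau)))
    }
    nb <- min(tau, max(0, K - tot0)) # births occur in the first nb steps only
    if (Ns0 == 0) {
      return(list(Nf = Nf0 + pmin(steps, nb), Ns = rep(0, tau)))
    }
    if (Nf0 == 0) {
      return(list(Nf = rep(0, tau), Ns = Ns0 + pmin(steps, nb)))
    }
    slow <- logical(nb)
    if (nb > 0) {
      u <- stats::runif(nb)
      nf <- Nf0; ns <- Ns0
      for (i in seq_len(nb)) {
        ps <- w * ns / (nf + w * ns)
        if (u[i] < ps) { ns <- ns + 1; slow[i] <- TRUE } else nf <- nf + 1
      }
    }
    ns_cum <- c(cumsum(slow), rep(sum(slow), tau - nb))
    nf_cum <- pmin(steps, nb) - ns_cum
    return(list(Nf = Nf0 + nf_cum, Ns = Ns0 + ns_cum))
  }
  # logistic kernel: birth accepted with probability 1 - N/K each step
  nf <- Nf0; ns <- Ns0
  Nf <- numeric(tau); Ns <- numeric(tau)
  for (i in steps) {
    tot <- nf + ns
    if (tot > 0 && tot < K && (nf > 0 || w > 0)) {
      if (stats::runif(1) < 1 - tot / K) {
        ps <- w * ns / (nf + w * ns)
        if (stats::runif(1) < ps) ns <- ns + 1 else nf <- nf + 1
      }
    }
    Nf[i] <- nf; Ns[i] <- ns
  }
  list(Nf = Nf, Ns = Ns)
}

#' Run one full within-patch growth and host-development cycle
#'
#' Executes \code{tau} time steps in a patch founded with \code{founders}
#' cells and \code{initial_hosts} developing hosts.  Each step performs one
#' microbial birth attempt and then one binomial host-mortality draw at the
#' post-birth abundances (decay probability from
#' [host_decay_probability()]).  Growth halts at carrying capacity but host
#' mortality continues; a sterile patch never decays.
#'
#' The survivor count is drawn as a single
#' \code{Binomial(initial_hosts, prod(1 - delta_t))} on the realised
#' microbial trajectory, which by composition of binomial thinning has
#' exactly the same law as applying the per-step draws sequentially.
#'
#' @param founders Length-2 vector \code{c(Nf0, Ns0)} of founder cells.
#' @param initial_hosts Developing hosts at step 0.
#' @param tau Development time (steps).
#' @param growth A [growth_params()] object.
#' @param decay A [decay_params()] object.
#' @return An object of class \code{"patch_cycle_result"}: a list with
#'   \code{final_state} (a [patch_state()]), \code{survivors} and
#'   \code{initial_hosts}.
#' @examples
#' set.seed(1)
#' run_patch_cycle(c(4, 1), 100, tau = 1000,
#'                 growth_params(c = 0.15, K = 1e4), decay_params(0.1, 0.1))
#' @export
run_patch_cycle <- function(founders, initial_hosts, tau, growth, decay) {
  stopifnot(length(founders) == 2L, all(founders >= 0),
            sum(founders) <= growth$K, initial_hosts >= 0, tau >= 0)
  Nf0 <- founders[[1]]; Ns0 <- founders[[2]]
  traj <- simulate_trajectory(Nf0, Ns0, as.integer(tau), growth)
  if (tau == 0L) {
    final <- patch_state(Nf0, Ns0, initial_hosts, 0)
    surv <- as.integer(initial_hosts)
  } else {
    delta <- host_decay_probability(traj$Nf, traj$Ns, decay, growth$K)
    p_survive <- prod(1 - delta)
    surv <- stats::rbinom(1L, as.integer(initial_hosts), p_survive)
    n <- length(traj$Nf)
    final <- patch_state(traj$Nf[n], traj$Ns[n], surv, tau)
  }
  structure(list(final_state = final, survivors = surv,
                 initial_hosts = as.integer(initial_hosts)),
            class = "patch_cycle_result")
}

#' @export
print.patch_cycle_result <- function(x, ...) {
  cat(sprintf("patch cycle: %d of %d hosts survived; final microbes Nf = %g, Ns = %g\n",
              x$survivors, x$initial_hosts, x$final_state$Nf, x$final_state$Ns))
  invisible(x)
}

#' Semi-analytic expected host survival in one patch cycle
#'
#' The probability that a developing host survives \code{tau} steps,
#' \eqn{S(\tau) = \prod_{t=1}^{\tau} (1 - \delta(t))}, where \eqn{\delta(t)}
#' is evaluated on the deterministic expected microbial trajectory: each step
#' adds one expected birth, allocated fractionally between the types by the
#' current birth probabilities and capped at \code{K}.  For single-type
#' founders the expected trajectory coincides with every realised trajectory,
#' so \eqn{S(\tau)} is the exact per-host survival probability; for mixed
#' founders it is a mean-trajectory approximation.  Deterministic and
#' non-increasing in \code{tau}.
#'
#' @inheritParams run_patch_cycle
#' @return Survival probability in \code{[0, 1]}.
#' @examples
#' expected_host_survival(c(5, 0), 1000, growth_params(0.15, 1e4),
#'                        decay_params(0.1, 0.1))
#' @export
expected_host_survival <- function(founders, tau, growth, decay) {
  stopifnot(length(founders) == 2L, all(founders >= 0),
            sum(founders) <= growth$K, tau >= 0)
  nf <- founders[[1]]; ns <- founders[[2]]
  K <- growth$K
  w <- 1 - growth$c
  logS <- 0
  for (t in seq_len(tau)) {
    tot <- nf + ns
    room <- K - tot
    if (room > 0 && tot > 0 && (nf > 0 || w > 0)) {
      birth <- min(1, room)
      if (growth$kernel == "logistic") birth <- birth * (1 - tot / K)
      ps <- w * ns / (nf + w * ns)
      ns <- ns + birth * ps
      nf <- nf + birth * (1 - ps)
    }
    delta <- decay$delta_K * (nf + decay$delta_s * ns) / K
    if (delta >= 1) return(0)
    logS <- logS + log1p(-delta)
  }
  exp(logS)
}

#' Exact final-composition distribution of the pure-birth process
#'
#' Dynamic-programming enumeration of the within-patch pure-birth process:
#' forward recursion over totals \code{n = Nf0 + Ns0, ..., K} with the
#' transition probabilities of [birth_probabilities()], yielding the exact
#' distribution of \code{(Nf, Ns)} when the patch reaches carrying capacity.
#' Intended as a small-\code{K} testing oracle for the stochastic simulator.
#'
#' @param Nf0,Ns0 Founder counts, \code{Nf0 + Ns0 >= 1}.
#' @param params A [growth_params()] with \code{K <= 100} (larger capacities
#'   are refused: the enumeration is meant for small patches) and the
#'   \code{pure_birth} kernel.  The logistic kernel only slows the clock
#'   without changing which birth occurs, so its final-composition law is the
#'   identical distribution.
#' @return A \code{data.frame} with columns \code{Nf}, \code{Ns}, \code{prob}
#'   (probabilities summing to 1), ordered by \code{Ns}.
#' @examples
#' exact_final_composition_distribution(1, 1, growth_params(c = 0, K = 4))
#' @export
exact_final_composition_distribution <- function(Nf0, Ns0, params) {
  stopifnot(inherits(params, "growth_params"), Nf0 >= 0, Ns0 >= 0)
  K <- params$K
  if (K > 100) stop("K too large to enumerate exactly (limit 100)", call. = FALSE)
  if (Nf0 + Ns0 < 1) stop("at least one founder cell required", call. = FALSE)
  if (Nf0 + Ns0 > K) stop("founders exceed carrying capacity", call. = FALSE)
  w <- 1 - params$c
  n0 <- Nf0 + Ns0
  if (n0 == K) return(data.frame(Nf = Nf0, Ns = Ns0, prob = 1))
  if (w == 0 && Nf0 == 0) { # slow-only founders that cannot reproduce: frozen
    return(data.frame(Nf = Nf0, Ns = Ns0, prob = 1))
  }
  # prob[j] = P(Ns = Ns0 + j - 1) at the current total
  prob <- c(1, numeric(K - n0))
  for (n in n0:(K - 1)) {
    j <- seq_len(n - n0 + 1)
    ns <- Ns0 + j - 1
    nf <- n - ns
    denom <- nf + w * ns
    ps <- ifelse(denom > 0, w * ns / denom, 0)
    nxt <- numeric(length(prob))
    nxt[j] <- prob[j] * (1 - ps)     # fast birth: Ns unchanged
    nxt[j + 1] <- nxt[j + 1] + prob[j] * ps # slow birth
    prob <- nxt
  }
  ns_final <- Ns0 + seq_along(prob) - 1
  keep <- prob > 0 | ns_final == Ns0
  data.frame(Nf = K - ns_final[keep], Ns = ns_final[keep], prob = prob[keep])
}
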