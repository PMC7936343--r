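#' Initialise a metapopulation state
#'
#' Seeds the landscape: a fraction \code{colonized_fraction} of the \code{M}
#' patches (rounded, and at least one when an invader is requested) receives
#' \code{N0} founder microbial cells, and every patch receives one virtual
#' founding clutch of \code{H0} developing hosts.
#'
#' @param params A [sim_params()] object.
#' @param invader \code{FALSE}: all founders are fast-type. \code{TRUE} (or
#'   \code{"one"}): a single uniformly chosen colonised patch has exactly one
#'   founder cell converted to slow (e.g. \code{N0 = 5} gives 4 fast + 1
#'   slow), the single-invader setup of fixation experiments. \code{"all"}:
#'   every colonised patch has one founder converted to slow, the
#'   per-patch mixed-founder setup of sustained-coexistence experiments.
#' @param seed Optional RNG seed.
#' @return An object of class \code{"metapop_state"}: a list with
#'   \code{patches} (a data.frame of \code{Nf}, \code{Ns}, \code{H} over
#'   patches), \code{cycle}, and \code{params}.
#' @examples
#' initialize_metapop(sim_params(M = 10), invader = TRUE, seed = 1)
#' @export
initialize_metapop <- function(params, invader = FALSE, seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  invader <- match_invader(invader)
  set_seed_if_given(seed)
  M <- params$M
  n_col <- round(params$colonized_fraction * M)
  if (invader != "none" && n_col < 1) {
    if (params$colonized_fraction == 0) {
      stop("cannot place an invader with colonized_fraction = 0", call. = FALSE)
    }
    n_col <- 1L
  }
  if (invader != "none" && params$N0 < 1) {
    stop("invader requires N0 >= 1 founder cell", call. = FALSE)
  }
  Nf <- numeric(M); Ns <- numeric(M)
  col <- if (n_col > 0) sample.int(M, n_col) else integer(0)
  Nf[col] <- params$N0
  if (invader == "one" && n_col > 0) {
    pick <- col[sample.int(length(col), 1L)]
    Nf[pick] <- Nf[pick] - 1
    Ns[pick] <- 1
  } else if (invader == "all") {
    Nf[col] <- Nf[col] - 1
    Ns[col] <- 1
  }
  structure(list(patches = data.frame(Nf = Nf, Ns = Ns,
                                      H = rep(params$H0, M)),
                 cycle = 0L, params = params),
            class = "metapop_state")
}

match_invader <- function(invader) {
  if (isTRUE(invader)) return("one")
  if (isFALSE(invader)) return("none")
  match.arg(invader, c("none", "one", "all"))
}

#' @export
print.metapop_state <- function(x, ...) {
  occ <- sum(x$patches$Nf + x$patches$Ns > 0)
  f <- slow_fraction(sum(x$patches$Nf), sum(x$patches$Ns))
  cat(sprintf("metapop_state: cycle %d, %d/%d patches occupied, %g live hosts, metapopulation slow fraction %s\n",
              x$cycle, occ, nrow(x$patches), sum(x$patches$H),
              ifelse(is.na(f), "undefined (no microbes)", sprintf("%.4f", f))))
  invisible(x)
}

# Grow all patches for one development period and collect the mature carriers.
# Returns list(patches = end-of-growth data.frame, carriers = data.frame).
grow_generation <- function(patches, params) {
  g <- as_growth_params(params)
  d <- as_decay_params(params)
  M <- nrow(patches)
  Nf_end <- numeric(M); Ns_end <- numeric(M); surv <- integer(M)
  for (i in seq_len(M)) {
    res <- run_patch_cycle(c(patches$Nf[i], patches$Ns[i]), patches$H[i],
                           params$tau, g, d)
    Nf_end[i] <- res$final_state$Nf
    Ns_end[i] <- res$final_state$Ns
    surv[i] <- res$survivors
  }
  src <- rep.int(seq_len(M), surv)
  f_src <- slow_fraction(Nf_end, Ns_end)[src]
  sterile <- is.na(f_src)
  bs <- integer(length(src))
  if (any(!sterile)) bs[!sterile] <- stats::rbinom(sum(!sterile), params$b, f_src[!sterile])
  bf <- ifelse(sterile, 0L, params$b - bs)
  list(patches = data.frame(Nf = Nf_end, Ns = Ns_end, H = surv),
       carriers = data.frame(source_patch = src, bf = bf, bs = bs))
}

#' Advance the metapopulation by one synchronous dispersal cycle
#'
#' Runs one full generation: every patch executes a within-patch growth and
#' host-development cycle ([run_patch_cycle()]); survivors become mature
#' carriers with an uptake sample of \code{b} cells each; at most \code{D}
#' of them enter the common dispersal pool; pooled hosts are assigned
#' uniformly to \code{M} brand-new empty patches; \code{m} host-independent
#' migrant cells are sampled from the old generation's patches; and the new
#' patches are founded from carried cells, migrants, and \code{H0} eggs per
#' colonising host.
#'
#' @param state A [initialize_metapop()] state.
#' @param params A [sim_params()] object (defaults to the state's own).
#' @param weighting How \code{f_patch} averages over patches:
#'   \code{"patch"} (default) gives each occupied patch equal weight;
#'   \code{"cell"} weights by microbial abundance (the pooled slow fraction
#'   of all cells).
#' @return A list with \code{state} (the advanced \code{metapop_state}) and
#'   \code{record}, a one-row data.frame with the cycle's summary computed at
#'   the end of growth, before founding: \code{cycle}, \code{f_patch} (mean
#'   slow fraction over occupied patches), \code{f_host} (mean carried slow
#'   fraction over pooled hosts with at least one microbe), and counts
#'   \code{occupied_patches}, \code{mature_hosts}, \code{pool_size},
#'   \code{live_hosts_total} (developing hosts founding the next
#'   generation).
#' @export
synchronous_cycle <- function(state, params = state$params,
                              weighting = c("patch", "cell")) {
  stopifnot(inherits(state, "metapop_state"))
  weighting <- match.arg(weighting)
  gen <- grow_generation(state$patches, params)
  grown <- gen$patches
  f <- slow_fraction(grown$Nf, grown$Ns)
  occupied <- sum(!is.na(f))
  f_patch <- if (occupied == 0) NA_real_
    else if (weighting == "patch") mean(f, na.rm = TRUE)
    else sum(grown$Ns) / (sum(grown$Nf) + sum(grown$Ns))
  pool <- form_dispersal_pool(gen$carriers, params$D)
  carried <- pool$bf + pool$bs
  f_host <- if (any(carried > 0)) {
    mean(pool$bs[carried > 0] / carried[carried > 0])
  } else NA_real_
  assignment <- assign_hosts(nrow(pool), params$M)
  migrants <- host_independent_sample(grown$Nf, grown$Ns, params$m, params$M)
  fresh <- found_patches(assignment, pool, migrants, params$M, params$H0,
                         params$K)
  record <- data.frame(cycle = state$cycle, f_patch = f_patch,
                       f_host = f_host, occupied_patches = occupied,
                       mature_hosts = nrow(gen$carriers),
                       pool_size = nrow(pool),
                       live_hosts_total = sum(fresh$H))
  state$patches <- fresh
  state$cycle <- state$cycle + 1L
  list(state = state, record = record)
}

#' Simulate a fixed number of dispersal cycles
#'
#' Convenience engine: initialises a metapopulation and runs
#' [synchronous_cycle()] for \code{n_cycles} generations, collecting the
#' per-cycle records.
#'
#' @inheritParams initialize_metapop
#' @inheritParams synchronous_cycle
#' @param n_cycles Number of dispersal cycles to run.
#' @return An object of class \code{"mp_records"}: a data.frame of per-cycle
#'   records (see [synchronous_cycle()]) with the final \code{metapop_state}
#'   attached as attribute \code{"final_state"} and the parameters as
#'   attribute \code{"params"}.
#' @examples
#' r <- run_simulation(sim_params(M = 5, K = 200, tau = 50, D = 20),
#'                     n_cycles = 3, invader = "all", seed = 1)
#' r
#' @export
run_simulation <- function(params, n_cycles, invader = "all", seed = NULL,
                           weighting = c("patch", "cell")) {
  weighting <- match.arg(weighting)
  state <- initialize_metapop(params, invader = invader, seed = seed)
  records <- vector("list", n_cycles)
  for (k in seq_len(n_cycles)) {
    step <- synchronous_cycle(state, params, weighting = weighting)
    state <- step$state
    records[[k]] <- step$record
  }
  out <- do.call(rbind, records)
  if (is.null(out)) {
    out <- data.frame(cycle = integer(0), f_patch = numeric(0),
                      f_host = numeric(0), occupied_patches = integer(0),
                      mature_hosts = integer(0), pool_size = integer(0),
                      live_hosts_total = integer(0))
  }
  structure(out, class = c("mp_records", "data.frame"),
            final_state = state, params = params)
}

#' Run the metapopulation until one microbial type fixes
#'
#' Repeats [synchronous_cycle()] until the metapopulation slow fraction
#' (evaluated over all patch cells at cycle boundaries, when all carried
#' cells have been deposited) reaches 0 or 1, microbes go extinct, hosts go
#' extinct, or \code{max_cycles} is hit (censoring).
#'
#' @inheritParams initialize_metapop
#' @param record Keep the per-cycle record stream?
#' @return An object of class \code{"fixation_outcome"}: a list with
#'   \code{outcome} (one of \code{"slow_fixed"}, \code{"fast_fixed"},
#'   \code{"microbes_extinct"}, \code{"hosts_extinct"}, \code{"censored"}),
#'   \code{cycles}, and (if requested) \code{records}.
#' @examples
#' run_until_fixation(sim_params(M = 5, K = 200, tau = 50, D = 20,
#'                               max_cycles = 50), seed = 1)
#' @export
run_until_fixation <- function(params, invader = TRUE, seed = NULL,
                               record = FALSE) {
  state <- initialize_metapop(params, invader = invader, seed = seed)
  records <- if (record) list() else NULL
  repeat {
    s <- sum(state$patches$Ns)
    fst <- sum(state$patches$Nf)
    outcome <- if (s + fst == 0) "microbes_extinct"
      else if (s == 0) "fast_fixed"
      else if (fst == 0) "slow_fixed"
      else if (sum(state$patches$H) == 0) "hosts_extinct"
      else NA_character_
    if (!is.na(outcome)) break
    if (state$cycle >= params$max_cycles) {
      outcome <- "censored"
      break
    }
    step <- synchronous_cycle(state, params)
    state <- step$state
    if (record) records[[length(records) + 1L]] <- step$record
  }
  structure(list(outcome = outcome, cycles = state$cycle,
                 records = if (record) do.call(rbind, records)),
            class = "fixation_outcome")
}

#' @export
print.fixation_outcome <- function(x, ...) {
  cat(sprintf("fixation run: %s after %d cycles\n", x$outcome, x$cycles))
  invisible(x)
}

#' Estimate the fixation probability of a single slow invader
#'
#' Runs \code{replicates} independent [run_until_fixation()] simulations,
#' each on its own RNG stream derived from the master seed by
#' [derive_seed()], and estimates the probability that the slow type fixes.
#' Censored runs (those hitting \code{max_cycles}) are excluded from both
#' numerator and denominator and reported separately.
#'
#' @inheritParams initialize_metapop
#' @param replicates Number of independent runs.
#' @param conf_level Confidence level of the Clopper-Pearson binomial
#'   interval.
#' @param record Collect per-cycle records of every replicate (used by
#'   [run_sweep()] for mean slow-fraction summaries)?
#' @return An object of class \code{"fixation_estimate"}: a list with
#'   \code{estimate}, \code{ci} (length-2 vector), \code{replicates},
#'   \code{censored}, \code{outcomes} (a table), \code{runs} (a data.frame
#'   with one row per replicate: derived \code{seed}, \code{outcome},
#'   \code{cycles} - the seed ledger enabling exact re-runs), and optional
#'   \code{mean_f_patch}, \code{mean_f_host}.
#' @examples
#' estimate_fixation_probability(sim_params(M = 5, K = 200, tau = 50, D = 20,
#'                                          max_cycles = 50),
#'                               replicates = 10, seed = 1)
#' @export
estimate_fixation_probability <- function(params, replicates, seed = 1L,
                                          invader = TRUE, conf_level = 0.95,
                                          record = FALSE) {
  stopifnot(replicates >= 1)
  seeds <- derive_seed(seed, seq_len(replicates) - 1L)
  outcome <- character(replicates)
  cycles <- integer(replicates)
  fp <- numeric(replicates); fh <- numeric(replicates)
  for (i in seq_len(replicates)) {
    run <- run_until_fixation(params, invader = invader, seed = seeds[i],
                              record = record)
    outcome[i] <- run$outcome
    cycles[i] <- run$cycles
    if (record) {
      fp[i] <- if (is.null(run$records)) NA_real_ else
        mean(run$records$f_patch, na.rm = TRUE)
      fh[i] <- if (is.null(run$records)) NA_real_ else
        mean(run$records$f_host, na.rm = TRUE)
    }
  }
  censored <- sum(outcome == "censored")
  n_eff <- replicates - censored
  k <- sum(outcome == "slow_fixed")
  if (n_eff > 0) {
    est <- k / n_eff
    ci <- as.numeric(stats::binom.test(k, n_eff,
                                       conf.level = conf_level)$conf.int)
  } else {
    est <- NA_real_
    ci <- c(NA_real_, NA_real_)
  }
  structure(list(estimate = est, ci = ci, replicates = replicates,
                 censored = censored, outcomes = table(outcome),
                 runs = data.frame(seed = seeds, outcome = outcome,
                                   cycles = cycles),
                 mean_f_patch = if (record) mean(fp, na.rm = TRUE),
                 mean_f_host = if (record) mean(fh, na.rm = TRUE)),
            class = "fixation_estimate")
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("fixation probability of the slow type: %.4f  [%.4f, %.4f]\n",
              x$estimate, x$ci[1], x$ci[2]))
  cat(sprintf("  %d replicates (%d censored); outcomes: %s\n",
              x$replicates, x$censored,
              paste(names(x$outcomes), as.integer(x$outcomes),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Independent-patch experiment
#'
#' Runs \code{n_patches} within-patch cycles with identical founders and no
#' dispersal coupling, returning each patch's final slow fraction and host
#' survivor count - the setup behind histograms of final compositions and
#' the survivor-vs-composition relationship.
#'
#' @param founders Length-2 founder vector \code{c(Nf0, Ns0)}.
#' @param n_patches Number of independent patches.
#' @param initial_hosts Developing hosts per patch.
#' @param params A [sim_params()] object (supplies \code{K}, \code{c},
#'   \code{tau}, decay parameters, kernel).
#' @param seed Optional RNG seed.
#' @return An object of class \code{"patch_experiment"}: a data.frame with
#'   columns \code{final_f} (\code{NA} for sterile patches) and
#'   \code{survivors}.
#' @examples
#' independent_patches_experiment(c(4, 1), 100, 100,
#'                                sim_params(K = 1000, tau = 200), seed = 1)
#' @export
independent_patches_experiment <- function(founders, n_patches, initial_hosts,
                                           params, seed = NULL) {
  stopifnot(n_patches >= 1)
  set_seed_if_given(seed)
  g <- as_growth_params(params)
  d <- as_decay_params(params)
  final_f <- numeric(n_patches)
  survivors <- integer(n_patches)
  for (i in seq_len(n_patches)) {
    res <- run_patch_cycle(founders, initial_hosts, params$tau, g, d)
    final_f[i] <- slow_fraction(res$final_state)
    survivors[i] <- res$survivors
  }
  structure(data.frame(final_f = final_f, survivors = survivors),
            class = c("patch_experiment", "data.frame"), params = params,
            founders = founders)
}
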