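#' Asynchronous metapopulation dynamics with patch renewal
#'
#' Generalisation of the synchronous cycle to a single global clock: each
#' developing host has its own integer development time, uniform on
#' \code{[tau - tau_d, tau + tau_d]}; on maturation a host samples \code{b}
#' microbes from its patch, immediately disperses to a uniformly random
#' patch (no pooling - the dispersal-pool cap \code{D} plays no role here),
#' and lays \code{H0} eggs there.  At renewal events, \code{M0} uniformly
#' chosen patches are replaced by empty patches (their microbes and any
#' hosts still developing there are lost).  Renewal inter-event times are
#' geometric with mean \code{renewal_mean}, or exactly periodic with that
#' period when \code{renewal = "periodic"}.
#'
#' Each time step applies, in order: one microbial birth attempt per patch,
#' per-host binomial mortality at the post-birth load, maturation sampling,
#' renewal (if scheduled), and landing of the dispersing hosts.  With
#' \code{tau_d = 0}, \code{M0 = M} and periodic renewal at \code{tau}, the
#' dynamics reduce to the synchronous engine with an unbounded dispersal
#' pool.
#'
#' @inheritParams initialize_metapop
#' @param total_steps Number of global time steps to run.
#' @param snapshot_every Record a snapshot every this many steps (default
#'   \code{tau}).
#' @param renewal \code{"geometric"} or \code{"periodic"} renewal schedule.
#' @return An object of class \code{"mp_async_records"}: a data.frame of
#'   snapshots with columns \code{step}, \code{f_patch} (mean slow fraction
#'   over occupied patches), \code{f_host} (mean carried slow fraction over
#'   hosts that dispersed since the previous snapshot, \code{NA} if none
#'   carried microbes), \code{occupied_patches}, \code{dispersed_hosts},
#'   \code{live_hosts_total}.  Snapshots are taken after the step's growth
#'   and mortality but before its dispersal, so in the degenerate
#'   synchronous limit the snapshot at \code{t = k * tau} describes the same
#'   end-of-growth moment as the synchronous engine's cycle
#'   \code{k - 1} record.
#' @examples
#' p <- sim_params(M = 10, K = 500, tau = 100, tau_d = 20, M0 = 1,
#'                 renewal_mean = 50)
#' asynchronous_run(p, total_steps = 300, seed = 1)
#' @export
asynchronous_run <- function(params, total_steps, invader = "all",
                             seed = NULL, snapshot_every = params$tau,
                             renewal = c("geometric", "periodic")) {
  stopifnot(inherits(params, "sim_params"), total_steps >= 1,
            snapshot_every >= 1)
  renewal <- match.arg(renewal)
  init <- initialize_metapop(params, invader = invader, seed = seed)
  M <- params$M; K <- params$K
  w <- 1 - params$c
  Nf <- init$patches$Nf; Ns <- init$patches$Ns
  dev_time <- function(n) {
    if (params$tau_d == 0) rep.int(params$tau, n)
    else params$tau + sample.int(2L * params$tau_d + 1L, n, replace = TRUE) -
      params$tau_d - 1L
  }
  n0 <- sum(init$patches$H)
  hosts <- data.frame(patch = rep.int(seq_len(M), init$patches$H),
                      mature_at = dev_time(n0))
  next_renewal <- if (renewal == "periodic") round(params$renewal_mean)
    else stats::rgeom(1, 1 / params$renewal_mean) + 1
  snaps <- list()
  win_bf <- integer(0); win_bs <- integer(0); win_n <- 0L

  for (t in seq_len(total_steps)) {
    ## one birth attempt per occupied, below-capacity patch
    tot <- Nf + Ns
    active <- which(tot > 0 & tot < K & (Nf > 0 | w > 0))
    if (length(active)) {
      if (params$kernel == "logistic") {
        acc <- stats::runif(length(active)) < 1 - tot[active] / K
        active <- active[acc]
      }
      if (length(active)) {
        ps <- w * Ns[active] / (Nf[active] + w * Ns[active])
        slow <- stats::runif(length(active)) < ps
        Ns[active] <- Ns[active] + slow
        Nf[active] <- Nf[active] + !slow
      }
    }
    ## per-host mortality at post-birth load (iid Bernoulli = binomial draw)
    if (nrow(hosts)) {
      delta <- params$delta_K * (Nf + params$delta_s * Ns) / K
      dies <- stats::runif(nrow(hosts)) < delta[hosts$patch]
      if (any(dies)) hosts <- hosts[!dies, , drop = FALSE]
    }
    ## snapshot at end-of-growth, before this step's dispersal: comparable
    ## to the synchronous engine's per-cycle record
    if (t %% snapshot_every == 0 || t == total_steps) {
      f <- slow_fraction(Nf, Ns)
      carried <- win_bf + win_bs
      snaps[[length(snaps) + 1L]] <- data.frame(
        step = t,
        f_patch = if (any(!is.na(f))) mean(f, na.rm = TRUE) else NA_real_,
        f_host = if (any(carried > 0)) {
          mean(win_bs[carried > 0] / carried[carried > 0])
        } else NA_real_,
        occupied_patches = sum(!is.na(f)),
        dispersed_hosts = win_n,
        live_hosts_total = nrow(hosts))
      win_bf <- integer(0); win_bs <- integer(0); win_n <- 0L
    }
    ## maturation: sample carried microbes from the source patch
    maturing <- hosts$mature_at == t
    n_mat <- sum(maturing)
    if (n_mat) {
      src <- hosts$patch[maturing]
      hosts <- hosts[!maturing, , drop = FALSE]
      f_src <- slow_fraction(Nf, Ns)[src]
      sterile <- is.na(f_src)
      bs <- integer(n_mat)
      if (any(!sterile)) {
        bs[!sterile] <- stats::rbinom(sum(!sterile), params$b, f_src[!sterile])
      }
      bf <- ifelse(sterile, 0L, params$b - bs)
    }
    ## renewal: wipe M0 random patches (microbes and resident hosts)
    if (t == next_renewal) {
      if (params$M0 > 0) {
        wiped <- sample.int(M, params$M0)
        Nf[wiped] <- 0; Ns[wiped] <- 0
        if (nrow(hosts)) {
          hosts <- hosts[!(hosts$patch %in% wiped), , drop = FALSE]
        }
      }
      next_renewal <- t + if (renewal == "periodic") round(params$renewal_mean)
        else stats::rgeom(1, 1 / params$renewal_mean) + 1
    }
    ## landing: dispersers deposit their cells and lay H0 eggs
    if (n_mat) {
      dest <- sample.int(M, n_mat, replace = TRUE)
      di <- factor(dest, levels = seq_len(M))
      Nf <- Nf + as.numeric(tapply(bf, di, sum, default = 0))
      Ns <- Ns + as.numeric(tapply(bs, di, sum, default = 0))
      over <- which(Nf + Ns > K)
      for (i in over) {
        keep_s <- stats::rhyper(1, m = Ns[i], n = Nf[i], k = K)
        Ns[i] <- keep_s; Nf[i] <- K - keep_s
      }
      if (params$H0 > 0) {
        eggs <- data.frame(patch = rep.int(dest, params$H0),
                           mature_at = t + dev_time(n_mat * params$H0))
        hosts <- rbind(hosts, eggs)
      }
      win_bf <- c(win_bf, bf); win_bs <- c(win_bs, bs); win_n <- win_n + n_mat
    }
  }
  structure(do.call(rbind, snaps),
            class = c("mp_async_records", "data.frame"), params = params)
}
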