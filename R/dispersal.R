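#' Microbial uptake by a dispersing host
#'
#' Each mature host leaving a patch inadvertently carries a sample of
#' \code{b} cells of the local microbial population.  Because the bottleneck
#' \code{b} is orders of magnitude below the patch capacity, uptake is
#' modelled on the type proportions: the carried slow count is
#' \code{Binomial(b, f)} where \code{f} is the source patch's slow fraction,
#' so the carried composition is on average identical to the source
#' community.  Hosts from sterile patches carry nothing.
#'
#' @param source_f Slow-type fraction of the source patch in \code{[0, 1]},
#'   or \code{NA} for a sterile source (see [slow_fraction()]).
#' @param b Bottleneck size (cells carried per host).
#' @param n Number of hosts to sample uptake for (vectorised draw).
#' @param method \code{"binomial"} (proportion-based, the model's default) or
#'   \code{"hypergeometric"} (without-replacement on absolute counts, for
#'   tiny patches; requires \code{Nf}, \code{Ns}).
#' @param Nf,Ns Absolute source counts, only for the hypergeometric method.
#' @return A data.frame with columns \code{bf}, \code{bs} (one row per host);
#'   \code{bf + bs = b} for non-sterile sources, \code{0} otherwise.
#' @examples
#' set.seed(1)
#' host_uptake(0.2, b = 5, n = 3)
#' @export
host_uptake <- function(source_f, b, n = 1L,
                        method = c("binomial", "hypergeometric"),
                        Nf = NULL, Ns = NULL) {
  method <- match.arg(method)
  stopifnot(b >= 0, n >= 0)
  if (n == 0L) return(data.frame(bf = integer(0), bs = integer(0)))
  if (is.na(source_f) || b == 0) {
    return(data.frame(bf = integer(n), bs = integer(n)))
  }
  stopifnot(source_f >= 0, source_f <= 1)
  if (method == "binomial") {
    bs <- stats::rbinom(n, b, source_f)
  } else {
    stopifnot(!is.null(Nf), !is.null(Ns), Nf + Ns >= b)
    bs <- stats::rhyper(n, m = Ns, n = Nf, k = b)
  }
  data.frame(bf = b - bs, bs = bs)
}

#' Form the common dispersal pool
#'
#' At most \code{D} mature hosts, drawn uniformly without replacement from
#' all survivors across all patches, enter the common dispersal pool.  If
#' fewer than \code{D} hosts matured, all of them enter (no padding).
#' Sampling is blind to carried composition and source patch.
#'
#' @param mature_hosts A data.frame of carriers with columns
#'   \code{source_patch}, \code{bf}, \code{bs} (one row per host).
#' @param D Pool capacity.
#' @return The pooled subset, same columns, at most \code{D} rows.
#' @export
form_dispersal_pool <- function(mature_hosts, D) {
  stopifnot(is.data.frame(mature_hosts), D >= 0)
  n <- nrow(mature_hosts)
  if (n <= D) return(mature_hosts)
  mature_hosts[sample.int(n, D), , drop = FALSE]
}

#' Assign pooled hosts to fresh patches
#'
#' Each host in the dispersal pool is independently assigned to one of the
#' \code{M} new patches, uniformly at random; several hosts may land on the
#' same patch and patches may stay uncolonised.
#'
#' @param n_hosts Number of hosts in the pool.
#' @param M Number of new patches.
#' @return Integer vector of patch indices in \code{1..M}, one per host.
#' @export
assign_hosts <- function(n_hosts, M) {
  stopifnot(n_hosts >= 0, M >= 1)
  if (n_hosts == 0L) return(integer(0))
  sample.int(M, n_hosts, replace = TRUE)
}

#' Host-independent microbial migrants
#'
#' Samples \code{m} microbial cells from across all source patches
#' (abundance-weighted, so each cell is slow with probability equal to the
#' pooled metapopulation slow fraction) and assigns each uniformly to one of
#' the \code{M} new patches.  If all source patches are empty, no cells
#' disperse.
#'
#' @param Nf,Ns Vectors of per-patch source abundances.
#' @param m Number of migrant cells.
#' @param M Number of destination patches.
#' @return A data.frame with columns \code{patch} (destination index) and
#'   \code{slow} (logical), one row per migrant cell (possibly zero rows).
#' @export
host_independent_sample <- function(Nf, Ns, m, M) {
  stopifnot(m >= 0, M >= 1, length(Nf) == length(Ns))
  tot <- sum(Nf) + sum(Ns)
  if (m == 0L || tot == 0) {
    return(data.frame(patch = integer(0), slow = logical(0)))
  }
  f_meta <- sum(Ns) / tot
  data.frame(patch = sample.int(M, m, replace = TRUE),
             slow = stats::runif(m) < f_meta)
}

#' Relative strength of host-independent dispersal
#'
#' \code{p = m / (b * D)}: the number of host-independently dispersing cells
#' relative to the maximum number of cells dispersing within hosts.
#'
#' @param m Migrant cells per dispersal event.
#' @param b Bottleneck size.
#' @param D Dispersal-pool capacity.
#' @return The fraction \code{p}.
#' @examples
#' relative_independent_dispersal(50, 5, 100) # 0.1
#' @export
relative_independent_dispersal <- function(m, b, D) {
  if (b * D <= 0) stop("b * D must be positive", call. = FALSE)
  m / (b * D)
}

#' Found the next generation of patches
#'
#' Combines the cells carried by each patch's assigned hosts with its
#' host-independent migrants into the founding microbial population, and
#' seeds \code{n_hosts * H0} developing hosts (each colonising host lays
#' \code{H0} eggs).  Patches without hosts get no eggs but may still receive
#' migrant cells.  In the rare case that combined founders exceed \code{K},
#' they are subsampled uniformly without replacement down to \code{K}
#' (composition-preserving in expectation).
#'
#' @param assignment Integer vector of destination patches, one per pooled
#'   host (from [assign_hosts()]).
#' @param pool Pooled carriers, a data.frame with columns \code{bf},
#'   \code{bs} aligned with \code{assignment}.
#' @param migrants Migrant cells from [host_independent_sample()].
#' @param M Number of new patches.
#' @param H0 Eggs per colonising host.
#' @param K Patch carrying capacity.
#' @return A data.frame of \code{M} rows with columns \code{Nf}, \code{Ns},
#'   \code{H} describing the freshly founded patches.
#' @export
found_patches <- function(assignment, pool, migrants, M, H0, K) {
  stopifnot(length(assignment) == nrow(pool), M >= 1, H0 >= 0, K >= 1)
  idx <- factor(assignment, levels = seq_len(M))
  Nf <- as.numeric(tapply(pool$bf, idx, sum, default = 0))
  Ns <- as.numeric(tapply(pool$bs, idx, sum, default = 0))
  n_hosts <- as.numeric(table(idx))
  if (nrow(migrants) > 0) {
    midx <- factor(migrants$patch, levels = seq_len(M))
    Nf <- Nf + as.numeric(tapply(!migrants$slow, midx, sum, default = 0))
    Ns <- Ns + as.numeric(tapply(migrants$slow, midx, sum, default = 0))
  }
  over <- which(Nf + Ns > K)
  for (i in over) { # guard: b << K makes this rare; preserves composition
    keep_s <- stats::rhyper(1, m = Ns[i], n = Nf[i], k = K)
    Ns[i] <- keep_s
    Nf[i] <- K - keep_s
  }
  data.frame(Nf = Nf, Ns = Ns, H = n_hosts * H0)
}
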