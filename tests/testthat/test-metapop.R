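test_that("initialisation seeds founders, an invader and the founding clutches", {
  p <- sim_params() # reference values: M = 50, N0 = 5, H0 = 100
  st <- initialize_metapop(p, invader = TRUE, seed = 1)
  tots <- st$patches$Nf + st$patches$Ns
  expect_equal(sum(tots == 5), 50)          # all patches colonised with N0
  expect_equal(sum(st$patches$Ns), 1)       # exactly one slow founder cell
  inv <- which(st$patches$Ns == 1)
  expect_equal(st$patches$Nf[inv], 4)       # that patch holds 4 fast + 1 slow
  expect_true(all(st$patches$H == 100))

  st10 <- initialize_metapop(sim_params(colonized_fraction = 0.1), seed = 2)
  expect_equal(sum(st10$patches$Nf + st10$patches$Ns > 0), 5)

  all_fast <- initialize_metapop(sim_params(M = 10), invader = FALSE, seed = 3)
  expect_true(all(all_fast$patches$Nf == 5 & all_fast$patches$Ns == 0))

  per_patch <- initialize_metapop(sim_params(M = 10), invader = "all", seed = 4)
  expect_true(all(per_patch$patches$Nf == 4 & per_patch$patches$Ns == 1))

  expect_error(
    initialize_metapop(sim_params(colonized_fraction = 0), invader = TRUE),
    "colonized_fraction")
})

test_that("a sterile landscape passes through a cycle without decay", {
  p <- tiny_params(colonized_fraction = 0, m = 0)
  st <- initialize_metapop(p, invader = FALSE, seed = 1)
  out <- synchronous_cycle(st)
  expect_equal(out$record$mature_hosts, p$M * p$H0) # nobody dies
  expect_equal(out$record$occupied_patches, 0)
  expect_true(is.na(out$record$f_patch))
  expect_true(all(out$state$patches$Nf + out$state$patches$Ns == 0))
  expect_lte(out$record$pool_size, p$D)
})

test_that("slow-type patches contribute more hosts to the pool", {
  p <- tiny_params(D = 1000, H0 = 100)
  set.seed(2)
  from_slow <- 0; from_fast <- 0
  for (i in 1:50) {
    st <- initialize_metapop(p, invader = FALSE, seed = NULL)
    st$patches$Nf <- c(0, 5, 0, 0, 0)
    st$patches$Ns <- c(5, 0, 0, 0, 0)
    st$patches$H <- c(100, 100, 0, 0, 0)
    out <- synchronous_cycle(st)
    # survivors identified through their carried composition (pure sources)
    carried <- out$state$patches
    from_slow <- from_slow + sum(carried$Ns)
    from_fast <- from_fast + sum(carried$Nf)
  }
  expect_gt(from_slow, from_fast)
})

test_that("fixation runs classify all terminal states and censoring", {
  p <- tiny_params()
  none <- run_until_fixation(p, invader = FALSE, seed = 1)
  expect_equal(none$outcome, "fast_fixed")
  expect_equal(none$cycles, 0L)

  p1 <- tiny_params(max_cycles = 1)
  res <- run_until_fixation(p1, invader = TRUE, seed = 2)
  expect_true(res$outcome %in% c("censored", "fast_fixed", "slow_fixed",
                                 "microbes_extinct", "hosts_extinct"))
  if (res$outcome == "censored") expect_equal(res$cycles, p1$max_cycles)

  # a non-reproducing single slow cell (c = 1) is diluted and lost
  pc1 <- tiny_params(c = 1, b = 1)
  lost <- vapply(1:10, function(i) {
    run_until_fixation(pc1, seed = i)$outcome != "slow_fixed"
  }, logical(1))
  expect_true(all(lost))
})

test_that("fixation estimates are exact for impossible invasions and logged per seed", {
  p <- tiny_params()
  est <- estimate_fixation_probability(p, replicates = 8, seed = 3,
                                       invader = FALSE)
  expect_equal(est$estimate, 0)
  expect_equal(nrow(est$runs), 8)
  expect_equal(est$runs$seed, derive_seed(3, 0:7))
  expect_true(all(est$ci >= 0 & est$ci <= 1))
  expect_true(est$ci[1] <= est$estimate && est$estimate <= est$ci[2])
})

test_that("cell-weighted patch averaging pools abundances across patches", {
  p <- tiny_params()
  st <- initialize_metapop(p, invader = FALSE, seed = 21)
  st$patches$Nf <- c(10, 0, 0, 0, 0)
  st$patches$Ns <- c(0, 90, 0, 0, 0)
  st$patches$H <- rep(0, 5)
  # pure patches grow deterministically: 10 + 50 = 60 fast, 90 + 50 = 140 slow
  pw <- synchronous_cycle(st, p)$record$f_patch
  cw <- synchronous_cycle(st, p, weighting = "cell")$record$f_patch
  expect_equal(pw, 0.5)         # each occupied patch weighted equally
  expect_equal(cw, 140 / 200)   # pooled over cells
})

test_that("identical seeds and parameters reproduce records bit-identically", {
  p <- tiny_params()
  r1 <- run_simulation(p, n_cycles = 4, invader = "all", seed = 11)
  r2 <- run_simulation(p, n_cycles = 4, invader = "all", seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  f1 <- run_until_fixation(p, seed = 12, record = TRUE)
  f2 <- run_until_fixation(p, seed = 12, record = TRUE)
  expect_identical(f1$records, f2$records)
  expect_identical(f1$outcome, f2$outcome)
})

test_that("independent patches reproduce within-patch statistics without coupling", {
  p <- scaled_params()
  pure_slow <- independent_patches_experiment(c(0, 5), 50, 100, p, seed = 4)
  expect_true(all(pure_slow$final_f == 1))

  set.seed(5)
  mixed <- independent_patches_experiment(c(4, 1), 400, 100, p)
  expect_true(all(mixed$final_f >= 0 & mixed$final_f <= 1))
  # patches richer in the slow type keep more hosts alive
  expect_gt(stats::cor(mixed$final_f, mixed$survivors), 0)
  # the fast type dominates in most patches
  expect_lt(stats::median(mixed$final_f), 0.2)
})

test_that("full neutrality equalises host and patch slow fractions on average", {
  p <- tiny_params(c = 0, delta_s = 1)
  diffs <- vapply(1:60, function(i) {
    r <- run_simulation(p, n_cycles = 3, invader = "all",
                        seed = derive_seed(6, i - 1))
    mean(r$f_host - r$f_patch, na.rm = TRUE)
  }, numeric(1))
  diffs <- diffs[is.finite(diffs)]
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})
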