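test_that("birth probabilities follow the weighted urn and its boundary rules", {
  g <- growth_params(c = 0, K = 100)
  expect_equal(birth_probabilities(1, 1, g), c(Pf = 0.5, Ps = 0.5))

  g15 <- growth_params(c = 0.15, K = 100)
  pr <- birth_probabilities(4, 1, g15)
  expect_equal(pr[["Pf"]], 4 / 4.85)
  expect_equal(pr[["Ps"]], 0.85 / 4.85)

  # at capacity (any split) and in an empty patch both probabilities vanish
  expect_equal(birth_probabilities(60, 40, g15), c(Pf = 0, Ps = 0))
  expect_equal(birth_probabilities(120, 40, g15), c(Pf = 0, Ps = 0))
  expect_equal(birth_probabilities(0, 0, g15), c(Pf = 0, Ps = 0))

  expect_error(birth_probabilities(-1, 2, g15), "non-negative")
})

test_that("birth probabilities are normalised on all interior states", {
  set.seed(42)
  g <- growth_params(c = runif(1), K = 50)
  for (i in 1:50) {
    nf <- sample(0:49, 1)
    ns <- sample(0:(49 - nf), 1)
    if (nf + ns == 0 || (nf == 0 && g$c == 1)) next
    pr <- birth_probabilities(nf, ns, g)
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
})

test_that("a growth step adds exactly one cell below capacity and none at it", {
  g <- growth_params(c = 0.15, K = 10)
  at_cap <- patch_state(10, 0)
  expect_equal(growth_step(at_cap, g)$Nf, 10)

  set.seed(1)
  s <- patch_state(0, 3)
  s2 <- growth_step(s, g)
  expect_equal(c(s2$Nf, s2$Ns), c(0, 4)) # single-type patch self-amplifies

  set.seed(2)
  s <- patch_state(2, 3)
  s2 <- growth_step(s, g)
  expect_equal(s2$Nf + s2$Ns, 6)
  expect_equal(s2$t, s$t + 1)
})

test_that("the realised slow-birth fraction matches the urn probability", {
  g <- growth_params(c = 0.15, K = 100)
  ps <- birth_probabilities(4, 1, g)[["Ps"]]
  set.seed(7)
  n <- 1e4
  slow <- vapply(seq_len(n), function(i) {
    growth_step(patch_state(4, 1), g)$Ns == 2
  }, logical(1))
  expect_lt(abs(mean(slow) - ps), 3 * sqrt(ps * (1 - ps) / n))
})

test_that("host decay probability implements the load-proportional rule", {
  d <- fig_decay()
  K <- 1e4
  expect_identical(host_decay_probability(K, 0, d, K), 0.1)
  expect_identical(host_decay_probability(0, 0, d, K), 0)
  expect_equal(host_decay_probability(0, K, d, K), 0.01)
  expect_error(host_decay_probability(K, 1, d, K), "capacity")

  # bounded by delta_K on all admissible loads
  nf <- c(0, 10, 5000, 9999)
  ns <- c(0, 17, 5000, 1)
  delta <- host_decay_probability(nf, ns, d, K)
  expect_true(all(delta >= 0 & delta <= d$delta_K))
})

test_that("patch quality rescales decay and degrades with fast-type load", {
  d <- fig_decay()
  expect_identical(patch_quality(0, d), 1)
  expect_identical(patch_quality(d$delta_K, d), 0)
  # fully slow-occupied patch: minimal quality (1 - delta_s) * Ns / K = 0.9
  K <- 1e4
  expect_equal(patch_quality(host_decay_probability(0, K, d, K), d), 0.9)
  expect_error(patch_quality(0.2, d), "delta")
  expect_identical(patch_quality(0, decay_params(0, 0.5)), 1)

  # strictly decreasing in Nf at fixed Ns
  rho <- patch_quality(host_decay_probability(0:5 * 1000, 200, d, K), d)
  expect_true(all(diff(rho) < 0))
})

test_that("host mortality draws are binomial in H and delta", {
  expect_identical(host_decay_step(100, 0), 0L)
  expect_identical(host_decay_step(100, 1), 100L)
  set.seed(3)
  n <- 4e3
  deaths <- vapply(seq_len(n), function(i) host_decay_step(100, 0.1), integer(1))
  expect_true(all(deaths >= 0 & deaths <= 100))
  se <- sqrt(100 * 0.1 * 0.9 / n)
  expect_lt(abs(mean(deaths) - 10), 3 * se)
})

test_that("a patch cycle respects capacity, sterility and the zero-time edge", {
  g <- growth_params(c = 0.15, K = 50)
  d <- fig_decay()

  sterile <- run_patch_cycle(c(0, 0), 100, tau = 30, g, d)
  expect_equal(sterile$survivors, 100)
  expect_equal(c(sterile$final_state$Nf, sterile$final_state$Ns), c(0, 0))

  frozen <- run_patch_cycle(c(5, 0), 100, tau = 0, g, d)
  expect_equal(frozen$survivors, 100)
  expect_equal(frozen$final_state$Nf, 5)

  set.seed(4)
  for (i in 1:20) {
    res <- run_patch_cycle(c(3, 2), 10, tau = 100, g, d)
    tot <- res$final_state$Nf + res$final_state$Ns
    expect_lte(tot, g$K)                    # capacity never exceeded
    expect_gte(res$final_state$Nf, 3)       # counts never decrease
    expect_gte(res$final_state$Ns, 2)
    expect_true(res$survivors >= 0 && res$survivors <= 10)
  }
})

test_that("hosts survive longer in slow-type patches (survival ordering)", {
  g <- growth_params(c = 0.15, K = 1000)
  d <- fig_decay()
  set.seed(5)
  n <- 200
  surv <- function(founders) {
    mean(vapply(seq_len(n), function(i) {
      run_patch_cycle(founders, 100, tau = 200, g, d)$survivors
    }, integer(1)))
  }
  s_slow <- surv(c(0, 5))
  s_mix <- surv(c(3, 2))
  s_fast <- surv(c(5, 0))
  expect_gt(s_slow, s_fast)
  expect_true(s_slow >= s_mix && s_mix >= s_fast)
})

test_that("neutral dynamics are invariant under relabelling the two types", {
  g <- growth_params(c = 0, K = 12)
  da <- exact_final_composition_distribution(3, 1, g)
  db <- exact_final_composition_distribution(1, 3, g)
  # mirror: P(Ns = k | start (3,1)) = P(Nf = k | start (1,3))
  expect_equal(da$prob, db$prob[match(da$Ns, db$Nf)])
})

test_that("semi-analytic host survival matches its closed forms and simulation", {
  g <- growth_params(c = 0.15, K = 1000)
  d <- fig_decay()
  expect_identical(expected_host_survival(c(0, 0), 500, g, d), 1)

  gK <- growth_params(c = 0.15, K = 100)
  expect_equal(expected_host_survival(c(100, 0), 40, gK, d),
               (1 - d$delta_K)^40)

  s <- vapply(c(0, 50, 100, 200), function(tau) {
    expected_host_survival(c(5, 0), tau, g, d)
  }, numeric(1))
  expect_true(all(diff(s) <= 0)) # non-increasing in tau

  # single-type founders: deterministic trajectory, so the Monte-Carlo
  # survivor fraction must agree within 3 sigma of the replicate mean
  set.seed(6)
  n <- 300; H <- 100
  frac <- vapply(seq_len(n), function(i) {
    run_patch_cycle(c(5, 0), H, tau = 200, g, d)$survivors / H
  }, numeric(1))
  s_exp <- expected_host_survival(c(5, 0), 200, g, d)
  expect_lt(abs(mean(frac) - s_exp), 3 * sd(frac) / sqrt(n))
})

test_that("the exact enumeration oracle reproduces classical urn results", {
  u <- exact_final_composition_distribution(1, 1, growth_params(c = 0, K = 4))
  expect_equal(u$prob, rep(1 / 3, 3)) # Polya-urn uniformity on {1,2,3}
  expect_equal(u$Ns, 1:3)

  one <- exact_final_composition_distribution(1, 0, growth_params(c = 0.3, K = 4))
  expect_equal(one$Ns, 0)
  expect_equal(one$prob, 1)

  d <- exact_final_composition_distribution(2, 3, growth_params(c = 0.4, K = 30))
  expect_equal(sum(d$prob), 1)
  expect_true(all(d$Nf + d$Ns == 30))

  expect_error(
    exact_final_composition_distribution(1, 1, growth_params(c = 0, K = 500)),
    "too large")
})

test_that("stochastic growth agrees with the enumeration oracle on a small patch", {
  g <- growth_params(c = 0.15, K = 10)
  oracle <- exact_final_composition_distribution(1, 1, g)
  set.seed(8)
  n <- 2e4
  ns_final <- integer(n)
  for (i in seq_len(n)) {
    res <- run_patch_cycle(c(1, 1), 0, tau = g$K, growth_params(c = 0.15, K = 10),
                           decay_params(0, 0))
    ns_final[i] <- res$final_state$Ns
  }
  obs <- tabulate(ns_final, nbins = max(oracle$Ns))[oracle$Ns]
  expect_gt(stats::chisq.test(obs, p = oracle$prob)$p.value, 0.01)
})

test_that("the logistic kernel slows growth without breaking capacity", {
  gl <- growth_params(c = 0.15, K = 50, kernel = "logistic")
  gp <- growth_params(c = 0.15, K = 50)
  set.seed(9)
  tot <- function(g) {
    mean(vapply(1:100, function(i) {
      st <- run_patch_cycle(c(2, 2), 0, tau = 40, g, decay_params(0, 0))$final_state
      st$Nf + st$Ns
    }, numeric(1)))
  }
  t_log <- tot(gl); t_pure <- tot(gp)
  expect_lt(t_log, t_pure)      # density dependence slows the clock
  expect_lte(t_log, 50)
  # at capacity the logistic step is also a no-op
  s <- growth_step(patch_state(50, 0), gl)
  expect_equal(s$Nf, 50)
})
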