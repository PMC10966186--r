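test_that("transition_probability matches the two-state closed forms", {
  er <- mk_params(0.5)
  expect_equal(transition_probability(0, er), diag(2), ignore_attr = TRUE)
  # ER: P_stay(t) = (1 + exp(-2 q t)) / 2
  P <- transition_probability(1, er)
  expect_equal(P[1, 1], (1 + exp(-1)) / 2, tolerance = 1e-12)
  expect_equal(P[1, 1], 0.683940, tolerance = 1e-6 / 0.68394)
  # uniform limit
  Pinf <- transition_probability(1e6, mk_params(0.1))
  expect_equal(as.vector(Pinf), rep(0.5, 4), tolerance = 1e-12)
  # ARD rows are stochastic and converge to the stationary distribution
  ard <- mk_params(0.3, 0.1, "ARD")
  Pa <- transition_probability(2.5, ard)
  expect_equal(rowSums(Pa), c("0" = 1, "1" = 1), tolerance = 1e-12)
  expect_equal(as.vector(transition_probability(1e6, ard)[, 2]),
               rep(0.3 / 0.4, 2), tolerance = 1e-9)
  expect_error(transition_probability(-1, er), "non-negative")
  expect_error(mk_params(0.2, 0.3, "ER"), "q01 == q10")
})

test_that("tree_log_likelihood matches closed forms on a cherry", {
  phy <- read_topology(text = "(A:2,B:2);")
  q <- 0.3; t <- 2
  e <- exp(-2 * q * t)                    # independent closed form
  P00 <- (1 + e) / 2; P10 <- (1 - e) / 2
  ll <- tree_log_likelihood(phy, c(A = 0, B = 0), mk_params(q))
  expect_equal(ll, log((P00^2 + P10^2) / 2), tolerance = 1e-12)
  # no-change limit with a flat prior
  ll0 <- tree_log_likelihood(phy, c(A = 0, B = 0), mk_params(1e-12))
  expect_equal(ll0, log(0.5), tolerance = 1e-9)
  expect_error(tree_log_likelihood(phy, c(A = 0), mk_params(q)), "B")
})

test_that("likelihood equals exhaustive enumeration and ignores child order", {
  set.seed(77)
  for (i in 1:20) {
    phy <- rand_dated_tree(sample(4:7, 1))
    st <- rand_tip_states(phy)
    prm <- mk_params(stats::runif(1, 0.02, 0.6), stats::runif(1, 0.02, 0.6),
                     "ARD", sample(c("flat", "stationary"), 1))
    ll <- tree_log_likelihood(phy, st, prm)
    expect_equal(ll, attr(brute_force_asr(phy, st, prm), "loglik"),
                 tolerance = 1e-10)
    # child-order permutation via ladderizing both ways
    expect_equal(tree_log_likelihood(ape::ladderize(phy, right = TRUE), st, prm), ll,
                 tolerance = 1e-12)
    expect_equal(tree_log_likelihood(ape::ladderize(phy, right = FALSE), st, prm), ll,
                 tolerance = 1e-12)
  }
})

test_that("marginal_asr: tips certain, rows normalized, symmetric root is 50/50", {
  phy <- read_topology(text = "(A:1.5,B:1.5);")
  m <- marginal_asr(phy, c(A = 0, B = 1), mk_params(0.2))
  expect_equal(rowSums(m), rep(1, 3), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unname(m["A", ]), c(1, 0), ignore_attr = TRUE)
  expect_equal(unname(m["B", ]), c(0, 1), ignore_attr = TRUE)
  expect_equal(unname(m[3, ]), c(0.5, 0.5), tolerance = 1e-12)  # symmetry
})

test_that("marginal_asr equals the brute-force oracle on random instances", {
  set.seed(303)
  for (i in 1:30) {
    phy <- rand_dated_tree(sample(4:8, 1))
    st <- rand_tip_states(phy)
    prm <- mk_params(stats::runif(1, 0.01, 0.8), stats::runif(1, 0.01, 0.8),
                     "ARD", sample(c("flat", "stationary"), 1))
    a <- marginal_asr(phy, st, prm)
    b <- brute_force_asr(phy, st, prm)
    expect_lt(max(abs(a - b)), 1e-10)
  }
  big <- rand_dated_tree(15)
  expect_error(brute_force_asr(big, rand_tip_states(big), mk_params(0.1)),
               "too many internal nodes")
})

test_that("brute force limit: vanishing rate pins ancestors to the tip state", {
  phy <- rand_dated_tree(5)
  st <- stats::setNames(rep(1L, 5), phy$tip.label)
  b <- brute_force_asr(phy, st, mk_params(1e-10))
  expect_equal(unname(b[, "p_endo"]), rep(1, nrow(b)), tolerance = 1e-6)
})

test_that("fit_rate_ml: degenerate data, local optimality, recovery", {
  phy <- rand_dated_tree(8)
  same <- stats::setNames(rep(0L, 8), phy$tip.label)
  expect_warning(fit0 <- fit_rate_ml(phy, same), "lower bound")
  expect_equal(fit0$q01, 1e-8)

  set.seed(55)
  phy2 <- rand_dated_tree(16)
  st2 <- rand_tip_states(phy2)
  while (length(unique(st2)) < 2) st2 <- rand_tip_states(phy2)
  fit <- fit_rate_ml(phy2, st2)
  llhat <- attr(fit, "loglik")
  up <- mk_params(fit$q01 * 1.1)
  dn <- mk_params(fit$q01 * 0.9)
  expect_gte(llhat, tree_log_likelihood(phy2, st2, up))
  expect_gte(llhat, tree_log_likelihood(phy2, st2, dn))

  # parameter recovery under the generative twin (scaled to 32 tips x 25
  # replicates to keep the default suite fast; the acceptance run of the
  # same check uses the spec sizes)
  set.seed(66)
  sc <- simulation_scenario(n_extant = 32, n_fossil = 0, death = 0)
  qhat <- replicate(25, {
    tr <- simulate_tree(sc)
    st <- simulate_states(tr, mk_params(0.05))$tip_states
    if (length(unique(st)) < 2) NA_real_ else fit_rate_ml(tr, st)$q01
  })
  expect_gt(sum(!is.na(qhat)), 15)
  med <- stats::median(qhat, na.rm = TRUE)
  expect_gte(med, 0.025); expect_lte(med, 0.1)
})

test_that("fitted likelihood agrees with ape::ace up to its constant offset", {
  # ace sums the root conditionals unweighted, i.e. our flat-prior likelihood
  # plus log(2); the maximized values must coincide after that shift
  set.seed(99)
  phy <- rand_dated_tree(12)
  st <- rand_tip_states(phy)
  while (length(unique(st)) < 2) st <- rand_tip_states(phy)
  fit <- fit_rate_ml(phy, st)
  ac <- ape::ace(factor(st[phy$tip.label]), phy, type = "discrete", model = "ER")
  expect_equal(attr(fit, "loglik") + log(2), ac$loglik, tolerance = 1e-4)
})
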