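# ODE oracle: integrate the extinction and flow equations numerically and
# assemble the same conditioned likelihood. Independent of the analytic
# per-segment solutions used by the package.
ode_bd_loglik <- function(tree, lambda, mu, rho = 1) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  deriv <- function(t, y, parms) {
    E <- y[1]; D <- y[2]
    list(c(mu - (lambda + mu) * E + lambda * E^2,
           -(lambda + mu) * D + 2 * lambda * E * D))
  }
  times <- sort(unique(c(0, ages[internal], ages[root])))
  sol <- deSolve::lsoda(c(E = 1 - rho, D = rho), times, deriv, NULL,
                        rtol = 1e-12, atol = 1e-14)
  Efun <- approxfun(sol[, "time"], sol[, "E"])
  Dfun <- approxfun(sol[, "time"], sol[, "D"])
  sum(log(lambda) + log(Dfun(ages[internal]))) +
    2 * (log(Dfun(ages[root])) - log(1 - Efun(ages[root])))
}

test_that("constant-rate likelihood matches the closed-form Yule oracle", {
  set.seed(31)
  for (i in 1:10) {
    tr <- random_ultra_tree(10)
    lam <- runif(1, 0.2, 2)
    expect_equal(constant_bd_loglik(tr, lam, 0, 1), yule_loglik(tr, lam),
                 tolerance = 1e-10)
  }
})

test_that("constant-rate likelihood matches a numeric ODE oracle", {
  skip_if_not_installed("deSolve")
  set.seed(32)
  for (i in 1:50) {
    tr <- random_ultra_tree(10)
    lam <- runif(1, 0.3, 1.5)
    mu <- runif(1, 0, 0.9 * lam)
    rho <- runif(1, 0.3, 1)
    a <- constant_bd_loglik(tr, lam, mu, rho)
    b <- ode_bd_loglik(tr, lam, mu, rho)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("the lambda == mu limit is finite", {
  tr <- random_ultra_tree(8, seed = 33)
  ll <- constant_bd_loglik(tr, 0.5, 0.5, 1)
  expect_true(is.finite(ll))
  # continuity: approaching the limit from nearby mu
  expect_equal(constant_bd_loglik(tr, 0.5, 0.5 - 1e-9, 1), ll,
               tolerance = 1e-6)
})

test_that("episodic likelihood reduces exactly to the constant-rate case", {
  tr <- random_ultra_tree(12, seed = 34)
  base <- episodic_bd_loglik(tr, episodic_bd_model(0.6, 0.2))
  expect_equal(episodic_bd_loglik(tr, episodic_bd_model(c(0.6, 0.6),
                                                        c(0.2, 0.2),
                                                        boundaries = 0.4)),
               base, tolerance = 1e-12)
  for (t_me in c(0.1, 0.5, 0.9) * max(node_ages(tr))) {
    m <- episodic_bd_model(0.6, 0.2,
                           me_events = list(list(time = t_me, survival = 1)))
    expect_equal(episodic_bd_loglik(tr, m), base, tolerance = 1e-12)
  }
  # survival -> 1 converges to the no-event likelihood
  near <- episodic_bd_model(0.6, 0.2,
                            me_events = list(list(time = 0.5, survival = 1 - 1e-9)))
  expect_equal(episodic_bd_loglik(tr, near), base, tolerance = 1e-6)
})

test_that("likelihood is invariant to tip-label order", {
  tr <- random_ultra_tree(10, seed = 35)
  tr2 <- ape::rotateConstr(tr, sample(tr$tip.label))
  m <- episodic_bd_model(c(0.5, 0.8), c(0.1, 0.3), boundaries = 0.5,
                         me_events = list(list(time = 0.7, survival = 0.2)))
  expect_equal(episodic_bd_loglik(tr, m), episodic_bd_loglik(tr2, m),
               tolerance = 1e-10)
})

test_that("polytomies and non-ultrametric trees are rejected", {
  poly <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(constant_bd_loglik(poly, 1, 0), "polytom")
  nonu <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(constant_bd_loglik(nonu, 1, 0), "ultrametric")
})

test_that("constant-rate ML recovers simulated rates", {
  set.seed(36)
  tr <- ape::rphylo(500, 0.07, 0)
  f <- fit_constant_bd(tr)
  expect_lt(abs(f$lambda_hat - 0.07) / 0.07, 0.15)
  expect_lt(f$mu_hat, 0.01)
  expect_true(all(c("lambda", "mu") %in% names(f$hyperpriors)))
  expect_error(fit_constant_bd(ape::read.tree(text = "(A:1,B:1);")),
               "fewer than 3 tips")
})

test_that("Bayes-factor arithmetic follows the odds definition", {
  # craft a posterior object with known event frequencies
  mk_post <- function(freq, n = 400, nu = 0.5, T_root = 10) {
    has <- seq_len(n) <= round(freq * n)
    structure(list(
      samples = list(me_t = lapply(has, function(h) if (h) 5 else numeric(0)),
                     n_me = as.integer(has),
                     shift_t = replicate(n, numeric(0), simplify = FALSE),
                     n_shift = integer(n)),
      settings = list(max_me = 2L, max_shifts = 2L, event_prior_mean = nu,
                      root_age = T_root)), class = "comet_posterior")
  }
  # choose nu so the prior probability of >=1 event overall is exactly 0.25
  nu25 <- uniroot(function(nu) {
    p <- dpois(0:2, nu); 1 - p[1] / sum(p) - 0.25
  }, c(0.01, 2), tol = 1e-14)$root
  post <- mk_post(0.75, nu = nu25)
  bf <- bayes_factors(post, time_grid = c(0, 10))
  expect_equal(bf$me_overall$BF, (0.75 / 0.25) / (0.25 / 0.75), tolerance = 1e-8)
  expect_equal(bf$me_overall$two_ln_bf, 2 * log(9), tolerance = 1e-8)
  expect_equal(bf$me$label, "none")  # 4.39 < 6
  post99 <- mk_post(0.99, nu = nu25)
  bf99 <- bayes_factors(post99, time_grid = c(0, 10))
  expect_equal(bf99$me_overall$two_ln_bf, 2 * log((0.99 / 0.01) * 3),
               tolerance = 1e-8)
  expect_equal(bf99$me$label, "strong")
  # posterior == prior gives BF 1
  postp <- mk_post(0.25, nu = nu25)
  expect_equal(bayes_factors(postp, c(0, 10))$me_overall$two_ln_bf, 0,
               tolerance = 1e-8)
})

test_that("rates-through-time summaries reproduce the turnover arithmetic", {
  mk <- function(lam, mu) structure(list(
    samples = list(lam0 = lam, mu0 = mu, n_shift = 0L, n_me = 0L,
                   loglik = 0,
                   shift_t = list(numeric(0)), shift_lam = list(numeric(0)),
                   shift_mu = list(numeric(0)),
                   me_t = list(numeric(0)), me_s = list(numeric(0))),
    settings = list(root_age = 100, max_me = 2L, max_shifts = 2L,
                    event_prior_mean = 0.5)), class = "comet_posterior")
  r1 <- rates_through_time(mk(0.07, 0.03), grid = c(0, 50))
  expect_equal(unique(r1$r), 0.04)
  expect_equal(unique(r1$turnover), 0.03 / 0.07, tolerance = 1e-12)
  r2 <- rates_through_time(mk(0.07, 0.04), grid = 0)
  expect_equal(r2$turnover, 4 / 7, tolerance = 1e-12)
  r3 <- rates_through_time(mk(0.07, 0), grid = 0)
  expect_equal(r3$turnover, 0)
  expect_equal(r3$r, 0.07)
  expect_error(rates_through_time(structure(list(
    samples = list(lam0 = numeric(0)), settings = list()),
    class = "comet_posterior")), "empty posterior")
})

test_that("the rjMCMC is seed-deterministic and prior-correct", {
  tr <- ape::rphylo(40, 0.08, 0.02)
  a <- comet_mcmc(tr, n_gen = 2000, thin = 5, seed = 44)
  b <- comet_mcmc(tr, n_gen = 2000, thin = 5, seed = 44)
  expect_identical(a$samples$loglik, b$samples$loglik)
  expect_identical(a$samples$n_me, b$samples$n_me)
  expect_true(all(a$samples$n_me <= 2), all(a$samples$n_shift <= 2))
  # likelihood off: event counts reproduce the truncated compound-Poisson prior
  pr <- comet_mcmc(tr, n_gen = 60000, thin = 20, seed = 45,
                   likelihood = FALSE)
  p <- dpois(0:2, 0.5); p <- p / sum(p)
  tab_me <- table(factor(pr$samples$n_me, levels = 0:2))
  tab_sh <- table(factor(pr$samples$n_shift, levels = 0:2))
  expect_gt(chisq.test(tab_me, p = p)$p.value, 0.01)
  expect_gt(chisq.test(tab_sh, p = p)$p.value, 0.01)
  expect_true(all(c("ess", "geweke_z", "converged") %in%
                    names(a$diagnostics)))
})
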