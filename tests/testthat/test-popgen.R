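test_that("ladder alleles halve the budget per gametogenic mitosis", {
  expect_equal(allele_size(7, M = 10300), 10300 / 128)  # ~80, Volvox sperm
  expect_equal(allele_size(0, M = 10300), 10300)
  expect_equal(allele_size(9, M = 1024), 2)
  expect_error(allele_size(10, M = 1024, d = 9), "0..d")
  expect_error(allele_size(-1, M = 1024), "0..d")
})

test_that("fitness vector collapses to mutant fitness against a fixed partner", {
  cfg <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 4),
                    d = 3, N = 100, generations = 1)
  m <- allele_size(0:3, 100)
  # minus type fixed on allele 2
  st <- population_state(random_freq(4), c(0, 0, 1, 0))
  w <- fitness_vector(st, "plus", cfg)
  expect_equal(w, mutant_fitness(m, m[3], 100, cfg$params))
  # both types fixed on allele 1 (m = 50)
  st2 <- population_state(c(0, 1, 0, 0), c(0, 1, 0, 0))
  w2 <- fitness_vector(st2, "plus", cfg)
  expect_equal(w2[2], (100 / 50) * exp(-1 / 50) * exp(-4 / 100))
  # symmetry under mating-type relabeling when frequencies agree
  st3 <- population_state(random_freq(4), random_freq(4))
  st3_sym <- population_state(st3$freq_plus, st3$freq_plus)
  expect_equal(fitness_vector(st3_sym, "plus", cfg),
               fitness_vector(st3_sym, "minus", cfg))
})

test_that("selection reweights by relative fitness within each type", {
  cfg <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 4),
                    d = 1, N = 100, generations = 1)
  # replicator identity on two alleles with fitnesses w and frequencies x:
  # post frequencies are x w / sum(x w)
  st <- population_state(c(0.5, 0.5), c(0.5, 0.5))
  w <- fitness_vector(st, "plus", cfg)
  post <- selection_step(st, cfg)
  expect_equal(post$freq_plus, (c(0.5, 0.5) * w) / sum(0.5 * w))
  expect_equal(sum(post$freq_plus), 1)
  expect_equal(sum(post$freq_minus), 1)
  # all gametes below the survival threshold: extinction
  cfg_dead <- sim_config(M = 100,
                         params = survival_params(beta = 4, delta = 1000,
                                                  variant = "threshold"),
                         d = 1, N = 100, generations = 1)
  expect_error(selection_step(st, cfg_dead), "extinction")
})

test_that("stepwise mutation moves mu/2 per neighbour with the edge rule", {
  mu <- 1e-3
  T <- mutation_matrix(d = 2, mu = mu)
  # interior allele 1 at frequency 1
  expect_equal(as.vector(T %*% c(0, 1, 0)), c(mu / 2, 1 - mu, mu / 2))
  # edge allele 0 loses only mu/2
  expect_equal(as.vector(T %*% c(1, 0, 0)), c(1 - mu / 2, mu / 2, 0))
  # columns are stochastic, so any frequency vector keeps its mass
  expect_equal(colSums(T), rep(1, 3))
  x <- random_freq(3)
  expect_equal(sum(T %*% x), 1)
  # mu = 0 is the identity
  expect_equal(mutation_matrix(5, 0), diag(6))
  cfg <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 4),
                    d = 2, mu = 0, N = 100, generations = 1)
  st <- population_state(random_freq(3), random_freq(3))
  expect_equal(mutation_step(st, cfg), st)
})

test_that("multinomial drift has the right mean, variance and support", {
  cfg <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 4),
                    d = 1, N = 1e4, generations = 1)
  # degenerate state is unchanged
  st_fixed <- population_state(c(1, 0), c(1, 0))
  expect_equal(drift_step(st_fixed, cfg), st_fixed)
  # Monte-Carlo moments at x = 0.5, N = 1e4
  set.seed(11)
  st <- population_state(c(0.5, 0.5), c(0.5, 0.5))
  reps <- replicate(1e4, drift_step(st, cfg)$freq_plus[1])
  se_mean <- sqrt(0.25 / 1e4) / sqrt(1e4)
  expect_lt(abs(mean(reps) - 0.5), 3 * se_mean)
  expect_equal(var(reps), 0.5 * 0.5 / 1e4, tolerance = 0.1)
  # frequencies are exact multiples of 1/N
  one <- drift_step(st, cfg)
  expect_equal(one$freq_plus * 1e4, round(one$freq_plus * 1e4))
  # infinite N disables drift
  cfg_inf <- sim_config(M = 100, params = survival_params(alpha = 1, beta = 4),
                        d = 1, N = Inf, generations = 1)
  expect_equal(drift_step(st, cfg_inf), st)
})

test_that("frequencies stay normalized through every recursion step", {
  set.seed(21)
  cfg <- volvox_config(d = 9, N = 1e3, generations = 1)
  for (rep in 1:20) {
    st <- population_state(random_freq(10), random_freq(10))
    for (step in list(selection_step, mutation_step, drift_step)) {
      st <- step(st, cfg)
      expect_lt(abs(sum(st$freq_plus) - 1), 1e-12)
      expect_lt(abs(sum(st$freq_minus) - 1), 1e-12)
      expect_true(all(st$freq_plus >= 0))
    }
  }
})

test_that("zero generations report the isogamous initial state", {
  out <- run_simulation(volvox_config(generations = 0, seed = 1))
  expect_equal(out$modal_allele_plus, 0L)
  expect_equal(out$modal_allele_minus, 0L)
  expect_equal(out$ratio, 1)
  expect_equal(out$classification, "isogamy")
})

test_that("outcome classification compares modal alleles symmetrically", {
  base <- run_simulation(volvox_config(generations = 0, seed = 1))
  o1 <- base; o1$modal_allele_plus <- 0L; o1$modal_allele_minus <- 7L
  o2 <- base; o2$modal_allele_plus <- 7L; o2$modal_allele_minus <- 0L
  o3 <- base; o3$modal_allele_plus <- 3L; o3$modal_allele_minus <- 3L
  expect_equal(classify_outcome(o1), "anisogamy")
  expect_equal(classify_outcome(o2), "anisogamy")
  expect_equal(classify_outcome(o3), "isogamy")
})

test_that("deterministic recursion without mutation fixes on the ESS ladder pair", {
  # perturbed isogamic start, drift off: converges to alleles {0, 7}, the
  # ladder points nearest the exact ESS sizes for the Volvox parameters
  cfg <- volvox_config(mu = 0, N = Inf, generations = 3000)
  n <- 10
  fp <- rep(1e-3, n); fp[1] <- 1 - 9e-3
  fm <- rep(1e-3, n); fm[8] <- 1 - 9e-3
  out <- run_simulation(cfg, init = population_state(fp, fm))
  ess <- solve_anisogamous_ess(volvox_params(), M = 10300)
  sizes <- allele_size(0:9, 10300)
  expect_equal(out$modal_allele_plus, which.min(abs(log(sizes / ess$b))) - 1L)
  expect_equal(out$modal_allele_minus, which.min(abs(log(sizes / ess$a))) - 1L)
  expect_equal(out$ratio, 128)
})

test_that("deterministic outcomes are invariant under mating-type relabeling", {
  cfg <- volvox_config(mu = 0, N = Inf, generations = 2000)
  n <- 10
  fp <- rep(1e-3, n); fp[1] <- 1 - 9e-3
  fm <- rep(1e-3, n); fm[8] <- 1 - 9e-3
  out_ab <- run_simulation(cfg, init = population_state(fp, fm))
  out_ba <- run_simulation(cfg, init = population_state(fm, fp))
  expect_equal(out_ab$ratio, out_ba$ratio)
  expect_equal(out_ab$classification, out_ba$classification)
  expect_equal(out_ab$modal_allele_plus, out_ba$modal_allele_minus)
  expect_equal(out_ab$modal_allele_minus, out_ba$modal_allele_plus)
})

test_that("evolved size ratios are powers of two and isogamy persists when stable", {
  # unstable-isogamy run: dimorphism with a power-of-two ratio
  out <- run_simulation(volvox_config(N = 1e3, generations = 3000, seed = 5))
  expect_equal(log2(out$ratio), round(log2(out$ratio)))
  # beta < 4 alpha: both types keep the same modal allele
  cfg_iso <- sim_config(M = 10300,
                        params = survival_params(alpha = 1000, beta = 2000),
                        N = 1e3, generations = 3000, seed = 5)
  out_iso <- run_simulation(cfg_iso)
  expect_equal(out_iso$classification, "isogamy")
  expect_equal(out_iso$ratio, 1)
})
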