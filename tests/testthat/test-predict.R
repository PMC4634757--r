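test_that("symmetric parameters give the uniform posterior", {
  fit <- make_toy_fit(c("a", "b"), beta_mat(rep(0.4, 4)),
                      beta_mat(rep(1.2, 4)))
  ob <- obs_vector("O", c(a = 1L, b = 0L), c(a = 2))
  post <- posterior_stage(fit, ob)
  expect_equal(unname(post$probabilities), rep(0.25, 4), tolerance = 1e-12)
  expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
})

test_that("the two-stage single-gene posterior matches hand Bayes", {
  # p = 1 everywhere (huge logits), fourth-root means PD: 1, PM: 3,
  # resid_sd 0.5, observed y^(1/4) = 1, uniform prior on {PD, PM}:
  # likelihood ratio = exp((4^2 - 0)/(2 * 0.25)) = e^32... restricted to
  # the stated example: posterior PD = 1 / (1 + exp(-8))
  fit <- make_toy_fit("g", beta_mat(rep(30, 4)),
                      beta_mat(c(1, 3, 50, 50)))
  ob <- obs_vector("O", c(g = 1L), c(g = 1))  # y = 1, y^(1/4) = 1
  post <- posterior_stage(fit, ob, prior = c(0.5, 0.5, 0, 0))
  # log L(PD) - log L(PM) = (-(0)^2 + (2)^2 * 4) ... direct: dnorm ratio
  expected_pd <- dnorm(1, 1, 0.5) / (dnorm(1, 1, 0.5) + dnorm(1, 3, 0.5))
  expect_equal(unname(post$probabilities["PD"]), expected_pd,
               tolerance = 1e-10)
  expect_equal(expected_pd, 1 / (1 + exp(-8)), tolerance = 1e-10)
})

test_that("prior odds propagate multiplicatively", {
  fit <- make_toy_fit(c("a", "b"), beta_mat(c(0.5, -0.5, 1, -1)),
                      beta_mat(c(1, 2, 1.5, 2.5)))
  ob <- obs_vector("GC", c(a = 1L, b = 1L), c(a = 3, b = 0.5))
  p1 <- posterior_stage(fit, ob, prior = c(0.25, 0.25, 0.25, 0.25))
  p2 <- posterior_stage(fit, ob, prior = c(0.4, 0.2, 0.2, 0.2))
  odds1 <- p1$probabilities["PD"] / p1$probabilities["PM"]
  odds2 <- p2$probabilities["PD"] / p2$probabilities["PM"]
  expect_equal(unname(odds2 / odds1), 2, tolerance = 1e-10)
})

test_that("binary-only posterior discards level information", {
  # identical detection probabilities across stages, distinct means
  fit <- make_toy_fit("g", beta_mat(rep(0.7, 4)),
                      beta_mat(c(1, 2, 3, 4)))
  ob <- obs_vector("O", c(g = 1L), c(g = 16))
  post_bin <- posterior_stage_binary_only(fit, ob)
  expect_equal(unname(post_bin$probabilities), rep(0.25, 4),
               tolerance = 1e-12)
  post_full <- posterior_stage(fit, ob)
  expect_gt(max(post_full$probabilities), 0.5)  # level separates stages
})

test_that("two-stage Bernoulli example gives 0.9", {
  fit <- make_toy_fit("g", beta_mat(c(qlogis(0.9), qlogis(0.1), -50, -50)),
                      beta_mat(rep(1, 4)))
  ob <- obs_vector("O", c(g = 1L), c(g = 1))
  post <- posterior_stage_binary_only(fit, ob, prior = c(0.5, 0.5, 0, 0))
  expect_equal(unname(post$probabilities["PD"]), 0.9, tolerance = 1e-9)
})

test_that("a flat level model reduces the full posterior to the binary one", {
  fit_flat <- make_toy_fit(c("a", "b"), beta_mat(c(1, 0, -1, 0.5)),
                           beta_mat(c(1, 2, 3, 4)), resid_sd = 1e7)
  ob <- obs_vector("O", c(a = 1L, b = 1L), c(a = 2, b = 5))
  pf <- posterior_stage(fit_flat, ob)
  pb <- posterior_stage_binary_only(fit_flat, ob)
  expect_equal(pf$probabilities, pb$probabilities, tolerance = 1e-6)
})

test_that("posterior equals brute-force Bayes on small panels", {
  set.seed(17)
  for (rep_i in 1:10) {
    n_g <- sample(1:3, 1)
    genes <- paste0("g", seq_len(n_g))
    fit <- make_toy_fit(
      genes,
      beta_mat(rnorm(4)), beta_mat(rnorm(4, mean = 2)),
      modes_b_bin = matrix(rnorm(n_g * 4, sd = 0.5), n_g, 4),
      modes_u_bin = matrix(rnorm(n_g * 2, sd = 0.3), n_g, 2),
      modes_b_lvl = matrix(rnorm(n_g * 4, sd = 0.5), n_g, 4),
      modes_u_lvl = matrix(rnorm(n_g * 2, sd = 0.3), n_g, 2),
      resid_sd = 0.4)
    z <- setNames(rbinom(n_g, 1, 0.7), genes)
    y <- setNames(exp(rnorm(n_g)), genes)[z == 1L]
    ob <- obs_vector(sample(c("O", "GC"), 1), z, y)
    prior <- runif(4); prior <- prior / sum(prior)
    for (variant in c(TRUE, FALSE)) {
      got <- if (variant) posterior_stage(fit, ob, prior)
             else posterior_stage_binary_only(fit, ob, prior)
      want <- oracle_posterior(fit, ob, prior, use_level = variant)
      expect_equal(got$probabilities, want, tolerance = 1e-10)
    }
  }
})

test_that("gene order does not change the posterior", {
  genes <- c("a", "b", "c")
  fit <- make_toy_fit(genes, beta_mat(rnorm(4)), beta_mat(rnorm(4, 2)),
                      modes_b_lvl = matrix(rnorm(12), 3, 4))
  z <- c(a = 1L, b = 0L, c = 1L)
  y <- c(a = 2, c = 0.5)
  p1 <- posterior_stage(fit, obs_vector("O", z, y))
  p2 <- posterior_stage(fit, obs_vector("O", z[c(3, 1, 2)], y[c(2, 1)]))
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})

test_that("an uninformative gene leaves the posterior unchanged", {
  fit1 <- make_toy_fit("a", beta_mat(c(1, 0, -1, 2)),
                       beta_mat(c(1, 2, 3, 4)))
  # gene u cancels the stage structure through its modes, so its
  # parameters are identical across stages
  fitc <- make_toy_fit(c("a", "u"),
                       beta_mat(c(1, 0, -1, 2)), beta_mat(c(1, 2, 3, 4)),
                       modes_b_bin = rbind(rep(0, 4), -c(1, 0, -1, 2)),
                       modes_b_lvl = rbind(rep(0, 4), -c(1, 2, 3, 4)))
  p1 <- posterior_stage(fit1, obs_vector("O", c(a = 1L), c(a = 2)))
  p2 <- posterior_stage(fitc, obs_vector("O", c(a = 1L, u = 1L),
                                         c(a = 2, u = 1)))
  expect_equal(p1$probabilities, p2$probabilities, tolerance = 1e-12)
})

test_that("unknown genes are skipped with a warning", {
  fit <- make_toy_fit("a", beta_mat(rnorm(4)), beta_mat(rnorm(4, 2)))
  ob <- obs_vector("O", c(a = 1L, zz = 1L), c(a = 2, zz = 3))
  expect_warning(post <- posterior_stage(fit, ob), "zz")
  expect_equal(sum(post$probabilities), 1, tolerance = 1e-12)
})

test_that("resampling from a single replicate is degenerate and deterministic", {
  d <- generate_design(1, 1, 0)
  genes <- paste0("g", 1:5)
  rel <- matrix(exp(rnorm(5 * nrow(d))), 5, nrow(d),
                dimnames = list(genes, d$sample_id))
  det <- matrix(1L, 5, nrow(d), dimnames = dimnames(rel))
  vs <- resample_vectors(rel, det, d, "PM", "O", n = 7, seed = 1)
  expect_length(vs, 7L)
  col <- which(d$stage == "PM" & d$compartment == "O")
  for (v in vs) expect_equal(unname(v$y), unname(rel[, col]))
  # determinism under seed
  a <- resample_vectors(rel, det, d, "SC", "GC", 5, seed = 3)
  b <- resample_vectors(rel, det, d, "SC", "GC", 5, seed = 3)
  expect_identical(a, b)
  expect_error(resample_vectors(rel, det, d, "NONE", "MT", 5), "no samples")
})

test_that("resampling draws replicates uniformly", {
  d <- generate_design(4, 4, 0)
  genes <- "g1"
  cols <- which(d$stage == "PD" & d$compartment == "O")
  rel <- matrix(seq_len(nrow(d)), 1, nrow(d),
                dimnames = list(genes, d$sample_id))
  det <- matrix(1L, 1, nrow(d), dimnames = dimnames(rel))
  vs <- resample_vectors(rel, det, d, "PD", "O", n = 4000, seed = 2)
  picked <- vapply(vs, function(v) unname(v$y[1]), 0)
  freq <- table(factor(picked, levels = rel[1, cols]))
  expect_true(all(abs(freq / 4000 - 0.25) < 3 * sqrt(0.25 * 0.75 / 4000)))
})

test_that("evaluate_predictions aggregates posteriors and confusion counts", {
  fit <- make_toy_fit("g", beta_mat(c(5, -5, -5, -5)),
                      beta_mat(rep(1, 4)))
  vecs <- replicate(6, obs_vector("O", c(g = 1L), c(g = 1)),
                    simplify = FALSE)
  rep_ <- evaluate_predictions(fit, list(
    list(stage = "PD", compartment = "O", vectors = vecs)))
  expect_equal(rep_$summary$n, 6L)
  expect_gt(rep_$summary$mean_posterior_true, 0.9)
  expect_equal(sum(rep_$confusion$O["PD", ]), 6L)
  # empty set
  rep0 <- evaluate_predictions(fit, list(
    list(stage = "PM", compartment = "O", vectors = list())))
  expect_equal(rep0$summary$n, 0L)
  expect_true(all(rep0$confusion$O == 0L))
})
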