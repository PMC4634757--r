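test_that("efficiency fit recovers the textbook doubling assay", {
  eff <- fit_efficiency(c(1, 0.1, 0.01), c(20, 23.3219, 26.6439))
  expect_equal(eff$slope, -3.3219, tolerance = 1e-4)
  expect_equal(eff$efficiency, 2, tolerance = 1e-4)
})

test_that("efficiency is invariant to a uniform Ct shift", {
  cts <- c(20, 23.3219, 26.6439)
  a <- fit_efficiency(c(1, 0.1, 0.01), cts)
  b <- fit_efficiency(c(1, 0.1, 0.01), cts + 5)
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$efficiency, b$efficiency, tolerance = 1e-12)
})

test_that("efficiency refit recovers a forward-simulated E exactly", {
  dil <- c(1, 1 / 3, 1 / 9, 1 / 18, 1 / 36)  # the assay's serial scheme
  for (E in c(1.9, 2.0, 1.75)) {
    cts <- 22 - log(dil) / log(E)
    eff <- fit_efficiency(dil, cts)
    expect_equal(eff$efficiency, E, tolerance = 1e-6)
  }
})

test_that("degenerate dilution series are rejected", {
  expect_error(fit_efficiency(c(1, 0.1), c(20, 23)), ">= 3")
  expect_error(fit_efficiency(c(1, 0.1, 0.01), c(20, 18, 16)),
               "quality failure")
})

test_that("Pfaffl quantity follows its defining identities", {
  expect_equal(pfaffl_quantity(19, 20, 2), 2)
  expect_equal(pfaffl_quantity(20, 20, 2), 1)
  expect_equal(pfaffl_quantity(25, 22, 1.9), 1.9^-3, tolerance = 1e-12)
  expect_equal(pfaffl_quantity(25, 22, 1.9), 0.1458, tolerance = 1e-4)
  expect_true(is.na(pfaffl_quantity(NA, 20, 2)))
  # strictly decreasing in ct and multiplicative per cycle
  q1 <- pfaffl_quantity(24, 20, 1.8)
  q2 <- pfaffl_quantity(25, 20, 1.8)
  expect_gt(q1, q2)
  expect_equal(q1, 1.8 * q2, tolerance = 1e-12)
})

test_that("reference normalization divides by the geometric mean", {
  rel <- rbind(ref1 = c(1, 1), ref2 = c(2, 1), ref3 = c(4, 1),
               target = c(8, 3))
  colnames(rel) <- c("s1", "s2")
  out <- normalize_by_references(rel, c("ref1", "ref2", "ref3"))
  expect_equal(out["target", "s1"], 4)        # 8 / (1*2*4)^(1/3)
  expect_equal(out["target", "s2"], 3)        # references all 1
  rel2 <- rel; rel2[1:3, 1] <- 2
  out2 <- normalize_by_references(rel2, c("ref1", "ref2", "ref3"))
  expect_equal(out2["target", "s1"], 4)       # every target divided by 2
})

test_that("ratio structure is preserved under common rescaling", {
  set.seed(1)
  rel <- matrix(exp(rnorm(20)), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  refs <- paste0("g", 1:3)
  base <- normalize_by_references(rel, refs)
  scaled <- normalize_by_references(sweep(rel, 2, c(2, 3, 0.5, 10), "*"),
                                    refs)
  expect_equal(unname(base), unname(scaled), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("samples with undetected references are excluded with a warning", {
  rel <- rbind(r1 = c(1, NA), r2 = c(1, 1), r3 = c(1, 1), t = c(5, 5))
  colnames(rel) <- c("ok", "bad")
  expect_warning(out <- normalize_by_references(rel, c("r1", "r2", "r3")),
                 "bad")
  expect_equal(colnames(out), "ok")
  expect_equal(attr(out, "excluded_samples"), "bad")
})

test_that("geNorm M is zero for perfectly co-regulated candidates", {
  s <- exp(rnorm(6))
  rel <- rbind(a = s, b = 2 * s, c = 0.5 * s)
  colnames(rel) <- paste0("x", 1:6)
  st <- genorm_stability(rel, c("a", "b", "c"))
  expect_true(all(abs(st$M) < 1e-12))
})

test_that("geNorm excludes a planted noisy reference first", {
  n_excluded_first <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    base <- exp(rnorm(50, sd = 1))        # per-sample global scale
    tight <- vapply(1:3, function(i) base * exp(rnorm(50, sd = 0.05 * log(2))),
                    numeric(50))
    noisy <- base * exp(rnorm(50, sd = 1 * log(2)))
    rel <- t(cbind(tight, noisy))
    rownames(rel) <- c("t1", "t2", "t3", "noisy")
    colnames(rel) <- paste0("s", 1:50)
    st <- genorm_stability(rel, rownames(rel))
    if (st$exclusion_order[1] == "noisy") n_excluded_first <- n_excluded_first + 1L
  }
  expect_gte(n_excluded_first, 95L)
})

test_that("geNorm M values ignore per-sample global scaling", {
  set.seed(3)
  rel <- matrix(exp(rnorm(40)), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  a <- genorm_stability(rel, rownames(rel))
  b <- genorm_stability(sweep(rel, 2, exp(rnorm(10)), "*"), rownames(rel))
  expect_equal(a$M, b$M, tolerance = 1e-12)
})

test_that("detection calling applies cutoff and control margin", {
  ct <- rbind(g1 = c(25, NA, 39.5), g2 = c(41, 30, 35))
  colnames(ct) <- paste0("s", 1:3)
  z <- call_detection(ct, cycle_cutoff = 40)
  expect_equal(unname(z["g1", ]), c(1L, 0L, 1L))
  expect_equal(unname(z["g2", ]), c(0L, 1L, 1L))
  # negative control 39.8 with margin 3 kills the 39.5 call
  z2 <- call_detection(ct, 40, negative_controls = c(g1 = 39.8), margin = 3)
  expect_equal(unname(z2["g1", ]), c(1L, 0L, 0L))
  expect_equal(unname(z2["g2", ]), c(0L, 1L, 1L))  # no control for g2
})

test_that("simulated Ct round-trips through quantification and normalization", {
  set.seed(7)
  q_true <- matrix(exp(rnorm(24, sd = 1.2)), 6, 4,
                   dimnames = list(c(paste0("t", 1:3), paste0("r", 1:3)),
                                   paste0("s", 1:4)))
  E <- 1.87
  ct <- ct_from_quantity(q_true, 24, E)
  eff <- fit_efficiency(c(1, 1/3, 1/9, 1/18, 1/36),
                        ct_from_quantity(c(1, 1/3, 1/9, 1/18, 1/36), 24, E))
  rel <- pfaffl_table(ct, eff$efficiency, calibrator = "s1")
  # recover quantities relative to sample s1
  expect_equal(unname(rel), unname(sweep(q_true, 1, q_true[, 1], "/")),
               tolerance = 1e-9, ignore_attr = TRUE)
  norm <- normalize_by_references(rel, paste0("r", 1:3))
  oracle <- sweep(sweep(q_true, 1, q_true[, 1], "/"), 2,
                  exp(colMeans(log(sweep(q_true[4:6, ], 1,
                                         q_true[4:6, 1], "/")))), "/")
  expect_equal(unname(norm), unname(oracle), tolerance = 1e-9,
               ignore_attr = TRUE)
})
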