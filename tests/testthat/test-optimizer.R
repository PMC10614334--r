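sphere <- function(z) sum(z^2)

test_that("circle map iterates by hand and stays on the unit interval", {
  expect_equal(circle_map_next(0.2, 0.5, 0.2), 0.32432, tolerance = 1e-4)
  expect_equal(circle_map_next(0.37, 0, 0), 0.37)  # identity at a = b = 0
  x <- 0.123
  for (i in 1:10000) {
    x <- circle_map_next(x)
    expect_true(x >= 0 && x < 1)
  }
})

test_that("space selection follows the best-anchored contraction", {
  Z <- rbind(c(2, 2), c(0, 0))
  prop <- select_space(Z, z_best = c(1, 1), z_mean = c(0, 0), beta = 2,
                       ra = c(0.5, 0.3))
  expect_equal(prop[1, ], c(-1, -1))                    # hand arithmetic
  prop0 <- select_space(Z, c(1, 1), c(0, 0), beta = 2, ra = c(0, 0))
  expect_equal(prop0[1, ], c(1, 1))                     # ra = 0 -> Z_best
  propm <- select_space(rbind(c(3, 3)), c(1, 1), z_mean = c(3, 3), beta = 2,
                        ra = 0.77)
  expect_equal(propm[1, ], c(1, 1))                     # Z_i = Z_mean -> Z_best
})

test_that("spiral coefficients are normalised and match closed forms", {
  one <- spiral_coeffs(1, phase = "search", draws = list(ran1 = 0.3, ran2 = 0.9))
  expect_lte(abs(one$p), 1)
  expect_lte(abs(one$Y), 1)

  sw <- spiral_coeffs(2, beta = 2, phase = "swoop", draws = list(ran3 = c(0, 0.25)))
  expect_equal(sw$pr[1], 0)          # theta = 0: sinh 0 = 0
  expect_equal(sw$Yr[1], sw$ran[1])  # cosh 0 = 1 (ran = theta = 0 here)

  det <- spiral_coeffs(3, phase = "search", chaotic_polar = TRUE, it = 1)
  expect_equal(det$theta[1], 0.83135, tolerance = 1e-4)
  expect_equal(det$ran[1], 0.5 * atan(1))
})

test_that("search update reduces to hand-computable special cases", {
  Z <- rbind(c(2, 4), c(1, 1))
  id <- search_update(Z, list(p = c(0, 0), Y = c(0, 0)), g = c(1, 1),
                      eta_k = 1, R1 = c(1, 1), z_mean = c(0, 0))
  expect_equal(id, Z)
  half <- search_update(Z, list(p = c(0, 0), Y = c(0, 0)), g = c(2, 2),
                        eta_k = 1, R1 = c(1, 1), z_mean = c(0, 0))
  expect_equal(half, Z / 2)
  # zero gradient gets floored, result stays finite (then clipped by bounds)
  fin <- search_update(Z, list(p = c(0, 0), Y = c(0, 0)), g = c(0, 0),
                       eta_k = 1, R1 = c(1, 1), z_mean = c(0, 0),
                       bounds = c(-5, 5))
  expect_true(all(is.finite(fin)))
  expect_true(all(abs(fin) <= 5))
})

test_that("weighted standard deviation matches its definition", {
  expect_equal(weighted_std(rep(3, 5), runif(5) + 0.1), 0)
  expect_equal(weighted_std(c(1, 3), c(1, 1)), sqrt(2), tolerance = 1e-5)
  set.seed(9)
  z <- rnorm(12); w <- runif(12)
  expect_equal(weighted_std(z, w), weighted_std(z, 7.3 * w))
  expect_error(weighted_std(z, rep(0, 12)), "all zero")
  expect_error(weighted_std(z, w[-1]), "equal length")
})

test_that("swoop update honours the neutral-denominator special cases", {
  Z <- rbind(1); zb <- 2; zm <- 0
  num_only <- swoop_update(Z, zb, zm, list(p = 0.2, Y = 0.1), rand = 0.5,
                           g = 1, V = matrix(0, 1, 1), eta_k = 1, alpha_k = 0,
                           R1 = 1, R2 = 0, sd_w = 2, it1 = 2, it2 = 2)
  expect_equal(num_only[1, 1], 1.8)  # 2 * (1 + 0.2*1 + 0.1*(1-4))

  best <- swoop_update(Z, zb, zm, list(p = 0, Y = 0), rand = 1, g = 1,
                       V = matrix(0, 1, 1), eta_k = 1, alpha_k = 0, R1 = 1,
                       R2 = 0, sd_w = 1)
  expect_equal(best[1, 1], 2)        # Z_best
})

test_that("runs are greedy, deterministic, bounded, and robust to failures", {
  cfg <- ssu_bes_config(dim = 4, pop = 8, iters = 30, bounds = c(-5, 5), seed = 5)
  r1 <- run_ssu_bes(sphere, cfg)
  r2 <- run_ssu_bes(sphere, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_false(is.unsorted(-r1$trace$best_cost))
  expect_true(all(abs(r1$best) <= 5))

  rb <- run_bes(sphere, cfg)
  expect_false(is.unsorted(-rb$trace$best_cost))

  # adversarial objective: errors and NaN become the sentinel, run continues
  nasty <- function(z) {
    u <- sum(z^2)
    if (u > 10) stop("boom")
    if (u > 5) NaN else u
  }
  rn <- run_ssu_bes(nasty, cfg)
  expect_true(is.finite(rn$best_cost))
  expect_false(is.unsorted(-rn$trace$best_cost))
  expect_true(all(is.finite(rn$best)))

  # chaotic_polar variant runs and stays monotone
  cfgp <- ssu_bes_config(dim = 4, pop = 8, iters = 15, bounds = c(-5, 5),
                         seed = 5, chaotic_polar = TRUE)
  rp <- run_ssu_bes(sphere, cfgp)
  expect_false(is.unsorted(-rp$trace$best_cost))
})

test_that("SSU-BES beats an equal-budget random search on the sphere", {
  finals <- sapply(1:20, function(s) {
    cfg <- ssu_bes_config(dim = 5, pop = 10, iters = 40, bounds = c(-5, 5), seed = s)
    c(run_ssu_bes(sphere, cfg)$best_cost, run_random_search(sphere, cfg)$best_cost)
  })
  expect_lte(median(finals[1, ]), median(finals[2, ]))
})

test_that("configuration constraints are enforced", {
  expect_error(ssu_bes_config(dim = 2, beta = 3), "\\[0.5, 2\\]")
  expect_error(ssu_bes_config(dim = 2, it1 = 0.2), "\\[1, 2\\]")
  expect_error(ssu_bes_config(dim = 2, bounds = c(1, -1)), "bounds")
})

test_that("the training objective is reciprocal validation accuracy", {
  set.seed(31)
  X <- matrix(runif(12 * 6), 12, 6)
  y <- rep(c(0L, 1L), 6)
  tri <- tri_classifier_params(6, dbn_sizes = c(4), seed = 31)
  obj <- tri_objective(X, y, tri)
  vec <- encode_solution(tri)
  # independent route: per-trial single predictions
  acc <- mean(sapply(seq_len(nrow(X)), function(i) {
    ensemble_predict(X[i, ], tri)$label
  }) == y)
  expect_equal(obj(vec), 1 / max(acc, 1e-6))
  # closed-form spots of the cost map
  expect_equal(1 / max(0.8, 1e-6), 1.25)
  expect_equal(1 / max(1.0, 1e-6), 1)
  expect_equal(1 / max(0, 1e-6), 1e6)
})
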