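test_that("a noiseless linear ask pattern is recovered exactly", {
  withr::with_seed(3, {
    x <- matrix(rbinom(100 * 12, 1, 0.4), 100, 12)
  })
  y <- x[, 3] # ask flag exactly equals the beef count (0/1 design)
  fit <- fit_term_model(x, y)
  want <- rep(0, 12)
  want[3] <- 1
  expect_equal(unname(fit$coefficients), want, tolerance = 1e-8)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r2i, 1, tolerance = 1e-10)
  expect_equal(fit$n_askers, sum(y))
})

test_that("R2 under independence shrinks like p/(n-1)", {
  withr::with_seed(4, {
    n <- 50000
    x <- matrix(rpois(n * 12, 1), n, 12)
    y <- rbinom(n, 1, 0.05)
  })
  fit <- fit_term_model(x, y)
  expect_lt(fit$r2i, 0.001)
  expect_gt(fit$r2i, 0)
})

test_that("a 3-user system matches the explicit normal-equations solve", {
  x <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2) # users x {food1, food2}
  y <- c(0, 0, 1)
  fit <- fit_term_model(x, y)
  d <- cbind(1, x)
  oracle <- solve(t(d) %*% d, t(d) %*% y)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), oracle[-1, 1], tolerance = 1e-10)
})

test_that("OLS matches the normal equations across random small designs", {
  errs <- withr::with_seed(10, vapply(1:100, function(i) {
    n <- sample(20:50, 1)
    p <- sample(2:6, 1)
    x <- matrix(rpois(n * p, 2), n, p)
    y <- rbinom(n, 1, 0.4)
    if (var(y) == 0 || qr(cbind(1, x))$rank < p + 1) return(0)
    fit <- fit_term_model(x, y)
    d <- cbind(1, x)
    oracle <- drop(solve(crossprod(d), crossprod(d, y)))
    max(abs(c(fit$intercept, fit$coefficients) - oracle))
  }, numeric(1)))
  expect_lt(max(errs), 1e-8)
})

test_that("degenerate designs are rejected or solved minimum-norm", {
  x <- matrix(rbinom(40 * 2, 1, 0.5), 40, 2)
  expect_error(fit_term_model(x, rep(1, 40)), "constant")
  expect_error(fit_term_model(x[1:2, ], c(0, 1)), "at least")
  # duplicated column: rank deficient, warned, fitted values still optimal
  xd <- cbind(x, x[, 1])
  y <- c(rep(0, 20), rep(1, 20))
  expect_warning(fit <- fit_term_model(xd, y), "minimum-norm")
  full <- lm.fit(cbind(1, x), y)
  expect_equal(
    drop(cbind(1, xd) %*% c(fit$intercept, fit$coefficients)),
    unname(full$fitted.values),
    tolerance = 1e-8
  )
})

test_that("CoB12 honors Pearson affine invariance and alignment", {
  foods <- food_reference()
  c_vec <- foods$b12_mcg_100g
  expect_equal(compute_cob12(-c_vec, foods)$cob12, -1, tolerance = 1e-12)
  expect_equal(compute_cob12(c_vec + 5, foods)$cob12, 1, tolerance = 1e-12)
  expect_equal(
    compute_cob12(0.3 * c_vec + 2, foods)$cob12, 1, tolerance = 1e-12
  )
  # textbook Pearson formula as the oracle for an arbitrary vector
  b <- as.numeric(1:12)
  num <- sum((b - mean(b)) * (c_vec - mean(c_vec)))
  den <- sqrt(sum((b - mean(b))^2) * sum((c_vec - mean(c_vec))^2))
  expect_equal(compute_cob12(b, foods)$cob12, num / den, tolerance = 1e-12)
  # named vectors are re-aligned to canonical food order
  named <- setNames(c_vec, foods$food)
  shuffled <- named[rev(foods$food)]
  expect_equal(compute_cob12(shuffled, foods)$cob12, 1, tolerance = 1e-12)
  expect_warning(
    out <- compute_cob12(rep(1, 12), foods), "Zero-variance"
  )
  expect_true(is.na(out$cob12))
})

test_that("model fitting is equivariant to food-column permutation", {
  cfg <- small_config(seed = 121, n_users = 2000)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  prof <- aggregate_users(sim$events, rec, cfg$lexicon)
  foods <- food_reference()
  x <- as.matrix(prof[foods$food])
  y <- prof$ask_gabapentin
  fit <- fit_term_model(x, y)
  perm <- withr::with_seed(2, sample(12))
  fit_p <- fit_term_model(x[, perm], y)
  expect_equal(
    unname(fit_p$coefficients), unname(fit$coefficients[perm]),
    tolerance = 1e-8
  )
  expect_equal(fit_p$r2i, fit$r2i, tolerance = 1e-10)
  # CoB12 likewise unchanged when contents are permuted consistently
  foods_p <- foods[perm, ]
  cb <- compute_cob12(setNames(fit$coefficients, foods$food), foods)
  cb_p <- compute_cob12(setNames(fit_p$coefficients, foods_p$food), foods_p)
  expect_equal(cb_p$cob12, cb$cob12, tolerance = 1e-10)
})

test_that("term ranking sorts by fit, then askers, then label", {
  res <- tibble::tibble(
    term = c("a", "b", "c", "d"),
    set = "target",
    n_askers = c(5L, 10L, 10L, 1L),
    r2i = c(0.2, 0.1, 0.1, 0.3),
    cob12 = 0
  )
  top <- rank_terms(res, k = 3)
  expect_equal(top$term, c("d", "a", "b"))
  expect_equal(rank_terms(res, k = 10)$term, c("d", "a", "b", "c"))
})

test_that("set contrasts are symmetric under relabeling", {
  withr::with_seed(6, {
    res <- tibble::tibble(
      term = paste0("t", 1:24),
      set = rep(c("target", "control"), each = 12),
      n_askers = rep(100L, 24),
      r2i = rep(runif(12, 0.001, 0.01), 2),
      cob12 = rep(runif(12, -0.5, 0.5), 2)
    )
  })
  ct <- contrast_sets(res, k = 10)
  expect_equal(ct$median_ratio, 1)
  expect_equal(ct$mean_cob12_target, ct$mean_cob12_control)
  expect_error(contrast_sets(res[res$set == "target", ]), "nonempty")
  expect_message(contrast_sets(res, k = 20), "Lowering k")
})

test_that("strong target effects separate the sets on synthetic data", {
  cfg <- small_config(seed = 131, n_users = 20000)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  prof <- aggregate_users(sim$events, rec, cfg$lexicon)
  res <- fit_term_models(prof, dplyr::select(cfg$lexicon, term, set))
  ct <- contrast_sets(res)
  expect_lt(ct$mean_cob12_target, 0)
  expect_lt(ct$mean_cob12_target, ct$mean_cob12_control)
  expect_lt(ct$ranksum_p_cob12, 0.05)
  expect_gt(ct$median_ratio, 1)
})

test_that("popularity correlations match a brute-force tied Spearman", {
  res <- tibble::tibble(
    term = paste0("t", 1:5),
    set = "target",
    n_askers = c(10L, 20L, 20L, 40L, 50L),
    r2i = c(0.001, 0.002, 0.003, 0.004, 0.005),
    cob12 = c(-0.1, -0.2, -0.3, -0.4, -0.5)
  )
  out <- popularity_correlations(res)
  rx <- rank(res$n_askers) # average ranks on the tie
  ry <- rank(res$r2i)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(out$rho_r2i_vs_n, rho, tolerance = 1e-12)
  expect_equal(out$rho_r2i_vs_cob12_target, -1, tolerance = 1e-12)
  # strictly monotone pairing gives rho = 1
  res2 <- res
  res2$n_askers <- c(1L, 2L, 3L, 4L, 5L)
  expect_equal(popularity_correlations(res2)$rho_r2i_vs_n, 1)
})

test_that("the tomato negative control flags degenerate ratios", {
  foods <- food_reference()
  res <- tibble::tibble(term = c("a", "b"), set = "target")
  for (f in foods$food) res[[paste0("beta_", f)]] <- c(0.2, 0.4)
  eq <- tomato_check(res, foods)
  expect_equal(eq$ratio, 1)
  res$beta_tomato <- c(0, 0)
  inf <- tomato_check(res, foods)
  expect_true(is.infinite(inf$ratio))
  expect_true(inf$ratio_infinite)
  res$beta_tomato <- NULL
  expect_error(tomato_check(res, foods), "beta_tomato")
})

test_that("tomato coefficients stay small when only B12 content matters", {
  cfg <- small_config(seed = 141, n_users = 20000)
  rec <- simulate_recipes(cfg)
  sim <- simulate_search_log(cfg, rec)
  prof <- aggregate_users(sim$events, rec, cfg$lexicon)
  res <- fit_term_models(prof, dplyr::select(cfg$lexicon, term, set))
  tc <- tomato_check(res)
  expect_gt(tc$ratio, 1)
})
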