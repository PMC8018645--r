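test_that("environmental index is the per-environment variety mean", {
  g <- c(A = 1, B = -1, C = 0); h <- c(E1 = 2, E2 = 0, E3 = -2, E4 = 1)
  mm <- 10 + outer(g, h, "+")
  expect_equal(environmental_index(mm), 10 + mean(g) + h - mean(g),
               tolerance = 1e-12)
  const <- matrix(4, 2, 2, dimnames = list(c("A", "B"), c("E1", "E2")))
  expect_equal(unname(environmental_index(const)), c(4, 4))
  holey <- const; holey[1, 1] <- NA
  expect_error(environmental_index(holey), "missing cell")
})

test_that("FW regression trivial cases and the slope-average identity", {
  I <- c(E1 = 1, E2 = 3, E3 = 7, E4 = 2)
  mm <- rbind(A = I, B = I, C = I)  # every variety tracks the index
  fw <- fw_regression(mm)
  expect_equal(unname(coef(fw)), c(1, 1, 1), tolerance = 1e-12)

  mm2 <- rbind(A = c(1, 2, 3, 6), B = c(5, 5, 5, 5), C = c(0, 1, 2, 5))
  colnames(mm2) <- paste0("E", 1:4)
  fw2 <- fw_regression(mm2)
  expect_equal(unname(coef(fw2))[2], 0, tolerance = 1e-12)  # constant variety
  expect_equal(mean(coef(fw2)), 1, tolerance = 1e-12)

  set.seed(30)
  for (rep in 1:5) {
    mm3 <- toy_means(V = 5, E = 8, seed = rep)
    expect_equal(mean(coef(fw_regression(mm3))), 1, tolerance = 1e-9)
  }
  expect_error(fw_regression(matrix(1, 3, 4)), "degenerate")
})

test_that("FW residuals and fitted values reconstruct the data", {
  mm <- toy_means(V = 4, E = 6, seed = 31)
  fw <- fw_regression(mm)
  expect_equal(fitted(fw) + residuals(fw), mm, tolerance = 1e-12)
  # per-variety OLS oracle via lm()
  I <- colMeans(mm)
  for (v in rownames(mm)) {
    fit <- lm(mm[v, ] ~ I)
    expect_equal(unname(coef(fw)[v]), unname(coef(fit)[2]),
                 tolerance = 1e-9)
  }
})

test_that("ecovalence is zero for additive tables and sums to interaction SS", {
  additive <- 5 + outer(c(1, -1, 0), c(2, 0, -1, -1), "+")
  dimnames(additive) <- list(paste0("V", 1:3), paste0("E", 1:4))
  eco <- ecovalence(additive)
  expect_lt(max(eco$ecovalence), 1e-20)

  mm <- toy_means(V = 5, E = 6, seed = 32)
  eco2 <- ecovalence(mm)
  expect_true(all(eco2$ecovalence >= 0))
  expect_equal(sum(eco2$ecovalence), interaction_ss_bruteforce(mm),
               tolerance = 1e-9)
  expect_equal(sum(eco2$share), 1, tolerance = 1e-12)
})

test_that("single-cell perturbation spreads through the double centring", {
  V <- 4; E <- 5; delta <- 2.7
  base <- 3 + outer(seq_len(V), seq_len(E), "+")  # additive, W = 0
  dimnames(base) <- list(paste0("V", 1:V), paste0("E", 1:E))
  pert <- base; pert[2, 3] <- pert[2, 3] + delta
  eco <- ecovalence(pert)
  # brute-force oracle on the perturbed table
  R <- pert
  R <- sweep(R, 1, rowMeans(R)); R <- sweep(R, 2, colMeans(R))
  expect_equal(eco$ecovalence, rowSums(R^2), tolerance = 1e-9,
               ignore_attr = TRUE)
  # touched variety's contribution matches the closed form
  expect_equal(eco$ecovalence[2],
               ((1 - 1 / V) * (1 - 1 / E) * delta)^2 +
                 (E - 1) * ((1 - 1 / V) * delta / E)^2,
               tolerance = 1e-9)
})

test_that("AMMI identities: centring, orthonormality, SS partition, reconstruction", {
  mm <- toy_means(V = 5, E = 7, seed = 33)
  am <- ammi(mm, K = 2)
  expect_lt(abs(sum(am$g)), 1e-9)
  expect_lt(abs(sum(am$h)), 1e-9)
  expect_equal(t(am$alpha) %*% am$alpha, diag(length(am$lambda)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(t(am$gamma) %*% am$gamma, diag(length(am$lambda)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(sum(am$lambda^2), sum(ecovalence(mm)$ecovalence),
               tolerance = 1e-9)
  full <- fitted(am, K = length(am$lambda))
  expect_equal(full, mm, tolerance = 1e-9)
  expect_error(ammi(mm, K = 10), "K must be")
})

test_that("a planted rank-1 interaction is recovered on one axis", {
  sp <- one_compound_spec(seed = 34, n_varieties = 6, n_locations = 6,
                          sd_gxe = 1.2, sd_eps = 0, interaction_rank = 1)
  mm <- block_means(simulate_panel(sp)$table, compound = "X")
  am <- ammi(mm, K = 1)
  expect_lt(am$lambda[2] / am$lambda[1], 1e-9)
})

test_that("ecovalence and AMMI are invariant to global and environment shifts", {
  mm <- toy_means(V = 4, E = 5, seed = 35)
  shifted <- mm + 11.3
  shifted2 <- sweep(mm, 2, runif(5, -3, 3), "+")
  expect_equal(ecovalence(shifted)$ecovalence,
               ecovalence(mm)$ecovalence, tolerance = 1e-9)
  expect_equal(ecovalence(shifted2)$ecovalence,
               ecovalence(mm)$ecovalence, tolerance = 1e-9)
  expect_equal(ammi(shifted, K = 2)$lambda, ammi(mm, K = 2)$lambda,
               tolerance = 1e-9)
})

test_that("AMMI axis signs follow the deterministic convention", {
  mm <- toy_means(V = 5, E = 6, seed = 36)
  am <- ammi(mm, K = 2)
  for (k in seq_along(am$lambda)) {
    j <- which.max(abs(am$gamma[, k]))
    expect_gt(am$gamma[j, k], 0)
  }
  # flipping input row order must not change the ranking of environments
  am2 <- ammi(mm[rev(rownames(mm)), ], K = 2)
  for (v in rownames(mm))
    expect_equal(best_environments(am2, v)$environment,
                 best_environments(am, v)$environment)
})

test_that("best_environments ranks by the modelled cell mean", {
  additive <- 5 + outer(c(1, -1, 0), c(2, 0, -1, 3), "+")
  dimnames(additive) <- list(paste0("V", 1:3), paste0("E", 1:4))
  am0 <- ammi(additive, K = 0)
  ranks <- lapply(rownames(additive),
                  function(v) best_environments(am0, v)$environment)
  expect_true(all(vapply(ranks, identical, logical(1), ranks[[1]])))

  mm <- toy_means(V = 4, E = 6, seed = 37)
  am_full <- ammi(mm, K = min(dim(mm)) - 1)
  for (v in rownames(mm))
    expect_equal(best_environments(am_full, v)$environment,
                 colnames(mm)[order(-mm[v, ])])
  expect_error(best_environments(am_full, "nope"), "unknown variety")
})

test_that("planted FW slopes are recovered within OLS error on noisy panels", {
  beta <- c(0.5, 0.75, 1.0, 1.25, 1.5)
  sp <- sim_spec(5, 10, 2, 3,
                 compounds = sim_compound("X", mu = 10, sd_g = 1, sd_e = 2,
                                          sd_gxe = 0, sd_eps = 0.6),
                 fw_slopes = beta, block_sd = 0.2, seed = 38)
  mm <- block_means(simulate_panel(sp)$table, compound = "X")
  fw <- fw_regression(mm)
  co <- fw$coefficients
  expect_true(all(abs(co$slope - beta) <= 2 * co$slope_se))
})

test_that("IPC1 scores correlate with planted scores under noise", {
  hits <- 0
  for (seed in 1:40) {
    sp <- one_compound_spec(seed = seed, n_varieties = 6, n_locations = 8,
                            sd_gxe = 1.6, sd_eps = 0.4,
                            interaction_rank = 1)
    pan <- simulate_panel(sp)
    mm <- block_means(pan$table, compound = "X")
    am <- ammi(mm, K = 1)
    planted <- svd(pan$truth$compounds$X$interaction)$u[, 1]
    hits <- hits + (abs(cor(am$alpha[, 1], planted)) > 0.9)
  }
  expect_gt(hits / 40, 0.9)
})
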