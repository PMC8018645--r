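test_that("PCA inertia, orthogonality and reconstruction identities hold", {
  # points exactly on a line: first component carries all inertia
  line <- cbind(1:6, 2 * (1:6))
  fit <- pca(line)
  expect_equal(fit$inertia[1], 1, tolerance = 1e-12)

  set.seed(10)
  m <- matrix(rnorm(15 * 6), 15, 6)
  fit <- pca(m)
  expect_true(all(diff(fit$inertia) <= 1e-12))
  expect_lt(max(abs(colMeans(fit$scores))), 1e-12)
  # score covariance is diagonal with the eigenvalues on the diagonal
  cv <- cov(fit$scores)
  expect_equal(unname(diag(cv)), unname(fit$sdev^2), tolerance = 1e-9)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-9)
  # full-rank reconstruction reproduces the centred input
  centred <- scale(m, scale = FALSE)
  expect_equal(fit$scores %*% t(fit$loadings), unname(centred),
               tolerance = 1e-9, ignore_attr = TRUE)
  # deterministic sign convention: largest |loading| per axis is positive
  for (k in seq_len(ncol(fit$loadings)))
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, k])), k], 0)
})

test_that("triangle area matches hand values and Heron's formula", {
  unit <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(variety_area(unit)$area, 0.5)
  collinear <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))
  expect_equal(variety_area(collinear)$area, 0)
  set.seed(11)
  for (rep in 1:10) {
    p <- matrix(rnorm(9), 3, 3)
    expect_equal(variety_area(p)$area, heron_area(p), tolerance = 1e-9)
  }
  expect_error(variety_area(matrix(0, 2, 3)), "exactly 3 points")
})

test_that("area is rotation-invariant, scales quadratically, and ignores PC signs", {
  set.seed(12)
  p <- matrix(rnorm(9), 3, 3)
  a0 <- variety_area(p)$area
  # random rotation via QR
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(variety_area(p %*% q)$area, a0, tolerance = 1e-9)
  expect_equal(variety_area(3 * p)$area, 9 * a0, tolerance = 1e-9)
  flip <- p; flip[, 2] <- -flip[, 2]
  expect_equal(variety_area(flip)$area, a0, tolerance = 1e-12)
})

test_that("weighted area uses inertia-derived axis weights", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  inertia <- c(0.3, 0.2, 0.1)
  res <- variety_area(p, inertia = inertia)
  w <- inertia / mean(inertia)
  expect_equal(res$weighted_area, 0.5 * w[1] * w[2], tolerance = 1e-12)
  raw <- variety_area(p, inertia = inertia, weight_mode = "raw")
  expect_equal(raw$weighted_area, 0.5 * inertia[1] * inertia[2],
               tolerance = 1e-12)
})

test_that("a variety with an amplified environment response has the largest area", {
  # variety V01 responds 4x more strongly to environments on all compounds
  comp <- rbind(sim_compound("X", mu = 10, sd_e = 2),
                sim_compound("Y", mu = 8, sd_e = 2),
                sim_compound("Z", mu = 12, sd_e = 2))
  beta <- matrix(1, 6, 3); beta[1, ] <- 4
  beta <- sweep(beta, 2, colMeans(beta), "/")  # keep mean slope at 1
  sp <- sim_spec(6, 3, 1, 2, compounds = comp, fw_slopes = beta, seed = 14)
  pan <- simulate_panel(sp)
  sm <- scale_compounds(panel_matrix(pan$table, level = "mean"))
  fit <- pca(sm)
  areas <- pca_areas(fit)
  expect_equal(areas$variety[1], "V01")
})

test_that("Ward clustering recovers separated groups and matches brute force", {
  set.seed(15)
  g1 <- matrix(rnorm(10, 0, 0.1), 5, 2)
  g2 <- matrix(rnorm(10, 5, 0.1), 5, 2)
  m <- rbind(g1, g2)
  rownames(m) <- paste0("V", 1:10)
  wc <- ward_clustering(m, k = 2)
  expect_equal(length(unique(wc$clusters[1:5])), 1)
  expect_equal(length(unique(wc$clusters[6:10])), 1)
  expect_true(wc$clusters[1] != wc$clusters[10])
  expect_error(ward_clustering(m, k = 11), "exceeds")

  # first merge on 3 points equals the pair minimizing the Ward cost
  p3 <- rbind(A = c(0, 0), B = c(1, 0), C = c(5, 0))
  wc3 <- ward_clustering(p3)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  costs <- vapply(pairs, function(ij)
    0.5 * sum((p3[ij[1], ] - p3[ij[2], ])^2), numeric(1))
  best <- pairs[[which.min(costs)]]
  expect_setequal(-wc3$hclust$merge[1, ], best)

  # assignment invariant to input row order
  perm <- c(3, 1, 4, 2, 5:10)
  wc_perm <- ward_clustering(m[perm, ], k = 2)
  expect_equal(unname(wc_perm$clusters[rownames(m)] ==
                        wc_perm$clusters["V1"]),
               unname(wc$clusters[rownames(m)] == wc$clusters["V1"]))
})

test_that("dendrograms export as parseable Newick", {
  set.seed(16)
  m <- matrix(rnorm(8), 4, 2, dimnames = list(paste0("V", 1:4), NULL))
  nwk <- dendrogram_newick(ward_clustering(m))
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("marker screen finds a planted discriminant compound", {
  offs <- data.frame(variety = "V01", compound = "M", offset = 6)
  comp <- rbind(sim_compound("M", mu = 10, sd_g = 0, sd_e = 0.5,
                             sd_gxe = 0, sd_eps = 0.5),
                sim_compound("N1", mu = 10, sd_g = 0, sd_e = 0.5,
                             sd_gxe = 0, sd_eps = 0.5),
                sim_compound("N2", mu = 10, sd_g = 0, sd_e = 0.5,
                             sd_gxe = 0, sd_eps = 0.5))
  sp <- sim_spec(3, 4, 1, 3, compounds = comp, marker_offsets = offs,
                 seed = 17)
  pan <- simulate_panel(sp)
  m <- scale_compounds(panel_matrix(pan$table))
  scr <- marker_screen(m, attr(m, "meta")$variety, n_trees = 100,
                       n_perm = 39, seed = 1)
  expect_equal(scr$compound[1], "M")
  expect_true(scr$selected[scr$compound == "M"])
  # only V01 carries signal; the other two classes stay at chance, so the
  # forest must merely beat the 2/3 all-chance error
  expect_lt(attr(scr, "oob_error"), 2 / 3)
})

test_that("marker screen errors are at chance under permuted labels", {
  sp <- sim_spec(3, 4, 1, 3,
                 compounds = sim_compound("X", sd_g = 0, sd_gxe = 0),
                 seed = 18)
  pan <- simulate_panel(sp)
  m <- scale_compounds(panel_matrix(pan$table))
  set.seed(2)
  labels <- sample(attr(m, "meta")$variety)
  scr <- marker_screen(m, labels, n_trees = 200, n_perm = 9, seed = 3)
  # chance level 1 - 1/3; allow generous Monte-Carlo slack
  expect_gt(attr(scr, "oob_error"), 1 - 1 / 3 - 0.3)
  expect_error(marker_screen(m, rep("A", nrow(m))), "two variety classes")
})
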