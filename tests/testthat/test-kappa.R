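test_that("kappa matches hand-checked contingency values", {
  x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)
  expect_equal(cohen_kappa(x, y), 0)           # p_o = p_e = 0.5
  expect_equal(cohen_kappa(x, x), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0, 0), c(1, 0, 0, 0, 0)),
               (0.8 - 0.56) / 0.44)
  expect_true(is.na(cohen_kappa(c(0, 0, 0), c(0, 1, 0))))
  expect_true(is.na(cohen_kappa(c(1, 1, 1), c(1, 1, 1))))
  expect_error(cohen_kappa(c(1, 0, 2), c(0, 0, 1)), "0/1")
})

test_that("kappa equals the 2x2-contingency oracle exhaustively", {
  # all 16 x 16 pairs of binary vectors of length 4
  grid <- expand.grid(rep(list(0:1), 4))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      x <- as.numeric(grid[i, ]); y <- as.numeric(grid[j, ])
      expect_equal(cohen_kappa(x, y), oracle_kappa(x, y), tolerance = 1e-12)
    }
  }
  # random longer vectors
  withr::with_seed(17, {
    for (r in 1:50) {
      n <- sample(5:6, 1)
      x <- stats::rbinom(n, 1, 0.5); y <- stats::rbinom(n, 1, 0.5)
      expect_equal(cohen_kappa(x, y), oracle_kappa(x, y), tolerance = 1e-12)
    }
  })
})

test_that("the kappa matrix is symmetric, unit-diagonal and matches the
           scalar kappa entrywise", {
  tab <- random_table(60, seed = 41)
  km <- kappa_matrix(tab, "tender", seed = 42)
  m <- unclass(km)
  expect_equal(m, t(m))
  one <- resample_one_per_patient(tab, seed = 42)
  X <- as.matrix(one[flag_columns("tender")])
  colnames(X) <- ra_joints()$joint
  for (pair in list(c("r_wrist", "l_wrist"), c("l_mcp2", "r_pip3"),
                    c("r_knee", "r_mcp5"))) {
    expect_equal(m[pair[1], pair[2]],
                 cohen_kappa(X[, pair[1]], X[, pair[2]]), tolerance = 1e-12)
  }
  nondeg <- !(colMeans(X) %in% c(0, 1))
  expect_equal(unname(diag(m)[nondeg]), rep(1, sum(nondeg)))
})

test_that("an all-zero cohort yields an all-NA kappa matrix", {
  tab <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_assessment(paste0("P", i))
  }))
  km <- kappa_matrix(tab, "tender", seed = 1)
  expect_true(all(is.na(unclass(km))))
})

test_that("perfect left-right mirroring gives within-pair kappa of 1", {
  tab <- random_table(40, seed = 51)
  for (s in joint_sites()) {
    for (sym in c("tender", "swollen")) {
      tab[[paste0("r_", s, "_", sym)]] <- tab[[paste0("l_", s, "_", sym)]]
    }
  }
  km <- unclass(kappa_matrix(tab, "tender", seed = 52))
  for (s in joint_sites()) {
    k <- km[paste0("l_", s), paste0("r_", s)]
    if (!is.na(k)) expect_equal(k, 1)
  }
})

test_that("embedding components are orthonormal and conserve variance", {
  tab <- random_table(80, seed = 61)
  emb <- eigen_embedding(tab, "tender", "all", seed = 62)
  R <- as.matrix(emb$loadings[, grep("^PC", names(emb$loadings))])
  expect_equal(crossprod(R), diag(ncol(R)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(emb$explained), nrow(emb$loadings), tolerance = 1e-8)
  # sign convention: each component's largest-magnitude loading is positive
  for (j in seq_len(ncol(R))) {
    expect_gt(R[which.max(abs(R[, j])), j], 0)
  }
})

test_that("the embedding is invariant to patient row order", {
  tab <- random_table(70, seed = 71)
  one <- resample_one_per_patient(tab, seed = 72)
  emb1 <- eigen_embedding(one, "tender", resample = FALSE)
  shuffled <- withr::with_seed(73, dplyr::slice_sample(one, prop = 1))
  emb2 <- eigen_embedding(shuffled, "tender", resample = FALSE)
  expect_equal(emb1$loadings, emb2$loadings, tolerance = 1e-8)
})

test_that("degenerate joints are dropped with a warning; too few is an error", {
  tab <- dplyr::bind_rows(
    make_assessment("P1", tender = c("r_wrist", "l_knee", "r_mcp2")),
    make_assessment("P2", tender = c("r_wrist", "l_mcp3")),
    make_assessment("P3", tender = c("l_knee", "r_mcp2", "l_mcp3"))
  )
  expect_warning(emb <- eigen_embedding(tab, "tender"), "degenerate")
  expect_equal(sort(emb$loadings$joint),
               sort(c("r_wrist", "l_knee", "r_mcp2", "l_mcp3")))
  all_zero <- dplyr::bind_rows(make_assessment("P1"), make_assessment("P2"),
                               make_assessment("P3"))
  expect_error(suppressWarnings(eigen_embedding(all_zero, "tender")),
               "fewer than 3")
})

test_that("planted two-block structure separates linearly in the embedding", {
  # large_wrist strongly active and internally correlated; mcp likewise;
  # pip silent (dropped): the embedding must separate the two live blocks
  act <- matrix(0, 6, 3); act[1, ] <- c(0.4, 0.4, 0)
  cfg <- cohort_config(
    n_patients = 1500, visits_per_patient = c(1, 1),
    archetype_weights = c(1, 0, 0, 0, 0, 0), archetype_activity = act,
    site_multiplier = stats::setNames(rep(1, 14), joint_sites()),
    within_block_rho = 0.7, between_block_rho = 0, symmetry_rho = 0.7,
    right_bias = 0, shoulder_swell_attenuation = 1, seed = 81
  )
  sim <- generate_cohort(cfg)
  emb <- suppressWarnings(eigen_embedding(sim$assessments, "tender",
                                          seed = 82))
  sep <- group_separation(emb)
  expect_gt(sep$silhouette, 0.4)
})

test_that("group separation handles limit and degenerate geometries", {
  fake <- function(xy, group) {
    joints <- ra_joints()[seq_len(nrow(xy)), ]
    joints$group <- group
    structure(list(
      loadings = dplyr::bind_cols(joints,
                                  tibble::tibble(PC1 = xy[, 1],
                                                 PC2 = xy[, 2])),
      explained = c(1, 1), dropped = character(0), symptom = "tender",
      joint_subset = "all", n_patients = 10L
    ), class = "joint_embedding")
  }
  tight <- fake(rbind(matrix(0, 4, 2), matrix(5, 4, 2)),
                rep(c("a", "b"), each = 4))
  expect_gt(group_separation(tight)$silhouette, 0.95)
  flat <- fake(matrix(0, 6, 2), rep(c("a", "b"), each = 3))
  res <- group_separation(flat)
  expect_true(res$degenerate)
  expect_true(is.na(res$silhouette))
  one_group <- fake(matrix(stats::rnorm(12), 6, 2), rep("a", 6))
  expect_error(group_separation(one_group), "at least 2")
})

test_that("repeats are identical when every patient has a single visit", {
  single <- random_table(50, max_visits = 1, seed = 91)
  rep1 <- suppressWarnings(   # sparse table: some joints are all-zero
    resample_repeats(single, "tender", k_repeats = 3, seed = 92)
  )
  expect_equal(rep1$embeddings[[1]]$loadings,
               rep1$embeddings[[2]]$loadings)
  expect_true(all(rep1$agreement$abs_correlation > 1 - 1e-10))
})

test_that("every resample separates the three planted joint groups", {
  cfg <- cohort_config(n_patients = 1500, within_block_rho = 0.6,
                       between_block_rho = 0.1, seed = 93)
  sim <- generate_cohort(cfg)
  reps <- resample_repeats(sim$assessments, "tender", k_repeats = 5,
                           seed = 94)
  for (e in reps$embeddings) {
    expect_gt(group_separation(e)$silhouette, 0.3)
  }
})

test_that("component loadings are reproducible across resamples when the
           components are well separated", {
  # two active blocks give distinct eigenvalues (severity axis, then the
  # block contrast), so individual components are identifiable; with three
  # symmetric blocks the trailing contrasts are nearly degenerate and only
  # the subspace, not each axis, is stable
  act <- matrix(0, 6, 3); act[1, ] <- c(0.4, 0.4, 0)
  cfg <- cohort_config(
    n_patients = 1500, visits_per_patient = c(2, 6),
    archetype_weights = c(1, 0, 0, 0, 0, 0), archetype_activity = act,
    site_multiplier = stats::setNames(rep(1, 14), joint_sites()),
    within_block_rho = 0.7, between_block_rho = 0.05, symmetry_rho = 0.7,
    right_bias = 0, shoulder_swell_attenuation = 1, seed = 95
  )
  sim <- generate_cohort(cfg)
  reps <- suppressWarnings(
    resample_repeats(sim$assessments, "tender", k_repeats = 5, seed = 96)
  )
  expect_true(all(reps$agreement$abs_correlation > 0.9))
})
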