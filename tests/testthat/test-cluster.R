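test_that("group rates reproduce the worked examples", {
  four_mcp <- make_assessment("P1", tender = c("r_mcp1", "r_mcp2",
                                               "l_mcp3", "l_mcp5"))
  gr <- group_rates(four_mcp)
  expect_equal(gr$mcp, 0.4)
  expect_equal(gr$large_wrist, 0)
  expect_equal(gr$pip, 0)

  pips <- ra_joints()$joint[ra_joints()$group == "pip"]
  all_pip <- make_assessment("P2", tender = pips, swollen = pips)
  expect_equal(group_rates(all_pip)$pip, 2)

  none <- group_rates(make_assessment("P3"))
  expect_equal(unlist(none[, c("large_wrist", "mcp", "pip")]),
               c(large_wrist = 0, mcp = 0, pip = 0))
})

test_that("group rates are bounded and decompose additively", {
  tab <- random_table(40, seed = 11)
  gr <- group_rates(tab)
  rates <- as.matrix(gr[, c("large_wrist", "mcp", "pip")])
  expect_true(all(rates >= 0 & rates <= 2))
  # tender-only + swollen-only contributions sum to the full rate
  tender_only <- tab
  for (col in flag_columns("swollen")) tender_only[[col]] <- 0L
  swollen_only <- tab
  for (col in flag_columns("tender")) swollen_only[[col]] <- 0L
  gt <- group_rates(tender_only)
  gs <- group_rates(swollen_only)
  for (g in c("large_wrist", "mcp", "pip")) {
    expect_equal(gr[[g]], gt[[g]] + gs[[g]])
  }
})

test_that("evaluation sampling caps per patient and hits target_n", {
  two <- dplyr::bind_rows(make_assessment("P1", 1L),
                          make_assessment("P1", 2L))
  expect_equal(nrow(sample_evaluations(two, 6, seed = 1)), 2)

  ten <- dplyr::bind_rows(lapply(1:10, function(v) {
    make_assessment("P1", as.integer(v))
  }))
  expect_equal(nrow(sample_evaluations(ten, 6, seed = 2)), 6)
  expect_error(sample_evaluations(ten, 6, target_n = 7, seed = 3),
               "exceeds")
  pool <- dplyr::bind_rows(ten,
                           make_assessment("P2", 1L),
                           make_assessment("P2", 2L))
  sub <- sample_evaluations(pool, 6, target_n = 5, seed = 4)
  expect_equal(nrow(sub), 5)
  expect_equal(sub, sample_evaluations(pool, 6, target_n = 5, seed = 4))
})

test_that("per-visit retention under the cap is uniform", {
  # 5000 patients with 7 visits, cap 6: each visit kept 6/7 of the time
  n <- 5000
  tab <- tibble::tibble(
    patient_id = rep(sprintf("P%04d", seq_len(n)), each = 7),
    visit_index = rep(1:7, n), visit_year = 2011L
  )
  for (col in flag_columns()) tab[[col]] <- 0L
  kept <- sample_evaluations(tab, 6, seed = 5)
  freq <- as.vector(table(kept$visit_index)) / n
  expect_true(all(abs(freq - 6 / 7) < 0.01))
})

test_that("ward clustering matches the Lance-Williams oracle on small
           instances", {
  withr::with_seed(21, {
    for (r in 1:1000) {
      n <- sample(4:8, 1)
      X <- matrix(stats::runif(n * 3, 0, 2), n, 3)
      model <- ward_cluster(tibble::tibble(
        patient_id = paste0("P", seq_len(n)), visit_index = 1L,
        large_wrist = X[, 1], mcp = X[, 2], pip = X[, 3]
      ), k = 2)
      expect_equal(model$tree$height, oracle_ward_heights(X),
                   tolerance = 1e-8)
    }
  })
})

test_that("ward clustering recovers planted blobs and orders labels by
           activity", {
  withr::with_seed(31, {
    lo <- matrix(stats::rnorm(60 * 3, 0.1, 0.02), 60, 3)
    hi <- matrix(stats::rnorm(40 * 3, 1.5, 0.02), 40, 3)
    X <- rbind(lo, hi)
  })
  feats <- tibble::tibble(patient_id = paste0("P", 1:100), visit_index = 1L,
                          large_wrist = X[, 1], mcp = X[, 2], pip = X[, 3])
  model <- ward_cluster(feats, k = 2)
  expect_equal(model$features$subgroup, rep(c(1L, 2L), c(60, 40)))

  one <- ward_cluster(feats, k = 1)
  expect_true(all(one$features$subgroup == 1L))
  expect_error(ward_cluster(feats[1:3, ], k = 6), "at least k")
})

test_that("characterization conserves shares and reports means", {
  feats <- tibble::tibble(patient_id = paste0("P", 1:50), visit_index = 1L,
                          large_wrist = stats::runif(50, 0, 2),
                          mcp = stats::runif(50, 0, 2),
                          pip = stats::runif(50, 0, 2))
  one <- characterize(ward_cluster(feats, k = 1))
  expect_equal(one$share, 1)
  expect_equal(one$large_wrist, mean(feats$large_wrist))
  six <- characterize(ward_cluster(feats, k = 6))
  expect_equal(sum(six$share), 1, tolerance = 1e-12)
  expect_equal(sum(six$n), 50L)
})

test_that("the regularity rule is strict at the 60% boundary", {
  fake_model <- function(labels_by_patient) {
    feats <- purrr::imap_dfr(labels_by_patient, function(labs, pid) {
      tibble::tibble(patient_id = pid,
                     visit_index = seq_along(labs),
                     large_wrist = 0, mcp = 0, pip = 0,
                     subgroup = labs)
    })
    structure(list(tree = NULL, k = 6L, features = feats, centers = NULL),
              class = "subgroup_model")
  }
  model <- fake_model(list(
    A = c(1, 1, 1, 2),        # 3/4 = 0.75 -> regular
    B = c(1, 1, 1, 2, 3),     # 3/5 = 0.60 -> NOT regular (strict)
    C = c(4, 4, 4, 4, 4),     # 5/5 -> regular
    D = c(1, 2),              # 2 evaluations -> not eligible
    E = c(1, 1, 2, 2)         # 2/4 = 0.5 -> not regular
  ))
  rep <- regularity(model)
  expect_equal(rep$summary$n_eligible, 4L)
  expect_equal(rep$summary$n_regular, 2L)
  p <- rep$patients
  expect_true(p$regular[p$patient_id == "A"])
  expect_false(p$regular[p$patient_id == "B"])
  expect_true(p$regular[p$patient_id == "C"])
  expect_false("D" %in% p$patient_id)
  expect_false(p$regular[p$patient_id == "E"])
})
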