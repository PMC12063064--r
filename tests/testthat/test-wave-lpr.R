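test_that("gap-rule clustering matches hand-derived partitions", {
  p <- cluster_waves(c(5.0, 5.5, 6.0, 8.0), tolerance_mm = 1, linkage = "single")
  expect_equal(p$clusters, list(c(5.0, 5.5, 6.0)))
  expect_equal(p$isolated, 8.0)

  # the linkage choice matters: a chain of 0.8 mm steps spans 1.6 mm
  p_single <- cluster_waves(c(5.0, 5.8, 6.6), 1, "single")
  expect_equal(p_single$clusters, list(c(5.0, 5.8, 6.6)))
  expect_length(p_single$isolated, 0)
  p_complete <- cluster_waves(c(5.0, 5.8, 6.6), 1, "complete")
  expect_equal(p_complete$clusters, list(c(5.0, 5.8)))
  expect_equal(p_complete$isolated, 6.6)

  # a singleton can never be clustered
  p1 <- cluster_waves(7.0, 1)
  expect_length(p1$clusters, 0)
  expect_equal(p1$isolated, 7.0)

  # boundary ties are clustered: the rule is "difference <= tolerance"
  expect_length(cluster_waves(c(5.0, 6.0), 1)$clusters, 1)
  expect_length(cluster_waves(c(5.0, 6.01), 1)$clusters, 0)

  expect_error(cluster_waves(numeric(0), 1), "empty metastasis set")
  expect_error(cluster_waves(c(5, -1), 1), "positive")
})

test_that("LPR formula identities hold", {
  # all clustered -> +1
  all_c <- compute_lpr(cluster_waves(c(5.0, 5.2, 5.4), 1))
  expect_identical(all_c$lpr, 1)
  expect_identical(all_c$sum_isolated, 0L)
  # none clustered -> -1
  none_c <- compute_lpr(cluster_waves(c(5, 10, 20), 1))
  expect_identical(none_c$lpr, -1)
  expect_identical(none_c$sum_clustered, 0L)
  # sum_c = 3, sum_i = 1 -> 0.5
  half <- compute_lpr(cluster_waves(c(5.0, 5.5, 6.0, 8.0), 1))
  expect_equal(half$sum_clustered, 3L)
  expect_equal(half$sum_isolated, 1L)
  expect_equal(half$lpr, 0.5)
})

test_that("per-patient summary composes clustering, LPR and descriptives", {
  s <- summarize_patient(c(6.0, 6.5, 6.5, 12.0), organ = "lung")
  expect_equal(s$n_total, 4L)
  expect_equal(s$largest_diameter_mm, 12.0)
  expect_equal(s$n_waves, 1L)
  expect_equal(s$n_isolated, 1L)
  expect_equal(s$lpr, 0.5)
  expect_false(s$low_n)

  tied <- summarize_patient(c(10, 10, 10), organ = "liver")
  expect_equal(tied$sd_diameter_mm, 0)
  expect_equal(tied$lpr, 1)
  expect_equal(tied$n_waves, 1L)

  single <- summarize_patient(16.0, organ = "liver")
  expect_equal(single$n_total, 1L)
  expect_equal(single$lpr, -1)
  expect_true(single$low_n)
  expect_true(is.na(single$sd_diameter_mm))
})

test_that("organ tolerances default to the measurement precision", {
  expect_equal(default_tolerance("lung"), 1.0)
  expect_equal(default_tolerance("liver"), 3.0)
  expect_error(default_tolerance("bone"))
})

test_that("clustering is conservative, order-free and bounded", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(1:15, 1)
    d <- round(runif(n, 1, 30), 1)
    tol <- sample(c(0.5, 1, 3), 1)
    link <- sample(c("single", "complete"), 1)
    p <- cluster_waves(d, tol, link)
    # conservation of the multiset
    expect_equal(sort(c(unlist(p$clusters), p$isolated)), sort(d))
    # every cluster has >= 2 members
    expect_true(all(lengths(p$clusters) >= 2))
    # permutation invariance
    p2 <- cluster_waves(d[sample.int(length(d))], tol, link)
    expect_identical(p, p2)
    # LPR bounds and conservation
    r <- compute_lpr(p)
    expect_gte(r$lpr, -1); expect_lte(r$lpr, 1)
    expect_equal(r$sum_clustered + r$sum_isolated, n)
    if (link == "single") {
      # within-cluster adjacent gaps <= tol; gaps between blocks > tol
      for (cl in p$clusters) expect_true(all(diff(cl) <= tol))
    } else {
      for (cl in p$clusters) expect_lte(max(cl) - min(cl), tol)
    }
  }
})

test_that("single-linkage partition maximises clustered count (brute force, n <= 8)", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    d <- round(runif(n, 1, 15), 1)
    tol <- sample(c(0.5, 1, 2), 1)
    got <- compute_lpr(cluster_waves(d, tol, "single"))$sum_clustered
    expect_equal(got, brute_force_sigma_c(d, tol, "single"),
                 info = paste(d, collapse = ","))
  }
})

test_that("greedy complete linkage follows the leftmost-first construction", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(2:10, 1)
    d <- sort(round(runif(n, 1, 15), 1))
    tol <- 1
    p <- cluster_waves(d, tol, "complete")
    # reconstruct the greedy blocks independently
    blocks <- list(); cur <- d[1]
    for (x in d[-1]) {
      if (x - cur[1] <= tol) cur <- c(cur, x)
      else { blocks <- c(blocks, list(cur)); cur <- x }
    }
    blocks <- c(blocks, list(cur))
    iso <- unlist(blocks[lengths(blocks) < 2])
    if (is.null(iso)) iso <- numeric(0)
    expect_equal(p$clusters, unname(blocks[lengths(blocks) >= 2]))
    expect_equal(p$isolated, iso)
  }
})

test_that("clustered count grows monotonically with tolerance (single linkage)", {
  set.seed(41)
  for (rep in 1:25) {
    d <- round(runif(sample(3:12, 1), 1, 25), 1)
    tols <- sort(runif(5, 0.1, 6))
    sc <- vapply(tols, function(tt)
      compute_lpr(cluster_waves(d, tt, "single"))$sum_clustered / length(d), 0)
    expect_true(all(diff(sc) >= 0))
  }
})

test_that("degenerate tolerance limits behave as expected", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    d <- round(runif(n, 1, 20), 1)
    # tolerance spanning the whole range clusters everything
    wide <- compute_lpr(cluster_waves(d, max(d) - min(d) + 0.1, "single"))
    expect_equal(wide$lpr, 1)
    # near-zero tolerance clusters only exact ties
    tiny <- cluster_waves(d, 1e-9, "single")
    for (cl in tiny$clusters) expect_true(all(cl == cl[1]))
    expect_equal(sum(lengths(tiny$clusters)), sum(table(d)[table(d) >= 2]))
  }
})

test_that("cohort-level summaries apply organ tolerances per set", {
  mets <- data.frame(
    patient_id = c(rep("P1", 4), rep("P2", 2)),
    organ = c(rep("lung", 4), rep("liver", 2)),
    diameter_mm = c(6.0, 6.5, 6.5, 12.0, 16, 18)
  )
  s <- summarize_cohort(mets)
  expect_equal(nrow(s), 2)
  expect_equal(s$lpr[s$patient_id == "P1"], 0.5)
  # 2 mm apart clusters under the 3 mm liver tolerance
  expect_equal(s$lpr[s$patient_id == "P2"], 1)
  expect_equal(s$tolerance_mm, c(1, 3))
})
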