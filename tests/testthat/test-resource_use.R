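test_that("blank correction subtracts the water control and clamps at zero", {
  expect_equal(blank_correct(0.25, 0.05), 0.20)
  expect_equal(blank_correct(0.03, 0.05), 0)      # clamped
  expect_equal(blank_correct(c(0.1, 0.4), 0), c(0.1, 0.4))  # identity
  expect_error(blank_correct(-0.1, 0.05), "non-negative")
})

test_that("use calls apply the strict > threshold", {
  expect_true(call_resource_use(0.011))
  expect_false(call_resource_use(0.010))
  expect_false(call_resource_use(0))
  expect_error(call_resource_use(0.1, threshold = -0.01), "non-negative")
})

test_that("niche width and efficiency follow the use calls", {
  prof <- toy_profiles(list(full = rep(0.5, 95),
                            none = rep(0, 95),
                            two = c(0.2, 0.1, 0.005),
                            pair = c(0.2, 0.1),
                            single = 0.3))
  nm <- niche_metrics(prof)
  expect_equal(nm$niche_width[nm$isolate_id == "full"], 95)
  expect_equal(nm$niche_width[nm$isolate_id == "none"], 0)
  expect_equal(nm$niche_width[nm$isolate_id == "two"], 2)
  expect_equal(nm$efficiency[nm$isolate_id == "pair"], 0.15)
  expect_equal(nm$efficiency[nm$isolate_id == "single"], 0.3)
  expect_true(is.na(nm$efficiency[nm$isolate_id == "none"]))
})

test_that("niche overlap reproduces its defining cases", {
  a <- pad95(c(0.2, 0.1))
  b <- pad95(c(0.1, 0.3))
  expect_equal(niche_overlap(a, b), 0.75)   # (0.1/0.2 + 0.1/0.1)/2
  expect_equal(niche_overlap(a, a), 1)
  expect_equal(niche_overlap(a, rep(0, 95)), 0)  # disjoint target
  expect_warning(w <- niche_overlap(rep(0, 95), b), "uses no substrate")
  expect_true(is.na(w))
})

test_that("overlap obeys range, self-identity, monotonicity and scale invariance", {
  set.seed(401)
  for (k in 1:50) {
    od_a <- pad95(round(stats::runif(10, 0, 0.6), 3))
    od_b <- pad95(round(stats::runif(10, 0, 0.6), 3))
    if (all(od_a <= 0.01)) od_a[1] <- 0.2
    w <- niche_overlap(od_a, od_b)
    expect_gte(w, 0)
    expect_lte(w, 1)
    expect_equal(niche_overlap(od_a, od_a), 1)
    # raising the target pointwise never lowers the overlap
    bump <- od_b + stats::runif(95, 0, 0.2)
    expect_gte(niche_overlap(od_a, bump), w)
    # common positive rescaling (with the threshold rescaled) is neutral
    expect_equal(niche_overlap(3 * od_a, 3 * od_b, threshold = 0.03), w)
  }
})

test_that("vectorised overlap matrix equals the naive double-loop oracle", {
  set.seed(402)
  for (k in 1:100) {
    n <- sample(3:6, 1)
    ods <- lapply(seq_len(n), function(i) {
      v <- stats::runif(95, 0, 0.5)
      v[stats::runif(95) < 0.5] <- 0
      v
    })
    names(ods) <- paste0("i", seq_len(n))
    prof <- toy_profiles(ods)
    des <- toy_design(names(ods), rep("p1", n))
    om <- suppressWarnings(overlap_matrix(prof, des))
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        expect_equal(om$omega[a, b], naive_overlap(ods[[a]], ods[[b]]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("group overlap summaries match brute-force enumeration", {
  # two identical isolates on one plant
  prof <- toy_profiles(list(a = c(0.2, 0.3), b = c(0.2, 0.3)))
  des <- toy_design(c("a", "b"), c("p1", "p1"))
  expect_equal(overlap_matrix(prof, des)$group_summary$mean_overlap, 1)

  # two disjoint isolates
  prof2 <- toy_profiles(list(a = c(0.2, 0, 0), b = c(0, 0.3, 0.1)))
  expect_equal(overlap_matrix(prof2, des)$group_summary$mean_overlap, 0)

  # three hand-set isolates: 6 ordered pairs
  ods <- list(a = c(0.2, 0.1, 0), b = c(0.1, 0.3, 0), c = c(0.4, 0, 0.2))
  prof3 <- toy_profiles(ods)
  des3 <- toy_design(c("a", "b", "c"), rep("p1", 3))
  om <- overlap_matrix(prof3, des3)
  expect_equal(om$group_summary$n_pairs, 6)
  vals <- c(naive_overlap(ods$a, ods$b), naive_overlap(ods$a, ods$c),
            naive_overlap(ods$b, ods$a), naive_overlap(ods$b, ods$c),
            naive_overlap(ods$c, ods$a), naive_overlap(ods$c, ods$b))
  expect_equal(om$group_summary$mean_overlap, mean(vals),
               tolerance = 1e-12)

  # singleton group summary is undefined, with a message
  des4 <- toy_design(c("a", "b", "c"), c("p1", "p1", "p2"))
  expect_message(om4 <- overlap_matrix(prof3, des4), "single isolate")
  expect_true(is.na(
    om4$group_summary$mean_overlap[om4$group_summary$group == "p2"]))
})

test_that("per-isolate substrate shares sum to one and group SEs behave", {
  ods <- list(a = c(0.2, 0.2, 0.6), b = c(0.2, 0.2, 0.6))
  prof <- toy_profiles(ods)
  des <- toy_design(c("a", "b"), c("p1", "p1"))
  sp <- group_substrate_profile(prof, des, level = "plant")
  expect_equal(sum(sp$mean_share), 1, tolerance = 1e-9)
  expect_equal(sp$mean_share[1:3], c(0.2, 0.2, 0.6))
  expect_true(all(sp$se == 0))  # identical isolates

  ods2 <- list(a = c(0.1, 0.3), b = c(0.3, 0.1))
  prof2 <- toy_profiles(ods2)
  sp2 <- group_substrate_profile(prof2, des, level = "plant")
  # hand arithmetic: shares a = (.25,.75), b = (.75,.25)
  expect_equal(sp2$mean_share[1:2], c(0.5, 0.5))
  expect_equal(sp2$se[1], stats::sd(c(0.25, 0.75)) / sqrt(2))

  # zero-width isolates are excluded with a warning
  ods3 <- c(ods2, list(z = rep(0, 95)))
  prof3 <- toy_profiles(ods3)
  des3 <- toy_design(c("a", "b", "z"), rep("p1", 3))
  expect_warning(sp3 <- group_substrate_profile(prof3, des3,
                                                level = "plant"),
                 "zero total absorbance")
  expect_equal(unique(sp3$n), 2)
})

test_that("share normalisation also supports pooled group profiles", {
  ods <- list(a = c(0.1, 0.3), b = c(0.3, 0.1))
  prof <- toy_profiles(ods)
  des <- toy_design(c("a", "b"), c("p1", "p1"))
  sp <- group_substrate_profile(prof, des, level = "plant",
                                per_isolate = FALSE)
  expect_equal(sp$mean_share[1:2], c(0.5, 0.5))
  expect_equal(sum(sp$mean_share), 1, tolerance = 1e-9)
})
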