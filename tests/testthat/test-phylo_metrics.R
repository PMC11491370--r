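three_tip <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
star4 <- ape::read.tree(text = "(t1:1,t2:1,t3:1,t4:1);")

test_that("Faith's PD matches manual branch sums on the 3-tip tree", {
  expect_equal(faith_pd(three_tip, c("A", "B")), 4)                # 1+1+2
  expect_equal(faith_pd(three_tip, c("A", "B"), include_root = FALSE), 2)
  expect_equal(faith_pd(three_tip, c("A", "B", "C")), 7)
  expect_equal(faith_pd(three_tip, "C"), 3)  # path to root
  expect_error(faith_pd(three_tip, c("A", "Z")), "unknown tip")
  expect_error(faith_pd(three_tip, character(0)), "at least one")
})

test_that("Faith's PD is monotone under adding tips", {
  set.seed(51)
  for (k in 1:20) {
    tr <- ape::rtree(sample(5:15, 1))
    tips <- sample(tr$tip.label, sample(2:4, 1))
    extra <- sample(setdiff(tr$tip.label, tips), 1)
    expect_gte(faith_pd(tr, c(tips, extra)), faith_pd(tr, tips))
    expect_gte(faith_pd(tr, c(tips, extra), include_root = FALSE),
               faith_pd(tr, tips, include_root = FALSE))
  }
})

test_that("Faith's PD agrees with the picante oracle on random trees", {
  skip_if_not_installed("picante")
  set.seed(52)
  for (k in 1:50) {
    tr <- ape::rtree(sample(5:20, 1))
    tips <- sample(tr$tip.label, sample(2:ape::Ntip(tr), 1))
    comm <- matrix(as.integer(tr$tip.label %in% tips), 1,
                   ape::Ntip(tr), dimnames = list("g", tr$tip.label))
    expect_equal(faith_pd(tr, tips),
                 picante::pd(comm, tr, include.root = TRUE)$PD,
                 tolerance = 1e-9)
    expect_equal(faith_pd(tr, tips, include_root = FALSE),
                 picante::pd(comm, tr, include.root = FALSE)$PD,
                 tolerance = 1e-9)
  }
})

test_that("unweighted UniFrac reproduces the star-tree cases", {
  expect_equal(unweighted_unifrac(star4, c("t1", "t2"), c("t1", "t2")), 0)
  expect_equal(unweighted_unifrac(star4, c("t1", "t2"), c("t3", "t4")), 1)
  expect_equal(unweighted_unifrac(star4, c("t1", "t2"), c("t2", "t3")),
               2 / 3)
  expect_error(unweighted_unifrac(star4, character(0), "t1"), "non-empty")
  expect_error(unweighted_unifrac(star4, "t9", "t1"), "unknown tip")
})

test_that("unweighted UniFrac is a metric on random small trees", {
  set.seed(53)
  for (k in 1:20) {
    tr <- ape::rtree(sample(6:12, 1))
    pick <- function() sample(tr$tip.label, sample(2:4, 1))
    a <- pick(); b <- pick(); c <- pick()
    dab <- unweighted_unifrac(tr, a, b)
    expect_equal(dab, unweighted_unifrac(tr, b, a))
    expect_equal(unweighted_unifrac(tr, a, a), 0)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_lte(dab, unweighted_unifrac(tr, a, c) +
                 unweighted_unifrac(tr, c, b) + 1e-12)
  }
})

test_that("pairwise UniFrac agrees with the picante oracle on random trees", {
  skip_if_not_installed("picante")
  set.seed(54)
  for (k in 1:50) {
    tr <- ape::rtree(sample(6:20, 1))
    n <- ape::Ntip(tr)
    groups <- list(g1 = sample(tr$tip.label, sample(2:n, 1)),
                   g2 = sample(tr$tip.label, sample(2:n, 1)),
                   g3 = sample(tr$tip.label, sample(2:n, 1)))
    comm <- t(vapply(groups, function(tp) {
      as.integer(tr$tip.label %in% tp)
    }, integer(n)))
    colnames(comm) <- tr$tip.label
    mine <- pairwise_unifrac(tr, groups)
    ref <- as.matrix(picante::unifrac(comm, tr))
    expect_equal(unname(mine), unname(ref[rownames(mine),
                                          colnames(mine)]),
                 tolerance = 1e-9)
  }
})

test_that("pairwise UniFrac matrix is consistent with the two-group distance", {
  groups <- list(a = c("t1", "t2"), b = c("t2", "t3"))
  d <- pairwise_unifrac(star4, groups)
  expect_equal(dim(d), c(2, 2))
  expect_equal(d["a", "b"],
               unweighted_unifrac(star4, groups$a, groups$b))
  identical4 <- list(a = c("t1", "t2"), b = c("t1", "t2"),
                     c = c("t1", "t2"), d = c("t1", "t2"))
  expect_true(all(pairwise_unifrac(star4, identical4) == 0))
})

test_that("PERMANOVA partitions SS like the direct oracle and vegan", {
  skip_if_not_installed("vegan")
  set.seed(55)
  for (k in 1:10) {
    n <- sample(6:12, 1)
    x <- matrix(stats::rnorm(n * 3), n)
    d <- stats::dist(x)
    groups <- factor(sample(rep(c("u", "v"), length.out = n)))
    if (length(unique(groups)) < 2) next
    df <- data.frame(g = groups)
    res <- permanova(d, df, "g", n_permutations = 49, seed = k)
    oracle <- naive_dist_ss(d, groups)
    expect_equal(res$SS[res$term == "g"], unname(oracle["between"]),
                 tolerance = 1e-9)
    expect_equal(res$SS[res$term == "Residual"],
                 unname(oracle["within"]), tolerance = 1e-9)
    ref <- vegan::adonis2(d ~ g, data = df, permutations = 49,
                          by = "terms")
    expect_equal(res$F[1], ref$F[1], tolerance = 1e-9)
    expect_equal(res$R2[1], ref$R2[1], tolerance = 1e-9)
  }
})

test_that("nested-term PERMANOVA matches vegan's sequential partition", {
  skip_if_not_installed("vegan")
  exp <- simulate_experiment(sim_config(seed = 21))
  pu <- plant_unifrac(exp)
  res <- permanova(pu$d, pu$info, c("richness", "richness:fungicide"),
                   n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(pu$d) ~ richness +
                          richness:fungicide,
                        data = pu$info, permutations = 99, by = "terms")
  expect_equal(res$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_equal(res$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-9)
  expect_equal(res$df[1:2], ref$Df[1:2])
})

test_that("PERMANOVA handles no-signal and degenerate inputs", {
  # two groups with identical composition in distance space
  x <- c(1, 2, 1, 2)
  d <- stats::dist(x)
  df <- data.frame(g = c("a", "a", "b", "b"))
  res <- permanova(d, df, "g", n_permutations = 99, seed = 2)
  expect_equal(res$SS[1], 0, tolerance = 1e-12)
  expect_equal(res$p[1], 1)

  expect_error(permanova(d, data.frame(g = rep("a", 4)), "g",
                         n_permutations = 9), "constant factor")
  expect_error(permanova(stats::dist(c(1, 2)),
                         data.frame(g = c("a", "b")), "g",
                         n_permutations = 9), "degrees of freedom")
})

test_that("PERMANOVA p is invariant to group relabeling and row order", {
  set.seed(56)
  x <- matrix(stats::rnorm(30), 10)
  d <- as.matrix(stats::dist(x))
  g <- rep(c("a", "b"), 5)
  res1 <- permanova(d, data.frame(g = g), "g", n_permutations = 99,
                    seed = 7)
  res2 <- permanova(d, data.frame(g = chartr("ab", "xy", g)), "g",
                    n_permutations = 99, seed = 7)
  expect_equal(res1$F, res2$F)
  expect_equal(res1$p, res2$p)
  ord <- sample(10)
  res3 <- permanova(d[ord, ord], data.frame(g = g[ord]), "g",
                    n_permutations = 99, seed = 7)
  expect_equal(res3$F[1], res1$F[1], tolerance = 1e-9)
  expect_equal(res3$SS, res1$SS, tolerance = 1e-9)
})

test_that("restricted permutation within richness plots is supported", {
  exp <- simulate_experiment(sim_config(seed = 22))
  pu <- plant_unifrac(exp)
  res <- permanova(pu$d, pu$info, c("richness", "richness:fungicide"),
                   n_permutations = 99, seed = 3,
                   strata = pu$info$richness)
  expect_true(all(res$p[1:2] > 0 & res$p[1:2] <= 1))
})

test_that("per-group PD table covers the treatment cells", {
  exp <- simulate_experiment(sim_config(seed = 23))
  iso <- exp$design$isolates
  groups <- split(iso$isolate_id,
                  paste(iso$richness, iso$fungicide, sep = ":"))
  tab <- pd_by_group(exp$tree, groups)
  expect_equal(nrow(tab), 4)
  expect_equal(sum(tab$n_tips), 80)
  whole <- faith_pd(exp$tree, exp$tree$tip.label)
  expect_true(all(tab$pd <= whole + 1e-9))
})
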