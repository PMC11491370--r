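test_that("nested ANOVA conserves SS/df and matches the projection oracle", {
  set.seed(61)
  for (n_per_cell in c(3, 6)) {
    r <- rep(c("mono", "poly"), each = 2 * n_per_cell)
    f <- rep(rep(c("unt", "trt"), each = n_per_cell), 2)
    y <- stats::rnorm(length(r)) + (r == "poly") * 0.5 +
      (f == "trt" & r == "mono") * 0.3
    res <- nested_anova(y, r, f)$table
    # SS and df conservation
    expect_equal(sum(res$SS), sum((y - mean(y))^2), tolerance = 1e-9)
    expect_equal(sum(res$df), length(y) - 1)
    # sequential SS equal the group-mean projections
    oracle <- nested_ss_oracle(y, r, f)
    expect_equal(res$SS, unname(oracle), tolerance = 1e-9)
  }
})

test_that("nested ANOVA handles unbalanced data with sequential SS", {
  set.seed(62)
  r <- c(rep("mono", 7), rep("poly", 11))
  f <- c(rep("unt", 3), rep("trt", 4), rep("unt", 6), rep("trt", 5))
  y <- stats::rnorm(18)
  res <- nested_anova(y, r, f)$table
  oracle <- nested_ss_oracle(y, r, f)
  expect_equal(res$SS, unname(oracle), tolerance = 1e-9)
})

test_that("nested ANOVA degenerate cases behave", {
  r <- rep(c("mono", "poly"), each = 4)
  f <- rep(c("unt", "trt"), 4)
  res <- nested_anova(rep(2, 8), r, f)$table
  expect_equal(res$F[1:2], c(0, 0))
  expect_equal(res$p[1:2], c(1, 1))

  expect_error(nested_anova(stats::rnorm(4), c("m", "m", "p", "p"),
                            c("u", "t", "u", "t")),
               "zero residual degrees of freedom")
  expect_error(nested_anova(stats::rnorm(4), rep("m", 4),
                            factor(rep("u", 4), levels = c("u", "t"))),
               "empty treatment cell|constant|contrasts")
})

test_that("Tukey HSD reduces to the studentized-range closed form for two groups", {
  set.seed(63)
  for (k in 1:10) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2, 0.8)
    res <- tukey_hsd(c(x, y), rep(c("A", "B"), c(n1, n2)))
    s2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    tstat <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
    p_ref <- stats::ptukey(sqrt(2) * abs(tstat), 2, n1 + n2 - 2,
                           lower.tail = FALSE)
    expect_equal(res$pairs$p_adj, p_ref, tolerance = 1e-9)
  }
})

test_that("letter displays summarise the pairwise significance pattern", {
  set.seed(64)
  # four identical groups: everyone shares one letter
  y <- stats::rnorm(32)
  g <- rep(c("a", "b", "c", "d"), each = 8)
  res <- tukey_hsd(y, g)
  expect_false(any(res$pairs$significant))
  expect_true(all(res$letters == "a"))

  # one group shifted by 10 within-group SDs gets a unique letter
  y2 <- y + (g == "d") * 10
  res2 <- tukey_hsd(y2, g)
  others <- paste(res2$letters[c("a", "b", "c")], collapse = "")
  expect_false(any(strsplit(res2$letters[["d"]], "")[[1]] %in%
                     strsplit(others, "")[[1]]))

  # consistency: two groups share a letter iff not significant
  for (r in seq_len(nrow(res2$pairs))) {
    shared <- length(intersect(
      strsplit(res2$letters[[res2$pairs$g1[r]]], "")[[1]],
      strsplit(res2$letters[[res2$pairs$g2[r]]], "")[[1]])) > 0
    expect_equal(shared, !res2$pairs$significant[r])
  }

  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "singleton")
})

test_that("Tukey pairwise p-values are symmetric in group order", {
  set.seed(65)
  y <- stats::rnorm(24)
  g <- rep(c("a", "b", "c"), each = 8)
  res1 <- tukey_hsd(y, g)
  res2 <- tukey_hsd(rev(y), rev(g))
  key1 <- paste(pmin(res1$pairs$g1, res1$pairs$g2),
                pmax(res1$pairs$g1, res1$pairs$g2))
  key2 <- paste(pmin(res2$pairs$g1, res2$pairs$g2),
                pmax(res2$pairs$g1, res2$pairs$g2))
  expect_equal(res1$pairs$p_adj[order(key1)],
               res2$pairs$p_adj[order(key2)], tolerance = 1e-9)
})

test_that("Pearson R2 matches hand computation and guards degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r2(x, 2 * x + 1)$r2, 1)
  # orthogonal contrast: zero correlation by construction
  expect_equal(pearson_r2(c(-1, 0, 1), c(1, -2, 1))$r2, 0,
               tolerance = 1e-12)
  # 5-point hand dataset via the textbook formula
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  res <- pearson_r2(x, y)
  expect_equal(res$r2, r_hand^2, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_warning(cc <- pearson_r2(rep(1, 5), y), "constant")
  expect_true(is.na(cc$r2))
  expect_error(pearson_r2(c(1, 2), c(3, 4)), "at least 3")
})

test_that("FDR adjustment follows the step-up definition and BY dominates BH", {
  expect_equal(fdr_adjust(0.03)$adjusted, 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$adjusted,
               rep(0.04, 4))
  set.seed(66)
  for (k in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    bh <- fdr_adjust(p, "BH")$adjusted
    by <- fdr_adjust(p, "BY")$adjusted
    expect_equal(bh, naive_bh(p), tolerance = 1e-12)
    expect_true(all(by >= bh - 1e-12))
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bh <= 1))
    # monotone in raw-p rank order
    expect_true(all(diff(bh[order(p)]) >= -1e-12))
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("per-substrate tests assemble families, directions and exclusions", {
  exp <- simulate_experiment(null_config(seed = 67))
  prof <- resource_profiles(exp$plates)
  # force one substrate to zero variance everywhere
  prof$od[, "s001"] <- 0.5
  expect_message(res <- per_substrate_tests(prof, exp$design),
                 "zero")
  expect_equal(nrow(res), 95)
  expect_true(all(c("p_fung_monoculture", "p_fung_polyculture",
                    "p_richness", "p_nested_richness",
                    "p_nested_fungicide",
                    "padj_fung_monoculture") %in% names(res)))
  expect_true(is.na(res$p_fung_monoculture[res$substrate == "s001"]))
  ok <- !is.na(res$p_fung_monoculture)
  expect_true(all(res$padj_fung_monoculture[ok] >=
                    res$p_fung_monoculture[ok] - 1e-12))
})

test_that("nutrient correlations are computed per stratum with matching n", {
  exp <- simulate_experiment(sim_config(seed = 68))
  dens <- sample_density(exp$counts)
  corr <- correlate_nutrients(dens$summary, exp$soil, exp$design)
  expect_equal(sort(unique(corr$stratum)),
               c("monoculture", "polyculture"))
  expect_true(all(corr$n == 12))  # 12 samples per richness plot
  expect_true(all(corr$r2 >= 0 & corr$r2 <= 1, na.rm = TRUE))
  expect_equal(corr$r2, corr$r^2, tolerance = 1e-12)
})
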