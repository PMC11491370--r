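# shared fixture builders: everything is generated in code, no files

SUBS <- sprintf("s%03d", 1:95)

pad95 <- function(x) c(x, rep(0, 95 - length(x)))

# build a raw_plates table from a named list of (short) od vectors; the
# water control is 0 so the blank-corrected od equals the input
toy_plates <- function(od_list, water = 0) {
  raw <- do.call(rbind, lapply(od_list, pad95)) + water
  df <- cbind(data.frame(isolate_id = names(od_list), water = water),
              as.data.frame(raw))
  names(df)[-(1:2)] <- SUBS
  attr(df, "substrates") <- SUBS
  class(df) <- c("raw_plates", "data.frame")
  df
}

toy_profiles <- function(od_list, threshold = 0.01) {
  resource_profiles(toy_plates(od_list), threshold = threshold)
}

# minimal design: one plant per unique plant label, all isolates known
toy_design <- function(iso_ids, plants,
                       richness = rep("mono", length(iso_ids)),
                       fungicide = rep("unt", length(iso_ids))) {
  iso <- data.frame(isolate_id = iso_ids, richness = richness,
                    fungicide = fungicide, plant = plants)
  plant_rows <- unique(iso[c("richness", "fungicide", "plant")])
  samples <- data.frame(sample_id = paste0("S.", plant_rows$plant),
                        plant_rows)
  suppressWarnings(experiment_design(samples, iso))
}

# naive double-loop oracle for the asymmetric overlap statistic
naive_overlap <- function(od_a, od_b, threshold = 0.01) {
  acc <- 0
  n <- 0
  for (i in seq_along(od_a)) {
    if (od_a[i] > threshold) {
      acc <- acc + min(od_a[i], od_b[i]) / od_a[i]
      n <- n + 1
    }
  }
  if (n == 0) NA_real_ else acc / n
}

# naive O(m^2) step-up BH oracle
naive_bh <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    ri <- rank(p, ties.method = "max")[i]
    min(1, min(vapply(seq_len(m), function(j) {
      rj <- rank(p, ties.method = "max")[j]
      if (p[j] >= p[i]) m * p[j] / rj else Inf
    }, numeric(1))))
  }, numeric(1))
}

# brute-force sequential SS for the nested layout, from group means
nested_ss_oracle <- function(y, r, f) {
  gm <- mean(y)
  rmean <- stats::ave(y, r)
  cellmean <- stats::ave(y, r, f)
  c(richness = sum((rmean - gm)^2),
    nested = sum((cellmean - rmean)^2),
    residual = sum((y - cellmean)^2))
}

# direct within/between SS partition of a distance matrix, one factor
naive_dist_ss <- function(d, groups) {
  m <- as.matrix(d)
  n <- nrow(m)
  ss_total <- sum(m[lower.tri(m)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    mm <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(mm[lower.tri(mm)]^2) / length(idx)
  }
  c(between = ss_total - ss_within, within = ss_within,
    total = ss_total)
}

# plant-level unifrac matrix + factors, the input PERMANOVA consumes
plant_unifrac <- function(experiment) {
  iso <- experiment$design$isolates
  groups <- split(iso$isolate_id, iso$plant)
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  uf <- pairwise_unifrac(experiment$tree, groups)
  info <- unique(iso[c("plant", "richness", "fungicide")])
  info <- info[match(rownames(uf), info$plant), ]
  list(d = uf, info = info)
}
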