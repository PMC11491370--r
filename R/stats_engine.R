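#' Nested analysis of variance: fungicide within richness
#'
#' Fits the classical nested fixed-effects model with sequential (Type I)
#' sums of squares, richness entered first and the fungicide term nested
#' within richness (`y ~ richness + richness:fungicide`). Both terms are
#' tested against the residual mean square, treating plants (or isolates)
#' within subplots as replicates. Terms with zero sum of squares report
#' `F = 0, p = 1`.
#'
#' @param values numeric response vector.
#' @param richness,fungicide factors (or coercible) aligned with `values`.
#' @return list of class `nested_anova` with `table` (data.frame `term`,
#'   `df`, `SS`, `MS`, `F`, `p`; terms `richness`,
#'   `fungicide_in_richness`, `Residual`) and the fitted `aov` object.
#' @export
nested_anova <- function(values, richness, fungicide) {
  richness <- factor(richness)
  fungicide <- factor(fungicide)
  stopifnot(length(values) == length(richness),
            length(values) == length(fungicide))
  if (anyNA(values)) {
    keep <- !is.na(values)
    values <- values[keep]
    richness <- droplevels(richness[keep])
    fungicide <- droplevels(fungicide[keep])
  }
  cells <- table(richness, fungicide)
  if (any(cells == 0)) stop("empty treatment cell", call. = FALSE)
  fit <- stats::aov(values ~ richness + richness:fungicide)
  if (stats::df.residual(fit) < 1) {
    stop("zero residual degrees of freedom: need >= 2 observations in ",
         "some cell", call. = FALSE)
  }
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  out <- data.frame(term = c("richness", "fungicide_in_richness",
                             "Residual"),
                    df = s$Df[match(c("richness", "richness:fungicide",
                                      "Residuals"), terms)],
                    SS = s$`Sum Sq`[match(c("richness",
                                            "richness:fungicide",
                                            "Residuals"), terms)])
  out$MS <- out$SS / out$df
  ms_res <- out$MS[out$term == "Residual"]
  # a term SS at rounding-noise scale is an exact zero
  tiny <- sqrt(.Machine$double.eps) * (sum(values^2) + 1)
  null_term <- out$SS < tiny
  out$F <- ifelse(out$term == "Residual", NA,
                  ifelse(null_term, 0, out$MS / ms_res))
  out$p <- ifelse(out$term == "Residual", NA,
                  ifelse(null_term, 1,
                         stats::pf(out$F, out$df,
                                   out$df[out$term == "Residual"],
                                   lower.tail = FALSE)))
  structure(list(table = out, fit = fit), class = "nested_anova")
}

#' @export
print.nested_anova <- function(x, ...) {
  cat("Nested ANOVA (fungicide within richness, sequential SS):\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# compact letter display by insert-and-absorb: groups sharing a letter are
# not significantly different; ties broken by group order
letter_display <- function(groups, sig_pairs) {
  k <- length(groups)
  sets <- list(rep(TRUE, k))  # each set of groups becomes one letter
  sp <- sig_pairs[sig_pairs$significant, , drop = FALSE]
  for (r in seq_len(nrow(sp))) {
    i <- match(sp$g1[r], groups)
    j <- match(sp$g2[r], groups)
    nxt <- list()
    for (s in sets) {
      if (s[i] && s[j]) {
        s1 <- s; s1[i] <- FALSE
        s2 <- s; s2[j] <- FALSE
        nxt <- c(nxt, list(s1), list(s2))
      } else {
        nxt <- c(nxt, list(s))
      }
    }
    nxt <- nxt[!duplicated(vapply(nxt, paste, character(1),
                                  collapse = ""))]
    # absorb sets that are subsets of another
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) {
      for (b in seq_along(nxt)) {
        if (a != b && keep[a] && keep[b] &&
            all(nxt[[a]] | !nxt[[b]]) &&
            !identical(nxt[[a]], nxt[[b]])) {
          keep[b] <- FALSE
        }
      }
    }
    sets <- nxt[keep]
  }
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(sets, `[`, logical(1), i))], collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' Tukey HSD pairwise comparisons with a compact letter display
#'
#' Studentized-range (Tukey, Tukey-Kramer for unequal group sizes)
#' pairwise comparisons of all group means after a one-way fit, plus a
#' compact letter display assigned by the insert-and-absorb algorithm: two
#' groups share a letter iff they are not significantly different at
#' `alpha`. Letters are assigned in the order groups first appear.
#'
#' @param values numeric response.
#' @param groups group labels aligned with `values`.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list of class `tukey_hsd` with `pairs` (data.frame `g1`, `g2`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`) and `letters` (named
#'   character vector group -> letters).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  g <- factor(groups, levels = unique(as.character(groups)))
  stopifnot(length(values) == length(g))
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop("singleton group(s): ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(g1 = vapply(nm, `[`, character(1), 2),
                      g2 = vapply(nm, `[`, character(1), 1),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  pairs$significant <- pairs$p_adj < alpha
  lets <- letter_display(levels(g), pairs)
  structure(list(pairs = pairs, letters = lets, alpha = alpha),
            class = "tukey_hsd")
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat("Tukey HSD pairwise comparisons (alpha =", x$alpha, "):\n")
  print(x$pairs, row.names = FALSE)
  cat("Letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Squared Pearson correlation with its two-sided p-value
#'
#' @param x,y numeric vectors, `n >= 3`, non-constant.
#' @return list `r` (correlation), `r2`, `p` (two-sided, from the t
#'   transform on n-2 df), `n`; `r2` and `p` are `NA` for constant input.
#' @export
pearson_r2 <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, r2 = NA_real_, p = NA_real_,
                n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p = ct$p.value, n = length(x))
}

#' False-discovery-rate adjustment (Benjamini-Hochberg / Benjamini-Yekutieli)
#'
#' Step-up adjusted p-values; BY multiplies the BH factor by the harmonic
#' sum over the family size and is therefore never smaller than BH.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\] (`NA` allowed
#'   and preserved).
#' @param method `"BH"` (default) or `"BY"`.
#' @param q discovery level for the `discoveries` field (default 0.05).
#' @return list of class `fdr_result`: `raw`, `adjusted`, `method`, `q`,
#'   `discoveries` (logical, adjusted <= q).
#' @export
fdr_adjust <- function(pvalues, method = c("BH", "BY"), q = 0.05) {
  method <- match.arg(method)
  ok <- stats::na.omit(pvalues)
  if (any(ok < 0 | ok > 1)) stop("p-values must lie in [0, 1]",
                                 call. = FALSE)
  adj <- stats::p.adjust(pvalues, method = method)
  structure(list(raw = pvalues, adjusted = adj, method = method, q = q,
                 discoveries = !is.na(adj) & adj <= q),
            class = "fdr_result")
}

#' Per-carbon-source treatment tests with FDR control
#'
#' For each of the 95 substrates, tests the blank-corrected absorbance
#' for (a) a fungicide effect within each richness level (pairwise
#' two-sample test, Welch by default), (b) a richness effect (pairwise
#' test pooling fungicide levels), and (c) the nested ANOVA terms. Each
#' test family is FDR-adjusted across substrates. Substrates with zero
#' variance everywhere in a family are excluded from that family with a
#' message and carry `NA`.
#'
#' @param profiles a [resource_profiles()] object.
#' @param design an [experiment_design()].
#' @param pairwise `"welch"` (default), `"student"` or `"mann-whitney"`.
#' @param fdr_method `"BH"` (default) or `"BY"`.
#' @param q discovery level (default 0.05).
#' @return data.frame with one row per substrate: raw and adjusted p per
#'   family (`p_fung_<richness>`, `p_richness`, `p_nested_richness`,
#'   `p_nested_fungicide`, and matching `padj_*` columns) plus the
#'   direction of the fungicide effect per richness level
#'   (`delta_fung_<richness>`, treated minus untreated mean).
#' @export
per_substrate_tests <- function(profiles, design, pairwise = "welch",
                                fdr_method = "BH", q = 0.05) {
  stopifnot(inherits(profiles, "resource_profiles"))
  ids <- rownames(profiles$od)
  info <- design_lookup(design, ids)
  rich_levels <- intersect(design$richness_levels, info$richness)
  fung_levels <- intersect(design$fungicide_levels, info$fungicide)
  if (length(fung_levels) != 2) {
    stop("per-substrate fungicide tests need exactly two fungicide levels",
         call. = FALSE)
  }

  pair_p <- function(x, y) {
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    if (stats::sd(c(x, y)) == 0) return(NA_real_)
    switch(pairwise,
      welch = stats::t.test(x, y)$p.value,
      student = stats::t.test(x, y, var.equal = TRUE)$p.value,
      `mann-whitney` = stats::wilcox.test(x, y, exact = FALSE)$p.value,
      stop("unknown pairwise test: ", pairwise, call. = FALSE))
  }

  subs <- colnames(profiles$od)
  res <- data.frame(substrate = subs)
  for (rl in rich_levels) {
    sel1 <- info$richness == rl & info$fungicide == fung_levels[1]
    sel2 <- info$richness == rl & info$fungicide == fung_levels[2]
    res[[paste0("p_fung_", rl)]] <- vapply(subs, function(s) {
      pair_p(profiles$od[sel1, s], profiles$od[sel2, s])
    }, numeric(1))
    res[[paste0("delta_fung_", rl)]] <- vapply(subs, function(s) {
      mean(profiles$od[sel2, s]) - mean(profiles$od[sel1, s])
    }, numeric(1))
  }
  if (length(rich_levels) == 2) {
    selr1 <- info$richness == rich_levels[1]
    selr2 <- info$richness == rich_levels[2]
    res$p_richness <- vapply(subs, function(s) {
      pair_p(profiles$od[selr1, s], profiles$od[selr2, s])
    }, numeric(1))
    nested <- vapply(subs, function(s) {
      v <- profiles$od[, s]
      if (stats::sd(v) == 0) return(c(NA_real_, NA_real_))
      tab <- nested_anova(v, info$richness, info$fungicide)$table
      c(tab$p[tab$term == "richness"],
        tab$p[tab$term == "fungicide_in_richness"])
    }, numeric(2))
    res$p_nested_richness <- nested[1, ]
    res$p_nested_fungicide <- nested[2, ]
  }

  pcols <- grep("^p_", names(res), value = TRUE)
  dropped <- unique(res$substrate[rowSums(is.na(res[pcols])) > 0])
  if (length(dropped)) {
    message(length(dropped), " substrate(s) with undefined tests (zero ",
            "variance) excluded from the affected FDR families")
  }
  for (col in pcols) {
    res[[sub("^p_", "padj_", col)]] <-
      fdr_adjust(res[[col]], method = fdr_method, q = q)$adjusted
  }
  rownames(res) <- NULL
  res
}

#' Pearson correlations of density metrics against soil nutrients
#'
#' Correlates per-sample density responses (total density, inhibitor
#' density, inhibitory proportion) with each nutrient, within each level
#' of a stratifying factor (default richness, pairing the samples of one
#' plot).
#'
#' @param density_summary the `summary` element of [sample_density()].
#' @param soil soil table from [read_soil()].
#' @param design an [experiment_design()].
#' @param within design column to stratify by (default `"richness"`).
#' @return data.frame `stratum`, `response`, `nutrient`, `r`, `r2`, `p`,
#'   `n`.
#' @export
correlate_nutrients <- function(density_summary, soil, design,
                                within = "richness") {
  info <- design_lookup(design, density_summary$sample_id)
  strata <- info[[within]]
  nutrients <- c("C_pct", "N_pct", "P_ppm", "K_ppm", "OM_pct", "pH")
  responses <- c("total_cfu_g", "inhibitor_cfu_g", "proportion")
  soil_m <- soil[match(density_summary$sample_id, soil$sample_id), ]
  out <- list()
  for (st in unique(strata)) {
    sel <- strata == st
    for (rp in responses) {
      for (nu in nutrients) {
        r <- pearson_r2(density_summary[[rp]][sel], soil_m[[nu]][sel])
        out[[length(out) + 1]] <-
          data.frame(stratum = st, response = rp, nutrient = nu,
                     r = r$r, r2 = r$r2, p = r$p, n = r$n)
      }
    }
  }
  do.call(rbind, out)
}
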