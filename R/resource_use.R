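#' Blank-correct a plate row against its water control
#'
#' Subtracts the water-control absorbance from every carbon-source well and
#' clamps negative differences to zero (negative growth is unphysical and
#' the overlap statistic requires non-negative absorbances).
#'
#' @param raw numeric vector of raw well absorbances (AU590).
#' @param water scalar water-control absorbance (AU590).
#' @return numeric vector `pmax(raw - water, 0)`.
#' @export
blank_correct <- function(raw, water) {
  stopifnot(is.numeric(raw), is.numeric(water), length(water) == 1)
  if (any(raw < 0) || water < 0) stop("absorbances must be non-negative",
                                      call. = FALSE)
  pmax(raw - water, 0)
}

#' Call carbon-source use from blank-corrected absorbances
#'
#' A substrate is used when its blank-corrected absorbance strictly exceeds
#' the threshold (default 0.01 AU590): 0.011 is a use, 0.010 is not.
#'
#' @param od numeric vector of blank-corrected absorbances.
#' @param threshold use threshold in AU590; must be non-negative.
#' @return logical vector, `od > threshold`.
#' @export
call_resource_use <- function(od, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    stop("threshold must be a single non-negative number", call. = FALSE)
  }
  od > threshold
}

#' Build resource-use profiles from a raw plate table
#'
#' Blank-corrects every isolate's wells and applies the use threshold,
#' yielding the per-isolate absorbance and use-call matrices all downstream
#' niche metrics consume.
#'
#' @param plates a `raw_plates` table from [read_plate_table()] (or any
#'   data.frame with `isolate_id`, `water` and substrate columns).
#' @param threshold use threshold in AU590 (default 0.01, strict `>`).
#' @return An object of class `resource_profiles`: list with `od` and
#'   `used` matrices (isolates x substrates, rownames = isolate ids),
#'   and the `threshold`.
#' @export
resource_profiles <- function(plates, threshold = 0.01) {
  substrates <- attr(plates, "substrates")
  if (is.null(substrates)) {
    substrates <- setdiff(names(plates), c("isolate_id", "water"))
  }
  if (length(substrates) != N_SUBSTRATES) {
    stop("expected 95 carbon-source wells, found ", length(substrates),
         call. = FALSE)
  }
  raw <- as.matrix(plates[substrates])
  od <- t(vapply(seq_len(nrow(raw)),
                 function(i) blank_correct(raw[i, ], plates$water[i]),
                 numeric(length(substrates))))
  dimnames(od) <- list(plates$isolate_id, substrates)
  used <- call_resource_use(od, threshold)
  structure(list(od = od, used = used, threshold = threshold),
            class = "resource_profiles")
}

#' @export
print.resource_profiles <- function(x, ...) {
  cat("Resource-use profiles:", nrow(x$od), "isolates x", ncol(x$od),
      "carbon sources (use threshold", x$threshold, "AU590)\n")
  invisible(x)
}

#' Niche width and growth efficiency per isolate
#'
#' Niche width is the number of used substrates (0-95). Growth efficiency
#' is the mean blank-corrected absorbance over used substrates only, and is
#' `NA` for an isolate that uses none (an empty mean is undefined, not 0).
#'
#' @param profiles a [resource_profiles()] object.
#' @return data.frame with columns `isolate_id`, `niche_width`,
#'   `efficiency`.
#' @export
niche_metrics <- function(profiles) {
  stopifnot(inherits(profiles, "resource_profiles"))
  width <- rowSums(profiles$used)
  eff <- vapply(seq_len(nrow(profiles$od)), function(i) {
    u <- profiles$used[i, ]
    if (!any(u)) NA_real_ else mean(profiles$od[i, u])
  }, numeric(1))
  data.frame(isolate_id = rownames(profiles$od),
             niche_width = as.integer(width),
             efficiency = eff,
             row.names = NULL)
}

#' Asymmetric pairwise niche overlap
#'
#' For isolates `a` and `b`, the overlap of `a` onto `b` is the mean, over
#' the substrates that `a` uses, of `min(od_a, od_b) / od_a`: the fraction
#' of `a`'s realised niche that `b` matches. The statistic is asymmetric —
#' in general the overlap of `a` onto `b` differs from that of `b` onto
#' `a`. The sum runs only over `a`'s used substrates (where `od_a` exceeds
#' the use threshold), so no division by zero arises and self-overlap is 1.
#'
#' @param od_a,od_b numeric vectors of blank-corrected absorbances on the
#'   same substrates, in the same order.
#' @param threshold use threshold defining `a`'s used set.
#' @return overlap in \[0, 1\], or `NA` (with a warning) when `a` uses no
#'   substrate.
#' @export
niche_overlap <- function(od_a, od_b, threshold = 0.01) {
  stopifnot(length(od_a) == length(od_b))
  used_a <- call_resource_use(od_a, threshold)
  if (!any(used_a)) {
    warning("overlap undefined: source isolate uses no substrate",
            call. = FALSE)
    return(NA_real_)
  }
  mean(pmin(od_a[used_a], od_b[used_a]) / od_a[used_a])
}

#' All ordered pairwise niche overlaps, with within-group summaries
#'
#' Computes the full matrix of ordered-pair overlaps and summarises it
#' within groups (by default the plant of origin, the grouping at which the
#' sharing of carbon sources between co-occurring isolates is assessed):
#' the group value is the mean overlap over all ordered pairs of distinct
#' isolates in the group.
#'
#' @param profiles a [resource_profiles()] object.
#' @param design an [experiment_design()] whose isolates cover the profile
#'   rownames.
#' @param group_by design column to group by: `"plant"` (default),
#'   `"richness"` or `"fungicide"` (cells are formed by richness x
#'   fungicide when `"fungicide"` is chosen).
#' @return list of class `overlap_matrix` with elements `omega` (square
#'   matrix, rows = source isolate `a`, columns = target `b`), `groups`
#'   (per-isolate group label) and `group_summary` (data.frame `group`,
#'   `n_isolates`, `n_pairs`, `mean_overlap`; `NA` summary for singleton
#'   groups).
#' @export
overlap_matrix <- function(profiles, design, group_by = "plant") {
  stopifnot(inherits(profiles, "resource_profiles"))
  ids <- rownames(profiles$od)
  if (length(ids) < 2) stop("need at least two profiles", call. = FALSE)
  info <- design_lookup(design, ids)
  groups <- switch(group_by,
    plant = info$plant,
    richness = info$richness,
    fungicide = paste(info$richness, info$fungicide, sep = ":"),
    stop("unknown group_by: ", group_by, call. = FALSE))

  od <- profiles$od
  used <- profiles$used
  n <- nrow(od)
  omega <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  width <- rowSums(used)
  for (a in seq_len(n)) {
    if (width[a] == 0) next
    ua <- used[a, ]
    oa <- od[a, ua]
    # all targets at once: pmin against each row of od[, ua]
    tgt <- od[, ua, drop = FALSE]
    omega[a, ] <- rowMeans(sweep(pmin(tgt,
                                      matrix(oa, n, length(oa),
                                             byrow = TRUE)),
                                 2, oa, "/"))
  }
  if (any(width == 0)) {
    warning(sum(width == 0), " isolate(s) with zero niche width: ",
            "overlaps from them are undefined", call. = FALSE)
  }

  summ <- do.call(rbind, lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      message("group '", g, "' has a single isolate; overlap summary ",
              "undefined")
      return(data.frame(group = g, n_isolates = length(idx),
                        n_pairs = 0L, mean_overlap = NA_real_))
    }
    vals <- omega[idx, idx][row(omega[idx, idx]) != col(omega[idx, idx])]
    data.frame(group = g, n_isolates = length(idx),
               n_pairs = length(vals),
               mean_overlap = mean(vals, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  structure(list(omega = omega, groups = groups, group_by = group_by,
                 group_summary = summ),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Niche-overlap matrix:", nrow(x$omega), "isolates, grouped by",
      x$group_by, "\n")
  print(x$group_summary)
  invisible(x)
}

#' Per-isolate mean overlap with co-occurring isolates
#'
#' Summarises the overlap matrix to one value per isolate: the mean of the
#' ordered overlaps from that isolate onto every other isolate of its
#' group. This is the per-isolate response analysed against the treatment
#' design.
#'
#' @param om an [overlap_matrix()] result.
#' @return data.frame `isolate_id`, `group`, `mean_overlap`.
#' @export
isolate_overlap <- function(om) {
  stopifnot(inherits(om, "overlap_matrix"))
  ids <- rownames(om$omega)
  val <- vapply(seq_along(ids), function(a) {
    idx <- setdiff(which(om$groups == om$groups[a]), a)
    if (!length(idx)) return(NA_real_)
    mean(om$omega[a, idx])
  }, numeric(1))
  data.frame(isolate_id = ids, group = om$groups, mean_overlap = val,
             row.names = NULL)
}

#' Group-level carbon-source utilisation profile
#'
#' Normalises each isolate's blank-corrected absorbances to shares of its
#' total resource use (shares sum to 1 per isolate), then averages shares
#' across the isolates of each treatment group and reports the standard
#' error of that mean. Isolates with zero niche width carry no share
#' information and are excluded with a warning. Set
#' `per_isolate = FALSE` to pool absorbances across the group before
#' normalising instead.
#'
#' @param profiles a [resource_profiles()] object.
#' @param design an [experiment_design()].
#' @param level grouping: `"cell"` (richness x fungicide, default),
#'   `"richness"` or `"plant"`.
#' @param per_isolate normalise per isolate before averaging (default) or
#'   pool the group's absorbances first.
#' @return data.frame `group`, `substrate`, `mean_share`, `se`, `n`.
#' @export
group_substrate_profile <- function(profiles, design, level = "cell",
                                    per_isolate = TRUE) {
  stopifnot(inherits(profiles, "resource_profiles"))
  ids <- rownames(profiles$od)
  info <- design_lookup(design, ids)
  groups <- switch(level,
    cell = paste(info$richness, info$fungicide, sep = ":"),
    richness = info$richness,
    plant = info$plant,
    stop("unknown level: ", level, call. = FALSE))

  tot <- rowSums(profiles$od)
  keep <- tot > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep),
            " isolate(s) with zero total absorbance", call. = FALSE)
  }
  od <- profiles$od[keep, , drop = FALSE]
  groups <- groups[keep]
  if (!nrow(od)) stop("no isolates with non-zero resource use",
                      call. = FALSE)

  out <- lapply(unique(groups), function(g) {
    m <- od[groups == g, , drop = FALSE]
    if (!nrow(m)) stop("empty group: ", g, call. = FALSE)
    if (per_isolate) {
      shares <- m / rowSums(m)
      mu <- colMeans(shares)
      se <- apply(shares, 2, stats::sd) / sqrt(nrow(shares))
    } else {
      pooled <- colSums(m)
      mu <- pooled / sum(pooled)
      se <- rep(NA_real_, length(mu))
    }
    data.frame(group = g, substrate = colnames(od), mean_share = mu,
               se = se, n = nrow(m), row.names = NULL)
  })
  do.call(rbind, out)
}
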