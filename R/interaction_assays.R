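#' Soil suspension specification
#'
#' Mass of dry soil suspended and the suspension volume used for dilution
#' plating; defaults are 5 g of soil in 25 mL of sterile water.
#'
#' @param soil_mass_g grams of dry soil (default 5).
#' @param suspension_volume_ml suspension volume in mL (default 25).
#' @return list of class `suspension_spec`.
#' @export
suspension_spec <- function(soil_mass_g = 5, suspension_volume_ml = 25) {
  if (soil_mass_g <= 0 || suspension_volume_ml <= 0) {
    stop("soil mass and suspension volume must be > 0", call. = FALSE)
  }
  structure(list(soil_mass_g = soil_mass_g,
                 suspension_volume_ml = suspension_volume_ml),
            class = "suspension_spec")
}

#' Colony-forming units per gram of soil
#'
#' Standard plate-count arithmetic: the plated aliquot of `plated_volume`
#' mL at dilution `dilution` contained `count` colony-forming units, so the
#' suspension holds `count / (plated_volume * dilution)` CFU/mL and the
#' soil `suspension_volume / soil_mass` times that per gram.
#'
#' @param count colony count (non-negative; vectorised).
#' @param dilution dilution factor in (0, 1], e.g. `1e-2` (vectorised).
#' @param plated_volume_ml plated volume in mL (vectorised).
#' @param spec a [suspension_spec()].
#' @return CFU per gram of dry soil.
#' @export
cfu_per_gram <- function(count, dilution, plated_volume_ml,
                         spec = suspension_spec()) {
  stopifnot(inherits(spec, "suspension_spec"))
  if (any(count < 0)) stop("colony count must be non-negative",
                           call. = FALSE)
  if (any(dilution <= 0) || any(plated_volume_ml <= 0)) {
    stop("dilution and plated volume must be > 0", call. = FALSE)
  }
  (count / (plated_volume_ml * dilution)) *
    (spec$suspension_volume_ml / spec$soil_mass_g)
}

#' Per-sample densities and inhibitory fractions from dilution plates
#'
#' Converts every plate's counts to CFU/g first (so mixed dilutions are
#' handled correctly), then averages: the total density over all of a
#' sample's plates, and the inhibitor density per indicator overlay over
#' that overlay's plates. The inhibitory proportion is inhibitor density /
#' total density, per overlay and averaged over overlays; proportions above
#' 1 (possible because overlay and density counts are noisy) are reported
#' with a warning, not clipped, and a zero total density yields `NA`.
#'
#' @param counts a counts table as returned by [read_counts()].
#' @param spec a [suspension_spec()].
#' @return list of class `sample_density` with `totals` (data.frame
#'   `sample_id`, `total_cfu_g`), `by_overlay` (data.frame `sample_id`,
#'   `overlay`, `inhibitor_cfu_g`, `proportion`) and `summary` (data.frame
#'   `sample_id`, `total_cfu_g`, `inhibitor_cfu_g` and `proportion`
#'   averaged over overlays).
#' @export
sample_density <- function(counts, spec = suspension_spec()) {
  if (!nrow(counts)) stop("no count plates supplied", call. = FALSE)
  counts$total_cfu_g <- cfu_per_gram(counts$total_colonies,
                                     counts$dilution, counts$volume_ml,
                                     spec)
  counts$inhib_cfu_g <- cfu_per_gram(counts$inhibitory_colonies,
                                     counts$dilution, counts$volume_ml,
                                     spec)

  samples <- unique(counts$sample_id)
  totals <- data.frame(
    sample_id = samples,
    total_cfu_g = vapply(samples, function(s) {
      mean(counts$total_cfu_g[counts$sample_id == s])
    }, numeric(1)),
    row.names = NULL)

  ov <- counts[counts$overlay != "none", , drop = FALSE]
  by_overlay <- if (nrow(ov)) {
    key <- unique(ov[c("sample_id", "overlay")])
    key$inhibitor_cfu_g <- mapply(function(s, o) {
      mean(ov$inhib_cfu_g[ov$sample_id == s & ov$overlay == o])
    }, key$sample_id, key$overlay)
    tot <- totals$total_cfu_g[match(key$sample_id, totals$sample_id)]
    key$proportion <- ifelse(tot > 0, key$inhibitor_cfu_g / tot, NA_real_)
    rownames(key) <- NULL
    key
  } else {
    data.frame(sample_id = character(), overlay = character(),
               inhibitor_cfu_g = numeric(), proportion = numeric())
  }
  if (any(stats::na.omit(by_overlay$proportion) > 1)) {
    warning("inhibitory proportion > 1 for some sample/overlay ",
            "combinations (overlay counts exceed density counts); ",
            "reported unclipped", call. = FALSE)
  }

  summary <- totals
  summary$inhibitor_cfu_g <- vapply(summary$sample_id, function(s) {
    v <- by_overlay$inhibitor_cfu_g[by_overlay$sample_id == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  summary$proportion <- ifelse(summary$total_cfu_g > 0,
                               summary$inhibitor_cfu_g /
                                 summary$total_cfu_g, NA_real_)

  structure(list(totals = totals, by_overlay = by_overlay,
                 summary = summary),
            class = "sample_density")
}

#' @export
print.sample_density <- function(x, ...) {
  cat("Streptomyces dilution-plate densities for", nrow(x$totals),
      "samples\n")
  print(utils::head(x$summary))
  invisible(x)
}

#' Inhibitory proportion of a community
#'
#' @param total_density total CFU/g (must be > 0 for a defined value).
#' @param inhibitor_density inhibitor CFU/g.
#' @return `inhibitor_density / total_density`; `NA` when the total is 0;
#'   values above 1 trigger a warning but are not clipped.
#' @export
inhibitor_proportion <- function(total_density, inhibitor_density) {
  out <- ifelse(total_density > 0, inhibitor_density / total_density,
                NA_real_)
  if (any(stats::na.omit(out) > 1)) {
    warning("inhibitor density exceeds total density; proportion > 1 ",
            "reported unclipped", call. = FALSE)
  }
  out
}

#' Zone size from paired right-angle radial measurements
#'
#' A zone (inhibition or resistance) is measured twice from the edge of the
#' colony or disk to the edge of the clearing, at right angles; its size is
#' the mean of the two radii (mm).
#'
#' @param radius1_mm,radius2_mm the two radial measurements, mm
#'   (vectorised).
#' @return mean radius, mm.
#' @export
zone_size <- function(radius1_mm, radius2_mm) {
  if (any(radius1_mm < 0) || any(radius2_mm < 0)) {
    stop("zone radii must be non-negative", call. = FALSE)
  }
  (radius1_mm + radius2_mm) / 2
}

#' Isolate-by-antibiotic resistance matrix
#'
#' Averages zone sizes over replicate disks for every isolate x antibiotic
#' combination. Larger mean zones mean more susceptible isolates; smaller
#' zones mean more resistant ones. Missing combinations are `NA` and
#' flagged with a warning.
#'
#' @param zones a zones table as returned by [read_zones()].
#' @param isolates optional character vector fixing the row order (defaults
#'   to first appearance in `zones`).
#' @param antibiotics optional character vector fixing the column order.
#' @return numeric matrix (isolates x antibiotics) of mean zone radii, mm.
#' @export
resistance_profile <- function(zones, isolates = NULL, antibiotics = NULL) {
  zones$zone_mm <- zone_size(zones$radius1_mm, zones$radius2_mm)
  if (is.null(isolates)) isolates <- unique(zones$isolate_id)
  if (is.null(antibiotics)) antibiotics <- unique(zones$antibiotic)
  m <- matrix(NA_real_, length(isolates), length(antibiotics),
              dimnames = list(isolates, antibiotics))
  agg <- stats::aggregate(zone_mm ~ isolate_id + antibiotic, data = zones,
                          FUN = mean)
  m[cbind(match(agg$isolate_id, isolates),
          match(agg$antibiotic, antibiotics))] <- agg$zone_mm
  if (anyNA(m)) {
    warning(sum(is.na(m)), " isolate-antibiotic combination(s) without ",
            "replicates; reported as NA", call. = FALSE)
  }
  m
}
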