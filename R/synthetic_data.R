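#' Default antibiotic panel for simulated disk-diffusion assays
#'
#' The nine clinical antibiotics of the disk-diffusion panel.
#' @return character vector of nine antibiotic names.
#' @export
default_antibiotics <- function() {
  c("kanamycin", "streptomycin", "erythromycin", "vancomycin",
    "amoxicillin", "novobiocin", "chloramphenicol", "rifampin",
    "tetracycline")
}

# per-cell parameter table for the default (study-like) configuration:
# polyculture nutrients elevated; monoculture inhibitor fraction elevated
# and further raised under fungicide; fungicide lowers niche width in
# monoculture and raises it in polyculture
default_cells <- function(richness_levels, fungicide_levels) {
  grid <- expand.grid(fungicide = fungicide_levels,
                      richness = richness_levels,
                      stringsAsFactors = FALSE)[2:1]
  poly <- grid$richness == richness_levels[2]
  trt <- grid$fungicide == fungicide_levels[2]
  data.frame(
    grid,
    C_pct = ifelse(poly, 1.3, 0.9), C_sd = 0.15,
    N_pct = ifelse(poly, 0.12, 0.08), N_sd = 0.015,
    P_ppm = ifelse(poly, 35, 25), P_sd = 5,
    K_ppm = ifelse(poly, 70, 50), K_sd = 10,
    OM_pct = ifelse(poly, 2.8, 2.0), OM_sd = 0.3,
    pH = ifelse(poly, 6.2, 6.0), pH_sd = 0.15,
    density_log10 = ifelse(poly, 6.2, ifelse(trt, 5.9, 6.3)),
    inhibitor_fraction = ifelse(poly, 0.20, ifelse(trt, 0.45, 0.35)),
    niche_width_mean = ifelse(poly, ifelse(trt, 55, 48),
                              ifelse(trt, 45, 55)),
    stringsAsFactors = FALSE)
}

# cell x antibiotic mean zone radii (mm): monoculture isolates more
# susceptible (larger zones) to amoxicillin, erythromycin and
# chloramphenicol; fungicide adds susceptibility to amoxicillin
default_zone_means <- function(cells, antibiotics) {
  base <- c(kanamycin = 8, streptomycin = 6, erythromycin = 10,
            vancomycin = 7, amoxicillin = 12, novobiocin = 9,
            chloramphenicol = 11, rifampin = 10, tetracycline = 9)
  m <- matrix(rep(base[antibiotics], each = nrow(cells)),
              nrow(cells), length(antibiotics),
              dimnames = list(NULL, antibiotics))
  mono <- cells$richness == cells$richness[1]
  for (ab in intersect(c("amoxicillin", "erythromycin",
                         "chloramphenicol"), antibiotics)) {
    m[mono, ab] <- m[mono, ab] + 3
  }
  if ("amoxicillin" %in% antibiotics) {
    trt <- cells$fungicide == cells$fungicide[2]
    m[trt, "amoxicillin"] <- m[trt, "amoxicillin"] + 1.5
  }
  m
}

#' Configuration for the synthetic-experiment generator
#'
#' Encodes the hierarchical design (2 richness plots x 2 fungicide
#' subplots x 6 plants = 24 composite samples; 10 isolates per plant from
#' 2 plants per subplot = 80 isolates by default) and the per-cell
#' generating parameters: nutrient means/SDs, log10 plate densities,
#' inhibitor fractions, niche-width means and zone-size means. Defaults
#' emulate the study conditions with treatment-effect directions matching
#' the field observations; see the methods vignette for how magnitudes
#' were chosen.
#'
#' @param seed integer seed; every random substream derives from it.
#' @param richness_levels,fungicide_levels treatment labels.
#' @param plants_per_subplot plants (= composite samples) per treatment
#'   cell.
#' @param isolate_plants_per_subplot plants per cell from which isolates
#'   are drawn.
#' @param isolates_per_plant isolates per selected plant.
#' @param cells per-cell parameter data.frame (see [sim_config()]
#'   defaults for the required columns).
#' @param zone_mean_mm cell x antibiotic matrix of mean zone radii (mm).
#' @param use_od_mean,od_sd mean and SD (AU590) of the absorbance signal
#'   on used wells, and the well noise SD.
#' @param use_threshold use-call threshold (AU590, strict `>`).
#' @param water_od water-control absorbance (AU590).
#' @param density_log10_sd between-sample SD of log10 density.
#' @param dilution,plated_volume_ml,n_plate_reps dilution-plating design.
#' @param indicators indicator-strain overlays for the inhibition assay.
#' @param antibiotics antibiotic panel.
#' @param zone_sd_mm,zone_reps zone measurement SD (mm) and replicate
#'   disks per isolate-antibiotic combination.
#' @param tree_clustering probability in \[0, 1\] that a new isolate
#'   attaches within its richness clade when the tree is grown.
#' @param suspension a [suspension_spec()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       richness_levels = c("monoculture", "polyculture"),
                       fungicide_levels = c("untreated", "treated"),
                       plants_per_subplot = 6,
                       isolate_plants_per_subplot = 2,
                       isolates_per_plant = 10,
                       cells = default_cells(richness_levels,
                                             fungicide_levels),
                       zone_mean_mm = default_zone_means(
                         cells, default_antibiotics()),
                       use_od_mean = 0.25, od_sd = 0.08,
                       use_threshold = 0.01, water_od = 0.05,
                       density_log10_sd = 0.2,
                       dilution = 1e-3, plated_volume_ml = 0.1,
                       n_plate_reps = 3,
                       indicators = c("LK1324.2", "DL87"),
                       antibiotics = default_antibiotics(),
                       zone_sd_mm = 1.5, zone_reps = 2,
                       tree_clustering = 0.8,
                       suspension = suspension_spec()) {
  cfg <- list(seed = as.integer(seed), richness_levels = richness_levels,
              fungicide_levels = fungicide_levels,
              plants_per_subplot = plants_per_subplot,
              isolate_plants_per_subplot = isolate_plants_per_subplot,
              isolates_per_plant = isolates_per_plant,
              cells = cells, zone_mean_mm = zone_mean_mm,
              use_od_mean = use_od_mean, od_sd = od_sd,
              use_threshold = use_threshold, water_od = water_od,
              density_log10_sd = density_log10_sd,
              dilution = dilution, plated_volume_ml = plated_volume_ml,
              n_plate_reps = n_plate_reps, indicators = indicators,
              antibiotics = antibiotics, zone_sd_mm = zone_sd_mm,
              zone_reps = zone_reps, tree_clustering = tree_clustering,
              suspension = suspension)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  c <- cfg$cells
  if (any(c$inhibitor_fraction < 0 | c$inhibitor_fraction > 1)) {
    stop("inhibitor_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(c$niche_width_mean < 0 | c$niche_width_mean > N_SUBSTRATES)) {
    stop("niche_width_mean must lie in [0, 95]", call. = FALSE)
  }
  sds <- c(c$C_sd, c$N_sd, c$P_sd, c$K_sd, c$OM_sd, c$pH_sd,
           cfg$od_sd, cfg$zone_sd_mm, cfg$density_log10_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0",
                         call. = FALSE)
  if (cfg$tree_clustering < 0 || cfg$tree_clustering > 1) {
    stop("tree_clustering must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$isolate_plants_per_subplot > cfg$plants_per_subplot) {
    stop("cannot draw isolates from more plants than exist per subplot",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Null configuration: no treatment effect in any cell
#'
#' All four treatment cells share identical generating parameters (the
#' monoculture-untreated defaults) and the tree grower attaches tips
#' without any richness-clade bias (`tree_clustering = 0`), so any
#' rejection of a treatment term downstream — including the PERMANOVA on
#' tree distances — is a type-I error. Used by the calibration checks.
#'
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()].
#' @return a `sim_config` whose cells differ in zero parameter fields.
#' @export
null_config <- function(seed = 1, ...) {
  cfg <- sim_config(seed = seed, tree_clustering = 0, ...)
  param_cols <- setdiff(names(cfg$cells), c("richness", "fungicide"))
  cfg$cells[param_cols] <- cfg$cells[rep(1, nrow(cfg$cells)), param_cols]
  cfg$zone_mean_mm <- matrix(rep(cfg$zone_mean_mm[1, ],
                                 each = nrow(cfg$zone_mean_mm)),
                             nrow(cfg$zone_mean_mm),
                             ncol(cfg$zone_mean_mm),
                             dimnames = dimnames(cfg$zone_mean_mm))
  cfg
}

# normal draw truncated to [lower, upper] via the inverse CDF (no
# rejection loop); mean and sd recycle to length n
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  z <- sd == 0
  out[z] <- pmin(pmax(mean[z], lower), upper)
  if (any(!z)) {
    lo <- stats::pnorm(lower, mean[!z], sd[!z])
    hi <- stats::pnorm(upper, mean[!z], sd[!z])
    out[!z] <- stats::qnorm(stats::runif(sum(!z), lo, hi), mean[!z],
                            sd[!z])
  }
  out
}

# normal draw truncated to (-Inf, upper]
rnorm_below <- function(n, mean, sd, upper) {
  rnorm_trunc(n, mean, sd, upper = upper)
}

# --- tree growth: sequential attachment biased toward the new tip's
# richness clade ---------------------------------------------------------

new_tip <- function(label, bl) list(tip = label, bl = bl)
is_tip <- function(node) !is.null(node$tip)

tree_tips <- function(node) {
  if (is_tip(node)) return(node$tip)
  c(tree_tips(node$children[[1]]), tree_tips(node$children[[2]]))
}

# replace the pendant edge of `target` with a cherry holding the new tip
attach_tip <- function(node, target, label, new_bl, split_frac) {
  if (is_tip(node)) {
    if (node$tip == target) {
      inner <- list(children = list(new_tip(node$tip,
                                            node$bl * (1 - split_frac)),
                                    new_tip(label, new_bl)),
                    bl = node$bl * split_frac)
      return(inner)
    }
    return(node)
  }
  node$children <- lapply(node$children, attach_tip, target = target,
                          label = label, new_bl = new_bl,
                          split_frac = split_frac)
  node
}

to_newick <- function(node) {
  if (is_tip(node)) return(sprintf("%s:%.8f", node$tip, node$bl))
  sprintf("(%s,%s):%.8f", to_newick(node$children[[1]]),
          to_newick(node$children[[2]]), node$bl)
}

# grow a rooted binary tree over `labels`, attaching each new tip to a
# uniformly chosen existing tip — of the same group with probability
# `clustering` — by splitting that tip's pendant edge
grow_tree <- function(labels, groups, clustering, bl_mean = 0.05) {
  stopifnot(length(labels) >= 2, length(labels) == length(groups))
  root <- list(children = list(new_tip(labels[1],
                                       stats::rexp(1, 1 / bl_mean)),
                               new_tip(labels[2],
                                       stats::rexp(1, 1 / bl_mean))),
               bl = 0)
  placed_group <- groups[1:2]
  names(placed_group) <- labels[1:2]
  for (k in seq_along(labels)[-(1:2)]) {
    tips <- names(placed_group)
    same <- tips[placed_group == groups[k]]
    pool <- if (length(same) && stats::runif(1) < clustering) same
            else tips
    target <- pool[sample.int(length(pool), 1)]
    root <- attach_tip(root, target, labels[k],
                       new_bl = stats::rexp(1, 1 / bl_mean),
                       split_frac = stats::runif(1))
    placed_group[labels[k]] <- groups[k]
  }
  ape::read.tree(text = paste0(to_newick(root), ";"))
}

#' Generate a complete synthetic experiment
#'
#' Draws, from a single seeded stream, the full artefact set of one
#' hierarchical survey: the design, per-sample soil nutrients (truncated
#' normals at their physical bounds), per-isolate 95-substrate plates
#' (use calls drawn per substrate with the cell's mean niche width;
#' used-well absorbance `water + |N(use_od_mean, od_sd)| + threshold`,
#' unused-well noise truncated below the threshold — so the generated use
#' truth always matches [call_resource_use()]), dilution-plate counts
#' (Poisson totals around the cell density, Binomial inhibitory counts),
#' disk-diffusion zone radii (truncated normals), and a rooted isolate
#' tree grown by clade-biased sequential attachment.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_experiment` with elements `design`
#'   ([experiment_design()]), `soil`, `plates` (`raw_plates`), `counts`,
#'   `zones`, `tree` (`phylo`), `used_truth` (isolate x substrate logical
#'   matrix) and `truth` (the generating config).
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  cells <- config$cells
  substrates <- sprintf("s%03d", seq_len(N_SUBSTRATES))

  # design: one composite sample per plant
  samples <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    plant <- sprintf("R%d.F%d.p%d", match(cells$richness[ci],
                                          config$richness_levels),
                     match(cells$fungicide[ci], config$fungicide_levels),
                     seq_len(config$plants_per_subplot))
    data.frame(sample_id = paste0("S.", plant),
               richness = cells$richness[ci],
               fungicide = cells$fungicide[ci], plant = plant)
  }))
  isolates <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
    cell_plants <- samples$plant[samples$richness == cells$richness[ci] &
                                 samples$fungicide == cells$fungicide[ci]]
    picked <- sort(sample(cell_plants, config$isolate_plants_per_subplot))
    do.call(rbind, lapply(picked, function(pl) {
      data.frame(isolate_id = sprintf("%s.i%02d", pl,
                                      seq_len(config$isolates_per_plant)),
                 richness = cells$richness[ci],
                 fungicide = cells$fungicide[ci], plant = pl)
    }))
  }))
  design <- experiment_design(samples, isolates,
                              richness_levels = config$richness_levels,
                              fungicide_levels = config$fungicide_levels)

  cell_of <- function(richness, fungicide) {
    match(paste(richness, fungicide),
          paste(cells$richness, cells$fungicide))
  }

  # soil nutrients per composite sample
  ci <- cell_of(samples$richness, samples$fungicide)
  n_s <- nrow(samples)
  soil <- data.frame(
    sample_id = samples$sample_id,
    C_pct = rnorm_trunc(n_s, cells$C_pct[ci], cells$C_sd[ci], 0, 100),
    N_pct = rnorm_trunc(n_s, cells$N_pct[ci], cells$N_sd[ci], 0, 100),
    P_ppm = rnorm_trunc(n_s, cells$P_ppm[ci], cells$P_sd[ci], 0, Inf),
    K_ppm = rnorm_trunc(n_s, cells$K_ppm[ci], cells$K_sd[ci], 0, Inf),
    OM_pct = rnorm_trunc(n_s, cells$OM_pct[ci], cells$OM_sd[ci], 0, 100),
    pH = rnorm_trunc(n_s, cells$pH[ci], cells$pH_sd[ci], 1e-6,
                     14 - 1e-6))

  # phenotype-array plates
  iso_cell <- cell_of(isolates$richness, isolates$fungicide)
  n_i <- nrow(isolates)
  p_use <- cells$niche_width_mean[iso_cell] / N_SUBSTRATES
  nw <- n_i * N_SUBSTRATES
  # column-major fill recycles the per-isolate use probability correctly
  used_truth <- matrix(stats::runif(nw), n_i, N_SUBSTRATES) < p_use
  sig <- abs(matrix(stats::rnorm(nw, config$use_od_mean, config$od_sd),
                    n_i)) + config$use_threshold
  noise <- matrix(rnorm_below(nw, 0, config$od_sd, config$use_threshold),
                  n_i)
  raw <- ifelse(used_truth, config$water_od + sig,
                pmax(config$water_od + noise, 0))
  dimnames(used_truth) <- dimnames(raw) <-
    list(isolates$isolate_id, substrates)
  plates <- cbind(data.frame(isolate_id = isolates$isolate_id,
                             water = config$water_od),
                  as.data.frame(raw))
  attr(plates, "substrates") <- substrates
  class(plates) <- c("raw_plates", "data.frame")

  # dilution-plate counts: one latent density per sample, Poisson plate
  # counts, Binomial inhibitory counts
  plating_factor <- config$plated_volume_ml * config$dilution *
    config$suspension$soil_mass_g / config$suspension$suspension_volume_ml
  dens <- 10^stats::rnorm(n_s, cells$density_log10[ci],
                          config$density_log10_sd)
  cgrid <- expand.grid(plate_rep = seq_len(config$n_plate_reps),
                       overlay = config$indicators,
                       s = seq_len(n_s), stringsAsFactors = FALSE)
  total <- stats::rpois(nrow(cgrid), dens[cgrid$s] * plating_factor)
  inhib <- stats::rbinom(nrow(cgrid), total,
                         cells$inhibitor_fraction[ci[cgrid$s]])
  counts <- data.frame(sample_id = samples$sample_id[cgrid$s],
                       overlay = cgrid$overlay,
                       plate_rep = cgrid$plate_rep,
                       dilution = config$dilution,
                       volume_ml = config$plated_volume_ml,
                       total_colonies = total,
                       inhibitory_colonies = inhib)

  # disk-diffusion zones
  zgrid <- expand.grid(rep = seq_len(config$zone_reps),
                       antibiotic = config$antibiotics,
                       i = seq_len(n_i), stringsAsFactors = FALSE)
  mu <- config$zone_mean_mm[cbind(iso_cell[zgrid$i],
                                  match(zgrid$antibiotic,
                                        colnames(config$zone_mean_mm)))]
  zones <- data.frame(isolate_id = isolates$isolate_id[zgrid$i],
                      antibiotic = zgrid$antibiotic,
                      rep = zgrid$rep,
                      radius1_mm = rnorm_trunc(nrow(zgrid), mu,
                                               config$zone_sd_mm, 0, Inf),
                      radius2_mm = rnorm_trunc(nrow(zgrid), mu,
                                               config$zone_sd_mm, 0, Inf))

  # randomise the insertion order: sequential attachment makes early
  # tips systematically deeper, so inserting in design order would leak
  # block structure into the tree even without any clustering bias
  ord <- sample.int(n_i)
  tree <- grow_tree(isolates$isolate_id[ord], isolates$richness[ord],
                    config$tree_clustering)

  structure(list(design = design, soil = soil, plates = plates,
                 counts = counts, zones = zones, tree = tree,
                 used_truth = used_truth, truth = config),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic experiment (seed", x$truth$seed, "):",
      nrow(x$soil), "soil samples,", nrow(x$plates), "plates,",
      nrow(x$counts), "count plates,", length(x$tree$tip.label),
      "tree tips\n")
  invisible(x)
}

#' Write a synthetic experiment to a directory
#'
#' Writes `design.csv`, `soil.csv`, `plates.csv`, `counts.csv`,
#' `zones.csv`, `tree.nwk` and `truth.json` (the generating parameters).
#'
#' @param experiment a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_design(experiment$design, file.path(dir, "design.csv"))
  utils::write.csv(experiment$soil, file.path(dir, "soil.csv"),
                   row.names = FALSE, quote = FALSE)
  write_plate_table(experiment$plates, file.path(dir, "plates.csv"))
  utils::write.csv(experiment$counts, file.path(dir, "counts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(experiment$zones, file.path(dir, "zones.csv"),
                   row.names = FALSE, quote = FALSE)
  ape::write.tree(experiment$tree, file.path(dir, "tree.nwk"))
  truth <- experiment$truth
  truth$suspension <- unclass(truth$suspension)
  truth$zone_mean_mm <- as.data.frame(truth$zone_mean_mm)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
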