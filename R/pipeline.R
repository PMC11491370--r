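#' Read a full experiment directory
#'
#' Loads the five CSV tables plus the newick tree written by
#' [write_experiment()] (or assembled by hand in the same schemas).
#'
#' @param dir directory holding `design.csv`, `soil.csv`, `plates.csv`,
#'   `counts.csv`, `zones.csv`, `tree.nwk`.
#' @param outgroup optional outgroup tip to prune from the tree.
#' @return list with `design`, `soil`, `plates`, `counts`, `zones`,
#'   `tree`.
#' @export
read_experiment <- function(dir, outgroup = NULL) {
  design <- read_design(file.path(dir, "design.csv"))
  list(design = design,
       soil = read_soil(file.path(dir, "soil.csv")),
       plates = read_plate_table(file.path(dir, "plates.csv")),
       counts = read_counts(file.path(dir, "counts.csv")),
       zones = read_zones(file.path(dir, "zones.csv")),
       tree = read_tree(file.path(dir, "tree.nwk"), outgroup = outgroup,
                        design = design))
}

# per-isolate table joining design labels with niche metrics and overlap
isolate_table <- function(design, profiles, om) {
  nm <- niche_metrics(profiles)
  ov <- isolate_overlap(om)
  info <- design_lookup(design, nm$isolate_id)
  data.frame(isolate_id = nm$isolate_id, richness = info$richness,
             fungicide = info$fungicide, plant = info$plant,
             niche_width = nm$niche_width, efficiency = nm$efficiency,
             mean_overlap = ov$mean_overlap[match(nm$isolate_id,
                                                  ov$isolate_id)])
}

# nested ANOVA + Tukey letters for one response, returned as tidy rows
response_stats <- function(values, richness, fungicide, response,
                           alpha = 0.05) {
  an <- nested_anova(values, richness, fungicide)$table
  an <- cbind(response = response, an)
  cell <- paste(richness, fungicide, sep = ":")
  tk <- tukey_hsd(values[!is.na(values)], cell[!is.na(values)],
                  alpha = alpha)
  letters_df <- data.frame(response = response,
                           group = names(tk$letters),
                           letters = unname(tk$letters))
  list(anova = an, letters = letters_df,
       tukey = cbind(response = response, tk$pairs))
}

#' Run the full analysis pipeline on an experiment directory
#'
#' Reads the experiment, computes niche metrics and overlaps, dilution
#' plate densities and inhibitory proportions, the resistance matrix,
#' Faith's PD per treatment cell, pairwise unweighted UniFrac between
#' plant communities with a PERMANOVA on the nested design, nested
#' ANOVAs with Tukey letter displays for every response, nutrient
#' correlations, and per-substrate FDR-controlled tests; writes
#' everything as CSV plus a markdown summary and a reproducibility
#' manifest.
#'
#' @param input_dir experiment directory (see [read_experiment()]).
#' @param output_dir directory for results (created if needed).
#' @param threshold use-call threshold (AU590).
#' @param alpha significance level for ANOVA/Tukey letters.
#' @param fdr_method `"BH"` or `"BY"` for the per-substrate families.
#' @param n_permutations PERMANOVA permutations.
#' @param seed integer seed for the PERMANOVA permutation stream.
#' @param include_root include the root path in Faith's PD.
#' @param outgroup optional outgroup tip pruned from the tree.
#' @return (invisibly) a named list of the computed tables.
#' @export
run_report <- function(input_dir, output_dir, threshold = 0.01,
                       alpha = 0.05, fdr_method = "BH",
                       n_permutations = 999, seed = 17,
                       include_root = TRUE, outgroup = NULL) {
  exp <- read_experiment(input_dir, outgroup = outgroup)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  design <- exp$design

  profiles <- resource_profiles(exp$plates, threshold = threshold)
  om <- overlap_matrix(profiles, design, group_by = "plant")
  iso <- isolate_table(design, profiles, om)
  substrate_profile <- group_substrate_profile(profiles, design,
                                               level = "cell")

  dens <- sample_density(exp$counts, spec = suspension_spec())
  sinfo <- design_lookup(design, dens$summary$sample_id)
  dens_tab <- cbind(dens$summary,
                    sinfo[c("richness", "fungicide", "plant")])

  resist <- resistance_profile(exp$zones)
  rinfo <- design_lookup(design, rownames(resist))

  # phylogenetic comparison at the plant-community level
  iso_d <- design$isolates
  plant_groups <- split(iso_d$isolate_id, iso_d$plant)
  plant_groups <- plant_groups[vapply(plant_groups, length,
                                      integer(1)) > 0]
  uf <- pairwise_unifrac(exp$tree, plant_groups)
  plant_info <- unique(iso_d[c("plant", "richness", "fungicide")])
  plant_info <- plant_info[match(rownames(uf), plant_info$plant), ]
  perm <- permanova(uf, plant_info,
                    terms = c("richness", "richness:fungicide"),
                    n_permutations = n_permutations, seed = seed)
  cell_groups <- split(iso_d$isolate_id,
                       paste(iso_d$richness, iso_d$fungicide, sep = ":"))
  pd_tab <- pd_by_group(exp$tree, cell_groups,
                        include_root = include_root)

  # nested ANOVAs with Tukey letters for every response
  resp <- list(
    list(iso$niche_width, iso$richness, iso$fungicide, "niche_width"),
    list(iso$efficiency, iso$richness, iso$fungicide, "efficiency"),
    list(iso$mean_overlap, iso$richness, iso$fungicide, "niche_overlap"),
    list(dens_tab$total_cfu_g, dens_tab$richness, dens_tab$fungicide,
         "total_density"),
    list(dens_tab$inhibitor_cfu_g, dens_tab$richness,
         dens_tab$fungicide, "inhibitor_density"),
    list(dens_tab$proportion, dens_tab$richness, dens_tab$fungicide,
         "inhibitor_proportion"))
  for (nu in c("C_pct", "N_pct", "P_ppm", "K_ppm", "OM_pct", "pH")) {
    v <- exp$soil[[nu]][match(dens_tab$sample_id, exp$soil$sample_id)]
    resp[[length(resp) + 1]] <- list(v, dens_tab$richness,
                                     dens_tab$fungicide,
                                     paste0("soil_", nu))
  }
  for (ab in colnames(resist)) {
    resp[[length(resp) + 1]] <- list(resist[, ab], rinfo$richness,
                                     rinfo$fungicide,
                                     paste0("zone_", ab))
  }
  stats <- lapply(resp, function(r) {
    response_stats(r[[1]], r[[2]], r[[3]], r[[4]], alpha = alpha)
  })
  anova_tab <- do.call(rbind, lapply(stats, `[[`, "anova"))
  letters_tab <- do.call(rbind, lapply(stats, `[[`, "letters"))
  tukey_tab <- do.call(rbind, lapply(stats, `[[`, "tukey"))

  corr <- correlate_nutrients(dens$summary, exp$soil, design)
  per_sub <- per_substrate_tests(profiles, design,
                                 fdr_method = fdr_method, q = alpha)

  wr <- function(df, name) {
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  wr(iso, "niche_metrics.csv")
  wr(om$group_summary, "overlap_by_plant.csv")
  wr(substrate_profile, "substrate_profile.csv")
  wr(dens_tab, "densities.csv")
  wr(dens$by_overlay, "densities_by_overlay.csv")
  wr(cbind(isolate_id = rownames(resist), as.data.frame(resist)),
     "resistance_matrix.csv")
  wr(pd_tab, "pd_by_group.csv")
  wr(cbind(group = rownames(uf), as.data.frame(uf)), "unifrac.csv")
  wr(as.data.frame(perm), "permanova.csv")
  wr(anova_tab, "anova.csv")
  wr(letters_tab, "letters.csv")
  wr(tukey_tab, "tukey.csv")
  wr(corr, "correlations.csv")
  wr(per_sub, "per_substrate_tests.csv")

  manifest <- list(
    package = "strepniche",
    version = as.character(utils::packageVersion("strepniche")),
    input_dir = normalizePath(input_dir),
    options = list(threshold = threshold, alpha = alpha,
                   fdr_method = fdr_method,
                   n_permutations = n_permutations, seed = seed,
                   include_root = include_root,
                   outgroup = outgroup))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  md <- c("# Analysis summary", "",
          sprintf("- %d isolates, %d composite samples",
                  nrow(design$isolates), nrow(design$samples)),
          sprintf("- PERMANOVA (unweighted UniFrac between plant communities): richness p = %.4g, fungicide-in-richness p = %.4g",
                  perm$p[perm$term == "richness"],
                  perm$p[perm$term == "richness:fungicide"]),
          "",
          "## Nested ANOVA p-values per response", "")
  wide <- stats::reshape(
    anova_tab[anova_tab$term != "Residual",
              c("response", "term", "p")],
    idvar = "response", timevar = "term", direction = "wide")
  md <- c(md, "| response | p(richness) | p(fungicide in richness) |",
          "|---|---|---|",
          sprintf("| %s | %.4g | %.4g |", wide$response,
                  wide$p.richness, wide$p.fungicide_in_richness))
  writeLines(md, file.path(output_dir, "summary.md"))

  invisible(list(isolates = iso, substrate_profile = substrate_profile,
                 densities = dens_tab, resistance = resist,
                 pd = pd_tab, unifrac = uf, permanova = perm,
                 anova = anova_tab, letters = letters_tab,
                 tukey = tukey_tab, correlations = corr,
                 per_substrate = per_sub))
}

#' Simulate an experiment and write it to disk
#'
#' Convenience wrapper: build a [sim_config()] with the given seed,
#' [simulate_experiment()], and [write_experiment()] into `dir`.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param config optional pre-built [sim_config()] (its seed is
#'   overridden by `seed` when both are given).
#' @return `dir`, invisibly.
#' @export
run_simulate <- function(dir, seed = 1, config = NULL) {
  if (is.null(config)) {
    config <- sim_config(seed = seed)
  } else {
    config$seed <- as.integer(seed)
  }
  write_experiment(simulate_experiment(config), dir)
}
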