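#' Experimental design of a nested richness/fungicide survey
#'
#' Builds and validates the hierarchy richness plot -> fungicide subplot ->
#' plant -> composite sample / isolate. Each composite soil sample and each
#' isolate carries a `(richness, fungicide, plant)` label triple; every
#' isolate belongs to exactly one plant and every plant to exactly one
#' treatment cell.
#'
#' @param samples data.frame with columns `sample_id`, `richness`,
#'   `fungicide`, `plant` (one row per composite soil sample).
#' @param isolates data.frame with columns `isolate_id`, `richness`,
#'   `fungicide`, `plant` (one row per isolate). May have zero rows.
#' @param richness_levels,fungicide_levels treatment level labels; defaults
#'   are taken from the data in first-appearance order.
#'
#' @return An object of class `experiment_design`: a list with elements
#'   `richness_levels`, `fungicide_levels`, `samples`, `isolates`.
#' @export
experiment_design <- function(samples, isolates,
                              richness_levels = NULL,
                              fungicide_levels = NULL) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      stop(sprintf("%s table is missing column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  need(samples, c("sample_id", "richness", "fungicide", "plant"), "samples")
  need(isolates, c("isolate_id", "richness", "fungicide", "plant"), "isolates")
  samples[] <- lapply(samples, as.character)
  isolates[] <- lapply(isolates, as.character)

  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(isolates$isolate_id)) {
    stop("duplicate isolate id(s): ",
         paste(unique(isolates$isolate_id[duplicated(isolates$isolate_id)]),
               collapse = ", "), call. = FALSE)
  }
  # a plant must sit in exactly one treatment cell
  plant_cells <- unique(rbind(samples[c("richness", "fungicide", "plant")],
                              isolates[c("richness", "fungicide", "plant")]))
  dup <- plant_cells$plant[duplicated(plant_cells$plant)]
  if (length(dup)) {
    stop("plant(s) assigned to more than one treatment cell: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  if (is.null(richness_levels)) richness_levels <- unique(samples$richness)
  if (is.null(fungicide_levels)) fungicide_levels <- unique(samples$fungicide)

  cells <- table(factor(samples$richness, richness_levels),
                 factor(samples$fungicide, fungicide_levels))
  if (any(cells == 0)) {
    stop("empty treatment cell(s) in the sample table", call. = FALSE)
  }
  if (any(cells == 1)) {
    warning("unreplicated treatment cell(s): only one plant/sample in ",
            sum(cells == 1), " cell(s)", call. = FALSE)
  }

  structure(list(richness_levels = richness_levels,
                 fungicide_levels = fungicide_levels,
                 samples = samples[c("sample_id", "richness", "fungicide",
                                     "plant")],
                 isolates = isolates[c("isolate_id", "richness", "fungicide",
                                       "plant")]),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Experiment design:",
      length(x$richness_levels), "richness level(s) x",
      length(x$fungicide_levels), "fungicide level(s);",
      nrow(x$samples), "composite samples,",
      nrow(x$isolates), "isolates\n")
  invisible(x)
}

#' Look up design labels for sample or isolate identifiers
#'
#' @param design an [experiment_design()].
#' @param ids character vector of sample or isolate identifiers.
#' @return data.frame with columns `id`, `kind`, `richness`, `fungicide`,
#'   `plant`, one row per element of `ids`, in order.
#' @export
design_lookup <- function(design, ids) {
  stopifnot(inherits(design, "experiment_design"))
  s <- design$samples
  i <- design$isolates
  all <- rbind(data.frame(id = s$sample_id, kind = "sample",
                          s[c("richness", "fungicide", "plant")]),
               data.frame(id = i$isolate_id, kind = "isolate",
                          i[c("richness", "fungicide", "plant")]))
  hit <- match(ids, all$id)
  if (anyNA(hit)) {
    stop("unknown id(s): ", paste(ids[is.na(hit)], collapse = ", "),
         call. = FALSE)
  }
  out <- all[hit, ]
  rownames(out) <- NULL
  out
}

#' Read an experimental-design table
#'
#' The file is a UTF-8 CSV with columns `id`, `kind` (`sample` or
#' `isolate`), `richness`, `fungicide`, `plant`.
#'
#' @param path path to `design.csv`.
#' @return An [experiment_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- setdiff(c("id", "kind", "richness", "fungicide", "plant"),
                  names(df))
  if (length(need)) {
    stop("design file is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$kind), c("sample", "isolate"))
  if (length(bad)) {
    stop("unknown kind value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  s <- df[df$kind == "sample", ]
  i <- df[df$kind == "isolate", ]
  experiment_design(
    samples = data.frame(sample_id = s$id, richness = s$richness,
                         fungicide = s$fungicide, plant = s$plant),
    isolates = data.frame(isolate_id = i$id, richness = i$richness,
                          fungicide = i$fungicide, plant = i$plant))
}

#' Write an experimental-design table
#'
#' @param design an [experiment_design()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "experiment_design"))
  s <- design$samples
  i <- design$isolates
  df <- rbind(data.frame(id = s$sample_id, kind = "sample",
                         s[c("richness", "fungicide", "plant")]),
              data.frame(id = i$isolate_id, kind = "isolate",
                         i[c("richness", "fungicide", "plant")]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# number of carbon-source wells on the phenotype-array plate
N_SUBSTRATES <- 95L

#' Read a carbon-source utilisation plate table
#'
#' One row per isolate: an `isolate_id` column, a `water` column holding the
#' water-control absorbance (AU590), and exactly 95 carbon-source columns in
#' file order. Substrate identity is the column header string; no canonical
#' substrate dictionary is enforced.
#'
#' @param path path to `plates.csv`.
#' @param water_col name of the water-control column (default `"water"`).
#' @return A data.frame of class `raw_plates` with columns `isolate_id`,
#'   `water` and the 95 substrate columns; the substrate names are kept in
#'   attribute `"substrates"`.
#' @export
read_plate_table <- function(path, water_col = "water") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"isolate_id" %in% names(df)) {
    stop("plate table needs an 'isolate_id' column", call. = FALSE)
  }
  if (!water_col %in% names(df)) {
    stop("missing water-control column '", water_col, "'", call. = FALSE)
  }
  substrates <- setdiff(names(df), c("isolate_id", water_col))
  if (length(substrates) != N_SUBSTRATES) {
    stop("expected 95 carbon-source wells, found ", length(substrates),
         call. = FALSE)
  }
  vals <- df[c(water_col, substrates)]
  for (col in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[col]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      stop(sprintf("non-numeric absorbance for isolate %s, well %s",
                   df$isolate_id[row], col), call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg)) {
      stop(sprintf("negative absorbance for isolate %s, well %s",
                   df$isolate_id[neg[1]], col), call. = FALSE)
    }
    vals[[col]] <- v
  }
  out <- cbind(data.frame(isolate_id = as.character(df$isolate_id),
                          stringsAsFactors = FALSE), vals)
  names(out)[2] <- "water"
  attr(out, "substrates") <- substrates
  class(out) <- c("raw_plates", "data.frame")
  out
}

#' Write a carbon-source utilisation plate table
#'
#' @param plates a `raw_plates` table as returned by [read_plate_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  utils::write.csv(as.data.frame(plates), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogenetic tree of isolates
#'
#' Reads a newick file, requires a rooted topology with branch lengths, and
#' optionally prunes a named outgroup tip. If `design` is given, remaining
#' tip labels must all be known isolate identifiers.
#'
#' @param path path to a newick file.
#' @param outgroup optional tip label to drop after reading (e.g. the
#'   outgroup strain used to root the tree).
#' @param design optional [experiment_design()] used to validate tip labels.
#' @return An [ape::read.tree()] `phylo` object, rooted, with branch
#'   lengths.
#' @export
read_tree <- function(path, outgroup = NULL, design = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path,
                          call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; supply a rooted tree (it is not midpoint-rooted",
         " silently because phylogenetic diversity depends on the root)",
         call. = FALSE)
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup tip '", outgroup, "' not found in tree", call. = FALSE)
    }
    tree <- ape::drop.tip(tree, outgroup)
  }
  if (!is.null(design)) {
    unknown <- setdiff(tree$tip.label, design$isolates$isolate_id)
    if (length(unknown)) {
      stop("unknown isolate ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  tree
}

#' Read a soil nutrient table
#'
#' Columns: `sample_id`, `C_pct`, `N_pct`, `P_ppm`, `K_ppm`, `OM_pct`, `pH`.
#' Percentages must lie in \[0, 100\], ppm values must be non-negative and
#' pH in (0, 14).
#'
#' @param path path to `soil.csv`.
#' @return data.frame with the columns above.
#' @export
read_soil <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "C_pct", "N_pct", "P_ppm", "K_ppm",
                    "OM_pct", "pH"), names(df))
  if (length(need)) {
    stop("soil file is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  chk <- function(col, lo, hi, lo_open = FALSE) {
    v <- df[[col]]
    bad <- if (lo_open) v <= lo | v >= hi else v < lo | v > hi
    if (any(bad)) {
      stop(sprintf("%s out of range for sample %s", col,
                   df$sample_id[which(bad)[1]]), call. = FALSE)
    }
  }
  chk("C_pct", 0, 100); chk("N_pct", 0, 100); chk("OM_pct", 0, 100)
  chk("P_ppm", 0, Inf); chk("K_ppm", 0, Inf)
  chk("pH", 0, 14, lo_open = TRUE)
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Read a dilution-plate colony-count table
#'
#' Columns: `sample_id`, `overlay` (`none` or an indicator-strain id),
#' `plate_rep`, `dilution` (a factor in (0, 1]), `volume_ml` (plated volume,
#' mL), `total_colonies`, `inhibitory_colonies`.
#'
#' @param path path to `counts.csv`.
#' @return validated data.frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("sample_id", "overlay", "plate_rep", "dilution",
                    "volume_ml", "total_colonies", "inhibitory_colonies"),
                  names(df))
  if (length(need)) {
    stop("counts file is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$dilution <= 0 | df$dilution > 1)) {
    stop("dilution must lie in (0, 1]", call. = FALSE)
  }
  if (any(df$volume_ml <= 0)) stop("plated volume must be > 0",
                                   call. = FALSE)
  if (any(df$total_colonies < 0) || any(df$inhibitory_colonies < 0)) {
    stop("colony counts must be non-negative", call. = FALSE)
  }
  bad <- df$inhibitory_colonies > df$total_colonies
  if (any(bad)) {
    stop("inhibitory colonies exceed total colonies for sample ",
         df$sample_id[which(bad)[1]], call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$overlay <- as.character(df$overlay)
  df
}

#' Read a zone-measurement table
#'
#' Columns: `isolate_id`, `antibiotic`, `rep`, `radius1_mm`, `radius2_mm`.
#' Each radius is measured from the edge of the colony (or disk) to the
#' edge of the clearing; the two measurements are at right angles.
#'
#' @param path path to `zones.csv`.
#' @return validated data.frame.
#' @export
read_zones <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(c("isolate_id", "antibiotic", "rep", "radius1_mm",
                    "radius2_mm"), names(df))
  if (length(need)) {
    stop("zones file is missing column(s): ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$radius1_mm < 0) || any(df$radius2_mm < 0)) {
    stop("zone radii must be non-negative", call. = FALSE)
  }
  df$isolate_id <- as.character(df$isolate_id)
  df$antibiotic <- as.character(df$antibiotic)
  df
}
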