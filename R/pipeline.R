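#' Default run configuration
#'
#' @return Named list of pipeline defaults: segmentation parameters, band
#'   definitions (UVA 380--400, VIS 400--760, NIR 760--1000 nm), guard margin
#'   and QC limit. Every field can be overridden via the `config` argument of
#'   [run_pipeline()].
#' @export
default_config <- function() {
  list(
    segmentation = list(threshold_mode = "relative", relative_level = 0.98,
                        min_circularity = 0.6, min_area_px = NULL),
    guard_margin_px = 10,
    tau_qc_limit = 1.05,
    bands = list(UVA = c(380, 400), VIS = c(400, 760), NIR = c(760, 1000)),
    output_dir = NULL,
    seed = 1L,
    inputs = list()
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(override[[k]]))) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

load_config <- function(config) {
  if (is.character(config)) {
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(config)
    } else if (ext == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      stop("config file must be YAML or JSON: ", config)
    }
  }
  merge_config(default_config(), config)
}

#' Run the full transparency pipeline over a set of cubes
#'
#' For each input cube: segment eggs, estimate the seawater background
#' spectrum, convert each egg to a transmittance spectrum, and compute
#' bio-transparency and the visible attenuation coefficient; then aggregate
#' per individual and per species. Deterministic given inputs and config --
#' re-running writes byte-identical tables, and per-species results do not
#' depend on input order.
#'
#' @param config A named list or a YAML/JSON file path. Recognized fields:
#'   `inputs` -- list of entries `(path, dialect, individual_id, species,
#'   pixel_size_um, manual_diameters_um)`; `segmentation` -- parameters for
#'   [segment_eggs()]; `guard_margin_px`; `tau_qc_limit`; `output_dir`
#'   (optional: tables are written there when set).
#' @return List of data frames: `per_egg`, `per_individual`, `per_species`,
#'   `spectra_long`, `spectra_wide`, `qc` -- plus the resolved config.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (length(cfg$inputs) == 0) stop("config has no inputs")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  per_egg <- list(); spectra <- list(); qc_rows <- list()
  ids_seen <- character(0)
  for (inp in cfg$inputs) {
    if (is.null(inp$path)) stop("input entry lacks a cube path")
    if (!file.exists(inp$path)) stop("cannot read cube file: ", inp$path)
    key <- inp$individual_id
    if (key %in% ids_seen) stop("duplicate individual_id per cube: ", key)
    ids_seen <- c(ids_seen, key)
    cube <- read_cube(inp$path,
                      dialect = if (is.null(inp$dialect))
                        guess_dialect(inp$path) else inp$dialect,
                      pixel_size_um = inp$pixel_size_um)
    seg <- cfg$segmentation
    regions <- segment_eggs(
      cube,
      threshold_mode = seg$threshold_mode,
      relative_level = seg$relative_level,
      min_area_px = seg$min_area_px,
      min_circularity = seg$min_circularity)
    if (length(regions) == 0) {
      note("WARN: no egg regions found in %s", inp$path)
      next
    }
    bg <- background_mask(cube, regions, cfg$guard_margin_px)
    bg_spec <- estimate_background_spectrum(cube, bg)
    for (i in seq_along(regions)) {
      reg <- regions[[i]]
      diam <- if (!is.null(inp$manual_diameters_um) &&
                  i <= length(inp$manual_diameters_um)) {
        inp$manual_diameters_um[i]
      } else {
        reg$equivalent_diameter_um
      }
      egg_id <- sprintf("%s_egg%02d", key, i)
      spec <- egg_transmittance(cube, reg, bg_spec, egg_id = egg_id)
      row <- compute_egg_stats(spec, diam, egg_id = egg_id,
                               individual_id = key, species = inp$species,
                               tau_qc_limit = cfg$tau_qc_limit)
      per_egg[[length(per_egg) + 1L]] <- row
      spectra[[length(spectra) + 1L]] <- spec
      if (row$n_tau_gt1 > 0 || row$n_masked_bands > 0) {
        qc_rows[[length(qc_rows) + 1L]] <- data.frame(
          egg_id = egg_id, n_tau_gt1 = row$n_tau_gt1,
          n_masked_bands = row$n_masked_bands)
      }
    }
    note("INFO: %s -> %d egg(s)", inp$path, length(regions))
  }
  if (length(per_egg) == 0) {
    note("WARN: zero eggs across all inputs; tables are empty")
    res <- list(per_egg = data.frame(), per_individual = data.frame(),
                per_species = data.frame(), spectra_long = data.frame(),
                spectra_wide = data.frame(), qc = data.frame(), config = cfg)
    return(res)
  }
  per_egg <- do.call(rbind, per_egg)
  per_egg <- per_egg[order(per_egg$individual_id, per_egg$egg_id), ]
  rownames(per_egg) <- NULL
  per_ind <- do.call(rbind, lapply(
    split(per_egg, per_egg$individual_id), aggregate_individual))
  per_ind <- per_ind[order(per_ind$individual_id), ]
  rownames(per_ind) <- NULL
  per_sp <- do.call(rbind, lapply(
    split(per_ind, per_ind$species), species_variance))
  per_sp <- per_sp[order(per_sp$species), ]
  rownames(per_sp) <- NULL
  sp_exports <- export_spectra(spectra)
  qc <- if (length(qc_rows)) do.call(rbind, qc_rows) else data.frame()
  res <- list(per_egg = per_egg, per_individual = per_ind,
              per_species = per_sp, spectra_long = sp_exports$long,
              spectra_wide = sp_exports$wide, qc = qc, config = cfg)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) utils::write.csv(
      df, file.path(cfg$output_dir, name), row.names = FALSE)
    wr(per_egg, "per_egg.csv"); wr(per_ind, "per_individual.csv")
    wr(per_sp, "per_species.csv")
    wr(sp_exports$long, "spectra_long.csv")
    wr(sp_exports$wide, "spectra_wide.csv")
    if (nrow(qc)) wr(qc, "qc_flags.csv")
    writeLines(log_lines, file.path(cfg$output_dir, "run.log"))
    cfg_out <- cfg
    cfg_out$segmentation$min_area_px <-
      cfg_out$segmentation$min_area_px %||% "auto"
    yaml::write_yaml(cfg_out, file.path(cfg$output_dir,
                                        "resolved_config.yaml"))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Species trait table for phylogeny annotation
#'
#' One row per species: mean and SD of the individual mean bio-transparencies
#' and the number of individuals sampled. Species with a single individual
#' keep SD 0 and are flagged.
#'
#' @param per_individual Data frame from [run_pipeline()]'s `per_individual`.
#' @return Data frame: species, mean_bt_pct, sd_bt_pct, n_individuals,
#'   single_individual_flag.
#' @export
build_trait_table <- function(per_individual) {
  stopifnot(is.data.frame(per_individual), nrow(per_individual) >= 1)
  rows <- lapply(split(per_individual, per_individual$species), function(d) {
    n <- nrow(d)
    data.frame(species = d$species[1],
               mean_bt_pct = mean(d$mean_bt_pct),
               sd_bt_pct = if (n == 1) 0 else stats::sd(d$mean_bt_pct),
               n_individuals = n,
               single_individual_flag = n == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species), ]
  rownames(out) <- NULL
  out
}

normalize_name <- function(x) tolower(gsub("[_ ]+", " ", trimws(x)))

#' Annotate a phylogeny with bio-transparency as a continuous trait
#'
#' Joins a species trait table onto the tips of an existing Newick tree (no
#' tree inference here) and writes a NEXUS file carrying the tree plus a
#' continuous CHARACTERS block, together with a tip-to-trait CSV. Matching is
#' exact after underscore/space normalization and an optional alias map --
#' no fuzzy matching, since a silent mis-join is worse than an error.
#' Unmatched tips stay in the tree with a missing-value annotation and are
#' reported.
#'
#' @param tree_path Newick file.
#' @param traits Data frame with at least `species` and `mean_bt_pct`
#'   (e.g. from [build_trait_table()]).
#' @param name_map Optional named character vector: `tip label -> species`.
#' @param out_nexus NEXUS destination path.
#' @param out_csv Optional tip-to-trait CSV destination.
#' @return Data frame of tips with their matched trait (NA when unmatched),
#'   invisibly.
#' @export
annotate_tree <- function(tree_path, traits, name_map = NULL,
                          out_nexus, out_csv = NULL) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) stop("cannot parse Newick tree: ", tree_path)
  tips <- tree$tip.label
  mapped <- tips
  if (!is.null(name_map)) {
    hit <- tips %in% names(name_map)
    mapped[hit] <- unname(name_map[tips[hit]])
  }
  idx <- match(normalize_name(mapped), normalize_name(traits$species))
  if (all(is.na(idx))) {
    stop("no tree tip matches any trait species.\n  tips: ",
         paste(tips, collapse = ", "), "\n  traits: ",
         paste(traits$species, collapse = ", "))
  }
  join <- data.frame(tip = tips, species = mapped,
                     mean_bt_pct = traits$mean_bt_pct[idx],
                     stringsAsFactors = FALSE)
  unmatched <- tips[is.na(idx)]
  if (length(unmatched)) {
    message("unmatched tips kept without trait: ",
            paste(unmatched, collapse = ", "))
  }
  safe <- gsub("[^A-Za-z0-9_.]", "_", tips)
  tr_out <- tree; tr_out$tip.label <- safe
  vals <- ifelse(is.na(join$mean_bt_pct), "?",
                 format(join$mean_bt_pct, trim = TRUE, digits = 10))
  nexus <- c(
    "#NEXUS",
    "",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", length(tips)),
    paste0("  TAXLABELS ", paste(safe, collapse = " "), ";"),
    "END;",
    "",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=1;"),
    "  FORMAT DATATYPE=CONTINUOUS MISSING=?;",
    "  CHARSTATELABELS 1 bio_transparency_pct;",
    "  MATRIX",
    sprintf("    %s %s", safe, vals),
    "  ;",
    "END;",
    "",
    "BEGIN TREES;",
    sprintf("  TREE annotated = %s", ape::write.tree(tr_out)),
    "END;"
  )
  writeLines(nexus, out_nexus)
  if (!is.null(out_csv)) utils::write.csv(join, out_csv, row.names = FALSE)
  invisible(join)
}
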