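#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]: a list of strains
#' (each a named set of overrides to [sim_config()]), the replicate/cohort
#' design, and the analysis parameters of the downstream stages.
#'
#' @param strains Named list: one entry per strain, each itself a (possibly
#'   empty) list of `sim_config()` overrides. Names are the strain labels.
#' @param n_replicates Biological replicates simulated per strain.
#' @param n_cells Non-founder cells per replicate cohort.
#' @param seed Top-level integer seed; per-stage and per-cohort sub-seeds
#'   are derived deterministically from it.
#' @param grid_t,grid_l Kymograph grid (time x position bins).
#' @param width_px,pulse_width_px Segmented-line widths recorded in output
#'   headers for the localization (5 px) and pulse-chase (7 px) profiles.
#' @param normalization Per-cell kymograph normalization before averaging.
#' @param snapshot_fraction,pole_window Parameters of
#'   [pole_intensity_snapshot()].
#' @param terminal_fraction Brightest-pole window for the demograph.
#' @param threshold_fraction Label-boundary threshold for
#'   [measure_polar_growth()].
#' @param reference_strain Reference for pairwise super-plot contrasts;
#'   default the first strain.
#' @param value_column Per-cell quantity carried into the super plot.
#' @param adjust Multiplicity adjustment for pairwise contrasts.
#' @param emit_images Also render and write toy TIFF frames (slow; default
#'   off).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(strains = list(WT = list(rate_old = 0.133, rate_new = 0.057),
                                           mutant = list(rate_old = 0.095, rate_new = 0.095)),
                            n_replicates = 3, n_cells = 30, seed = 1L,
                            grid_t = 50, grid_l = 100,
                            width_px = 5, pulse_width_px = 7,
                            normalization = "row_sum",
                            snapshot_fraction = 0.25, pole_window = 0.1,
                            terminal_fraction = 0.1, threshold_fraction = 0.5,
                            reference_strain = NULL, value_column = "share_old",
                            adjust = "holm", emit_images = FALSE) {
  if (is.null(names(strains)) || any(names(strains) == "")) {
    abort("`strains` must be a named list", class = "polegrow_config_error")
  }
  cfg <- list(
    strains = strains, n_replicates = as.integer(n_replicates),
    n_cells = as.integer(n_cells), seed = as.integer(seed),
    grid_t = as.integer(grid_t), grid_l = as.integer(grid_l),
    width_px = as.integer(width_px), pulse_width_px = as.integer(pulse_width_px),
    normalization = normalization,
    snapshot_fraction = snapshot_fraction, pole_window = pole_window,
    terminal_fraction = terminal_fraction,
    threshold_fraction = threshold_fraction,
    reference_strain = reference_strain %||% names(strains)[1],
    value_column = value_column, adjust = adjust,
    emit_images = isTRUE(emit_images)
  )
  if (!cfg$reference_strain %in% names(strains)) {
    abort("`reference_strain` must name one of the strains",
          class = "polegrow_config_error")
  }
  # every strain override must be a valid sim_config argument
  for (s in names(strains)) {
    extra <- setdiff(names(strains[[s]]), names(formals(sim_config)))
    if (length(extra) > 0) {
      abort(sprintf("strain '%s': unknown sim_config key(s): %s", s,
                    paste(extra, collapse = ", ")),
            class = "polegrow_config_error")
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown top-level keys are rejected.
#'
#' @param path Path to a JSON file whose keys are [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$strains)) {
    raw$strains <- lapply(raw$strains, as.list)
  }
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")),
          class = "polegrow_config_error")
  }
  do.call(pipeline_config, raw)
}

# sim_config for one strain x replicate, with a derived sub-seed (< 2^31)
strain_sim_config <- function(config, strain, replicate_idx) {
  strain_idx <- match(strain, names(config$strains))
  overrides <- config$strains[[strain]]
  overrides$seed <- (config$seed + 7919L * strain_idx + 104729L * replicate_idx) %%
    2147483647L
  do.call(sim_config, overrides)
}

pipeline_stages <- c("simulate", "profile", "kymo", "demograph", "growth", "stats")

#' Run the full analysis pipeline on simulated cohorts
#'
#' Executes the requested stages in order -- `simulate` (lineages, raw
#' lab-frame localization profiles, pulse-chase pairs), `profile` (pole
#' orientation from lineage geometry), `kymo` (per-strain average
#' kymographs and pole-intensity snapshots), `demograph`, `growth`
#' (pulse-chase per-pole measurements), `stats` (replicate medians and the
#' paired one-way ANOVA) -- writing every intermediate as self-describing
#' delimited text under `out_dir`, plus a JSON run manifest with the config
#' snapshot, seed, and per-file MD5 digests. Re-running with the same
#' config and seed reproduces byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()] or path to a JSON pipeline config.
#' @param out_dir Output directory (created if needed).
#' @param stages Ordered subset of
#'   `c("simulate", "profile", "kymo", "demograph", "growth", "stats")`.
#' @param seed Optional override of `config$seed`.
#' @return The manifest, invisibly (also written to
#'   `run_manifest.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         stages = pipeline_stages, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown) > 0) {
    abort(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  stages <- pipeline_stages[pipeline_stages %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  need <- function(file, producer) {
    if (!file.exists(p(file))) {
      abort(sprintf("missing upstream artifact '%s': run stage '%s' first",
                    file, producer),
            class = "polegrow_missing_upstream")
    }
  }
  common_meta <- function() list(seed = config$seed,
                                 convention = "0-based sample_index; index 0 = new pole when orientation is new_to_old")
  written <- character(0)
  note <- function(f) written <<- unique(c(written, f))

  for (stage in stages) {
    message(sprintf("[polegrow] stage %s (seed %d)", stage, config$seed))
    switch(stage,
      simulate = {
        lineages <- NULL; raw_profiles <- NULL; pairs <- NULL
        for (strain in names(config$strains)) {
          for (rep_i in seq_len(config$n_replicates)) {
            scfg <- strain_sim_config(config, strain, rep_i)
            full_lin <- simulate_cohort(scfg, config$n_cells, full = TRUE)
            cohort <- full_lin[full_lin$in_cohort, ]
            prefix <- sprintf("%s_r%d_", strain, rep_i)
            relabel <- function(df) dplyr::mutate(
              df, cell_id = paste0(prefix, .data$cell_id),
              strain = strain, replicate = rep_i)
            tracks <- render_cohort_tracks(cohort, scfg, "lab")
            pc <- render_pulse_chase_cohort(cohort, scfg)
            lin <- flatten_lineage(full_lin) |>
              dplyr::mutate(cell_id = paste0(prefix, .data$cell_id),
                            mother_id = dplyr::if_else(
                              is.na(.data$mother_id), NA_character_,
                              paste0(prefix, .data$mother_id)),
                            strain = strain, replicate = rep_i)
            lineages <- dplyr::bind_rows(lineages, lin)
            raw_profiles <- dplyr::bind_rows(raw_profiles, relabel(tracks))
            pairs <- dplyr::bind_rows(pairs, relabel(pc))
            if (config$emit_images) {
              img <- render_frame_image(cohort, cohort$birth_frame[1], scfg)
              write_frames_tiff(list(img$phase), p(paste0(prefix, "phase.tif")))
              write_frames_tiff(list(img$fluor), p(paste0(prefix, "fluor.tif")))
              write_mask_tiff(list(img$mask), p(paste0(prefix, "mask.tif")))
              note(paste0(prefix, "phase.tif")); note(paste0(prefix, "fluor.tif"))
              note(paste0(prefix, "mask.tif"))
            }
          }
        }
        write_polegrow_table(lineages, p("lineage.tsv"),
                             c(common_meta(), stage = "simulate"))
        write_polegrow_table(raw_profiles, p("profiles_raw.tsv"),
                             c(common_meta(), stage = "simulate",
                               width_px = config$width_px))
        write_polegrow_table(pairs, p("pulsechase.tsv"),
                             c(common_meta(), stage = "simulate",
                               width_px = config$pulse_width_px))
        note("lineage.tsv"); note("profiles_raw.tsv"); note("pulsechase.tsv")
      },
      profile = {
        need("profiles_raw.tsv", "simulate"); need("lineage.tsv", "simulate")
        raw <- read_polegrow_table(p("profiles_raw.tsv"))
        lin <- read_polegrow_table(p("lineage.tsv"))
        oriented <- orient_track_new_to_old(raw, lin)
        write_polegrow_table(oriented, p("profiles.tsv"),
                             c(common_meta(), stage = "profile"))
        note("profiles.tsv")
      },
      kymo = {
        need("profiles.tsv", "profile")
        profiles <- read_polegrow_table(p("profiles.tsv"))
        snapshots <- NULL
        for (strain in names(config$strains)) {
          sub <- profiles[profiles$strain == strain, ]
          kymos <- kymographs_from_profiles(sub, config$grid_t, config$grid_l)
          avg <- average_kymographs(kymos, config$normalization)
          write_kymograph(avg, p(sprintf("avg_kymograph_%s.tsv", strain)),
                          meta = list(seed = config$seed, strain = strain))
          note(sprintf("avg_kymograph_%s.tsv", strain))
          snap <- pole_intensity_snapshot(kymos, config$snapshot_fraction,
                                          config$pole_window)
          snap$strain <- strain
          snapshots <- dplyr::bind_rows(snapshots, snap)
        }
        rep_lookup <- dplyr::distinct(profiles, .data$cell_id, .data$replicate)
        snapshots <- dplyr::left_join(snapshots, rep_lookup, by = "cell_id")
        write_polegrow_table(snapshots, p("pole_snapshot.tsv"),
                             c(common_meta(), stage = "kymo",
                               cycle_fraction = config$snapshot_fraction,
                               pole_window = config$pole_window))
        note("pole_snapshot.tsv")
      },
      demograph = {
        need("profiles.tsv", "profile")
        profiles <- read_polegrow_table(p("profiles.tsv"))
        for (strain in names(config$strains)) {
          sub <- profiles[profiles$strain == strain, ]
          # single-timepoint snapshot: each cell's last observed frame
          last <- sub |>
            dplyr::group_by(.data$cell_id) |>
            dplyr::filter(.data$frame == max(.data$frame)) |>
            dplyr::ungroup()
          demo <- build_demograph(last, config$terminal_fraction)
          write_demograph(demo, p(sprintf("demograph_%s.tsv", strain)),
                          meta = list(seed = config$seed, strain = strain))
          note(sprintf("demograph_%s.tsv", strain))
        }
      },
      growth = {
        need("pulsechase.tsv", "simulate"); need("lineage.tsv", "simulate")
        pairs <- read_polegrow_table(p("pulsechase.tsv"))
        lin <- read_polegrow_table(p("lineage.tsv"))
        # pole-resolved measurement requires known orientation
        founders <- lin$cell_id[lin$founder]
        n_excl <- length(intersect(unique(pairs$cell_id), founders))
        if (n_excl > 0) {
          message(sprintf("[polegrow] growth: excluding %d founder cell(s) with unknown pole identity", n_excl))
        }
        pairs <- pairs[!pairs$cell_id %in% founders, ]
        scfg1 <- strain_sim_config(config, names(config$strains)[1], 1L)
        meas <- measure_polar_growth_cohort(
          pairs, threshold_fraction = config$threshold_fraction,
          background = scfg1$background, pixel_size_um = scfg1$pixel_size_um)
        meas$growth_old_pct_birth <- NA_real_
        birth_len <- setNames(lin$birth_length_um, lin$cell_id)
        meas$growth_old_pct_birth <- 100 * meas$growth_old_um /
          birth_len[meas$cell_id]
        write_polegrow_table(meas, p("growth.tsv"),
                             c(common_meta(), stage = "growth",
                               threshold_fraction = config$threshold_fraction))
        note("growth.tsv")
      },
      stats = {
        need("growth.tsv", "growth")
        meas <- read_polegrow_table(p("growth.tsv"))
        med <- replicate_medians(meas, value = config$value_column)
        fit <- paired_oneway_anova(med, reference = config$reference_strain,
                                   adjust = config$adjust)
        write_polegrow_table(med, p("stats_medians.tsv"),
                             c(common_meta(), stage = "stats",
                               value = config$value_column))
        write_polegrow_table(tidy(fit), p("stats_anova.tsv"),
                             c(common_meta(), stage = "stats"))
        report <- utils::capture.output(print(fit))
        writeLines(c(sprintf("# polegrow stats report (seed %d, value %s)",
                             config$seed, config$value_column), report),
                   p("stats_report.txt"))
        note("stats_medians.tsv"); note("stats_anova.tsv"); note("stats_report.txt")
      }
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("polegrow")),
    seed = config$seed,
    stages = stages,
    config = unclass(config),
    digests = as.list(tools::md5sum(file.path(out_dir, sort(written)))) |>
      setNames(sort(written)),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
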