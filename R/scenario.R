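scenario_dir <- function() system.file("extdata", "scenarios",
                                       package = "drgstereo")

#' List shipped scenario configurations
#'
#' @return character vector of scenario ids.
#' @export
list_scenarios <- function() {
  sub("\\.yaml$", "", list.files(scenario_dir(), pattern = "\\.yaml$"))
}

#' Load a scenario configuration
#'
#' Reads a YAML scenario file (a shipped id or a path), validates it, and
#' builds the runnable configuration: subpopulation specs, injury scenario,
#' and label specs. For two-class tracer scenarios the marker class's
#' survival schedule is derived at load time as `base_survival * rho`, with
#' `rho = calibrate_survival_ratio(p_contra, p_ipsi)` — the calibration is
#' always recomputed from the target proportions, never stored.
#'
#' @param scenario scenario id (see [list_scenarios()]) or a YAML file path.
#' @return a `drg_scenario` list.
#' @export
load_scenario <- function(scenario) {
  if (inherits(scenario, "drg_scenario")) return(scenario)
  path <- if (file.exists(scenario)) scenario
          else file.path(scenario_dir(), paste0(scenario, ".yaml"))
  if (!file.exists(path))
    stop("unknown scenario '", scenario, "'; available: ",
         paste(list_scenarios(), collapse = ", "), call. = FALSE)
  cfg <- yaml::read_yaml(path)

  subpops <- lapply(cfg$subpopulations, function(s)
    subpop_spec(s$name, s$fraction, s$soma_area_mean, s$soma_area_sd,
                s$nucleus_ratio %||% 0.45, unlist(s$markers)))
  names(subpops) <- vapply(subpops, `[[`, character(1), "name")

  sched <- cfg$injury$survival_schedule
  if (!is.null(cfg$calibration)) {
    cal <- cfg$calibration
    rho <- calibrate_survival_ratio(cal$p_contra, cal$p_ipsi)
    base <- unlist(cal$base_survival)
    names(base) <- names(cal$base_survival)
    marker_sched <- stats::setNames(pmin(1, base * rho), names(base))
    sched <- stats::setNames(
      lapply(names(subpops), function(sp)
        if (sp == cal$marker_subpop) marker_sched else base),
      names(subpops))
    cfg$calibration$rho <- rho
  } else {
    sched <- lapply(sched, function(s) {
      v <- unlist(s); names(v) <- names(s); v
    })
  }
  injury <- injury_scenario(cfg$scenario_id,
                            unlist(cfg$injury$axotomized_territories),
                            sched)
  labels <- lapply(cfg$labels, function(l)
    label_spec(l$label, l$target, l$sensitivity, l$false_positive %||% 0,
               marker = l$marker, territory = l$territory))
  structure(list(scenario_id = cfg$scenario_id,
                 n_neurons = cfg$n_neurons,
                 semi_axes = unlist(cfg$semi_axes),
                 territory_fractions = unlist(cfg$territory_fractions),
                 subpops = subpops, injury = injury, labels = labels,
                 sectioning = cfg$sectioning,
                 timepoints = unlist(cfg$timepoints),
                 readouts = unlist(cfg$readouts),
                 colabel = cfg$colabel, calibration = cfg$calibration,
                 source = basename(path)),
            class = "drg_scenario")
}

#' @export
print.drg_scenario <- function(x, ...) {
  cat("Scenario", x$scenario_id, "-", x$n_neurons, "neurons,",
      length(x$subpops), "subpopulations; readouts:",
      paste(x$readouts, collapse = ", "), "\n")
  if (!is.null(x$calibration))
    cat(sprintf("  calibrated survival odds ratio rho = %.4f (p_contra %.3f -> p_ipsi %.3f)\n",
                x$calibration$rho, x$calibration$p_contra,
                x$calibration$p_ipsi))
  invisible(x)
}

simulate_one <- function(scn, seed, injured = TRUE) {
  g <- generate_ganglion(n = scn$n_neurons, semi_axes = scn$semi_axes,
                         subpops = scn$subpops,
                         territory_fractions = scn$territory_fractions,
                         seed = seed)
  if (injured)
    g <- apply_injury(g, scn$injury, day = 0, seed = derive_seed(seed, 1))
  g <- apply_labels(g, scn$labels, seed = derive_seed(seed, 2))
  g
}

section_scenario <- function(scn, g, seed) {
  sc <- scn$sectioning
  cut_sections(g, thickness = sc$thickness %||% 30, dz = sc$dz %||% 3,
               n_slides = sc$n_slides %||% 5,
               axial_shrinkage = sc$axial_shrinkage %||% 0.85,
               thickness_noise = sc$thickness_noise %||% 0.10,
               seed = derive_seed(seed, 3))
}

#' Run a scenario end to end
#'
#' For each seed: generate the ganglion, apply injury and labels, cut it
#' into serial sections, and compute the configured readouts at each
#' timepoint. `stereology` readouts give the total-number estimate and
#' per-label dissector counts on the analyzed slide; `colabel` readouts give
#' the co-labelling proportion of the reference-labelled nucleated cells on
#' the analyzed slide for the injured (ipsi) side and for an independently
#' generated uninjured (contra) ganglion. The same ganglion and section
#' series are reused across timepoints (survival quantiles are fixed per
#' neuron), so time courses are paired within a seed. Fully deterministic
#' given `(scenario, seeds)`.
#'
#' @param scenario scenario id, path, or `drg_scenario`.
#' @param seeds integer vector of seeds (>= 1 required).
#' @param timepoints days post-injury (default: the scenario's).
#' @param outdir optional output directory; when given, the results table,
#'   a deterministic summary JSON (with config hash and package version) and
#'   per-seed cell tables are written there.
#' @return a `scenario_run`: `scenario_id`, `seeds`, `timepoints`,
#'   `results` data frame, `config_hash`, `package_version`.
#' @export
run_scenario <- function(scenario, seeds, timepoints = NULL, outdir = NULL) {
  scn <- load_scenario(scenario)
  if (!length(seeds)) stop("need at least one seed", call. = FALSE)
  timepoints <- timepoints %||% scn$timepoints
  hash <- rlang::hash(unclass(scn))
  rows <- list()
  cells_out <- list()

  for (seed in seeds) {
    gi <- simulate_one(scn, seed, injured = TRUE)
    series <- section_scenario(scn, gi, seed)
    if ("colabel" %in% scn$readouts) {
      gc <- simulate_one(scn, derive_seed(seed, 10), injured = FALSE)
      series_c <- section_scenario(scn, gc, derive_seed(seed, 11))
      cells_c <- cells_from_series(gc, series_c, animal = seed,
                                   side = "contra")
    }
    for (day in timepoints) {
      gi <- alive_at(gi, day)
      if ("stereology" %in% scn$readouts) {
        est <- estimate_ganglion(gi, series)
        row <- data.frame(seed = seed, timepoint = day, side = "ipsi",
                          N_DRG = est$N_DRG, V_DRG = est$V_DRG,
                          N_v_bar = est$N_v_bar, l = est$l,
                          n_alive_true = sum(gi$neurons$alive))
        for (lab in scn$labels)
          row[[paste0("count_", lab$label)]] <-
            dissector_count(gi, series, label = lab$label)
        rows[[length(rows) + 1]] <- row
      }
      if ("colabel" %in% scn$readouts) {
        cells_i <- cells_from_series(gi, series, animal = seed,
                                     side = "ipsi")
        cells <- rbind(cells_i, cells_c)
        pr <- colabel_proportion(cells, scn$colabel$reference,
                                 scn$colabel$marker)
        pr$seed <- seed; pr$timepoint <- day
        rows[[length(rows) + 1]] <- pr
        cells_out[[paste0("seed", seed, "_day", day)]] <- cells
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  run <- structure(list(scenario_id = scn$scenario_id,
                        seeds = as.integer(seeds),
                        timepoints = timepoints, results = results,
                        config_hash = hash,
                        package_version =
                          as.character(utils::packageVersion("drgstereo"))),
                   class = "scenario_run")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(outdir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(scenario_id = run$scenario_id, config_hash = run$config_hash,
           package_version = run$package_version, seeds = run$seeds,
           timepoints = run$timepoints, results = results),
      file.path(outdir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (nm in names(cells_out))
      write_cells(cells_out[[nm]],
                  file.path(outdir, paste0("cells_", nm, ".csv")))
  }
  run
}

#' @export
print.scenario_run <- function(x, ...) {
  cat("Scenario run:", x$scenario_id, "-", length(x$seeds), "seed(s),",
      "timepoints", paste(x$timepoints, collapse = ", "),
      "\n  config hash:", x$config_hash, "\n")
  print(utils::head(x$results, 10), row.names = FALSE, digits = 4)
  if (nrow(x$results) > 10) cat("  ...", nrow(x$results), "rows\n")
  invisible(x)
}

cell_cols <- c("animal", "side", "section", "slide", "neuron_id",
               "nucleus_visible", "max_area", "labels")

#' Write / read a cell table
#'
#' CSV round trip for tables of counted cell profiles. Mandatory columns:
#' `animal`, `side`, `section`, `slide`, `neuron_id`, `nucleus_visible`,
#' `max_area`, `labels`; unknown extra columns are preserved.
#'
#' @param cells a cell table data frame.
#' @param path CSV path.
#' @return `write_cells` returns `path` invisibly; `read_cells` the table.
#' @export
write_cells <- function(cells, path) {
  missing <- setdiff(cell_cols, names(cells))
  if (length(missing))
    stop("cell table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
read_cells <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("failed to parse '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  missing <- setdiff(cell_cols, names(df))
  if (length(missing))
    stop("cell table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df$labels[is.na(df$labels)] <- ""
  df
}
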