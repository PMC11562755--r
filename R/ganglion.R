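#' Subpopulation specification
#'
#' Describes one molecularly defined class of DRG neurons: its share of the
#' ganglion, the mean and SD of its maximal soma cross-sectional area (µm²),
#' the nucleus-to-soma radius ratio, and the marker genes it expresses.
#' Soma areas are drawn from a lognormal moment-matched to (mean, SD), which
#' gives the positive, right-skewed size distributions seen in DRG soma-size
#' histograms.
#'
#' @param name subpopulation name.
#' @param fraction share of all neurons, in `[0, 1]`.
#' @param soma_area_mean mean maximal cross-sectional area, µm².
#' @param soma_area_sd SD of maximal cross-sectional area, µm².
#' @param nucleus_ratio nucleus radius as a fraction of soma radius, in (0, 1).
#' @param markers character vector of intrinsically expressed label names.
#' @return a `subpop_spec` list.
#' @export
subpop_spec <- function(name, fraction, soma_area_mean, soma_area_sd,
                        nucleus_ratio = 0.45, markers = character()) {
  stopifnot(is.character(name), length(name) == 1)
  check_prob(fraction, "fraction")
  if (soma_area_mean <= 0) stop("soma_area_mean must be > 0", call. = FALSE)
  if (soma_area_sd < 0) stop("soma_area_sd must be >= 0", call. = FALSE)
  if (nucleus_ratio <= 0 || nucleus_ratio >= 1)
    stop("nucleus_ratio must be in (0, 1)", call. = FALSE)
  structure(list(name = name, fraction = fraction,
                 soma_area_mean = soma_area_mean, soma_area_sd = soma_area_sd,
                 nucleus_ratio = nucleus_ratio, markers = as.character(markers)),
            class = "subpop_spec")
}

#' Default DRG subpopulation composition
#'
#' The composition used by the whole-DRG injury scenario: nonpeptidergic
#' (Mrgprd/NP1), peptidergic (CGRP), cold-sensitive (Trpm8), myelinated
#' (Thy1-sampled) and a residual class. Mrgprd soma sizes use the measured
#' 361 +/- 138 µm² (mean +/- SD) maximal cross-sectional area; other classes
#' use field-typical values (small nociceptors ~300-400 µm², myelinated
#' afferents substantially larger).
#'
#' @return a list of [subpop_spec()] objects whose fractions sum to 1.
#' @export
default_subpopulations <- function() {
  list(
    subpop_spec("mrgprd",     0.30, 361, 138, markers = "Mrgprd"),
    subpop_spec("cgrp",       0.30, 380, 150, markers = "CGRP"),
    subpop_spec("trpm8",      0.08, 300, 110, markers = "Trpm8"),
    subpop_spec("myelinated", 0.25, 700, 250, markers = "Thy1"),
    subpop_spec("other",      0.07, 450, 180)
  )
}

lognormal_pars <- function(mean, sd) {
  if (sd == 0) return(c(mu = log(mean), sigma = 0))
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# uniform sampling inside an axis-aligned ellipsoid by rejection from the
# bounding box (acceptance ~ pi/6)
sample_ellipsoid <- function(n, semi_axes) {
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    m <- max(16, ceiling((n - nrow(out)) * 2.2))
    x <- stats::runif(m, -1, 1); y <- stats::runif(m, -1, 1)
    z <- stats::runif(m, -1, 1)
    keep <- x^2 + y^2 + z^2 < 1
    out <- rbind(out, cbind(x[keep], y[keep], z[keep]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  sweep(out, 2, semi_axes, `*`)
}

#' Generate a synthetic ganglion with known ground truth
#'
#' Places `n` neurons uniformly at random inside an axis-aligned ellipsoid,
#' assigns each to a subpopulation by a multinomial draw on the configured
#' fractions, draws its maximal soma cross-sectional area from the
#' subpopulation's moment-matched lognormal (soma radius = sqrt(area/pi)),
#' puts a concentric spherical nucleus inside the soma, and assigns a
#' peripheral innervation territory (tibial/peroneal/sural). The default
#' scale (8000 neurons) matches a mouse L4 DRG. Deterministic given
#' `(config, seed)`.
#'
#' @param n number of neurons (>= 0).
#' @param semi_axes ellipsoid semi-axes `(a_x, a_y, a_z)` in µm.
#' @param subpops list of [subpop_spec()]; fractions must sum to 1.
#' @param territory_fractions named fractions for tibial/peroneal/sural.
#' @param seed integer seed.
#' @return a `ganglion` object: `semi_axes`, `neurons` data frame, `seed`,
#'   `params`.
#' @export
generate_ganglion <- function(n = 8000,
                              semi_axes = c(250, 200, 350),
                              subpops = default_subpopulations(),
                              territory_fractions = c(tibial = 0.35,
                                                      peroneal = 0.45,
                                                      sural = 0.20),
                              seed = 1L) {
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (length(semi_axes) != 3 || any(semi_axes <= 0))
    stop("semi_axes must be three positive lengths", call. = FALSE)
  if (inherits(subpops, "subpop_spec")) subpops <- list(subpops)
  fr <- vapply(subpops, `[[`, numeric(1), "fraction")
  check_fractions(fr, "subpopulation fractions")
  check_fractions(territory_fractions, "territory fractions")
  spnames <- vapply(subpops, `[[`, character(1), "name")
  names(subpops) <- spnames

  set.seed(seed)
  if (n == 0) {
    neurons <- data.frame(id = integer(), subpop = character(),
                          x = numeric(), y = numeric(), z = numeric(),
                          soma_radius = numeric(), nucleus_radius = numeric(),
                          territory = character(), axotomized = logical(),
                          alive = logical(), labels = character(),
                          stringsAsFactors = FALSE)
  } else {
    pos <- sample_ellipsoid(n, semi_axes)
    subpop <- sample(spnames, n, replace = TRUE, prob = fr)
    area <- numeric(n)
    ratio <- numeric(n)
    for (sp in spnames) {
      idx <- which(subpop == sp)
      if (!length(idx)) next
      lp <- lognormal_pars(subpops[[sp]]$soma_area_mean,
                           subpops[[sp]]$soma_area_sd)
      area[idx] <- stats::rlnorm(length(idx), lp["mu"], lp["sigma"])
      ratio[idx] <- subpops[[sp]]$nucleus_ratio
    }
    r <- sqrt(area / pi)
    territory <- sample(names(territory_fractions), n, replace = TRUE,
                        prob = territory_fractions)
    neurons <- data.frame(id = seq_len(n), subpop = subpop,
                          x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          soma_radius = r, nucleus_radius = ratio * r,
                          territory = territory, axotomized = FALSE,
                          alive = TRUE, labels = "",
                          stringsAsFactors = FALSE)
  }
  structure(list(semi_axes = as.numeric(semi_axes), neurons = neurons,
                 seed = as.integer(seed),
                 params = list(n = n, subpops = subpops,
                               territory_fractions = territory_fractions),
                 injury = NULL, day = 0),
            class = "ganglion")
}

#' @export
print.ganglion <- function(x, ...) {
  cat("Synthetic ganglion:", nrow(x$neurons), "neurons,",
      sum(x$neurons$alive), "alive (day", x$day, ")\n")
  cat("  semi-axes (um):", paste(x$semi_axes, collapse = " x "),
      " seed:", x$seed, "\n")
  if (nrow(x$neurons))
    print(round(100 * prop.table(table(x$neurons$subpop)), 1))
  invisible(x)
}

# piecewise-linear survival interpolation; day 0 survival is 1 by definition,
# survival is held constant beyond the last scheduled day
survival_at <- function(days, surv, day) {
  o <- order(days)
  days <- days[o]; surv <- surv[o]
  if (days[1] > 0) { days <- c(0, days); surv <- c(1, surv) }
  if (abs(days[1]) < 1e-12 && abs(surv[1] - 1) > 1e-9)
    stop("day-0 survival must be 1", call. = FALSE)
  if (any(diff(surv) > 1e-12))
    stop("survival fractions must be non-increasing over days", call. = FALSE)
  stats::approx(days, surv, xout = day, rule = 2)$y
}

#' Injury scenario specification
#'
#' @param scenario_id text identifier.
#' @param axotomized_territories territories whose neurons are axotomized
#'   (e.g. `c("tibial", "peroneal")` for spared nerve injury, which spares
#'   the sural branch).
#' @param survival_schedule named list: subpopulation -> named numeric vector
#'   of survival fractions by day (names are days). Fractions must be in
#'   `[0, 1]` and non-increasing; day-0 survival is 1.
#' @return an `injury_scenario` list.
#' @export
injury_scenario <- function(scenario_id, axotomized_territories,
                            survival_schedule) {
  for (sp in names(survival_schedule)) {
    s <- survival_schedule[[sp]]
    check_prob(unname(s), paste0("survival fractions for '", sp, "'"))
    survival_at(as.numeric(names(s)), as.numeric(s), 0) # validates monotone
  }
  structure(list(scenario_id = scenario_id,
                 axotomized_territories = axotomized_territories,
                 survival_schedule = survival_schedule),
            class = "injury_scenario")
}

#' Apply injury-induced neuron loss
#'
#' Flags neurons in the axotomized territories as axotomized and marks each
#' axotomized neuron alive at `day` with its subpopulation's scheduled
#' survival probability; intact neurons are always alive. Each neuron draws a
#' single survival quantile, so the set of survivors at a later day is nested
#' inside the set at any earlier day (death is instantaneous removal: the
#' method measures presence/absence only). Deterministic given the seed.
#'
#' @param g a `ganglion`.
#' @param scenario an [injury_scenario()].
#' @param day days post-injury at which to evaluate survival.
#' @param seed integer seed (defaults to a child of the ganglion seed).
#' @return the ganglion with `axotomized`, `alive` and survival state set;
#'   use [alive_at()] to re-evaluate other days without re-drawing.
#' @export
apply_injury <- function(g, scenario, day, seed = NULL) {
  stopifnot(inherits(g, "ganglion"))
  sched <- scenario$survival_schedule
  missing_sp <- setdiff(unique(g$neurons$subpop), names(sched))
  if (length(missing_sp))
    stop("survival schedule missing subpopulation(s): ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  seed <- seed %||% derive_seed(g$seed, 1L)
  set.seed(seed)
  n <- nrow(g$neurons)
  g$neurons$axotomized <- g$neurons$territory %in% scenario$axotomized_territories
  g$injury <- list(scenario_id = scenario$scenario_id,
                   schedule = sched,
                   survival_u = stats::runif(n), seed = seed)
  alive_at(g, day)
}

#' Evaluate survival at a given day
#'
#' Re-evaluates the `alive` flags of an injured ganglion at another day using
#' the survival quantiles drawn by [apply_injury()] (so survivor sets are
#' nested across days).
#'
#' @param g an injured `ganglion`.
#' @param day days post-injury.
#' @return the ganglion with `alive` and `day` updated.
#' @export
alive_at <- function(g, day) {
  stopifnot(inherits(g, "ganglion"))
  if (is.null(g$injury)) {
    g$day <- day
    g$neurons$alive <- rep(TRUE, nrow(g$neurons))
    return(g)
  }
  sched <- g$injury$schedule
  s <- rep(1, nrow(g$neurons))
  for (sp in names(sched)) {
    idx <- which(g$neurons$subpop == sp & g$neurons$axotomized)
    if (!length(idx)) next
    sc <- sched[[sp]]
    s[idx] <- survival_at(as.numeric(names(sc)), as.numeric(sc), day)
  }
  g$neurons$alive <- !g$neurons$axotomized | g$injury$survival_u <= s
  g$day <- day
  g
}

#' Labelling specification
#'
#' A label is applied to each neuron independently: with probability
#' `sensitivity` if the neuron is a member of the label's target set, else
#' with probability `false_positive`. Target sets cover the labelling
#' strategies used in practice: genetic reporters of a marker gene
#' (`target = "marker"`), injury-induced reporters (`"axotomized"` /
#' `"intact"`), retrograde tracers restricted to an innervation territory
#' (`"territory"`, e.g. FastBlue in the tibial territory), or constitutive
#' labels (`"all"`).
#'
#' @param label label name.
#' @param target one of `"marker"`, `"axotomized"`, `"intact"`,
#'   `"territory"`, `"all"`.
#' @param sensitivity P(labelled | member).
#' @param false_positive P(labelled | non-member).
#' @param marker marker name (for `target = "marker"`), matched against the
#'   subpopulations' `markers` sets.
#' @param territory territory name (for `target = "territory"`).
#' @return a `label_spec` list.
#' @export
label_spec <- function(label, target, sensitivity, false_positive = 0,
                       marker = NULL, territory = NULL) {
  target <- match.arg(target, c("marker", "axotomized", "intact",
                                "territory", "all"))
  check_prob(sensitivity, "sensitivity")
  check_prob(false_positive, "false_positive")
  if (target == "marker" && is.null(marker))
    stop("target 'marker' needs a marker name", call. = FALSE)
  if (target == "territory" && is.null(territory))
    stop("target 'territory' needs a territory name", call. = FALSE)
  structure(list(label = label, target = target, sensitivity = sensitivity,
                 false_positive = false_positive, marker = marker,
                 territory = territory),
            class = "label_spec")
}

label_membership <- function(g, spec) {
  nn <- g$neurons
  switch(spec$target,
         all = rep(TRUE, nrow(nn)),
         axotomized = nn$axotomized,
         intact = !nn$axotomized,
         territory = nn$territory == spec$territory,
         marker = {
           sp_has <- vapply(g$params$subpops, function(s)
             spec$marker %in% s$markers, logical(1))
           nn$subpop %in% names(g$params$subpops)[sp_has]
         })
}

#' Apply labels to a ganglion
#'
#' @param g a `ganglion`.
#' @param specs a [label_spec()] or list of them.
#' @param seed integer seed (defaults to a child of the ganglion seed).
#' @return the ganglion with labels appended to the `labels` column.
#' @export
apply_labels <- function(g, specs, seed = NULL) {
  stopifnot(inherits(g, "ganglion"))
  if (inherits(specs, "label_spec")) specs <- list(specs)
  seed <- seed %||% derive_seed(g$seed, 2L)
  set.seed(seed)
  n <- nrow(g$neurons)
  for (spec in specs) {
    member <- label_membership(g, spec)
    p <- ifelse(member, spec$sensitivity, spec$false_positive)
    hit <- stats::runif(n) < p
    g$neurons$labels[hit] <- add_label(g$neurons$labels[hit], spec$label)
  }
  g
}

#' Survival odds ratio reproducing a co-labelling proportion shift
#'
#' Given the contralateral (uninjured) proportion `p_contra` of
#' tracer-labelled neurons that carry a marker and the ipsilateral
#' (post-injury) proportion `p_ipsi`, returns the ratio
#' `rho = odds(p_ipsi) / odds(p_contra)`. Simulating marker-positive neurons
#' with survival `s * rho` against marker-negative survival `s` (any `s` with
#' `s * rho <= 1`) yields expected ipsilateral proportion `p_ipsi`, because
#' the post-injury odds of being marker-positive among survivors scale by the
#' survival ratio.
#'
#' @param p_contra proportion in (0, 1).
#' @param p_ipsi proportion in `[0, 1)`.
#' @return the survival odds ratio.
#' @export
calibrate_survival_ratio <- function(p_contra, p_ipsi) {
  if (!is.numeric(p_contra) || p_contra <= 0 || p_contra >= 1)
    stop("p_contra must be strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(p_ipsi) || p_ipsi < 0 || p_ipsi >= 1)
    stop("p_ipsi must be in [0, 1)", call. = FALSE)
  (p_ipsi / (1 - p_ipsi)) / (p_contra / (1 - p_contra))
}

#' Write / read a ganglion as CSV plus JSON sidecar
#'
#' One row per neuron; the generating configuration and seed go to a JSON
#' sidecar (`<path>.json`) for provenance.
#'
#' @param g a `ganglion`.
#' @param path CSV path.
#' @return `write_ganglion` returns `path` invisibly; `read_ganglion` returns
#'   a `ganglion` (without regenerating capability — survival state is frozen
#'   as written).
#' @export
write_ganglion <- function(g, path) {
  stopifnot(inherits(g, "ganglion"))
  utils::write.csv(g$neurons, path, row.names = FALSE)
  side <- list(semi_axes = g$semi_axes, seed = g$seed, day = g$day,
               n = g$params$n,
               territory_fractions = as.list(g$params$territory_fractions),
               subpops = lapply(g$params$subpops, unclass))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ganglion
#' @export
read_ganglion <- function(path) {
  nn <- utils::read.csv(path, stringsAsFactors = FALSE)
  nn$labels[is.na(nn$labels)] <- ""
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  subpops <- lapply(side$subpops, function(s)
    subpop_spec(s$name, s$fraction, s$soma_area_mean, s$soma_area_sd,
                s$nucleus_ratio, unlist(s$markers)))
  names(subpops) <- vapply(subpops, `[[`, character(1), "name")
  structure(list(semi_axes = as.numeric(side$semi_axes), neurons = nn,
                 seed = as.integer(side$seed),
                 params = list(n = side$n, subpops = subpops,
                               territory_fractions =
                                 unlist(side$territory_fractions)),
                 injury = NULL, day = side$day),
            class = "ganglion")
}
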