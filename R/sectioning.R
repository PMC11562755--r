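plane_grid <- function(z_lo, z_hi, dz) {
  K <- floor((z_hi - z_lo) / dz + 1e-9)
  z_lo + dz * (0:K)
}

#' Measured section thickness from local extremes
#'
#' Section thickness is measured as the mean of the thickest and thinnest
#' cell-containing regions of the section. With a single (uniform) local
#' thickness the nominal value is returned.
#'
#' @param local_thicknesses numeric vector of local thickness readings (µm).
#' @return `(max + min) / 2` in µm.
#' @export
measure_thickness <- function(local_thicknesses) {
  if (!length(local_thicknesses))
    stop("section has no cell-containing region; excluded from measurement",
         call. = FALSE)
  (max(local_thicknesses) + min(local_thicknesses)) / 2
}

#' Analytic cell-containing cross-sectional area
#'
#' Area of the ellipsoid's cross-section at height `z_m` (the middle optical
#' plane of a section): `pi * a_x * a_y * (1 - (z_m/a_z)^2)` for
#' `|z_m| <= a_z`, else 0 (with a warning, since such a section lies outside
#' the cell-containing region).
#'
#' @param z_m plane height, µm.
#' @param semi_axes ellipsoid semi-axes `(a_x, a_y, a_z)` in the same
#'   (processed-tissue) space as `z_m`.
#' @return area in µm².
#' @export
cell_area <- function(z_m, semi_axes) {
  a <- pi * semi_axes[1] * semi_axes[2] * (1 - (z_m / semi_axes[3])^2)
  outside <- abs(z_m) > semi_axes[3]
  if (any(outside)) {
    warning("section midplane outside the ganglion; area set to 0",
            call. = FALSE)
    a[outside] <- 0
  }
  a
}

#' Cut a ganglion into serial sections collected across slides
#'
#' Emulates cryosectioning: neuron z-coordinates are first rescaled by
#' `axial_shrinkage` (processed-tissue space), then the tissue is cut into
#' `thickness`-µm half-open sections `[z_lo, z_hi)` tiling the ganglion's
#' z-extent with a random phase offset (uniform in `[0, thickness)`, which
#' makes the Cavalieri sample a systematic uniform-random sample). Sections
#' are assigned serially to slides (`slide = index mod n_slides`) and one
#' slide is selected uniformly at random for analysis. Each section gets a
#' measured thickness — the mean of its thickest and thinnest simulated local
#' readings under a multiplicative uniform noise model — and its analytic
#' cell-containing area at the middle optical plane of its z-stack grid.
#'
#' @param g a `ganglion`.
#' @param thickness nominal section thickness, µm.
#' @param dz optical plane spacing, µm (z-stacks are built on this grid).
#' @param n_slides number of slides in serial collection.
#' @param axial_shrinkage axial shrinkage factor in (0, 1].
#' @param thickness_noise half-width of the multiplicative local-thickness
#'   variation (0 = uniform sections).
#' @param min_cell_fraction minimum fraction of the nominal thickness that
#'   must lie inside the tissue for an end section to be collected; thinner
#'   slivers are not identifiable as DRG sections and are excluded from the
#'   series (and from the section count `l`).
#' @param seed integer seed (defaults to a child of the ganglion seed).
#' @param phase optional explicit phase offset in `[0, thickness)`; by
#'   default drawn at random.
#' @return a `section_series`: a `sections` data frame (`index` 0-based,
#'   `z_lo`, `z_hi`, `slide` 0-based, `measured_thickness`,
#'   `mid_plane_area`), plus sectioning parameters, the analyzed slide, and
#'   processed-space geometry.
#' @export
cut_sections <- function(g, thickness = 30, dz = 3, n_slides = 5,
                         axial_shrinkage = 0.85, thickness_noise = 0.10,
                         min_cell_fraction = 0.5, seed = NULL, phase = NULL) {
  stopifnot(inherits(g, "ganglion"))
  if (thickness <= 0) stop("thickness must be > 0", call. = FALSE)
  if (dz <= 0 || dz >= thickness)
    stop("dz must satisfy 0 < dz < thickness", call. = FALSE)
  if (axial_shrinkage <= 0 || axial_shrinkage > 1)
    stop("axial_shrinkage must be in (0, 1]", call. = FALSE)
  seed <- seed %||% derive_seed(g$seed, 3L)
  set.seed(seed)

  if (any(2 * g$neurons$nucleus_radius >= thickness))
    warning("some nuclei have diameter >= section thickness; ",
            "the dissector counting rule may double-count them",
            call. = FALSE)

  az_p <- g$semi_axes[3] * axial_shrinkage
  if (is.null(phase)) phase <- stats::runif(1) * thickness
  start <- -az_p - phase
  n_sec <- ceiling((az_p - start) / thickness - 1e-9)
  idx <- 0:(n_sec - 1)
  z_lo <- start + idx * thickness
  z_hi <- z_lo + thickness

  # thickness and midplane refer to the cell-containing part of each
  # section: interior sections are tissue through their full depth, while a
  # section straddling a pole of the ganglion contains cells only over its
  # overlap with the tissue — the measured (cell-containing) thickness and
  # the middle optical section of the cell-containing series both live there
  tis_lo <- pmax(z_lo, -az_p)
  tis_hi <- pmin(z_hi, az_p)
  t_cell <- pmax(tis_hi - tis_lo, 0)
  mt <- vapply(idx, function(i) {
    tc <- t_cell[i + 1]
    if (tc <= 0) return(0)
    if (thickness_noise == 0) return(tc)
    measure_thickness(tc * stats::runif(4, 1 - thickness_noise,
                                        1 + thickness_noise))
  }, numeric(1))

  semi_p <- c(g$semi_axes[1:2], az_p)
  z_m <- vapply(idx, function(i) {
    pl <- plane_grid(z_lo[i + 1], z_hi[i + 1], dz)
    ctr <- (tis_lo[i + 1] + tis_hi[i + 1]) / 2
    pl[which.min(abs(pl - ctr))]
  }, numeric(1))
  area <- suppressWarnings(cell_area(z_m, semi_p))
  # end slivers with less than min_cell_fraction of a section's depth in
  # tissue are not identifiable as DRG sections and are never collected
  sliver <- t_cell < min_cell_fraction * thickness
  if (any(sliver & t_cell > 0))
    message(sum(sliver & t_cell > 0),
            " end section(s) with sub-threshold cell-containing depth ",
            "excluded from collection")
  area[sliver] <- 0
  mt[sliver] <- 0

  sections <- data.frame(index = idx, z_lo = z_lo, z_hi = z_hi,
                         slide = idx %% n_slides,
                         measured_thickness = mt,
                         mid_plane_area = area)
  structure(list(sections = sections, thickness = thickness, dz = dz,
                 n_slides = n_slides,
                 analyzed_slide = sample(0:(n_slides - 1), 1),
                 axial_shrinkage = axial_shrinkage,
                 thickness_noise = thickness_noise,
                 phase = phase, semi_axes_proc = semi_p, seed = seed),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  cat("Section series:", nrow(x$sections), "sections of", x$thickness,
      "um on", x$n_slides, "slides (analyzed slide", x$analyzed_slide, ")\n")
  cat("  dz:", x$dz, "um  axial shrinkage:", x$axial_shrinkage,
      " phase:", round(x$phase, 2), "um\n")
  invisible(x)
}

#' Build the confocal z-stack of one section
#'
#' Optical planes sit on the grid `z_lo + k*dz`, from the top frame at the
#' upper cut surface down to the deepest grid plane at or above the lower cut
#' surface; when `thickness` is a multiple of `dz` the bottom frame lies on
#' the lower surface itself (full-thickness stack), so consecutive sections
#' share that physical level and the dissector's top-frame exclusion removes
#' exactly the profiles already countable in the section above. A living
#' neuron contributes a soma profile on plane z iff `|z - z_c| < r_soma`
#' (area `pi * (r^2 - (z - z_c)^2)`, the circle-slice formula) and its
#' nucleus is visible iff `|z - z_nucleus| < r_nucleus`. Dead neurons
#' contribute nothing.
#'
#' @param series a `section_series` from [cut_sections()].
#' @param index 0-based section index.
#' @param g the `ganglion` that was sectioned (its current `alive` flags are
#'   used).
#' @return an `optical_stack`: `section_index`, `slide`, `plane_zs`, and a
#'   `profiles` data frame (`plane_index` 0-based, `z`, `neuron_id`,
#'   `profile_area`, `nucleus_visible`).
#' @export
build_stack <- function(series, index, g) {
  stopifnot(inherits(series, "section_series"), inherits(g, "ganglion"))
  sec <- series$sections[series$sections$index == index, ]
  if (nrow(sec) != 1) stop("no section with index ", index, call. = FALSE)
  planes <- plane_grid(sec$z_lo, sec$z_hi, series$dz)

  nn <- g$neurons[g$neurons$alive, , drop = FALSE]
  zc <- nn$z * series$axial_shrinkage
  cand <- which(zc + nn$soma_radius > sec$z_lo - series$dz &
                  zc - nn$soma_radius < sec$z_hi + series$dz)
  prof <- vector("list", length(planes))
  for (k in seq_along(planes)) {
    zp <- planes[k]
    dzc <- zp - zc[cand]
    vis <- abs(dzc) < nn$soma_radius[cand]
    if (!any(vis)) next
    i <- cand[vis]
    prof[[k]] <- data.frame(
      plane_index = k - 1L, z = zp, neuron_id = nn$id[i],
      profile_area = pi * (nn$soma_radius[i]^2 - dzc[vis]^2),
      nucleus_visible = abs(dzc[vis]) < nn$nucleus_radius[i])
  }
  profiles <- do.call(rbind, prof)
  if (is.null(profiles))
    profiles <- data.frame(plane_index = integer(), z = numeric(),
                           neuron_id = integer(), profile_area = numeric(),
                           nucleus_visible = logical())
  structure(list(section_index = index, slide = sec$slide,
                 plane_zs = planes, profiles = profiles),
            class = "optical_stack")
}
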