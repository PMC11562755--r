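#' Optical-dissector count for one z-stack
#'
#' Counts distinct neurons whose nucleus is visible on at least one plane of
#' the stack and **not** visible in the top frame (plane index 0); neurons
#' with a nucleus visible in any other field are included, including the
#' bottom frame. Each neuron is counted at most once per stack. The top-frame
#' exclusion makes the count a dissector: a nucleus spanning a cut surface is
#' visible in the top frame of the lower section and is therefore counted
#' only once, in the upper one.
#'
#' @param stack an `optical_stack` from [build_stack()].
#' @param ids optional neuron ids to restrict the count to (e.g. neurons
#'   carrying a reporter label).
#' @return integer count `N_sec`.
#' @export
count_section <- function(stack, ids = NULL) {
  stopifnot(inherits(stack, "optical_stack"))
  if (length(stack$plane_zs) < 2)
    stop("stack has fewer than 2 planes; top-frame exclusion undefined",
         call. = FALSE)
  pr <- stack$profiles[stack$profiles$nucleus_visible, , drop = FALSE]
  if (!is.null(ids)) pr <- pr[pr$neuron_id %in% ids, , drop = FALSE]
  visible <- unique(pr$neuron_id)
  top <- unique(pr$neuron_id[pr$plane_index == 0L])
  length(setdiff(visible, top))
}

#' Section volume
#'
#' `V_sec = t * a`: measured thickness times cell-containing cross-sectional
#' area.
#'
#' @param t measured section thickness, µm (> 0).
#' @param a cell-containing area, µm² (>= 0).
#' @return volume in µm³.
#' @export
section_volume <- function(t, a) {
  if (any(t <= 0)) stop("thickness must be > 0", call. = FALSE)
  if (any(a < 0)) stop("area must be >= 0", call. = FALSE)
  t * a
}

#' Cavalieri volume estimate
#'
#' `V_DRG = a_bar * t_bar * l`, where `a_bar` is the mean cell-containing
#' cross-sectional area, `t_bar` the mean measured thickness, and `l` the
#' dimensionless total number of sections collected across all slides (the
#' "length" of the ganglion in sections; the product only has volume units
#' with `l` a count).
#'
#' @param a_bar mean area, µm².
#' @param t_bar mean thickness, µm.
#' @param l integer total section count (>= 1).
#' @return volume in µm³.
#' @export
cavalieri_volume <- function(a_bar, t_bar, l) {
  if (length(l) != 1 || abs(l - round(l)) > 1e-9 || l < 1)
    stop("l must be a positive integer section count", call. = FALSE)
  if (t_bar <= 0) stop("t_bar must be > 0", call. = FALSE)
  if (a_bar < 0) stop("a_bar must be >= 0", call. = FALSE)
  a_bar * t_bar * l
}

#' Total neuron number from per-section counts
#'
#' Computes the neuron density `N_v = N_sec / V_sec` per analyzed section,
#' averages to `N_v_bar`, forms the Cavalieri volume `V_DRG` from the mean
#' area, mean thickness and total section count `l`, and returns
#' `N_DRG = N_v_bar * V_DRG` with all intermediates preserved. The pooled
#' alternative `sum(N_sec) / sum(V_sec)` is available with `pooled = TRUE`
#' (default off).
#'
#' @param counts per-section dissector counts on the analyzed slide.
#' @param thicknesses per-section measured thicknesses, µm.
#' @param areas per-section cell-containing areas, µm².
#' @param l total number of sections collected across all slides (>= number
#'   of analyzed sections).
#' @param section_index optional indices for the per-section table.
#' @param pooled logical; pool counts and volumes before dividing.
#' @return a `stereology_estimate`: `per_section` data frame, `t_bar`,
#'   `a_bar`, `l`, `V_DRG`, `N_v_bar`, `N_DRG`.
#' @export
estimate_total <- function(counts, thicknesses, areas, l,
                           section_index = seq_along(counts) - 1L,
                           pooled = FALSE) {
  m <- length(counts)
  if (length(thicknesses) != m || length(areas) != m)
    stop("counts, thicknesses and areas must be aligned per section",
         call. = FALSE)
  if (l < m) stop("l must be >= number of analyzed sections", call. = FALSE)
  v_sec <- section_volume(thicknesses, areas)
  if (any(v_sec == 0 & counts > 0))
    stop("zero section volume with a nonzero count", call. = FALSE)
  n_v <- ifelse(v_sec > 0, counts / v_sec, 0)
  n_v_bar <- if (m == 0) 0
             else if (pooled) sum(counts) / sum(v_sec)
             else mean(n_v)
  t_bar <- if (m) mean(thicknesses) else NA_real_
  a_bar <- if (m) mean(areas) else NA_real_
  v_drg <- if (m) cavalieri_volume(a_bar, t_bar, l) else 0
  structure(list(per_section = data.frame(section_index = section_index,
                                          N_sec = counts, t = thicknesses,
                                          a = areas, V_sec = v_sec,
                                          N_v = n_v),
                 t_bar = t_bar, a_bar = a_bar, l = as.integer(l),
                 V_DRG = v_drg, N_v_bar = n_v_bar,
                 N_DRG = n_v_bar * v_drg, pooled = pooled),
            class = "stereology_estimate")
}

#' @export
print.stereology_estimate <- function(x, ...) {
  cat("Stereology estimate over", nrow(x$per_section),
      "analyzed sections (l =", x$l, "collected)\n")
  cat(sprintf("  t_bar = %.2f um, a_bar = %.0f um^2, V_DRG = %.3g um^3\n",
              x$t_bar, x$a_bar, x$V_DRG))
  cat(sprintf("  N_v_bar = %.4g per um^3, N_DRG = %.0f\n",
              x$N_v_bar, x$N_DRG))
  invisible(x)
}

# sections whose middle optical plane shows cell-containing tissue; only
# these enter l (and, on the analyzed slide, the estimate)
collected_sections <- function(series) {
  series$sections[series$sections$mid_plane_area > 0, , drop = FALSE]
}

#' Dissector counts summed over the sections of a slide
#'
#' @param g a `ganglion` (current `alive` flags are used).
#' @param series a `section_series`.
#' @param slide 0-based slide number (default: the analyzed slide); `NULL`
#'   counts every section of the series.
#' @param label optional label name restricting the count to labelled
#'   neurons.
#' @param collected_only restrict to sections with a nonzero cell-containing
#'   midplane area (the collected set; default TRUE).
#' @return total count.
#' @export
dissector_count <- function(g, series, slide = series$analyzed_slide,
                            label = NULL, collected_only = TRUE) {
  secs <- if (collected_only) collected_sections(series) else series$sections
  if (!is.null(slide)) secs <- secs[secs$slide == slide, , drop = FALSE]
  ids <- NULL
  if (!is.null(label))
    ids <- g$neurons$id[has_label(g$neurons$labels, label)]
  total <- 0L
  for (i in secs$index)
    total <- total + count_section(build_stack(series, i, g), ids = ids)
  total
}

#' Full stereological estimate for a sectioned ganglion
#'
#' Runs the optical-dissector count on every collected section of the
#' analyzed slide and combines counts, measured thicknesses and analytic
#' midplane areas into the total-number estimate via [estimate_total()].
#' `l` is the number of collected sections (nonzero cell-containing midplane
#' area) across all slides; sections without a cell-containing region are
#' excluded from the analyzed set but leave `l` unchanged only in the sense
#' that they were never collected.
#'
#' @inheritParams dissector_count
#' @param pooled see [estimate_total()].
#' @return a `stereology_estimate`.
#' @export
estimate_ganglion <- function(g, series, slide = series$analyzed_slide,
                              label = NULL, pooled = FALSE) {
  coll <- collected_sections(series)
  secs <- coll[coll$slide == slide, , drop = FALSE]
  ids <- NULL
  if (!is.null(label))
    ids <- g$neurons$id[has_label(g$neurons$labels, label)]
  counts <- vapply(secs$index, function(i)
    count_section(build_stack(series, i, g), ids = ids), numeric(1))
  estimate_total(counts, secs$measured_thickness, secs$mid_plane_area,
                 l = nrow(coll), section_index = secs$index, pooled = pooled)
}
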