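#' Cell table of nucleated profiles on a slide
#'
#' Enumerates, per section of the given slide, every living neuron with a
#' nucleus visible anywhere within the section's z-stack (no top-frame
#' exclusion — the counting rule used for co-labelling proportions, where no
#' stereological correction is applied) together with its maximal soma
#' profile area in that section and its label set.
#'
#' @param g a `ganglion` (current `alive` flags are used).
#' @param series a `section_series`.
#' @param slide 0-based slide (default: analyzed slide).
#' @param animal animal identifier.
#' @param side side/condition label (e.g. `"ipsi"`, `"contra"`).
#' @return a data frame: `animal`, `side`, `section`, `slide`, `neuron_id`,
#'   `nucleus_visible`, `max_area`, `labels`.
#' @export
cells_from_series <- function(g, series, slide = series$analyzed_slide,
                              animal = 1L, side = "ipsi") {
  secs <- collected_sections(series)
  secs <- secs[secs$slide == slide, , drop = FALSE]
  rows <- list()
  for (i in secs$index) {
    st <- build_stack(series, i, g)
    pr <- st$profiles
    nucleated <- unique(pr$neuron_id[pr$nucleus_visible])
    if (!length(nucleated)) next
    a <- vapply(nucleated, function(id)
      max(pr$profile_area[pr$neuron_id == id]), numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      animal = animal, side = side, section = i, slide = slide,
      neuron_id = nucleated, nucleus_visible = TRUE, max_area = a,
      labels = g$neurons$labels[match(nucleated, g$neurons$id)],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(animal = integer(), side = character(),
                      section = integer(), slide = integer(),
                      neuron_id = integer(), nucleus_visible = logical(),
                      max_area = numeric(), labels = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Co-labelling proportion per group
#'
#' Blinded two-pass semantics: reference-labelled nucleated cells are
#' enumerated first, independently of marker status; the marker channel is
#' then revealed and co-labelling quantified. No stereological correction is
#' applied. Groups with zero reference cells are flagged missing and
#' excluded, with a warning.
#'
#' @param cells a cell table (see [cells_from_series()]): needs `labels`,
#'   `nucleus_visible`, and the grouping columns.
#' @param reference_label label defining the reference population (e.g.
#'   `"FB"`).
#' @param marker_label co-label of interest.
#' @param by grouping columns (default animal and side).
#' @return a `proportion_records` data frame: grouping columns,
#'   `n_reference`, `n_colabelled`, `percent`.
#' @export
colabel_proportion <- function(cells, reference_label, marker_label,
                               by = c("animal", "side")) {
  stopifnot(all(by %in% names(cells)), "labels" %in% names(cells))
  ref <- cells[cells$nucleus_visible &
                 has_label(cells$labels, reference_label), , drop = FALSE]
  grp_all <- unique(cells[by])
  out <- lapply(seq_len(nrow(grp_all)), function(r) {
    sel <- rep(TRUE, nrow(ref))
    for (b in by) sel <- sel & ref[[b]] == grp_all[[b]][r]
    n_ref <- sum(sel)
    rec <- grp_all[r, , drop = FALSE]
    rec$n_reference <- n_ref
    rec$n_colabelled <- sum(has_label(ref$labels[sel], marker_label))
    rec$percent <- if (n_ref > 0) 100 * rec$n_colabelled / n_ref else NA_real_
    rec
  })
  out <- do.call(rbind, out)
  if (any(out$n_reference == 0)) {
    warning(sum(out$n_reference == 0),
            " group(s) with zero reference cells; flagged missing and ",
            "excluded", call. = FALSE)
    out <- out[out$n_reference > 0, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("proportion_records", "data.frame")
  out
}

#' Group summary of proportion records
#'
#' Mean and SEM (SD over animals / sqrt(n)) per group; with a paired design,
#' per-animal differences between the two group levels are also returned
#' (animals must match across levels).
#'
#' @param records a `proportion_records` data frame (or any data frame with
#'   `animal`, a grouping column, and `percent`).
#' @param design `"unpaired"` or `"paired"`.
#' @param group_col grouping column name (default `"side"`).
#' @return a list: `summary` data frame (`group`, `n`, `mean`, `sem`) and,
#'   when paired, `paired_deltas` (`animal`, `delta`).
#' @export
summarize_groups <- function(records, design = c("unpaired", "paired"),
                             group_col = "side") {
  design <- match.arg(design)
  stopifnot(group_col %in% names(records), "percent" %in% names(records))
  groups <- unique(records[[group_col]])
  summ <- do.call(rbind, lapply(groups, function(gl) {
    v <- records$percent[records[[group_col]] == gl]
    v <- v[!is.na(v)]
    data.frame(group = gl, n = length(v), mean = mean(v),
               sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                     else NA_real_)
  }))
  if (any(summ$n < 2))
    message("groups with a single animal: SEM undefined, mean only")
  out <- list(summary = summ)
  if (design == "paired") {
    if (length(groups) != 2)
      stop("paired design needs exactly 2 group levels", call. = FALSE)
    a <- records[records[[group_col]] == groups[1], c("animal", "percent")]
    b <- records[records[[group_col]] == groups[2], c("animal", "percent")]
    if (!setequal(a$animal, b$animal) || anyDuplicated(a$animal) ||
        anyDuplicated(b$animal))
      stop("paired design with mismatched animal ids", call. = FALSE)
    b <- b[match(a$animal, b$animal), ]
    out$paired_deltas <- data.frame(animal = a$animal,
                                    delta = a$percent - b$percent)
  }
  out
}
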