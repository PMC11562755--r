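#' Read an Imaris-style nuclear spot table
#'
#' Reads a CSV export of detected nuclear spots (positions in µm, volumes in
#' µm³). Common header dialects are accepted: `"Position X"`,
#' `"Position X [µm]"`, `"x"`, and `"Volume"` / `"Volume [µm^3]"` all parse
#' identically. Row count is preserved; a missing volume column is a format
#' error naming the column.
#'
#' @param path CSV file path.
#' @return a `spot_table` data frame with columns `spot_id`, `x`, `y`, `z`,
#'   `volume` and, when present in the input, `drg` and `side`.
#' @export
read_spots <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  norm <- tolower(trimws(gsub("\\[[^]]*\\]|\\(([^)]*)\\)", "", names(df))))
  pick <- function(keys) {
    hit <- which(norm %in% keys)
    if (length(hit)) hit[1] else NA_integer_
  }
  ix <- pick(c("position x", "x")); iy <- pick(c("position y", "y"))
  iz <- pick(c("position z", "z"))
  iv <- pick(c("volume", "spot volume"))
  if (is.na(iv))
    stop("spot table is missing a 'Volume' column", call. = FALSE)
  if (is.na(ix) || is.na(iy) || is.na(iz))
    stop("spot table is missing position columns ('Position X/Y/Z')",
         call. = FALSE)
  out <- data.frame(spot_id = seq_len(nrow(df)),
                    x = as.numeric(df[[ix]]), y = as.numeric(df[[iy]]),
                    z = as.numeric(df[[iz]]), volume = as.numeric(df[[iv]]),
                    stringsAsFactors = FALSE)
  id <- pick(c("id", "spot id")); if (!is.na(id)) out$spot_id <- df[[id]]
  dg <- pick(c("drg", "source drg", "sample")); if (!is.na(dg)) out$drg <- df[[dg]]
  sd <- pick(c("side", "condition")); if (!is.na(sd)) out$side <- df[[sd]]
  spot_table(out)
}

#' Construct a spot table
#'
#' @param df data frame with at least a `volume` column (µm³; must be
#'   positive).
#' @return a `spot_table`.
#' @export
spot_table <- function(df) {
  if (!"volume" %in% names(df)) stop("'volume' column required", call. = FALSE)
  if (any(!is.finite(df$volume)) || any(df$volume <= 0))
    stop("spot volumes must be positive", call. = FALSE)
  structure(df, class = c("spot_table", "data.frame"))
}

#' Simulate a cleared-tissue nuclear spot table from a ganglion
#'
#' Exports the nuclear volumes (`4/3 * pi * r_nucleus^3`) of all living
#' neurons as a spot table, emulating nuclear-marker spot detection in
#' cleared whole DRG.
#'
#' @param g a `ganglion`.
#' @param drg DRG identifier for grouping.
#' @param side `"ipsi"` or `"contra"`.
#' @return a `spot_table`.
#' @export
simulate_spots <- function(g, drg = "DRG1", side = "contra") {
  nn <- g$neurons[g$neurons$alive, , drop = FALSE]
  spot_table(data.frame(spot_id = nn$id, x = nn$x, y = nn$y, z = nn$z,
                        volume = 4 / 3 * pi * nn$nucleus_radius^3,
                        drg = drg, side = side, stringsAsFactors = FALSE))
}

#' Filter spots by volume
#'
#' Marks very small (`volume < v_min`) and very large (`volume > v_max`)
#' spots — debris, labelled satellite glia, or doublets — with strict
#' inequalities, so boundary volumes pass. Filtering is idempotent.
#'
#' @param spots a `spot_table`.
#' @param v_min lower volume bound, µm³ (default 5).
#' @param v_max upper volume bound, µm³ (default 2000).
#' @return the table with a `filter_status` column
#'   (`pass`/`too_small`/`too_large`).
#' @export
filter_spots <- function(spots, v_min = 5, v_max = 2000) {
  stopifnot(inherits(spots, "spot_table"))
  if (v_min >= v_max) stop("v_min must be < v_max", call. = FALSE)
  spots$filter_status <- ifelse(spots$volume < v_min, "too_small",
                                ifelse(spots$volume > v_max, "too_large",
                                       "pass"))
  attr(spots, "filter_bounds") <- c(v_min = v_min, v_max = v_max)
  spots
}

#' Bin passing spots by nuclear volume
#'
#' Assigns each passing spot to a size bin — small (`v <= small_max`),
#' medium (`small_max < v <= medium_max`), large (`v > medium_max`) — and
#' tabulates per-DRG, per-side counts together with the combined
#' medium-plus-large category (`v > small_max`). Bin upper bounds are
#' inclusive (the small bound is defined as an upper bound of identified
#' small nuclei). The table must have been filtered first.
#'
#' @param spots a filtered `spot_table`.
#' @param small_max small/medium boundary, µm³ (default 258).
#' @param medium_max medium/large boundary, µm³ (default 400).
#' @return a `spot_bins` list: `spots` (with `size_bin` audit column) and
#'   `counts` (per group: `n_pass`, `small`, `medium`, `large`, `combined`).
#' @export
bin_spots <- function(spots, small_max = 258, medium_max = 400) {
  stopifnot(inherits(spots, "spot_table"))
  if (!"filter_status" %in% names(spots))
    stop("spots are unfiltered; run filter_spots() first", call. = FALSE)
  if (small_max >= medium_max)
    stop("small_max must be < medium_max", call. = FALSE)
  pass <- spots$filter_status == "pass"
  spots$size_bin <- rep(NA_character_, nrow(spots))
  spots$size_bin[pass] <-
    ifelse(spots$volume[pass] <= small_max, "small",
           ifelse(spots$volume[pass] <= medium_max, "medium", "large"))
  grp <- interaction(
    if ("drg" %in% names(spots)) spots$drg else rep("all", nrow(spots)),
    if ("side" %in% names(spots)) spots$side else rep("", nrow(spots)),
    sep = "/", drop = TRUE)
  if (!nrow(spots)) {
    counts <- data.frame(group = "all", n_pass = 0L, small = 0L,
                         medium = 0L, large = 0L, combined = 0L)
  } else {
    counts <- do.call(rbind, lapply(levels(grp), function(gl) {
      sb <- spots$size_bin[grp == gl & pass]
      data.frame(group = gl, n_pass = length(sb),
                 small = sum(sb == "small"), medium = sum(sb == "medium"),
                 large = sum(sb == "large"),
                 combined = sum(sb != "small"))
    }))
  }
  structure(list(spots = spots, counts = counts,
                 small_max = small_max, medium_max = medium_max),
            class = "spot_bins")
}

#' @export
print.spot_bins <- function(x, ...) {
  cat("Spot size bins (small <=", x$small_max, "< medium <=", x$medium_max,
      "< large, um^3)\n")
  print(x$counts, row.names = FALSE)
  invisible(x)
}
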