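#' Maximal soma profile area across a set of z-stacks
#'
#' For each requested neuron, returns the maximum soma profile area over all
#' planes of the supplied stacks — the "largest optical section" measurement
#' rule. Neurons absent from every stack are skipped with a warning and
#' returned as `NA`.
#'
#' @param ids neuron ids.
#' @param stacks an `optical_stack` or list of them.
#' @return named numeric vector of areas (µm²), `NA` for unmeasured neurons.
#' @export
soma_max_area <- function(ids, stacks) {
  if (inherits(stacks, "optical_stack")) stacks <- list(stacks)
  pr <- do.call(rbind, lapply(stacks, `[[`, "profiles"))
  out <- vapply(ids, function(id) {
    a <- pr$profile_area[pr$neuron_id == id]
    if (!length(a)) NA_real_ else max(a)
  }, numeric(1))
  names(out) <- ids
  if (anyNA(out))
    warning(sum(is.na(out)), " neuron(s) absent from the analyzed stacks; ",
            "skipped", call. = FALSE)
  out
}

#' Soma-size sample from the analyzed slide
#'
#' Collects maximal soma cross-sectional areas for neurons with a visible
#' nucleus in the stacks of one slide, optionally restricted to a label —
#' the profile-selection rule used for population size-distribution
#' comparisons (neurons are sampled through their nucleated profiles).
#'
#' @param g a `ganglion` (current `alive` flags are used).
#' @param series a `section_series`.
#' @param slide 0-based slide (default: analyzed slide).
#' @param label optional label restriction.
#' @return numeric vector of areas (µm²), one per sampled neuron.
#' @export
area_sample <- function(g, series, slide = series$analyzed_slide,
                        label = NULL) {
  secs <- collected_sections(series)
  secs <- secs[secs$slide == slide, , drop = FALSE]
  keep <- if (is.null(label)) rep(TRUE, nrow(g$neurons))
          else has_label(g$neurons$labels, label)
  ids_ok <- g$neurons$id[keep]
  out <- numeric(0)
  for (i in secs$index) {
    st <- build_stack(series, i, g)
    pr <- st$profiles[st$profiles$neuron_id %in% ids_ok, , drop = FALSE]
    nucleated <- unique(pr$neuron_id[pr$nucleus_visible])
    if (!length(nucleated)) next
    a <- vapply(nucleated, function(id)
      max(pr$profile_area[pr$neuron_id == id]), numeric(1))
    out <- c(out, a)
  }
  out
}

#' Empirical cumulative distribution function
#'
#' Right-continuous, nondecreasing step function from 0 to 1; evaluable at
#' any point (fraction of sample values `<= t`).
#'
#' @param values numeric sample (n >= 1).
#' @return a function of one argument.
#' @export
ecdf_fn <- function(values) {
  if (!length(values)) stop("empty sample", call. = FALSE)
  stats::ecdf(values)
}

# survival function of the Kolmogorov distribution, P(K > lambda)
kolmogorov_sf <- function(lambda) {
  if (lambda < 1e-8) return(1)
  j <- 1:100
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D = sup_t |F_x(t) - F_y(t)|` exactly by scanning the pooled
#' sample points (exact under ties, since ECDF differences are evaluated at
#' the pooled order statistics). The p-value comes from the asymptotic
#' Kolmogorov distribution with effective size
#' `n_eff = n_x * n_y / (n_x + n_y)`, or from a seeded permutation null with
#' `method = "permutation"`.
#'
#' @param x,y numeric samples (each n >= 1).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param n_perm number of permutations for the permutation p-value.
#' @param seed seed for the permutation null.
#' @return a `drg_test` with elements `statistic` (D), `p`, `n_x`, `n_y`,
#'   `method`.
#' @export
ks_two_sample <- function(x, y, method = c("asymptotic", "permutation"),
                          n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  D <- ks_statistic(x, y)
  n_x <- length(x); n_y <- length(y)
  n_eff <- n_x * n_y / (n_x + n_y)
  if (method == "asymptotic") {
    p <- kolmogorov_sf(sqrt(n_eff) * D)
  } else {
    set.seed(seed)
    pooled <- c(x, y)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_x + n_y, n_x)
      if (ks_statistic(pooled[idx], pooled[-idx]) >= D - 1e-12)
        hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(list(test = "two-sample Kolmogorov-Smirnov",
                 statistic = c(D = D), df = NULL, p = p,
                 n_x = n_x, n_y = n_y, method = method,
                 posttests = NULL, flags = character()),
            class = "drg_test")
}

ks_statistic <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  max(abs(Fx - Fy))
}
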