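# shared fixtures, built in code

one_pop <- function(mean = 361, sd = 138, name = "mrgprd", ratio = 0.45) {
  list(subpop_spec(name, 1, mean, sd, nucleus_ratio = ratio,
                   markers = name))
}

# a ganglion with hand-placed neurons (for analytic counting oracles);
# soma/nucleus radii and z positions are set explicitly
manual_ganglion <- function(z, nucleus_radius, soma_radius = 8,
                            semi_axes = c(50, 50, 60)) {
  n <- length(z)
  g <- generate_ganglion(0, semi_axes = semi_axes, subpops = one_pop(),
                         seed = 1)
  g$neurons <- data.frame(id = seq_len(n), subpop = "mrgprd",
                          x = 0, y = 0, z = z,
                          soma_radius = soma_radius,
                          nucleus_radius = nucleus_radius,
                          territory = "tibial", axotomized = FALSE,
                          alive = TRUE, labels = "",
                          stringsAsFactors = FALSE)
  g
}

# per-neuron brute-force dissector oracle over the whole section series:
# a nucleus is countable iff it is visible at >= 1 grid plane and not
# visible at the topmost plane of the whole series (independent scan over
# the global plane grid, no stack machinery)
brute_dissector_total <- function(g, series) {
  secs <- series$sections
  planes <- sort(unique(unlist(lapply(seq_len(nrow(secs)), function(i) {
    K <- floor((secs$z_hi[i] - secs$z_lo[i]) / series$dz + 1e-9)
    secs$z_lo[i] + series$dz * (0:K)
  }))))
  zc <- g$neurons$z * series$axial_shrinkage
  r <- g$neurons$nucleus_radius
  alive <- g$neurons$alive
  sum(vapply(seq_along(zc), function(i) {
    if (!alive[i]) return(FALSE)
    vis <- abs(planes - zc[i]) < r[i]
    any(vis) && !vis[1]
  }, logical(1)))
}

# brute-force KS D: scan |Fx - Fy| over every pooled data point
brute_ks_D <- function(x, y) {
  best <- 0
  for (t in c(x, y)) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > best) best <- d
  }
  best
}

# independent split-plot oracle via stats::aov with an Error() stratum
aov_oracle <- function(df) {
  fit <- stats::aov(value ~ between * within + Error(subject),
                    data = transform(df, subject = factor(subject),
                                     between = factor(between),
                                     within = factor(within)))
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1]]
  wtn <- s[["Error: Within"]][[1]]
  list(F_between = btw[["F value"]][1],
       F_within = wtn[["F value"]][1],
       F_interaction = wtn[["F value"]][2],
       p_between = btw[["Pr(>F)"]][1],
       p_within = wtn[["Pr(>F)"]][1],
       p_interaction = wtn[["Pr(>F)"]][2])
}

random_split_plot <- function(G, k, n, seed) {
  set.seed(seed)
  expand.grid(subject = seq_len(G * n), within = paste0("w", seq_len(k)),
              KEEP.OUT.ATTRS = FALSE) |>
    transform(between = paste0("g", ((subject - 1) %/% n) + 1),
              value = stats::rnorm(G * n * k))
}
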