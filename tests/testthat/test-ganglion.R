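test_that("empty and invalid configurations are handled", {
  g <- generate_ganglion(0, subpops = one_pop(), seed = 1)
  expect_s3_class(g, "ganglion")
  expect_equal(nrow(g$neurons), 0)

  bad <- list(subpop_spec("a", 0.6, 300, 100), subpop_spec("b", 0.3, 300, 100))
  expect_error(generate_ganglion(10, subpops = bad, seed = 1), "sum to 1")
  expect_error(subpop_spec("a", 0.5, -10, 5), "soma_area_mean")
  expect_error(generate_ganglion(10, semi_axes = c(-1, 1, 1), seed = 1),
               "positive")
})

test_that("soma sizes match the configured subpopulation parameters", {
  g <- generate_ganglion(1e5, subpops = one_pop(361, 138), seed = 11)
  area <- pi * g$neurons$soma_radius^2
  # moment-matched lognormal: mean and SD within 2% at n = 1e5
  expect_lt(abs(mean(area) / 361 - 1), 0.02)
  expect_lt(abs(sd(area) / 138 - 1), 0.02)
  # nucleus strictly inside soma
  expect_true(all(g$neurons$nucleus_radius < g$neurons$soma_radius))
})

test_that("mixed composition respects fractions and Mrgprd sizes", {
  g <- generate_ganglion(8000, seed = 5)
  expect_equal(nrow(g$neurons), 8000)
  frac <- prop.table(table(g$neurons$subpop))
  expect_lt(abs(frac[["mrgprd"]] - 0.30), 0.02)
  a_mrg <- pi * g$neurons$soma_radius[g$neurons$subpop == "mrgprd"]^2
  se <- 138 / sqrt(length(a_mrg))
  expect_lt(abs(mean(a_mrg) - 361), 3 * se)
})

test_that("placement is uniform inside the ellipsoid and seed-reproducible", {
  g1 <- generate_ganglion(1000, subpops = one_pop(), seed = 99)
  g2 <- generate_ganglion(1000, subpops = one_pop(), seed = 99)
  expect_identical(g1$neurons, g2$neurons)

  nn <- g1$neurons
  u <- (nn$x / g1$semi_axes[1])^2 + (nn$y / g1$semi_axes[2])^2 +
    (nn$z / g1$semi_axes[3])^2
  expect_true(all(u < 1))
  octant <- paste(nn$x > 0, nn$y > 0, nn$z > 0)
  expect_gt(stats::chisq.test(table(octant))$p.value, 0.01)
})

test_that("injury survival follows the schedule and is monotone", {
  sched <- list(mrgprd = c(`7` = 1, `14` = 0.45, `28` = 0.41, `56` = 0.39))
  scen <- injury_scenario("inj", c("tibial", "peroneal"), sched)
  g <- generate_ganglion(8000, subpops = one_pop(), seed = 3)

  g0 <- apply_injury(g, scen, day = 0)
  expect_true(all(g0$neurons$alive))
  expect_equal(mean(g0$neurons$axotomized), 0.80, tolerance = 0.05)

  g7 <- alive_at(g0, 7); g56 <- alive_at(g0, 56)
  ax <- g7$neurons$axotomized
  # nesting: survivors at 56 d are a subset of survivors at 7 d
  expect_true(all(g7$neurons$alive[g56$neurons$alive]))
  # intact neurons always alive
  expect_true(all(g56$neurons$alive[!ax]))
  # survival ratio matches the schedule within binomial error
  n7 <- sum(g7$neurons$alive & ax); n56 <- sum(g56$neurons$alive & ax)
  expect_lt(abs(n56 / n7 - 0.39), 3 * sqrt(0.39 * 0.61 / n7))

  # zero survival boundary
  scen0 <- injury_scenario("kill", c("tibial", "peroneal"),
                           list(mrgprd = c(`7` = 0)))
  gk <- apply_injury(g, scen0, day = 7)
  expect_equal(sum(gk$neurons$alive & gk$neurons$axotomized), 0)
  expect_true(all(gk$neurons$alive[!gk$neurons$axotomized]))

  # schedule validation
  expect_error(injury_scenario("bad", "tibial",
                               list(mrgprd = c(`7` = 0.4, `14` = 0.6))),
               "non-increasing")
  expect_error(apply_injury(g, injury_scenario("m", "tibial",
                                               list(zz = c(`7` = 1))), 7),
               "missing subpopulation")
})

test_that("labelling hits members and non-members at the configured rates", {
  g <- generate_ganglion(20000, subpops = one_pop(), seed = 13)

  exact <- label_spec("X", "territory", sensitivity = 1, false_positive = 0,
                      territory = "tibial")
  gx <- apply_labels(g, exact, seed = 2)
  expect_identical(has_label(gx$neurons$labels, "X"),
                   gx$neurons$territory == "tibial")

  scen <- injury_scenario("inj", c("tibial", "peroneal"),
                          list(mrgprd = c(`7` = 1)))
  gi <- apply_injury(g, scen, day = 7)
  gfp <- label_spec("GFP", "axotomized", 0.991, 0.046)
  gi <- apply_labels(gi, gfp, seed = 4)
  ax <- gi$neurons$axotomized
  p_ax <- mean(has_label(gi$neurons$labels[ax], "GFP"))
  expect_lt(abs(p_ax - 0.991), 3 * sqrt(0.991 * 0.009 / sum(ax)))

  gu <- apply_labels(g, gfp, seed = 4)  # uninjured: only false positives
  p_fp <- mean(has_label(gu$neurons$labels, "GFP"))
  expect_lt(abs(p_fp - 0.046), 3 * sqrt(0.046 * 0.954 / 20000))
})

test_that("survival odds-ratio calibration is exact and closes the loop", {
  expect_equal(calibrate_survival_ratio(0.15, 0.15), 1.0)
  expect_equal(calibrate_survival_ratio(0.15, 0.017), 0.0980, tolerance = 1e-3)
  expect_equal(calibrate_survival_ratio(0.156, 0.233), 1.644, tolerance = 1e-3)
  expect_error(calibrate_survival_ratio(1, 0.5), "p_contra")
  expect_error(calibrate_survival_ratio(0, 0.5), "p_contra")

  # closure: two-class simulation with survival s*rho vs s recovers p_ipsi
  set.seed(42)
  for (case in list(c(0.15, 0.017), c(0.083, 0.042), c(0.156, 0.233),
                    c(0.5, 0.2))) {
    p_c <- case[1]; p_i <- case[2]
    rho <- calibrate_survival_ratio(p_c, p_i)
    s <- 0.5
    n <- 1e5
    marker <- runif(n) < p_c
    alive <- runif(n) < ifelse(marker, s * rho, s)
    obs <- mean(marker[alive])
    expect_lt(abs(obs - p_i), 3 * sqrt(p_i * (1 - p_i) / sum(alive)))
  }
})

test_that("ganglion CSV round trip preserves the population", {
  g <- generate_ganglion(200, seed = 21)
  g <- apply_labels(g, label_spec("FB", "territory", 0.97,
                                  territory = "tibial"), seed = 1)
  path <- file.path(tempdir(), "gang.csv")
  write_ganglion(g, path)
  g2 <- read_ganglion(path)
  expect_equal(g2$neurons$x, g$neurons$x)
  expect_equal(g2$neurons$labels, g$neurons$labels)
  expect_equal(g2$semi_axes, g$semi_axes)
})
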