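test_that("within-gel scaling sets each gel's maximum to 1", {
  tab <- data.frame(gel_id = 1, ligand = "A", conc = c(0, 1e-9, 1e-8),
                    intensity = c(200, 500, 1000))
  s <- scale_within_gel(tab)
  expect_equal(s$intensity, c(0.2, 0.5, 1.0))
  expect_equal(scale_within_gel(s)$intensity, s$intensity)  # idempotent

  two <- data.frame(gel_id = rep(1:2, each = 2), ligand = "A",
                    conc = rep(c(1e-9, 1e-8), 2),
                    intensity = c(10, 20, 3, 6))
  expect_equal(scale_within_gel(two)$intensity, c(0.5, 1, 0.5, 1))

  bad <- data.frame(gel_id = 1, ligand = "A", conc = c(0, 1e-9),
                    intensity = c(0, 0))
  expect_error(scale_within_gel(bad), "all-zero")
})

test_that("replicate averaging returns means, SEMs and max-1 curves", {
  tab <- data.frame(gel_id = rep(1:2, each = 2), ligand = "A",
                    conc = rep(c(1e-9, 1e-8), 2),
                    intensity = c(0.5, 1.0, 0.7, 1.0))
  a <- average_replicates(tab)
  expect_equal(a$mean, c(0.6, 1.0))
  expect_equal(a$sem, c(0.1, 0))
  expect_equal(a$n, c(2L, 2L))

  # renormalization to a maximum mean of 1
  tab2 <- data.frame(gel_id = rep(1:2, each = 2), ligand = "A",
                     conc = rep(c(1e-9, 1e-8), 2),
                     intensity = c(0.4, 0.8, 0.4, 0.8))
  expect_equal(average_replicates(tab2)$mean, c(0.5, 1.0))

  # identical gels give SEM 0 everywhere
  tab3 <- data.frame(gel_id = rep(1:3, each = 2), ligand = "A",
                     conc = rep(c(1e-9, 1e-8), 3),
                     intensity = rep(c(0.5, 1.0), 3))
  expect_equal(average_replicates(tab3)$sem, c(0, 0))

  one <- data.frame(gel_id = 1, ligand = "A", conc = c(1e-9, 1e-8),
                    intensity = c(0.5, 1.0))
  expect_warning(a1 <- average_replicates(one), "single gel")
  expect_true(all(is.na(a1$sem)))
})

test_that("gluing-gel scaling derives global coefficients from glue means", {
  avg <- data.frame(ligand = rep(c("FGF4", "FGF8", "FGF9"), each = 2),
                    conc = rep(c(1e-9, 1e-8), 3),
                    mean = rep(c(0.5, 1), 3), sem = rep(0.05, 6), n = 3)
  glue <- data.frame(ligand = rep(c("FGF4", "FGF8", "FGF9"), each = 3),
                     intensity = rep(c(0.8, 1.0, 0.5), each = 3))
  g <- glue_scale(avg, glue)
  expect_equal(attr(g, "glue_coefficients"),
               c(FGF4 = 0.8, FGF8 = 1.0, FGF9 = 0.5))
  expect_equal(max(g$mean[g$ligand == "FGF8"]), 1)
  expect_equal(max(g$mean[g$ligand == "FGF9"]), 0.5)

  # all-equal glue means leave the curves unchanged
  glue_eq <- transform(glue, intensity = 1)
  expect_equal(glue_scale(avg, glue_eq)$mean, avg$mean)

  expect_error(glue_scale(avg, glue[glue$ligand != "FGF9", ]), "missing")

  # after global scaling exactly one ligand attains the maximum of 1
  expect_equal(sum(abs(tapply(g$mean, g$ligand, max) - 1) < 1e-12), 1L)
})

test_that("the pipeline recovers relative efficacies hidden by gel scales", {
  truth <- data.frame(response = "r", ligand = c("L1", "L2"),
                      etop = c(1.11, 0.70), ec50 = c(1.04e-8, 2.09e-9))
  grid <- std_grid()
  sim <- simulate_dose_response(dose_sim_spec(truth, grid), seed = 77)
  fits <- run_scaling_chain(sim)
  ratio <- fits$etop[fits$ligand == "L2"] / fits$etop[fits$ligand == "L1"]
  expect_equal(ratio, 0.70 / 1.11, tolerance = 0.12)
})

test_that("loss transform turns abundance curves into loss curves", {
  avg <- data.frame(ligand = "A", conc = c(0, 1e-9, 1e-8),
                    mean = c(1.0, 0.8, 0.6), sem = 0)
  expect_equal(loss_transform(avg)$mean, c(0, 0.2, 0.4))

  flat <- transform(avg, mean = 0.7)
  expect_equal(loss_transform(flat)$mean, c(0, 0, 0))

  # brute-force oracle on a random positive curve
  set.seed(3)
  v <- runif(6, 0.2, 2)
  rnd <- data.frame(ligand = "A", conc = c(0, 10^seq(-10, -6)),
                    mean = v, sem = 0)
  expect_equal(loss_transform(rnd)$mean, 1 - v / v[1])

  expect_error(loss_transform(avg[avg$conc > 0, ]), "baseline")
})

test_that("truncation keeps the prefix within 10% of the maximum", {
  expect_equal(truncate_for_fit(1:5, c(0.2, 0.6, 1.0, 0.95, 0.7)), 1:4)
  expect_equal(truncate_for_fit(1:3, c(0.2, 1.0, 0.5)), 1:2)
  expect_equal(truncate_for_fit(1:5, c(0.1, 0.2, 0.4, 0.7, 1.0)), 1:5)
  expect_error(truncate_for_fit(numeric(0), numeric(0)), "non-empty")

  # property: non-empty prefix always containing the argmax
  set.seed(4)
  for (i in 1:50) {
    y <- runif(8)
    keep <- truncate_for_fit(1:8, y)
    expect_gte(length(keep), 1L)
    expect_true(which.max(y) %in% keep)
    expect_equal(keep, seq_len(max(keep)))
  }
})

test_that("Hill fits recover exact curves and honor the half-max property", {
  x <- 10^seq(-10.5, -7.5, by = 0.5)
  f <- fit_hill(x, x * 1 / (x + 1e-9))
  expect_true(f$converged)
  expect_equal(f$etop, 1, tolerance = 1e-6)
  expect_equal(f$ec50, 1e-9, tolerance = 1e-6)

  # fitted response at x = EC50 equals Etop / 2 by construction
  pred <- predict(f$fit, newdata = data.frame(conc = f$ec50))
  expect_equal(pred, f$etop / 2, tolerance = 1e-8)

  expect_error(fit_hill(c(0, 1e-9, 2e-9), c(0, 0.5, 0.8)), "at least 3")
})

test_that("all-equal SEMs reproduce the unweighted fit", {
  set.seed(5)
  x <- 10^seq(-10.5, -7.5, by = 0.5)
  y <- x * 0.8 / (x + 2e-9) * (1 + rnorm(7, 0, 0.05))
  fw <- fit_hill(x, y, sem = rep(0.03, 7))
  fu <- fit_hill(x, y)
  expect_equal(fw$etop, fu$etop, tolerance = 1e-8)
  expect_equal(fw$ec50, fu$ec50, tolerance = 1e-8)
})

test_that("the weighted residual is stationary at the fitted solution", {
  set.seed(6)
  x <- 10^seq(-10.5, -7.5, by = 0.5)
  sem <- 0.03 * (1 + runif(7))
  y <- x * 0.9 / (x + 1e-9) * (1 + rnorm(7, 0, 0.05))
  f <- fit_hill(x, y, sem = sem)
  rss <- function(p) sum((y - x * p[1] / (x + p[2]))^2 / sem^2)
  p0 <- c(f$etop, f$ec50)
  for (j in 1:2) {
    h <- 1e-6 * p0[j]
    pp <- p0; pp[j] <- pp[j] + h
    pm <- p0; pm[j] <- pm[j] - h
    grad_rel <- (rss(pp) - rss(pm)) / (2 * h) * p0[j] / rss(p0)
    expect_lt(abs(grad_rel), 1e-3)
  }
})

test_that("scaling steps preserve within-curve response ratios", {
  set.seed(12)
  truth <- data.frame(response = "r", ligand = c("L1", "L2"),
                      etop = c(1.0, 0.6), ec50 = c(1e-9, 3e-9))
  sim <- simulate_dose_response(dose_sim_spec(truth, std_grid()),
                                seed = 13)
  tab <- sim$table[sim$table$gel_id == 1 & sim$table$ligand == "L1", ]
  ratios_raw <- tab$intensity[-1] / tab$intensity[nrow(tab)]
  s <- scale_within_gel(sim$table)
  stab <- s[s$gel_id == 1 & s$ligand == "L1", ]
  expect_equal(stab$intensity[-1] / stab$intensity[nrow(stab)], ratios_raw)

  avg <- average_replicates(s)
  g <- glue_scale(avg, sim$glue)
  for (l in c("L1", "L2")) {
    a <- avg$mean[avg$ligand == l]
    b <- g$mean[g$ligand == l]
    expect_equal(b / b[length(b)], a / a[length(a)], tolerance = 1e-12)
  }
})

test_that("fit_dose_response fits every response-ligand curve", {
  truth <- data.frame(response = rep(c("rA", "rB"), each = 2),
                      ligand = rep(c("L1", "L2"), 2),
                      etop = c(1.0, 0.7, 0.9, 0.5),
                      ec50 = c(1e-9, 3e-9, 5e-10, 2e-9))
  sim <- simulate_dose_response(
    dose_sim_spec(truth, std_grid(), noise_sd = 0.03), seed = 14)
  fits <- run_scaling_chain(sim)
  expect_equal(nrow(fits), 4L)
  expect_true(all(fits$converged))
  expect_true(all(fits$ec50 > 0 & fits$etop > 0))
})
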