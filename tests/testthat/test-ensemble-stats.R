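test_that("pooling handles constant, Gaussian and circular data correctly", {
  g <- fake_geometry(rep(2.0, 50))
  d <- pool_geometry(g, "shift")
  expect_equal(d$mean, 2.0)
  expect_equal(d$sd, 0)
  expect_equal(sum(d$counts > 0), 1)

  set.seed(10)
  g2 <- fake_geometry(rnorm(1e4, 1.5, 0.5))
  d2 <- pool_geometry(g2, "shift")
  expect_equal(d2$mean, 1.5, tolerance = 0.02 / 1.5)
  expect_equal(sum(d2$counts), d2$n_used)

  # circular mean at the wrap point is 180, not 0
  g3 <- fake_geometry(rep(0, 40), rotation = rep(c(170, -170), 20))
  d3 <- pool_geometry(g3, "rotation")
  expect_true(d3$circular)
  expect_equal(abs(d3$mean), 180, tolerance = 1e-6 + 1e-8)

  expect_error(pool_geometry(fake_geometry(numeric(0)), "shift"),
               "no transmembrane frames")
})

test_that("interfacial frames are excluded from pooling and counted", {
  g <- fake_geometry(c(rep(1, 30), rep(9, 10)))
  g$is_tm[31:40] <- FALSE
  d <- pool_geometry(g, "shift")
  expect_equal(d$n_used, 30)
  expect_equal(d$n_excluded, 10)
  expect_equal(d$mean, 1)
})

test_that("pooling is associative over replicas", {
  set.seed(11)
  parts <- lapply(1:4, function(r) fake_geometry(rnorm(200, r / 4, 0.5), replica = r))
  whole <- dplyr::bind_rows(parts)
  d_all <- pool_geometry(whole, "shift", binwidth = 0.25)
  # merge per-replica histograms on a common grid
  breaks <- d_all$breaks
  merged <- Reduce(`+`, lapply(parts, function(p) {
    graphics::hist(p$z_shift, breaks = breaks, plot = FALSE)$counts
  }))
  expect_equal(d_all$counts, merged)
})

test_that("comparisons give deltas, direction labels and replica bootstrap CIs", {
  set.seed(12)
  wt <- dplyr::bind_rows(lapply(1:6, function(r) fake_geometry(rnorm(100, 0, 0.4), replica = r)))
  mut <- dplyr::bind_rows(lapply(1:6, function(r) fake_geometry(rnorm(100, -1.5, 0.4), replica = r)))
  cmp <- compare_to_wildtype(mut, wt, variables = "shift", n_boot = 300)
  expect_equal(cmp$delta, -1.5, tolerance = 0.1 / 1.5)
  expect_equal(cmp$direction, "cytoplasmic")
  expect_true(cmp$conf_lo <= cmp$delta && cmp$delta <= cmp$conf_hi)

  # identical ensembles: delta 0, CI spans 0
  same <- compare_to_wildtype(wt, wt, variables = "shift", n_boot = 300)
  expect_equal(same$delta, 0, tolerance = 1e-10)
  expect_true(same$conf_lo <= 0 && same$conf_hi >= 0)

  # circular difference takes the shortest arc
  wtr <- fake_geometry(rep(0, 100), rotation = rep(-170, 100))
  mtr <- fake_geometry(rep(0, 100), rotation = rep(170, 100))
  cr <- compare_to_wildtype(mtr, wtr, variables = "rotation", n_boot = 50)
  expect_equal(abs(cr$delta), 20, tolerance = 1e-8)

  # frame-level bootstrap is refused when replica labels are missing
  bad <- wt; bad$replica <- NA_integer_
  expect_error(compare_to_wildtype(bad, wt), "replica labels")
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n_replicas)", {
  width_for <- function(n_rep, seed) {
    set.seed(seed)
    mk <- function(mu) dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
      fake_geometry(rnorm(60, mu + rnorm(1, 0, 0.3), 0.2), replica = r)
    }))
    cmp <- compare_to_wildtype(mk(1), mk(0), variables = "shift", n_boot = 400)
    cmp$conf_hi - cmp$conf_lo
  }
  w5 <- mean(vapply(1:4, function(s) width_for(5, s), numeric(1)))
  w20 <- mean(vapply(1:4, function(s) width_for(20, 100 + s), numeric(1)))
  ratio <- w5 / w20
  expect_gt(ratio, 1.3)   # shrinks with replicas...
  expect_lt(ratio, 3.2)   # ...roughly like sqrt(4) = 2
})

test_that("phenotype report orders mutants and degrades gracefully", {
  set.seed(13)
  mk <- function(mu) dplyr::bind_rows(lapply(1:5, function(r)
    fake_geometry(rnorm(80, mu, 0.3), replica = r)))
  geoms <- list(WT = mk(0), inact = mk(-1), act = mk(1))
  peps <- tibble::tibble(id = c("WT", "inact", "act"),
                         phenotype = c("wildtype", "kinase_inactive", "kinase_active"))
  rep <- phenotype_report(geoms, peps, "WT", n_boot = 200)
  tab <- rep$table
  expect_lt(tab$delta_shift[tab$id == "inact"], 0)
  expect_gt(tab$delta_shift[tab$id == "act"], 0)
  expect_equal(rep$shift_phenotype_correlation, 1)
  expect_equal(tab$shift_direction[tab$id == "inact"], "cytoplasmic")

  # single mutant: correlation undefined and flagged
  rep1 <- phenotype_report(geoms[c("WT", "act")], peps, "WT", n_boot = 100)
  expect_true(is.na(rep1$shift_phenotype_correlation))

  # shuffled labels destroy the sign pattern (permutation control)
  peps_shuf <- peps
  peps_shuf$phenotype <- c("wildtype", "kinase_active", "kinase_inactive")
  rep_shuf <- phenotype_report(geoms, peps_shuf, "WT", n_boot = 100)
  expect_equal(rep_shuf$shift_phenotype_correlation, -1)
})

test_that("tidy, glance and autoplot methods work on result objects", {
  g <- fake_geometry(rnorm(500, 1, 0.4))
  d <- pool_geometry(g, "shift")
  td <- generics::tidy(d)
  expect_true(all(c("bin_mid", "count", "density") %in% names(td)))
  gl <- generics::glance(d)
  expect_equal(gl$mean, d$mean)
  p <- ggplot2::autoplot(d)
  expect_s3_class(p, "ggplot")
})

test_that("circular primitives behave at the wrap point", {
  expect_equal(circ_mean_deg(c(170, -170)), 180 * sign(circ_mean_deg(c(170, -170))),
               tolerance = 1e-8)
  expect_equal(abs(circ_mean_deg(c(170, -170))), 180, tolerance = 1e-8)
  expect_equal(circ_diff_deg(170, -170), -20)
  expect_equal(circ_diff_deg(-170, 170), 20)
  set.seed(14)
  x <- rvonmises_deg(4000, mu = 90, kappa = 8)
  expect_true(all(x >= -180 & x < 180))
  expect_equal(circ_mean_deg(x), 90, tolerance = 2 / 90)
  # kappa = 0 is uniform: resultant length near zero
  u <- rvonmises_deg(4000, 0, 0)
  r <- sqrt(mean(sin(u * pi / 180))^2 + mean(cos(u * pi / 180))^2)
  expect_lt(r, 0.06)
})
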