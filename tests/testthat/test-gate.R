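ev <- function(gf, cf, radius = 4) {
  data.frame(gf_intensity = gf, cf_intensity = cf, radius_px = radius)
}

test_that("quadrant assignment follows the <=-goes-negative convention", {
  th <- gate_thresholds(100, 100)
  z <- assign_zones(ev(c(900, 0, 900, 50, 100, 101),
                       c(0, 800, 800, 50, 100, 100)), th)
  expect_equal(as.character(z$zone), c("C2", "C3", "C4", "C1", "C1", "C2"))
  expect_equal(as.integer(z$counts), c(2L, 2L, 1L, 1L))
})

test_that("non-finite intensities are excluded and counted invalid", {
  z <- assign_zones(ev(c(900, NA, Inf), c(0, 0, 0)), gate_thresholds(100, 100))
  expect_identical(z$invalid, 2L)
  expect_equal(sum(z$counts), 1)
})

test_that("every finite event lands in exactly one zone (partition)", {
  set.seed(7)
  e <- ev(rnorm(500, 100, 300), rnorm(500, 100, 300))
  z <- assign_zones(e, gate_thresholds(100, 100))
  expect_equal(sum(z$counts) + z$invalid, 500)
  expect_false(anyNA(z$zone))
})

test_that("Otsu auto-threshold splits a bimodal channel between the modes", {
  e <- ev(c(rnorm(50, 10, 1), rnorm(50, 1000, 50)),
          c(rnorm(50, 10, 1), rnorm(50, 1000, 50)))
  th <- auto_threshold(e)
  expect_gt(th$gf_cut, 15); expect_lt(th$gf_cut, 950)
  expect_gt(th$cf_cut, 15); expect_lt(th$cf_cut, 950)
  expect_false(th$fallback)
  # cross-check against an independent histogram Otsu (EBImage) on [0,1] data
  if (requireNamespace("EBImage", quietly = TRUE)) {
    x <- log1p(pmax(e$gf_intensity, 0))
    sc <- x / max(x)
    eb <- EBImage::otsu(EBImage::Image(matrix(sc, 10, 10)), range = c(0, 1)) * max(x)
    expect_lt(abs(log1p(th$gf_cut) - eb), 0.5)
  }
})

test_that("degenerate intensities trigger the quantile fallback, flagged", {
  e <- ev(rep(500, 20), rep(500, 20))
  th <- auto_threshold(e)
  expect_true(th$fallback)
  expect_equal(th$gf_cut, 500)
  expect_error(auto_threshold(ev(1:5, 1:5)), "fixed")
})

test_that("auto thresholds reproduce fixed-threshold zoning on separated classes", {
  set.seed(3)
  e <- ev(c(rnorm(60, 900, 60), rnorm(60, 5, 2)),
          c(rnorm(60, 5, 2), rnorm(60, 800, 50)))
  fixed <- gate_events(e, gate_thresholds(100, 100))
  auto <- gate_events(e, gate_thresholds(mode = "auto"))
  expect_identical(auto$counts, fixed$counts)
  expect_identical(auto$adjusted_wbc, fixed$adjusted_wbc)
  expect_identical(auto$adjusted_rbc, fixed$adjusted_rbc)
})

test_that("C4 resolution applies the size and intensity-ratio rules in order", {
  rules <- c4_rules(wbc_radius_um = c(3.5, 6), rbc_radius_um = c(2.5, 4),
                    pixel_size_um = 1)
  th <- gate_thresholds(100, 100)
  expect_identical(resolve_c4(ev(numeric(0), numeric(0), radius = numeric(0)),
                              rules, th),
                   character(0))
  # radius 1.6 x max single radius (6 um) -> doublet
  expect_identical(resolve_c4(ev(900, 800, radius = 9.6), rules, th), "DOUBLET")
  # far beyond the doublet band -> aggregate artifact
  expect_identical(resolve_c4(ev(900, 800, radius = 16), rules, th), "ARTIFACT")
  # sub-cellular radius -> artifact
  expect_identical(resolve_c4(ev(900, 800, radius = 1), rules, th), "ARTIFACT")
  # in-range: larger normalized channel wins; exact tie -> artifact
  expect_identical(resolve_c4(ev(900, 300, radius = 4), rules, th), "WBC")
  expect_identical(resolve_c4(ev(300, 900, radius = 4), rules, th), "RBC")
  expect_identical(resolve_c4(ev(500, 500, radius = 4), rules, th), "ARTIFACT")
})

test_that("a doublet contributes one count to each class", {
  e <- ev(c(900, 5, 900), c(5, 800, 800), radius = c(4, 3, 9.6))
  g <- gate_events(e, gate_thresholds(100, 100))
  expect_identical(g$doublet_count, 1L)
  expect_identical(g$adjusted_wbc, 2L)
  expect_identical(g$adjusted_rbc, 2L)
})

test_that("adjusted counts conserve events (doublets counted once as events)", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:80, 1)
    e <- ev(runif(n, 0, 1200), runif(n, 0, 1200), radius = runif(n, 0.5, 18))
    g <- gate_events(e, gate_thresholds(100, 100))
    expect_identical(g$adjusted_wbc + g$adjusted_rbc + g$artifact_count -
                       g$doublet_count,
                     as.integer(n))
  }
})

test_that("raising the GF cut never increases the adjusted WBC count", {
  set.seed(5)
  e <- ev(runif(200, 0, 1200), runif(200, 0, 1200), radius = runif(200, 2.5, 6))
  cuts <- c(10, 50, 100, 300, 600, 1100)
  wbc <- vapply(cuts, function(g)
    gate_events(e, gate_thresholds(g, 100))$adjusted_wbc, integer(1))
  expect_true(all(diff(wbc) <= 0))
})

test_that("zone counts equal generator class counts on separated events", {
  set.seed(9)
  n_w <- 600L; n_r <- 400L
  e <- ev(c(rlnorm(n_w, log(1000), 0.25), rlnorm(n_r, log(10), 0.5)),
          c(rlnorm(n_w, log(10), 0.5), rlnorm(n_r, log(800), 0.25)))
  g <- gate_events(e, gate_thresholds(100, 100))
  expect_identical(g$adjusted_wbc, n_w)
  expect_identical(g$adjusted_rbc, n_r)
  expect_identical(g$artifact_count, 0L)
})

test_that("engineered WBC-RBC overlaps are recovered within 5% via doublets", {
  set.seed(31)
  errs <- replicate(20, {
    n_w <- 45; n_r <- 45; n_d <- 10   # ten overlapping pairs
    e <- ev(c(rlnorm(n_w, log(1000), 0.25), rlnorm(n_r, log(10), 0.5),
              rlnorm(n_d, log(1000), 0.25)),
            c(rlnorm(n_w, log(10), 0.5), rlnorm(n_r, log(800), 0.25),
              rlnorm(n_d, log(800), 0.25)),
            radius = c(runif(n_w, 3.5, 6), runif(n_r, 2.5, 4),
                       runif(n_d, 9.1, 13)))
    g <- gate_events(e, gate_thresholds(100, 100))
    c(abs(g$adjusted_wbc - (n_w + n_d)) / (n_w + n_d),
      abs(g$adjusted_rbc - (n_r + n_d)) / (n_r + n_d))
  })
  expect_true(all(errs <= 0.05))
})

test_that("histogram summary mirrors adjusted counts and conserves events", {
  e <- ev(c(rep(900, 7), rep(5, 3)), c(rep(5, 7), rep(800, 3)))
  g <- gate_events(e, gate_thresholds(100, 100))
  h <- build_histogram(g, e)
  expect_identical(h$g1_count, 7L)
  expect_identical(h$g2_count, 3L)
  expect_equal(sum(h$gf_hist$counts), 10)
  h0 <- build_histogram(gate_events(e[0, ], gate_thresholds(100, 100)), e[0, ])
  expect_identical(h0$g1_count, 0L)
  expect_identical(h0$g2_count, 0L)
})
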