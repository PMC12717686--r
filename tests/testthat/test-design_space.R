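coarse_pars <- function() default_pars(grid_step = 0.05)

test_that("a 1x1 scan reproduces the single-scenario ROI", {
  p <- coarse_pars()
  tmpl <- scenario_table()$early
  surf <- scan_grid(0.3, 1.5, tmpl, p)
  expect_equal(dim(surf$roi_matrix), c(1, 1))
  expect_equal(surf$roi_matrix[1, 1], det_roi(0.3, 1.5, tmpl, p))
})

test_that("ROI falls along gamma, rises along delta, and is negative for costly no-benefit designs", {
  p <- coarse_pars()
  tmpl <- scenario_table()$early
  surf <- scan_grid(seq(0, 0.4, 0.1), seq(0, 3, 0.5), tmpl, p)
  for (i in seq_along(surf$delta_grid))
    expect_true(all(diff(surf$roi_matrix[i, ]) <= 1e-10))
  for (j in seq_along(surf$gamma_grid))
    expect_true(all(diff(surf$roi_matrix[, j]) >= -1e-10))
  # delta = 0 with gamma > 0: pure spend, no benefit
  expect_true(all(surf$roi_matrix[1, surf$gamma_grid > 0] < 0))
  expect_equal(surf$roi_matrix[1, 1], 0)  # delta = 0, gamma = 0
})

test_that("a stochastic scan with a point spec equals the deterministic scan", {
  p <- coarse_pars()
  tmpl <- scenario_table()$early
  dg <- c(0.1, 0.3); gg <- c(0.5, 1.5)
  det <- scan_grid(dg, gg, tmpl, p)
  sto <- scan_grid(dg, gg, tmpl, p, spec = delta_spec("point"), n = 3,
                   seed = 1)
  expect_equal(sto$roi_matrix, det$roi_matrix)
  expect_true(all(sto$positive_rate_matrix %in% c(0, 1)))
  # per-cell seeding makes repeated scans identical
  sto2 <- scan_grid(dg, gg, tmpl, p,
                    spec = delta_spec("truncnorm", sigma = 0.05), n = 5,
                    seed = 9)
  sto3 <- scan_grid(dg, gg, tmpl, p,
                    spec = delta_spec("truncnorm", sigma = 0.05), n = 5,
                    seed = 9)
  expect_identical(sto2, sto3)
})

test_that("contour extraction recovers the level set of a planted linear field", {
  dg <- seq(0, 0.4, 0.05)
  gg <- seq(0, 3, 0.25)
  a <- 403.7; b <- -61.3; c0 <- -29.17   # roi = a*delta + b*gamma + c0
  z <- outer(dg, gg, function(d, g) a * d + b * g + c0)
  surf <- structure(list(delta_grid = dg, gamma_grid = gg, roi_matrix = z,
                         cost_matrix = z * 0, positive_rate_matrix = NULL),
                    class = "roi_surface")
  for (lev in c(0, 50, 100)) {
    segs <- contour_levels(surf, lev)[[as.character(lev)]]
    expect_gt(length(segs), 0)
    for (seg in segs) {
      # linear interpolation is exact on a linear field
      expect_lt(max(abs(a * seg$delta + b * seg$gamma + c0 - lev)), 1e-9)
      expect_true(all(seg$delta >= min(dg) & seg$delta <= max(dg)))
      expect_true(all(seg$gamma >= min(gg) & seg$gamma <= max(gg)))
    }
  }
  # degenerate case: grid vertices falling exactly on the level; the
  # contour engine nudges such vertices by up to 1e-3 of the z-range, so
  # the recovered polyline stays within that fuzz (far below one cell)
  zd <- outer(dg, gg, function(d, g) 400 * d - 60 * g - 30)
  surfd <- structure(list(delta_grid = dg, gamma_grid = gg,
                          roi_matrix = zd, cost_matrix = zd * 0,
                          positive_rate_matrix = NULL),
                     class = "roi_surface")
  fuzz <- 2e-3 * diff(range(zd))
  for (seg in contour_levels(surfd, 50)[["50"]])
    expect_lt(max(abs(400 * seg$delta - 60 * seg$gamma - 30 - 50)), fuzz)

  # constant surface: no zero contour; level below the minimum: empty
  flat <- surf
  flat$roi_matrix[] <- 10
  expect_length(contour_levels(flat, 0)[["0"]], 0)
  expect_length(contour_levels(surf, -1e6)[["-1e+06"]], 0)
})

test_that("contour extraction is consistent under axis transposition", {
  dg <- seq(0, 0.4, 0.1); gg <- seq(0, 2, 0.5)
  z <- outer(dg, gg, function(d, g) 300 * d - 50 * g - 20)
  surf <- structure(list(delta_grid = dg, gamma_grid = gg, roi_matrix = z,
                         cost_matrix = z * 0, positive_rate_matrix = NULL),
                    class = "roi_surface")
  tsurf <- structure(list(delta_grid = gg, gamma_grid = dg,
                          roi_matrix = t(z), cost_matrix = t(z) * 0,
                          positive_rate_matrix = NULL),
                     class = "roi_surface")
  s1 <- contour_levels(surf, 0)[["0"]]
  s2 <- contour_levels(tsurf, 0)[["0"]]
  pts1 <- do.call(rbind, lapply(s1, function(s) cbind(s$delta, s$gamma)))
  pts2 <- do.call(rbind, lapply(s2, function(s) cbind(s$gamma, s$delta)))
  expect_equal(pts1[order(pts1[, 1]), ], pts2[order(pts2[, 1]), ],
               tolerance = 1e-9)
})

test_that("the cost-effectiveness frontier is the Pareto-undominated subset", {
  # brute-force oracle on random surfaces
  set.seed(42)
  for (rep in 1:5) {
    nd <- 4; ng <- 5
    surf <- structure(list(delta_grid = seq_len(nd) / 10,
                           gamma_grid = seq_len(ng) / 2,
                           roi_matrix = matrix(rnorm(nd * ng, 0, 50), nd, ng),
                           cost_matrix = matrix(runif(nd * ng, 100, 200),
                                                nd, ng),
                           positive_rate_matrix = NULL),
                      class = "roi_surface")
    fr <- cost_effectiveness_frontier(surf)
    brute <- vapply(seq_len(nrow(fr)), function(i) {
      !any(fr$total_cost <= fr$total_cost[i] & fr$roi > fr$roi[i] + 1e-12)
    }, logical(1))
    expect_equal(fr$on_frontier, brute)
    expect_true(all(diff(fr$total_cost) >= 0))
    # along the frontier no design is dominated by a cheaper one
    sub <- fr[fr$on_frontier, ]
    expect_true(all(diff(sub$roi) >= -1e-12))
  }
  # two points, one dominating
  two <- structure(list(delta_grid = c(0.1, 0.2), gamma_grid = 1,
                        roi_matrix = matrix(c(10, 50), 2, 1),
                        cost_matrix = matrix(c(200, 100), 2, 1),
                        positive_rate_matrix = NULL),
                   class = "roi_surface")
  fr2 <- cost_effectiveness_frontier(two)
  expect_equal(fr2$on_frontier, c(TRUE, FALSE))
  expect_equal(fr2$roi[fr2$on_frontier], 50)
  # single cell: trivially on the frontier
  one <- structure(list(delta_grid = 0.1, gamma_grid = 1,
                        roi_matrix = matrix(5), cost_matrix = matrix(100),
                        positive_rate_matrix = NULL),
                   class = "roi_surface")
  expect_true(cost_effectiveness_frontier(one)$on_frontier)
})

test_that("robustness stress tests behave as the identity and monotone limits require", {
  p <- coarse_pars()
  tab <- scenario_table()
  idn <- robustness_suite(tab, p, inflation_factor = 1, shortening = 0)
  expect_equal(idn$roi_inflated, idn$roi_baseline, tolerance = 1e-12)
  expect_equal(idn$roi_accelerated, idn$roi_baseline, tolerance = 1e-12)

  rb <- robustness_suite(tab, p, inflation_factor = 1.2, shortening = 0.15)
  expect_equal(nrow(rb), 5)  # baseline shape is excluded
  expect_true(all(rb$roi_inflated <= rb$roi_baseline + 1e-10))
  early <- rb[rb$scenario == "Early Adherence", ]
  expect_gt(early$roi_inflated, 0)
})

test_that("surface, contour and break-even writers emit the documented columns", {
  dir <- withr::local_tempdir()
  p <- coarse_pars()
  tmpl <- scenario_table()$early
  surf <- scan_grid(c(0.1, 0.3), c(0.5, 1.5), tmpl, p)
  sdf <- write_surface_csv(surf, file.path(dir, "surface.csv"))
  expect_equal(names(sdf),
               c("delta", "gamma", "roi", "total_cost", "positive_rate"))
  expect_equal(nrow(sdf), 4)

  cont <- contour_levels(surf, c(0, 1e6))
  cdf <- write_contours_csv(cont, file.path(dir, "contours.csv"))
  expect_equal(names(cdf), c("level", "polyline_id", "delta", "gamma"))

  bdf <- write_breakeven_csv(c(0.1, 0.25), tmpl, p,
                             file.path(dir, "breakeven.csv"))
  expect_equal(names(bdf), c("delta", "gamma_star", "bounded_flag"))
  expect_true(all(diff(bdf$gamma_star) > 0))
})
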