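# QC filtering: rule outcomes on hand-computable inputs, plus the
# idempotence / monotonicity / conservation properties.

make_nuclei_slide <- function(areas, perimeters = NULL,
                              duct_area = 10000) {
  n <- length(areas)
  if (is.null(perimeters)) perimeters <- 2 * sqrt(pi * areas)  # circles
  obj <- data.frame(
    object_id = c("s1", "d1", sprintf("n%d", seq_len(n))),
    class = c("stroma", "duct", rep("nucleus", n)),
    area = c(1e6, duct_area, areas),
    perimeter = c(4000, 2 * sqrt(pi * duct_area), perimeters),
    centroid_x = c(500, 100, 90 + 5 * seq_len(n)),
    centroid_y = c(500, 100, rep(100, n)),
    parent_duct_id = c(NA, NA, rep("d1", n)))
  slide_objects("f", obj, microns_per_pixel = 1)
}

test_that("shape factor matches analytic shapes and rejects bad input", {
  expect_equal(shape_factor(pi, 2 * pi), 1)            # unit circle
  expect_equal(shape_factor(1, 4), pi / 4)             # unit square
  expect_error(shape_factor(1, 0), "perimeter")
  expect_error(shape_factor(-1, 1), "area")
})

test_that("nucleus rules remove exactly the stated objects", {
  sl <- make_nuclei_slide(areas = c(5, 50, 50))
  cfg <- filter_config(nucleus_min_area = 10, nucleus_max_area = 1e6,
                       nucleus_min_perimeter = 0.1,
                       nucleus_max_perimeter = 1e6,
                       nucleus_min_shape_factor = 0)
  r <- filter_nuclei(sl, cfg)
  expect_equal(sum(r$slide$objects$class == "nucleus"), 2)
  expect_equal(r$report$removed$object_id, "n1")
  expect_equal(r$report$removed$rule, "area")

  # permissive thresholds are the identity
  cfg0 <- filter_config(nucleus_min_area = 0, nucleus_max_area = Inf,
                        nucleus_min_perimeter = 0,
                        nucleus_max_perimeter = Inf,
                        nucleus_min_shape_factor = 0,
                        duct_min_nuclei = 1,
                        duct_min_density = 0, duct_max_density = Inf,
                        duct_max_mean_min_nucl_dist = Inf)
  r0 <- filter_nuclei(sl, cfg0)
  expect_equal(nrow(r0$report$removed), 0)
  expect_equal(nrow(r0$slide$objects), nrow(sl$objects))

  # elongated object fails the shape rule and is attributed to it
  sl2 <- make_nuclei_slide(areas = c(50, 50),
                           perimeters = c(2 * sqrt(pi * 50),
                                          2 * sqrt(pi * 50 / 0.2)))
  cfg2 <- filter_config(nucleus_min_area = 0, nucleus_max_area = Inf,
                        nucleus_min_perimeter = 0,
                        nucleus_max_perimeter = Inf,
                        nucleus_min_shape_factor = 0.3)
  r2 <- filter_nuclei(sl2, cfg2)
  expect_equal(r2$report$removed$rule, "shape_factor")
  expect_equal(r2$report$removed$object_id, "n2")
})

test_that("duct rules fire in the documented order with exact outcomes", {
  # 2 nuclei vs duct_min_nuclei = 5
  sl <- make_nuclei_slide(areas = c(50, 50))
  r <- filter_ducts(sl, filter_config(duct_min_nuclei = 5))
  expect_equal(r$report$removed$rule[r$report$removed$class == "duct"],
               "min_nuclei")
  expect_equal(sum(r$slide$objects$class == "duct"), 0)
  # nuclei of the removed duct go with it
  expect_equal(sum(r$slide$objects$class == "nucleus"), 0)

  # density 50/10000 = 0.005 >= 0.001 passes
  sl2 <- make_nuclei_slide(areas = rep(50, 50))
  cfg2 <- filter_config(duct_min_nuclei = 1, duct_min_density = 0.001,
                        duct_max_density = Inf,
                        duct_max_mean_min_nucl_dist = Inf)
  r2 <- filter_ducts(sl2, cfg2)
  expect_equal(sum(r2$slide$objects$class == "duct"), 1)

  # collinear nuclei at x = 0, 3, 10: min dists {3, 3, 7}, mean 13/3
  obj <- data.frame(
    object_id = c("s1", "d1", "n1", "n2", "n3"),
    class = c("stroma", "duct", rep("nucleus", 3)),
    area = c(1e6, 10000, 50, 50, 50),
    perimeter = c(4000, 355, 25, 25, 25),
    centroid_x = c(500, 5, 0, 3, 10),
    centroid_y = c(500, 0, 0, 0, 0),
    parent_duct_id = c(NA, NA, "d1", "d1", "d1"))
  sl3 <- slide_objects("f3", obj, microns_per_pixel = 1)
  cfg3 <- filter_config(duct_min_nuclei = 1, duct_min_density = 0,
                        duct_max_density = Inf,
                        duct_max_mean_min_nucl_dist = 4.0)
  r3 <- filter_ducts(sl3, cfg3)
  expect_equal(r3$report$removed$rule[r3$report$removed$class == "duct"],
               "min_nucl_dist")
  cfg4 <- filter_config(duct_min_nuclei = 1, duct_min_density = 0,
                        duct_max_density = Inf,
                        duct_max_mean_min_nucl_dist = 13 / 3 + 1e-9)
  expect_equal(sum(filter_ducts(sl3, cfg4)$slide$objects$class == "duct"),
               1)
})

test_that("filtering is idempotent and reports reconcile with tables", {
  s <- simulate_slide(slide_sim_params(n_ducts = 10, seed = 5,
                                       nuclear_density_mean = 3e-3))
  cfg <- filter_config()
  f1 <- filter_slide(s, cfg)
  f2 <- filter_slide(f1$slide, cfg)
  expect_equal(nrow(f2$report$removed), 0)
  expect_identical(f1$slide$objects$object_id, f2$slide$objects$object_id)
  # conservation: in - removed = surviving, per class
  for (cls in c("nucleus", "duct")) {
    n_in <- sum(s$objects$class == cls)
    n_rm <- sum(f1$report$removed$class == cls)
    n_out <- sum(f1$slide$objects$class == cls)
    if (cls == "nucleus") {
      # nuclei can also be removed as collateral of duct removal
      expect_equal(n_in - n_rm, n_out)
    } else {
      expect_equal(n_in - n_rm, n_out)
    }
  }
})

test_that("tightening any single threshold never adds survivors", {
  s <- simulate_slide(slide_sim_params(n_ducts = 12, seed = 11))
  base <- filter_config()
  survivors <- function(cfg) nrow(filter_slide(s, cfg)$slide$objects)
  set.seed(42)
  tighten <- list(
    nucleus_min_area = function(c, f) { c$nucleus_min_area <- c$nucleus_min_area * (1 + f); c },
    nucleus_max_area = function(c, f) { c$nucleus_max_area <- c$nucleus_max_area * (1 - f / 2); c },
    nucleus_min_perimeter = function(c, f) { c$nucleus_min_perimeter <- c$nucleus_min_perimeter * (1 + f); c },
    nucleus_max_perimeter = function(c, f) { c$nucleus_max_perimeter <- c$nucleus_max_perimeter * (1 - f / 2); c },
    nucleus_min_shape_factor = function(c, f) { c$nucleus_min_shape_factor <- min(1, c$nucleus_min_shape_factor * (1 + f)); c },
    duct_min_nuclei = function(c, f) { c$duct_min_nuclei <- c$duct_min_nuclei + ceiling(10 * f); c },
    duct_min_density = function(c, f) { c$duct_min_density <- c$duct_min_density * (1 + 3 * f); c },
    duct_max_density = function(c, f) { c$duct_max_density <- c$duct_max_density * (1 - f / 2); c },
    duct_max_mean_min_nucl_dist = function(c, f) { c$duct_max_mean_min_nucl_dist <- c$duct_max_mean_min_nucl_dist * (1 - f / 2); c })
  n_base <- survivors(base)
  for (rep in seq_len(40)) {
    nm <- sample(names(tighten), 1)
    f <- runif(1, 0.05, 1)
    cfg2 <- tighten[[nm]](base, f)
    class(cfg2) <- "filter_config"
    expect_lte(survivors(cfg2), n_base)
  }
})
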