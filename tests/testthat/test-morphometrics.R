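# Per-duct measurements, slide summaries and redundancy pruning.

test_that("circular duct with circular nuclei matches analytic values", {
  sl <- toy_slide(duct_radii = 50, nuclei_per_duct = 50,
                  nucleus_radius = 2, spacing = 11)
  m <- measure_ducts(sl)
  expect_equal(nrow(m), 1)
  expect_equal(m$duct_area, pi * 50^2, tolerance = 1e-4)
  expect_equal(m$duct_circularity, 1, tolerance = 1e-3)
  expect_equal(m$duct_elongation, 1, tolerance = 1e-3)
  expect_equal(m$duct_solidity, 1, tolerance = 1e-3)
  expect_equal(m$equivalent_diameter, 100, tolerance = 1e-4)
  expect_equal(m$nuclei_count, 50)
  expect_equal(m$nuclei_density, 50 / (pi * 50^2), tolerance = 1e-4)
  expect_equal(m$mean_nuclear_area, pi * 4, tolerance = 1e-12)
  expect_equal(m$nuclear_area_fraction, 50 * pi * 4 / (pi * 50^2),
               tolerance = 1e-4)
  expect_equal(m$mean_nuclear_circularity, 1)
  expect_true(is.na(m$nearest_duct_distance))  # single duct
  expect_equal(m$duct_stroma_ratio, pi * 50^2 / 1e6, tolerance = 1e-4)
})

test_that("elongation and nearest-duct distance follow the geometry", {
  # 2:1 ellipse
  poly <- dcismorph:::ellipse_polygon(100, 100, 40, 20, 0.7, 512L)
  obj <- data.frame(object_id = c("s1", "d1"),
                    class = c("stroma", "duct"),
                    area = c(1e6, dcismorph:::poly_area(poly)),
                    perimeter = c(4000, dcismorph:::poly_perimeter(poly)),
                    centroid_x = c(500, 100), centroid_y = c(500, 100),
                    parent_duct_id = NA_character_)
  obj$polygon <- list(NULL, poly)
  m <- measure_ducts(slide_objects("e", obj, 1))
  expect_equal(m$duct_elongation, 2, tolerance = 1e-3)
  expect_equal(m$equivalent_diameter, sqrt(4 * m$duct_area / pi))

  sl2 <- toy_slide(duct_radii = c(50, 30))  # centers 300 um apart
  m2 <- measure_ducts(sl2)
  expect_equal(m2$nearest_duct_distance, c(300, 300))
})

test_that("summaries produce the 8 x 15 = 120 variable layout", {
  sl <- toy_slide(duct_radii = c(50, 30, 40))
  sv <- summarize_slide(measure_ducts(sl))
  vars <- setdiff(names(sv), c("slide_id", "n_ducts"))
  expect_length(vars, 120)
  expect_setequal(
    unique(sub(".*__", "", vars)),
    c("mean", "median", "sd", "iqr", "skewness", "kurtosis", "sum", "max"))
  expect_setequal(unique(sub("__.*", "", vars)),
                  dcismorph:::DUCT_MEASUREMENTS)
  expect_equal(sv$n_ducts, 3)
})

test_that("summary parameters match hand-computed values and conventions", {
  m <- data.frame(duct_id = c("a", "b", "c"), duct_area = c(1, 2, 3))
  attr(m, "slide_id") <- "x"
  sv <- summarize_slide(m, measurement_set = "duct_area")
  expect_equal(sv$duct_area__mean, 2)
  expect_equal(sv$duct_area__median, 2)
  expect_equal(sv$duct_area__sd, 1)
  expect_equal(sv$duct_area__sum, 6)
  expect_equal(sv$duct_area__max, 3)
  expect_equal(sv$duct_area__skewness, 0)
  # constant column: degenerate conventions map spread/shape to 0
  m2 <- data.frame(duct_id = c("a", "b", "c"), duct_area = c(5, 5, 5))
  sv2 <- summarize_slide(m2, measurement_set = "duct_area")
  expect_equal(sv2$duct_area__sd, 0)
  expect_equal(sv2$duct_area__skewness, 0)
  expect_equal(sv2$duct_area__kurtosis, 0)
  # empty table errors
  expect_error(summarize_slide(m[0, ]), "no ducts")
})

test_that("skewness and kurtosis match the moment definitions", {
  set.seed(8)
  x <- rexp(400)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  expect_equal(sample_skewness(x), m3 / m2^1.5)
  expect_equal(sample_kurtosis(x), m4 / m2^2 - 3)
  expect_equal(sample_skewness(c(2)), 0)
})

test_that("measurements are scale-equivariant by dimension", {
  sl <- toy_slide(duct_radii = c(50, 30), nuclei_per_duct = 9)
  c_scale <- 3
  sc <- sl
  sc$objects$area <- sl$objects$area * c_scale^2
  sc$objects$perimeter <- sl$objects$perimeter * c_scale
  sc$objects$centroid_x <- sl$objects$centroid_x * c_scale
  sc$objects$centroid_y <- sl$objects$centroid_y * c_scale
  sc$objects$polygon <- lapply(sl$objects$polygon, function(p)
    if (is.null(p)) NULL else p * c_scale)
  m1 <- measure_ducts(sl); m2 <- measure_ducts(sc)
  area_like <- c("duct_area", "mean_nuclear_area", "sd_nuclear_area")
  len_like <- c("duct_perimeter", "equivalent_diameter",
                "mean_min_nuclear_distance", "nearest_duct_distance")
  inv <- c("duct_circularity", "duct_elongation", "duct_solidity",
           "nuclei_count", "mean_nuclear_circularity",
           "nuclear_area_fraction", "duct_stroma_ratio")
  for (v in area_like) expect_equal(m2[[v]], m1[[v]] * c_scale^2,
                                    tolerance = 1e-8, label = v)
  for (v in len_like) expect_equal(m2[[v]], m1[[v]] * c_scale,
                                   tolerance = 1e-8, label = v)
  for (v in inv) expect_equal(m2[[v]], m1[[v]], tolerance = 1e-8,
                              label = v)
  expect_equal(m2$nuclei_density, m1$nuclei_density / c_scale^2,
               tolerance = 1e-8)
})

test_that("headline aliases equal the corresponding sums", {
  sl <- toy_slide(duct_radii = c(50, 30), nuclei_per_duct = 9)
  ft <- summarize_slides(list(sl))
  m <- measure_ducts(sl)
  hv <- headline_variables(ft)
  expect_equal(hv$total_dcis_area, sum(m$duct_area))
  expect_equal(hv$total_dcis_cells, sum(m$nuclei_count))
  expect_equal(hv$total_duct_stroma_ratio, sum(m$duct_stroma_ratio))
})

test_that("pruning removes duplicates, negations, and nothing else", {
  set.seed(21)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  ft <- as_feature_table(`rownames<-`(X, sprintf("s%02d", 1:n)))
  # independent noise: nothing removed
  pr0 <- prune_redundant(ft, threshold = 0.9)
  expect_length(pr0$retained, 3)
  expect_equal(nrow(pr0$trace), 0)
  # identical pair: exactly one removed
  X2 <- cbind(X, a2 = X[, "a"])
  pr1 <- prune_redundant(as_feature_table(
    `rownames<-`(X2, sprintf("s%02d", 1:n))), 0.9)
  expect_length(pr1$retained, 3)
  expect_equal(nrow(pr1$trace), 1)
  expect_true(xor("a" %in% pr1$retained, "a2" %in% pr1$retained))
  # perfect negation: |rho| = 1, one removed
  X3 <- cbind(X, neg = -X[, "b"])
  pr2 <- prune_redundant(as_feature_table(
    `rownames<-`(X3, sprintf("s%02d", 1:n))), 0.9)
  expect_length(pr2$retained, 3)
  # postcondition: no retained pair above threshold
  rho <- abs(cor(X3[, pr2$retained], method = "spearman"))
  diag(rho) <- 0
  expect_lte(max(rho), 0.9)
  expect_error(prune_redundant(ft[1:2, ]), "3 slides")
})

test_that("weak-correlation fraction matches its definition", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(sprintf("s%03d", 1:n), letters[1:6]))
  ft <- as_feature_table(X)
  pr <- prune_redundant(ft, 0.9)
  st <- correlation_heatmap_stats(ft, pr)
  expect_equal(st$fraction_weak, 1)
  # two strongly anticorrelated retained columns only
  Y <- cbind(u = rnorm(n))
  Y <- cbind(Y, v = -0.75 * Y[, "u"] + 0.4 * rnorm(n))
  fy <- as_feature_table(`rownames<-`(Y, sprintf("s%03d", 1:n)))
  pry <- prune_redundant(fy, 0.99)
  sty <- correlation_heatmap_stats(fy, pry)
  expect_equal(sty$fraction_weak, 0)
  # degenerate single retained column
  Z <- cbind(p = rnorm(n))
  Z <- cbind(Z, q = Z[, "p"])
  fz <- as_feature_table(`rownames<-`(Z, sprintf("s%03d", 1:n)))
  prz <- prune_redundant(fz, 0.9)
  expect_warning(stz <- correlation_heatmap_stats(fz, prz), "fewer than 2")
  expect_equal(stz$fraction_weak, 1)
})
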