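# Object-table / mask / annotation ingestion and unit conventions.

test_that("micron object tables pass through unchanged", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "#units=um", "#mpp=0.24",
    "object_id,class,area,perimeter,centroid_x,centroid_y,parent_duct_id",
    "s1,stroma,100000,2000,10,10,",
    "d1,duct,500,90,100,100,",
    "d2,duct,800,110,300,100,",
    "n1,nucleus,40,23,99,100,d1",
    "n2,nucleus,45,24,101,101,d1",
    "n3,nucleus,50,26,300,99,d2"), path)
  sl <- read_object_table(path)
  expect_s3_class(sl, "slide_objects")
  expect_equal(nrow(sl$objects), 6)
  expect_equal(sl$microns_per_pixel, 0.24)
  expect_equal(sl$objects$area[sl$objects$object_id == "d1"], 500)
})

test_that("pixel-unit tables are scaled by mpp and mpp^2", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "#units=px", "#mpp=0.24",
    "object_id,class,area,perimeter,centroid_x,centroid_y",
    "s1,stroma,1e6,4000,500,500",
    "d1,duct,100,40,50,60"), path)
  sl <- read_object_table(path)
  o <- sl$objects
  expect_equal(o$area[o$object_id == "d1"], 100 * 0.24^2)  # 5.76
  expect_equal(o$perimeter[o$object_id == "d1"], 40 * 0.24)
  expect_equal(o$centroid_x[o$object_id == "d1"], 50 * 0.24)
  # px -> um -> px round trip
  expect_equal(o$area[o$object_id == "d1"] / 0.24^2, 100,
               tolerance = 1e-9)
})

test_that("malformed object tables are rejected with useful errors", {
  p1 <- tempfile(fileext = ".csv")
  writeLines(c("object_id,class,area,perimeter,centroid_x",
               "d1,duct,5,9,1"), p1)
  expect_error(read_object_table(p1), "centroid_y")
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("object_id,class,area,perimeter,centroid_x,centroid_y",
               "s1,stroma,100,40,0,0",
               "d1,duct,-1,9,1,1"), p2)
  expect_error(read_object_table(p2), "d1")
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("object_id,class,area,perimeter,centroid_x,centroid_y",
               "x1,mitochondrion,5,9,1,1"), p3)
  expect_error(read_object_table(p3), "unknown object class")
})

test_that("slide validation enforces container invariants", {
  good <- toy_slide()
  expect_silent(validate_slide(good, deep = TRUE))
  bad <- good
  bad$objects$parent_duct_id[5] <- "duct_99"
  expect_error(validate_slide(bad), "duct_99")
  dup <- good
  dup$objects$object_id[2] <- dup$objects$object_id[1]
  expect_error(validate_slide(dup), "duplicated")
})

test_that("object tables round-trip through CSV including polygons", {
  sl <- toy_slide()
  path <- tempfile(fileext = ".csv")
  write_object_table(sl, path)
  back <- read_object_table(path, slide_id = sl$slide_id)
  expect_equal(back$objects$area, sl$objects$area, tolerance = 1e-5)
  expect_equal(back$objects$object_id, sl$objects$object_id)
  p0 <- sl$objects$polygon[[2]]
  p1 <- back$objects$polygon[[2]]
  expect_equal(dcismorph:::poly_area(p1), dcismorph:::poly_area(p0),
               tolerance = 1e-4)
})

test_that("mask components become objects with correct areas and parents", {
  pix <- matrix(0L, 30, 30)
  pix[2:3, 2:4] <- 2L                    # 6-px duct
  pix[10:11, 10:11] <- 2L                # 4-px duct
  mk <- label_mask("m", pix, microns_per_pixel = 1)
  so <- mask_to_objects(mk)
  d <- so$objects[so$objects$class == "duct", ]
  expect_equal(sort(d$area), c(4, 6))

  # 50x50 duct at mpp 0.24 -> 2500 * 0.0576 = 144 um^2
  pix2 <- matrix(0L, 60, 60)
  pix2[6:55, 6:55] <- 2L
  so2 <- mask_to_objects(label_mask("m2", pix2, 0.24))
  expect_equal(so2$objects$area[so2$objects$class == "duct"], 144)

  # nucleus blob centered in a duct blob gets that parent
  pix3 <- matrix(0L, 40, 40)
  pix3[5:30, 5:30] <- 2L
  pix3[15:18, 15:18] <- 3L
  so3 <- mask_to_objects(label_mask("m3", pix3, 1))
  nuc <- so3$objects[so3$objects$class == "nucleus", ]
  expect_equal(nuc$parent_duct_id, "duct_1")

  # empty mask is an empty table, not an error
  so4 <- mask_to_objects(label_mask("m4", matrix(0L, 5, 5), 1))
  expect_equal(nrow(so4$objects), 0)
  expect_error(label_mask("m5", matrix(-1L, 2, 2), 1), "non-negative")
})

test_that("GeoJSON annotations parse, split multipolygons, and validate", {
  path <- tempfile(fileext = ".geojson")
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(class = "DCIS"),
           geometry = list(type = "Polygon",
             coordinates = list(list(list(0, 0), list(10, 0),
                                     list(10, 10), list(0, 10),
                                     list(0, 0))))),
      list(type = "Feature",
           properties = list(class = "stroma"),
           geometry = list(type = "MultiPolygon",
             coordinates = list(
               list(list(list(20, 20), list(30, 20), list(30, 30),
                         list(20, 20))),
               list(list(list(40, 40), list(50, 40), list(50, 50),
                         list(40, 40))))))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
  ann <- read_annotations(path)
  expect_equal(nrow(ann$polygons), 3)
  expect_equal(ann$polygons$class, c("DCIS", "stroma", "stroma"))
  expect_equal(dcismorph:::poly_area(ann$polygons$polygon[[1]]), 100)

  # empty collection
  p2 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       p2, auto_unbox = TRUE)
  expect_equal(nrow(read_annotations(p2)$polygons), 0)

  # missing class property
  gj$features[[1]]$properties <- list()
  p3 <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p3, auto_unbox = TRUE)
  expect_error(read_annotations(p3), "class")
})

test_that("feature tables round-trip exactly and reject ragged input", {
  X <- matrix(rnorm(3 * 120), 3, 120,
              dimnames = list(NULL, sprintf("v%03d", 1:120)))
  ft <- data.frame(slide_id = c("a", "b", "c"), X, check.names = FALSE)
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$slide_id, ft$slide_id)
  expect_equal(as.matrix(back[, -1]), as.matrix(ft[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(write_feature_table(data.frame(x = 1), path), "slide_id")
  # header-only file for an empty collection
  write_feature_table(ft[0, ], path)
  expect_equal(nrow(read_feature_table(path)), 0)
})

test_that("cohort tables validate the status/event-time consistency", {
  co <- toy_cohort(event_years = c(1, 7, NA), followup_years = c(1, 7, 12))
  expect_s3_class(co$iibc_status5, "ordered")
  expect_equal(as.character(co$iibc_status5),
               c("event_0_5", "event_5_10", "no_event"))
  bad <- as.data.frame(co)
  bad$iibc_status5 <- as.character(bad$iibc_status5)
  bad$iibc_status5[1] <- "event_5_10"
  expect_error(read_cohort_table(bad), "inconsistent")
  bad2 <- as.data.frame(co)
  bad2$iibc_status5 <- as.character(bad2$iibc_status5)
  bad2$event_years[2] <- 99
  expect_error(read_cohort_table(bad2), "exceeds")
})

test_that("masks round-trip through PNG and TIFF", {
  pix <- matrix(0L, 12, 17)
  pix[3:5, 4:9] <- 2L
  pix[8, 2] <- 3L
  mk <- label_mask("io", pix, 0.5)
  for (ext in c(".png", ".tif")) {
    path <- tempfile(fileext = ext)
    if (ext == ".png") write_mask(mk, path)
    else tiff::writeTIFF(mk$pixels / 255, path)
    back <- read_mask(path, microns_per_pixel = 0.5)
    expect_equal(back$pixels, pix, ignore_attr = TRUE)
  }
})
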