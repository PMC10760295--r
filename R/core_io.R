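# Ingestion and serialization of segmented-object tables, label masks,
# pathologist annotations, feature tables and cohort tables. This module
# owns every unit convention: all geometry leaving it is in microns
# (lengths) and square microns (areas); nothing downstream ever sees
# pixels. Masks are 0-based pixel index grids; pixel i (0-based) maps to
# the continuous coordinate (i + 0.5) * mpp (pixel-center convention),
# with the origin at the slide top-left and y increasing downward.

OBJECT_CLASSES <- c("stroma", "duct", "nucleus")

#' Construct a slide object table
#'
#' The central container of the pipeline: all segmented objects (stroma
#' regions, DCIS ducts, nuclei) of one H&E whole-slide image, plus slide
#' metadata. Geometry is always in microns.
#'
#' @param slide_id character scalar.
#' @param objects data.frame with columns `object_id`, `class`
#'   (stroma/duct/nucleus), `area` (um^2), `perimeter` (um),
#'   `centroid_x`, `centroid_y` (um); optional `parent_duct_id`
#'   (nuclei), `elongation`, `solidity` (precomputed shape fields), and a
#'   list column `polygon` of two-column vertex matrices in um.
#' @param microns_per_pixel microns per pixel of the source image
#'   (default 0.24, a 20x scan).
#' @param qc_pass logical; slide-level visual QC flag. This is an input:
#'   slide QC (staining quality, section damage) is assessed by eye
#'   upstream and is not computed here.
#' @param validate run [validate_slide()] on the result.
#' @return object of class `slide_objects`.
#' @export
slide_objects <- function(slide_id, objects, microns_per_pixel = 0.24,
                          qc_pass = TRUE, validate = TRUE) {
  stopifnot(is.character(slide_id), length(slide_id) == 1L)
  objects <- as.data.frame(objects)
  req <- c("object_id", "class", "area", "perimeter",
           "centroid_x", "centroid_y")
  miss <- setdiff(req, names(objects))
  if (length(miss))
    stop("objects table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!"parent_duct_id" %in% names(objects))
    objects$parent_duct_id <- rep(NA_character_, nrow(objects))
  if (!"polygon" %in% names(objects))
    objects$polygon <- replicate(nrow(objects), NULL, simplify = FALSE)
  objects$object_id <- as.character(objects$object_id)
  objects$class <- as.character(objects$class)
  objects$parent_duct_id <- as.character(objects$parent_duct_id)
  x <- structure(
    list(slide_id = slide_id, microns_per_pixel = microns_per_pixel,
         objects = objects, qc_pass = isTRUE(qc_pass)),
    class = "slide_objects")
  if (validate) validate_slide(x)
  x
}

#' Validate a slide object table
#'
#' Checks the container invariants: positive microns-per-pixel, unique
#' object ids, known classes, positive areas and perimeters, nucleus
#' parents referencing existing ducts, at least one stroma object when
#' ducts are present, and (when `deep = TRUE`) that polygons are simple
#' and their shoelace area agrees with the stored `area` within 1%.
#'
#' @param x a `slide_objects` object.
#' @param deep also run the O(n^2) polygon simplicity check and the
#'   polygon-vs-area consistency check.
#' @return `x`, invisibly; errors describe every offending object id.
#' @export
validate_slide <- function(x, deep = FALSE) {
  stopifnot(inherits(x, "slide_objects"))
  if (!is.numeric(x$microns_per_pixel) || x$microns_per_pixel <= 0)
    stop("microns_per_pixel must be a positive number")
  o <- x$objects
  if (anyDuplicated(o$object_id))
    stop("duplicated object_id within slide: ",
         paste(unique(o$object_id[duplicated(o$object_id)]), collapse = ", "))
  bad_class <- setdiff(unique(o$class), OBJECT_CLASSES)
  if (length(bad_class))
    stop("unknown object class(es): ", paste(bad_class, collapse = ", "))
  bad <- o$object_id[!is.finite(o$area) | o$area <= 0 |
                       !is.finite(o$perimeter) | o$perimeter <= 0]
  if (length(bad))
    stop("non-positive area or perimeter for object(s): ",
         paste(bad, collapse = ", "))
  if (any(o$class == "duct") && !any(o$class == "stroma"))
    stop("slide has duct objects but no stroma object")
  nuc <- o[o$class == "nucleus" & !is.na(o$parent_duct_id), , drop = FALSE]
  ducts <- o$object_id[o$class == "duct"]
  orphan <- setdiff(unique(nuc$parent_duct_id), ducts)
  if (length(orphan))
    stop("nucleus parent_duct_id references unknown duct(s): ",
         paste(orphan, collapse = ", "))
  if (deep) {
    for (i in which(!vapply(o$polygon, is.null, logical(1)))) {
      p <- o$polygon[[i]]
      if (!poly_is_simple(p))
        stop("self-intersecting polygon for object ", o$object_id[i])
      pa <- poly_area(p)
      if (abs(pa - o$area[i]) > 0.01 * o$area[i])
        stop("polygon area disagrees with stored area (> 1%) for object ",
             o$object_id[i])
    }
  }
  invisible(x)
}

#' @export
print.slide_objects <- function(x, ...) {
  tab <- table(factor(x$objects$class, OBJECT_CLASSES))
  cat(sprintf(
    "<slide_objects> %s  (%.3g um/px, qc_pass=%s)\n  %d stroma, %d ducts, %d nuclei\n",
    x$slide_id, x$microns_per_pixel, x$qc_pass,
    tab[["stroma"]], tab[["duct"]], tab[["nucleus"]]))
  invisible(x)
}

# Subset a slide_objects to the rows where `keep` is TRUE.
subset_slide <- function(x, keep) {
  x$objects <- x$objects[keep, , drop = FALSE]
  rownames(x$objects) <- NULL
  x
}

#' Read a segmented-object CSV into a slide object table
#'
#' The CSV dialect mirrors the tables exported by commercial WSI
#' segmentation platforms: one row per object with columns
#' `object_id,class,area,perimeter,centroid_x,centroid_y` and optional
#' `polygon_wkt` and `parent_duct_id`. Leading comment lines `#units=um`
#' (or `px`) and `#mpp=<float>` declare the unit convention; pixel-unit
#' inputs are converted so that all returned geometry is in microns
#' (areas scaled by mpp^2, lengths by mpp).
#'
#' @param path CSV file path.
#' @param microns_per_pixel used when the file carries no `#mpp=` header.
#' @param slide_id defaults to the file name without extension.
#' @param qc_pass slide-level visual QC flag to attach.
#' @return a [slide_objects] table in micron units.
#' @export
read_object_table <- function(path, microns_per_pixel = 0.24,
                              slide_id = NULL, qc_pass = TRUE) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  units <- sub("^#units=", "", grep("^#units=", hdr, value = TRUE))
  mpp <- suppressWarnings(as.numeric(
    sub("^#mpp=", "", grep("^#mpp=", hdr, value = TRUE))))
  if (!length(mpp) || is.na(mpp[1])) mpp <- microns_per_pixel
  mpp <- mpp[1]
  units <- if (length(units)) units[1] else "um"
  if (!units %in% c("um", "px"))
    stop("unsupported units declaration: ", units)
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  req <- c("object_id", "class", "area", "perimeter",
           "centroid_x", "centroid_y")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("object table is missing required column(s): ",
         paste(miss, collapse = ", "))
  bad <- df$object_id[!is.finite(df$area) | df$area <= 0 |
                        !is.finite(df$perimeter) | df$perimeter <= 0]
  if (length(bad))
    stop("non-positive area or perimeter for object(s): ",
         paste(bad, collapse = ", "))
  polys <- if ("polygon_wkt" %in% names(df)) {
    lapply(df$polygon_wkt, parse_wkt_polygon)
  } else replicate(nrow(df), NULL, simplify = FALSE)
  if (units == "px") {
    df$area <- df$area * mpp^2
    df$perimeter <- df$perimeter * mpp
    df$centroid_x <- df$centroid_x * mpp
    df$centroid_y <- df$centroid_y * mpp
    polys <- lapply(polys, function(p) if (is.null(p)) NULL else p * mpp)
  }
  df$polygon_wkt <- NULL
  df$polygon <- polys
  if (is.null(slide_id))
    slide_id <- sub("\\.[^.]*$", "", basename(path))
  slide_objects(slide_id, df, microns_per_pixel = mpp, qc_pass = qc_pass)
}

#' Write a slide object table to the CSV dialect of [read_object_table()]
#'
#' Always writes micron units (`#units=um`); polygons are serialized as
#' WKT POLYGON strings.
#'
#' @param x a `slide_objects` table.
#' @param path output CSV path.
#' @export
write_object_table <- function(x, path) {
  stopifnot(inherits(x, "slide_objects"))
  o <- x$objects
  df <- o[, c("object_id", "class", "area", "perimeter",
              "centroid_x", "centroid_y", "parent_duct_id")]
  df$polygon_wkt <- vapply(o$polygon, function(p) {
    if (is.null(p)) "" else format_wkt_polygon(p)
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#units=um", sprintf("#mpp=%.12g", x$microns_per_pixel)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = which(
    names(df) %in% c("object_id", "class", "parent_duct_id", "polygon_wkt")))
  invisible(path)
}

parse_wkt_polygon <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  body <- regmatches(s, regexpr("\\(\\([^)]*\\)\\)", s))
  if (!length(body)) stop("cannot parse WKT polygon: ", substr(s, 1, 40))
  nums <- strsplit(trimws(strsplit(gsub("[()]", "", body), ",")[[1]]), "\\s+")
  xy <- do.call(rbind, lapply(nums, function(v) as.numeric(v[1:2])))
  close_check(xy)
}

format_wkt_polygon <- function(xy) {
  xy <- close_check(xy)
  xy <- rbind(xy, xy[1, ])
  sprintf("POLYGON((%s))",
          paste(sprintf("%.6g %.6g", xy[, 1], xy[, 2]), collapse = ", "))
}

#' Read a single-channel label mask (TIFF or PNG)
#'
#' Class encoding: 0 = background, 1 = stroma, 2 = duct, 3 = nucleus.
#' 16-bit images read by the png/tiff packages arrive scaled to [0, 1]
#' and are rescaled back to integer labels.
#'
#' @param path `.tif`/`.tiff` or `.png` file.
#' @param slide_id defaults to the file name.
#' @param microns_per_pixel micron size of one pixel.
#' @return object of class `label_mask`: list with `slide_id`, integer
#'   matrix `pixels` (rows = y), and `microns_per_pixel`.
#' @export
read_mask <- function(path, slide_id = NULL, microns_per_pixel = 0.24) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: .", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  pix <- round(img * 255)
  label_mask(if (is.null(slide_id)) sub("\\.[^.]*$", "", basename(path))
             else slide_id,
             pix, microns_per_pixel)
}

#' Construct a label mask
#' @param slide_id character scalar.
#' @param pixels integer matrix of class labels (rows = y, 0 background).
#' @param microns_per_pixel micron size of one pixel.
#' @export
label_mask <- function(slide_id, pixels, microns_per_pixel = 0.24) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("mask labels must be non-negative")
  structure(list(slide_id = slide_id, pixels = pixels,
                 microns_per_pixel = microns_per_pixel),
            class = "label_mask")
}

#' Write a label mask to PNG
#' @param mask a `label_mask`.
#' @param path output `.png` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  png::writePNG(mask$pixels / 255, path)
  invisible(path)
}

#' Extract segmented objects from a class-label mask
#'
#' Connected components (8-connectivity) of each class become
#' SegmentedObjects. Area is pixel count times mpp^2; perimeter is a
#' Crofton boundary estimate times mpp; the centroid is the component
#' pixel-center centroid in microns. Per-object elongation (from pixel
#' second moments) and solidity (component pixels over convex-hull
#' pixels) are attached so that downstream morphometrics do not require
#' polygons. Nuclei are assigned a `parent_duct_id` when their centroid
#' pixel lies on a duct component.
#'
#' @param mask a `label_mask` with class encoding 1 = stroma, 2 = duct,
#'   3 = nucleus.
#' @param qc_pass slide-level QC flag to attach.
#' @return a [slide_objects] table; an empty mask yields an empty table.
#' @export
mask_to_objects <- function(mask, qc_pass = TRUE) {
  stopifnot(inherits(mask, "label_mask"))
  mpp <- mask$microns_per_pixel
  pix <- mask$pixels
  rows <- list()
  duct_label <- NULL
  for (cls in c("stroma", "duct", "nucleus")) {
    code <- match(cls, OBJECT_CLASSES)
    lab <- label_components(pix == code)
    if (cls == "duct") duct_label <- lab
    k <- max(lab)
    if (k == 0L) next
    idx <- which(lab > 0L, arr.ind = TRUE)
    comp <- lab[lab > 0L]
    for (i in seq_len(k)) {
      sel <- comp == i
      rr <- idx[sel, 1]; cc <- idx[sel, 2]
      npix <- length(rr)
      # pixel-center coords in um: column -> x, row -> y (0-based + 0.5)
      cx <- (mean(cc) - 0.5) * mpp
      cy <- (mean(rr) - 0.5) * mpp
      sub <- matrix(FALSE, max(rr) - min(rr) + 1L, max(cc) - min(cc) + 1L)
      sub[cbind(rr - min(rr) + 1L, cc - min(cc) + 1L)] <- TRUE
      per <- crofton_perimeter(sub) * mpp
      el <- pixel_elongation(cc, rr)
      sol <- pixel_solidity(cc, rr)
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = sprintf("%s_%d", cls, i), class = cls,
        area = npix * mpp^2, perimeter = per,
        centroid_x = cx, centroid_y = cy,
        elongation = el, solidity = sol,
        parent_duct_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(slide_objects(mask$slide_id,
      data.frame(object_id = character(0), class = character(0),
                 area = numeric(0), perimeter = numeric(0),
                 centroid_x = numeric(0), centroid_y = numeric(0)),
      microns_per_pixel = mpp, qc_pass = qc_pass, validate = FALSE))
  }
  obj <- do.call(rbind, rows)
  # parent assignment: nucleus centroid inside a duct component. In
  # class-encoded masks nuclei overwrite the duct pixels beneath them,
  # so containment is resolved on the union of duct and nucleus pixels
  # and mapped back to the duct component occupying that region.
  if (!is.null(duct_label) && max(duct_label) > 0L) {
    nsel <- obj$class == "nucleus"
    if (any(nsel)) {
      fill_label <- label_components(pix == 2L | pix == 3L)
      fd <- fill_label > 0L & duct_label > 0L
      # fill component -> majority duct component within it
      fill_to_duct <- integer(max(fill_label))
      if (any(fd)) {
        tab <- table(fill_label[fd], duct_label[fd])
        fill_to_duct[as.integer(rownames(tab))] <-
          as.integer(colnames(tab))[apply(tab, 1, which.max)]
      }
      rr <- pmin(pmax(round(obj$centroid_y[nsel] / mpp + 0.5), 1L), nrow(pix))
      cc <- pmin(pmax(round(obj$centroid_x[nsel] / mpp + 0.5), 1L), ncol(pix))
      fl <- fill_label[cbind(rr, cc)]
      dl <- ifelse(fl > 0L, fill_to_duct[pmax(fl, 1L)], 0L)
      obj$parent_duct_id[nsel] <-
        ifelse(dl > 0L, sprintf("duct_%d", dl), NA_character_)
    }
  }
  # class-encoded masks may legitimately carry ducts with no annotated
  # stroma; skip the stroma-presence rule that full object tables obey
  out <- slide_objects(mask$slide_id, obj, microns_per_pixel = mpp,
                       qc_pass = qc_pass, validate = FALSE)
  if (anyDuplicated(obj$object_id))
    stop("duplicated object_id in mask-derived table")
  out
}

# Elongation from pixel-coordinate second moments, with the 1/12
# per-pixel variance term so single rows/columns stay finite.
pixel_elongation <- function(xs, ys) {
  cv <- stats::cov(cbind(xs, ys)) * (length(xs) - 1) / length(xs)
  if (any(!is.finite(cv))) cv <- matrix(0, 2, 2)
  cv <- cv + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

pixel_solidity <- function(xs, ys) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) < 3L) return(1)
  h <- grDevices::chull(pts)
  hull <- pts[h, , drop = FALSE]
  # count lattice points inside the hull of pixel centers
  gx <- seq(min(xs), max(xs)); gy <- seq(min(ys), max(ys))
  grid <- expand.grid(x = gx, y = gy)
  inside <- points_in_polygon(grid$x, grid$y, hull)
  min(1, nrow(pts) / max(sum(inside), nrow(pts)))
}

#' Read pathologist annotations from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon / MultiPolygon
#' features with a `class` property ("DCIS" or "stroma"); coordinates
#' are in microns. MultiPolygons are split into one annotation polygon
#' each; only outer rings are used.
#'
#' @param path GeoJSON file.
#' @param slide_id defaults to the file name.
#' @return object of class `annotation_set`: list with `slide_id`,
#'   `annotator`, and data.frame `polygons` (columns `class`, list
#'   column `polygon`).
#' @export
read_annotations <- function(path, slide_id = NULL) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection"))
    stop("annotation file is not a GeoJSON FeatureCollection")
  cls <- character(0); polys <- list()
  for (fi in seq_along(gj$features)) {
    f <- gj$features[[fi]]
    cl <- f$properties$class
    if (is.null(cl))
      stop("feature ", fi, " is missing the 'class' property")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("unsupported geometry type in feature ", fi, ": ", geom$type))
    for (ring in rings) {
      xy <- do.call(rbind, lapply(ring, function(pt)
        c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
      xy <- close_check(xy)
      if (!poly_is_simple(xy))
        stop("self-intersecting annotation polygon in feature ", fi)
      cls <- c(cls, cl)
      polys[[length(polys) + 1L]] <- xy
    }
  }
  ann <- f_annotator <- NULL
  structure(list(
    slide_id = if (is.null(slide_id)) sub("\\.[^.]*$", "", basename(path))
               else slide_id,
    annotator = if (!is.null(gj$annotator)) gj$annotator else NA_character_,
    polygons = data.frame(class = cls)[, , drop = FALSE] |>
      (\(d) { d$polygon <- polys; d })()
  ), class = "annotation_set")
}

#' Write slide feature vectors to CSV
#'
#' @param features data.frame of slide-level morphometric variables, one
#'   row per slide, keyed by `slide_id` (as produced by
#'   [summarize_slides()]). All slides must share one column set.
#' @param path output CSV.
#' @export
write_feature_table <- function(features, path) {
  features <- as.data.frame(features)
  if (!"slide_id" %in% names(features))
    stop("feature table must contain a slide_id column")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a slide feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data.frame keyed by `slide_id`.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read and validate a patient cohort table
#'
#' Required columns: `patient_id`, `slide_id`, `case_control`
#' ("case"/"control"), `followup_years`, `event_years` (NA when no
#' event), `iibc_status5` (one of `event_0_5`, `event_5_10`,
#' `event_10_15`, `event_gt15`, `no_event`), `grade` (1-3), and binary
#' `er`, `her2`, `cox2`. Consistency between `event_years` and the
#' 5-level status bins is enforced.
#'
#' @param path CSV path, or a data.frame to validate in place.
#' @return validated data.frame with `iibc_status5` as an ordered factor
#'   (earliest event first, `no_event` last).
#' @export
read_cohort_table <- function(path) {
  co <- if (is.data.frame(path)) path
        else utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "slide_id", "case_control", "followup_years",
           "event_years", "iibc_status5", "grade", "er", "her2", "cox2")
  miss <- setdiff(req, names(co))
  if (length(miss))
    stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  lv <- c("event_0_5", "event_5_10", "event_10_15", "event_gt15", "no_event")
  bad <- setdiff(unique(co$iibc_status5), lv)
  if (length(bad))
    stop("unknown iibc_status5 level(s): ", paste(bad, collapse = ", "))
  has_ev <- !is.na(co$event_years)
  if (any(co$event_years[has_ev] > co$followup_years[has_ev] + 1e-9))
    stop("event_years exceeds followup_years for patient(s): ",
         paste(co$patient_id[has_ev][
           co$event_years[has_ev] > co$followup_years[has_ev] + 1e-9],
           collapse = ", "))
  expect <- ifelse(!has_ev, "no_event",
    as.character(cut(co$event_years, c(0, 5, 10, 15, Inf), labels = lv[1:4],
                     right = FALSE)))
  off <- which(expect != co$iibc_status5)
  if (length(off))
    stop("iibc_status5 inconsistent with event_years for patient(s): ",
         paste(co$patient_id[off], collapse = ", "))
  co$iibc_status5 <- factor(co$iibc_status5, levels = lv, ordered = TRUE)
  co
}
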