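# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# Square polygon (counter-clockwise in a y-up frame).
square_poly <- function(x0 = 0, y0 = 0, w = 1, h = w) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# A hand-built slide: one stroma square, ducts as circles with regular
# nucleus grids; fully deterministic and analytically tractable.
toy_slide <- function(duct_radii = c(50, 30), nuclei_per_duct = 9,
                      nucleus_radius = 3, spacing = 12,
                      slide_id = "toy") {
  rows <- list()
  polys <- list()
  side <- 1000
  rows[[1]] <- data.frame(object_id = "stroma_1", class = "stroma",
                          area = side^2, perimeter = 4 * side,
                          centroid_x = side / 2, centroid_y = side / 2,
                          parent_duct_id = NA_character_)
  polys <- list(square_poly(0, 0, side))
  nuc <- 0L
  for (i in seq_along(duct_radii)) {
    r <- duct_radii[i]
    cx <- 150 + (i - 1) * 300; cy <- 200
    poly <- dcismorph:::ellipse_polygon(cx, cy, r, r, 0, 512L)
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = sprintf("duct_%d", i), class = "duct",
      area = dcismorph:::poly_area(poly),
      perimeter = dcismorph:::poly_perimeter(poly),
      centroid_x = cx, centroid_y = cy, parent_duct_id = NA_character_)
    polys <- c(polys, list(poly))
    k <- ceiling(sqrt(nuclei_per_duct))
    g <- expand.grid(gx = seq_len(k), gy = seq_len(k))[
      seq_len(nuclei_per_duct), ]
    for (j in seq_len(nrow(g))) {
      nuc <- nuc + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = sprintf("nucleus_%d", nuc), class = "nucleus",
        area = pi * nucleus_radius^2,
        perimeter = 2 * pi * nucleus_radius,
        centroid_x = cx - spacing + (g$gx[j] - 1) * spacing,
        centroid_y = cy - spacing + (g$gy[j] - 1) * spacing,
        parent_duct_id = sprintf("duct_%d", i))
      polys <- c(polys, list(NULL))
    }
  }
  obj <- do.call(rbind, rows)
  obj$polygon <- polys
  slide_objects(slide_id, obj, microns_per_pixel = 1)
}

# Cohort table derived from an outcome vector (event time or NA).
toy_cohort <- function(event_years, followup_years, slide_ids = NULL,
                       grade = NULL, er = NULL, her2 = NULL, cox2 = NULL) {
  n <- length(followup_years)
  lv <- c("event_0_5", "event_5_10", "event_10_15", "event_gt15",
          "no_event")
  status <- ifelse(is.na(event_years), "no_event",
    as.character(cut(event_years, c(0, 5, 10, 15, Inf), labels = lv[1:4],
                     right = FALSE)))
  read_cohort_table(data.frame(
    patient_id = sprintf("pt_%04d", seq_len(n)),
    slide_id = if (is.null(slide_ids)) sprintf("sl_%04d", seq_len(n))
               else slide_ids,
    case_control = ifelse(is.na(event_years), "control", "case"),
    followup_years = followup_years, event_years = event_years,
    iibc_status5 = status,
    grade = if (is.null(grade)) rep(2L, n) else grade,
    er = if (is.null(er)) rep(1L, n) else er,
    her2 = if (is.null(her2)) rep(0L, n) else her2,
    cox2 = if (is.null(cox2)) rep(0L, n) else cox2,
    stringsAsFactors = FALSE))
}

# Binary-outcome cohort for the classifier: y = 1 means an event well
# before the 5-year horizon, y = 0 a control followed past it.
classifier_cohort <- function(y, slide_ids) {
  toy_cohort(event_years = ifelse(y == 1, 2, NA),
             followup_years = ifelse(y == 1, 2, 10),
             slide_ids = slide_ids)
}

# Feature matrix wrapped as a feature table (slide_id + columns).
as_feature_table <- function(X) {
  data.frame(slide_id = rownames(X), X, check.names = FALSE,
             stringsAsFactors = FALSE)
}
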