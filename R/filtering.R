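# Rule-based True/False QC filtering of segmented objects. Nuclear
# objects are screened on area, perimeter and circular shape factor;
# duct objects on the number of surviving nuclei they contain, nuclear
# density, and the mean minimal nuclear distance within the duct.
# Evaluation order is fixed (nuclei first, then ducts; within each
# class the rules run in the order listed below, and an object is
# attributed to the first rule it fails), so filter reports are
# deterministic.

#' QC filter thresholds
#'
#' The rule structure (which quantities are screened) is fixed; every
#' numeric threshold is tunable here. The shipped defaults are this
#' package's placeholders chosen for typical H&E nuclear and duct
#' geometry -- they are not published cutoffs and should be reviewed
#' against each segmentation platform's error modes.
#'
#' @param nucleus_min_area,nucleus_max_area nuclear area bounds (um^2).
#' @param nucleus_min_perimeter,nucleus_max_perimeter nuclear perimeter
#'   bounds (um).
#' @param nucleus_min_shape_factor minimum circular shape factor
#'   (`4*pi*A/P^2`), in `[0, 1]`.
#' @param duct_min_nuclei minimum surviving nuclei per duct (>= 1).
#' @param duct_min_density,duct_max_density nuclei-per-um^2 bounds.
#' @param duct_max_mean_min_nucl_dist maximum mean nearest-neighbor
#'   nucleus distance within a duct (um).
#' @return object of class `filter_config`.
#' @export
filter_config <- function(nucleus_min_area = 10, nucleus_max_area = 200,
                          nucleus_min_perimeter = 10,
                          nucleus_max_perimeter = 60,
                          nucleus_min_shape_factor = 0.3,
                          duct_min_nuclei = 5L,
                          duct_min_density = 5e-4,
                          duct_max_density = 0.02,
                          duct_max_mean_min_nucl_dist = 30) {
  cfg <- list(nucleus_min_area = nucleus_min_area,
              nucleus_max_area = nucleus_max_area,
              nucleus_min_perimeter = nucleus_min_perimeter,
              nucleus_max_perimeter = nucleus_max_perimeter,
              nucleus_min_shape_factor = nucleus_min_shape_factor,
              duct_min_nuclei = as.integer(duct_min_nuclei),
              duct_min_density = duct_min_density,
              duct_max_density = duct_max_density,
              duct_max_mean_min_nucl_dist = duct_max_mean_min_nucl_dist)
  stopifnot(cfg$nucleus_min_area <= cfg$nucleus_max_area,
            cfg$nucleus_min_perimeter <= cfg$nucleus_max_perimeter,
            cfg$nucleus_min_shape_factor >= 0,
            cfg$nucleus_min_shape_factor <= 1,
            cfg$duct_min_nuclei >= 1L,
            cfg$duct_min_density <= cfg$duct_max_density)
  structure(cfg, class = "filter_config")
}

#' Read a filter configuration from YAML
#' @param path YAML file whose keys are [filter_config()] arguments.
#' @export
read_filter_config <- function(path) {
  do.call(filter_config, yaml::read_yaml(path))
}

#' Circular shape factor
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, decreasing toward 0
#' with boundary irregularity or elongation. Values slightly above 1
#' can occur for rasterized inputs whose perimeter estimate is noisy.
#'
#' @param area area(s), um^2; must be positive.
#' @param perimeter perimeter(s), um; must be positive.
#' @return dimensionless vector.
#' @export
shape_factor <- function(area, perimeter) {
  if (any(!is.finite(area) | area <= 0))
    stop("shape_factor: area must be positive")
  if (any(!is.finite(perimeter) | perimeter <= 0))
    stop("shape_factor: perimeter must be positive")
  4 * pi * area / perimeter^2
}

new_filter_report <- function(slide_id, removed, counts) {
  structure(list(slide_id = slide_id, removed = removed, counts = counts),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s\n", x$slide_id))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' Filter nuclear objects
#'
#' A nucleus survives iff its area and perimeter are inside the
#' configured bounds and its circular shape factor is at least the
#' configured minimum. Ducts and stroma are untouched.
#'
#' @param slide a [slide_objects] table.
#' @param cfg a [filter_config()].
#' @return list with `slide` (filtered) and `report` (a
#'   `filter_report`: removed object ids with the first failing rule,
#'   and per-rule counts).
#' @export
filter_nuclei <- function(slide, cfg = filter_config()) {
  stopifnot(inherits(slide, "slide_objects"), inherits(cfg, "filter_config"))
  o <- slide$objects
  nuc <- o$class == "nucleus"
  rule <- rep(NA_character_, nrow(o))
  sf <- rep(NA_real_, nrow(o))
  sf[nuc] <- shape_factor(o$area[nuc], o$perimeter[nuc])
  rule[nuc & (o$area < cfg$nucleus_min_area |
                o$area > cfg$nucleus_max_area)] <- "area"
  rule[nuc & is.na(rule) & (o$perimeter < cfg$nucleus_min_perimeter |
                o$perimeter > cfg$nucleus_max_perimeter)] <- "perimeter"
  rule[nuc & is.na(rule) & sf < cfg$nucleus_min_shape_factor] <-
    "shape_factor"
  removed <- data.frame(object_id = o$object_id[!is.na(rule)],
                        class = rep("nucleus", sum(!is.na(rule))),
                        rule = rule[!is.na(rule)],
                        stringsAsFactors = FALSE)
  counts <- data.frame(
    class = "nucleus",
    rule = c("area", "perimeter", "shape_factor"),
    n_in = sum(nuc),
    n_removed = c(sum(removed$rule == "area"),
                  sum(removed$rule == "perimeter"),
                  sum(removed$rule == "shape_factor")),
    stringsAsFactors = FALSE)
  list(slide = subset_slide(slide, is.na(rule)),
       report = new_filter_report(slide$slide_id, removed, counts))
}

#' Filter duct objects
#'
#' Applies to a slide whose nuclei have already been screened (see
#' [filter_nuclei()]). A duct survives iff (1) it contains at least
#' `duct_min_nuclei` surviving nuclei, (2) its nuclear density
#' (count / duct area) lies inside the configured bounds, and (3) the
#' mean over its nuclei of the distance to the nearest other nucleus in
#' the same duct is at most `duct_max_mean_min_nucl_dist`. Ducts with
#' fewer than 2 nuclei have no defined nearest-neighbor distance and
#' fail rule (1) first (which requires >= 1 anyway; the default is 5).
#' Nuclei belonging to removed ducts are removed with their duct, as
#' are nuclei with no containing duct (the pipeline measures cells
#' within ducts only).
#'
#' @inheritParams filter_nuclei
#' @return list with `slide` and `report` as in [filter_nuclei()].
#' @export
filter_ducts <- function(slide, cfg = filter_config()) {
  stopifnot(inherits(slide, "slide_objects"), inherits(cfg, "filter_config"))
  o <- slide$objects
  ducts <- which(o$class == "duct")
  nuc <- o$class == "nucleus"
  rule <- rep(NA_character_, length(ducts))
  names(rule) <- o$object_id[ducts]
  nuc_rows <- which(nuc & !is.na(o$parent_duct_id))
  by_parent <- split(nuc_rows, o$parent_duct_id[nuc_rows])
  for (k in seq_along(ducts)) {
    i <- ducts[k]
    id <- o$object_id[i]
    mine <- by_parent[[id]]
    n_n <- length(mine)
    if (n_n < max(cfg$duct_min_nuclei, 2L)) { rule[k] <- "min_nuclei"; next }
    dens <- n_n / o$area[i]
    if (dens < cfg$duct_min_density || dens > cfg$duct_max_density) {
      rule[k] <- "density"; next
    }
    d <- as.matrix(stats::dist(cbind(o$centroid_x[mine],
                                     o$centroid_y[mine])))
    diag(d) <- Inf
    if (mean(apply(d, 1, min)) > cfg$duct_max_mean_min_nucl_dist)
      rule[k] <- "min_nucl_dist"
  }
  bad_ducts <- names(rule)[!is.na(rule)]
  drop <- (o$class == "duct" & o$object_id %in% bad_ducts) |
    (nuc & (is.na(o$parent_duct_id) | o$parent_duct_id %in% bad_ducts))
  removed <- data.frame(
    object_id = o$object_id[drop],
    class = o$class[drop],
    rule = ifelse(o$class[drop] == "duct",
                  rule[match(o$object_id[drop], names(rule))],
                  "parent_duct_removed_or_missing"),
    stringsAsFactors = FALSE)
  counts <- data.frame(
    class = "duct",
    rule = c("min_nuclei", "density", "min_nucl_dist"),
    n_in = length(ducts),
    n_removed = c(sum(rule == "min_nuclei", na.rm = TRUE),
                  sum(rule == "density", na.rm = TRUE),
                  sum(rule == "min_nucl_dist", na.rm = TRUE)),
    stringsAsFactors = FALSE)
  list(slide = subset_slide(slide, !drop),
       report = new_filter_report(slide$slide_id, removed, counts))
}

#' Run the full QC filter (nuclei, then ducts)
#'
#' @inheritParams filter_nuclei
#' @return list with `slide` (filtered) and `report` (combined
#'   `filter_report`).
#' @export
filter_slide <- function(slide, cfg = filter_config()) {
  fn <- filter_nuclei(slide, cfg)
  fd <- filter_ducts(fn$slide, cfg)
  list(slide = fd$slide,
       report = new_filter_report(
         slide$slide_id,
         rbind(fn$report$removed, fd$report$removed),
         rbind(fn$report$counts, fd$report$counts)))
}
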