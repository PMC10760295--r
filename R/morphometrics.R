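# Per-duct morphological measurements and their slide-level
# summarization. Fifteen measurements are computed per surviving duct;
# eight distribution parameters summarize each measurement across the
# ducts of a slide, giving 120 candidate slide variables; redundant
# variables are pruned on pairwise Spearman rank correlation.
#
# The measurement and parameter sets are config-driven: the defaults
# carry the canonical 15 x 8 layout, but both lists can be restricted.

DUCT_MEASUREMENTS <- c(
  "duct_area", "duct_perimeter", "duct_circularity", "duct_elongation",
  "duct_solidity", "equivalent_diameter", "nuclei_count", "nuclei_density",
  "mean_nuclear_area", "sd_nuclear_area", "mean_nuclear_circularity",
  "mean_min_nuclear_distance", "nuclear_area_fraction",
  "nearest_duct_distance", "duct_stroma_ratio")

SUMMARY_PARAMETERS <- c("mean", "median", "sd", "iqr", "skewness",
                        "kurtosis", "sum", "max")

#' Moment-based sample skewness
#'
#' `g1 = m3 / m2^(3/2)` with central moments `m_k = mean((x - mean)^k)`.
#' Degenerate inputs (fewer than 2 values, or zero variance) return 0 by
#' convention so downstream feature matrices stay complete.
#' @param x numeric vector (NAs removed).
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

#' Moment-based sample excess kurtosis
#'
#' `g2 = m4 / m2^2 - 3`; degenerate inputs return 0 by convention.
#' @param x numeric vector (NAs removed).
#' @export
sample_kurtosis <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(0)
  m2 <- mean((x - mean(x))^2)
  if (m2 <= 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Compute the 15 per-duct morphological measurements
#'
#' One row per duct. Shape descriptors come from the duct polygon when
#' present (exact polygon formulas; elongation from the ellipse of
#' inertia of the region's second-order moments, solidity as area over
#' convex-hull area) or from precomputed `elongation`/`solidity`
#' columns for mask-derived objects. Ducts offering neither are dropped
#' with a warning. `nearest_duct_distance` is the centroid distance to
#' the nearest other duct (`NA` on single-duct slides; see
#' [summarize_slide()] for the missing-data policy), and
#' `duct_stroma_ratio` is duct area over the slide's total stroma area.
#'
#' @param slide a QC-filtered [slide_objects] table.
#' @return data.frame of class `duct_measurements` with `duct_id` plus
#'   the 15 measurement columns; attribute `slide_id`.
#' @export
measure_ducts <- function(slide) {
  stopifnot(inherits(slide, "slide_objects"))
  o <- slide$objects
  ducts <- which(o$class == "duct")
  stroma_area <- sum(o$area[o$class == "stroma"])
  if (!length(ducts)) {
    out <- as.data.frame(matrix(numeric(0), 0, 16,
      dimnames = list(NULL, c("duct_id", DUCT_MEASUREMENTS))))
    attr(out, "slide_id") <- slide$slide_id
    class(out) <- c("duct_measurements", "data.frame")
    return(out)
  }
  nuc_rows <- which(o$class == "nucleus" & !is.na(o$parent_duct_id))
  by_parent <- split(nuc_rows, o$parent_duct_id[nuc_rows])

  n <- length(ducts)
  m <- matrix(NA_real_, n, length(DUCT_MEASUREMENTS),
              dimnames = list(NULL, DUCT_MEASUREMENTS))
  keep <- rep(TRUE, n)
  for (k in seq_len(n)) {
    i <- ducts[k]
    A <- o$area[i]; P <- o$perimeter[i]
    poly <- o$polygon[[i]]
    if (!is.null(poly)) {
      elong <- poly_elongation(poly)
      solid <- poly_solidity(poly)
    } else if (all(c("elongation", "solidity") %in% names(o)) &&
               is.finite(o$elongation[i]) && is.finite(o$solidity[i])) {
      elong <- o$elongation[i]
      solid <- o$solidity[i]
    } else {
      keep[k] <- FALSE
      next
    }
    mine <- by_parent[[o$object_id[i]]]
    n_nuc <- length(mine)
    if (n_nuc >= 2L) {
      d <- as.matrix(stats::dist(cbind(o$centroid_x[mine],
                                       o$centroid_y[mine])))
      diag(d) <- Inf
      mmnd <- mean(apply(d, 1, min))
    } else mmnd <- 0
    m[k, ] <- c(
      duct_area = A,
      duct_perimeter = P,
      duct_circularity = 4 * pi * A / P^2,
      duct_elongation = elong,
      duct_solidity = solid,
      equivalent_diameter = sqrt(4 * A / pi),
      nuclei_count = n_nuc,
      nuclei_density = n_nuc / A,
      mean_nuclear_area = if (n_nuc) mean(o$area[mine]) else 0,
      sd_nuclear_area = if (n_nuc > 1) stats::sd(o$area[mine]) else 0,
      mean_nuclear_circularity =
        if (n_nuc) mean(shape_factor(o$area[mine], o$perimeter[mine]))
        else 0,
      mean_min_nuclear_distance = mmnd,
      nuclear_area_fraction = if (n_nuc) sum(o$area[mine]) / A else 0,
      nearest_duct_distance = NA_real_,  # filled below
      duct_stroma_ratio = A / stroma_area)
  }
  if (any(!keep))
    warning(sum(!keep), " duct(s) lacked polygons and shape fields; dropped")
  dc <- cbind(o$centroid_x[ducts], o$centroid_y[ducts])
  if (n >= 2L) {
    dd <- as.matrix(stats::dist(dc))
    diag(dd) <- Inf
    m[, "nearest_duct_distance"] <- apply(dd, 1, min)
  }
  out <- data.frame(duct_id = o$object_id[ducts][keep],
                    m[keep, , drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "slide_id") <- slide$slide_id
  class(out) <- c("duct_measurements", "data.frame")
  out
}

#' Summarize per-duct measurements into slide-level variables
#'
#' For each measurement column, computes the 8 distribution parameters
#' mean, median, sd, iqr (type-7 quantiles), skewness, kurtosis
#' (excess), sum and max, named `<measurement>__<parameter>`; with the
#' full default sets this yields 120 variables plus `n_ducts`.
#'
#' Degenerate-case conventions: on single-duct slides sd and iqr are 0
#' and skewness/kurtosis are 0; summaries ignore missing measurement
#' values (only `nearest_duct_distance` can be missing, on single-duct
#' slides) and an all-missing column summarizes to 0 with a warning.
#'
#' @param measurements a [measure_ducts()] table with >= 1 duct.
#' @param measurement_set,parameter_set subsets to compute (defaults:
#'   all 15 and all 8).
#' @return one-row data.frame: `slide_id`, the summary variables, and
#'   `n_ducts`.
#' @export
summarize_slide <- function(measurements,
                            measurement_set = DUCT_MEASUREMENTS,
                            parameter_set = SUMMARY_PARAMETERS) {
  stopifnot(inherits(measurements, "duct_measurements") ||
              is.data.frame(measurements))
  if (nrow(measurements) == 0L)
    stop("no ducts survive filtering; cannot summarize slide")
  funs <- list(
    mean = function(x) mean(x),
    median = function(x) stats::median(x),
    sd = function(x) if (length(x) > 1) stats::sd(x) else 0,
    iqr = function(x) if (length(x) > 1) stats::IQR(x, type = 7) else 0,
    skewness = sample_skewness,
    kurtosis = sample_kurtosis,
    sum = function(x) sum(x),
    max = function(x) max(x))
  bad <- setdiff(parameter_set, names(funs))
  if (length(bad)) stop("unknown summary parameter(s): ",
                        paste(bad, collapse = ", "))
  miss <- setdiff(measurement_set, names(measurements))
  if (length(miss)) stop("measurement column(s) absent: ",
                         paste(miss, collapse = ", "))
  vals <- list()
  for (mm in measurement_set) {
    x <- measurements[[mm]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      # single-duct slides have no nearest_duct_distance; other columns
      # should never be all-missing
      if (mm != "nearest_duct_distance")
        warning("all values missing for ", mm, "; summaries set to 0")
      x <- 0
    }
    for (pp in parameter_set)
      vals[[paste0(mm, "__", pp)]] <- funs[[pp]](x)
  }
  out <- data.frame(slide_id = attr(measurements, "slide_id") %||% NA,
                    vals, n_ducts = nrow(measurements),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure and summarize a collection of slides
#'
#' Convenience wrapper: [measure_ducts()] then [summarize_slide()] per
#' slide, row-bound into one feature table.
#'
#' @param slides list of filtered [slide_objects].
#' @param ... passed to [summarize_slide()].
#' @return data.frame, one row per slide.
#' @export
summarize_slides <- function(slides, ...) {
  do.call(rbind, lapply(slides, function(s)
    summarize_slide(measure_ducts(s), ...)))
}

#' Named aliases of the headline slide variables
#'
#' `total_dcis_area` is the per-slide sum of duct areas
#' (`duct_area__sum`); `total_dcis_cells` the sum of per-duct nuclei
#' counts (`nuclei_count__sum`); `total_duct_stroma_ratio` the summed
#' per-duct duct/stroma ratio, i.e. the slide's lesion burden relative
#' to its stroma.
#'
#' @param features feature table from [summarize_slides()].
#' @return data.frame with `slide_id` and the three aliases.
#' @export
headline_variables <- function(features) {
  data.frame(slide_id = features$slide_id,
             total_dcis_area = features[["duct_area__sum"]],
             total_dcis_cells = features[["nuclei_count__sum"]],
             total_duct_stroma_ratio = features[["duct_stroma_ratio__sum"]],
             stringsAsFactors = FALSE)
}

#' Prune redundant slide variables by Spearman correlation
#'
#' Computes pairwise Spearman rank correlations across slides and
#' greedily resolves every pair with `|rho|` above the threshold:
#' at each step the currently most-correlated pair is examined and the
#' member with the larger mean `|rho|` to all other retained variables
#' is removed (ties broken by column order: the later column goes).
#' Terminates when no retained pair exceeds the threshold.
#'
#' @param features feature table from [summarize_slides()] (>= 3
#'   slides).
#' @param threshold pruning threshold on `|rho|`, in (0, 1); default
#'   0.90.
#' @return object of class `pruned_features`: list with `retained`
#'   (variable names), `trace` (data.frame: removed variable, the kept
#'   partner, their `|rho|`), and `cor_matrix` (Spearman, all candidate
#'   variables).
#' @export
prune_redundant <- function(features, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  X <- feature_matrix(features)
  if (nrow(X) < 3L)
    stop("need at least 3 slides for rank-correlation pruning")
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[!is.finite(rho)] <- 0  # zero-variance columns never exceed threshold
  keep <- colnames(X)
  trace <- data.frame(removed = character(0), kept = character(0),
                      abs_rho = numeric(0), stringsAsFactors = FALSE)
  repeat {
    r <- abs(rho[keep, keep, drop = FALSE])
    diag(r) <- 0
    if (!length(r) || max(r) <= threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    mean_abs <- rowMeans(abs(rho[pair, keep, drop = FALSE])) -
      1 / length(keep)  # exclude self-correlation contribution
    drop_var <- if (mean_abs[1] > mean_abs[2]) pair[1]
      else if (mean_abs[2] > mean_abs[1]) pair[2]
      else pair[which.max(match(pair, colnames(X)))]
    trace <- rbind(trace, data.frame(
      removed = drop_var, kept = setdiff(pair, drop_var),
      abs_rho = max(r), stringsAsFactors = FALSE))
    keep <- setdiff(keep, drop_var)
  }
  structure(list(retained = keep, trace = trace, cor_matrix = rho,
                 threshold = threshold),
            class = "pruned_features")
}

#' @export
print.pruned_features <- function(x, ...) {
  cat(sprintf(
    "<pruned_features> %d retained of %d (|rho| threshold %.2f, %d removed)\n",
    length(x$retained), ncol(x$cor_matrix), x$threshold, nrow(x$trace)))
  invisible(x)
}

# Numeric feature columns of a feature table (drops slide_id/n_ducts).
feature_matrix <- function(features) {
  drop <- c("slide_id", "n_ducts")
  X <- as.matrix(features[, setdiff(names(features), drop), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Correlation structure of the retained variables
#'
#' Fraction of off-diagonal retained pairs whose Spearman rho lies in
#' the open interval (-0.5, 0.5) -- a weak-correlation summary of the
#' pruned set. With fewer than 2 retained variables the fraction is
#' reported as 1 with a warning.
#'
#' @param features feature table.
#' @param pruned a [prune_redundant()] result.
#' @return list: `fraction_weak`, `n_pairs`, `retained`.
#' @export
correlation_heatmap_stats <- function(features, pruned) {
  stopifnot(inherits(pruned, "pruned_features"))
  keep <- pruned$retained
  if (length(keep) < 2L) {
    warning("fewer than 2 retained variables; weak-correlation fraction ",
            "reported as 1")
    return(list(fraction_weak = 1, n_pairs = 0L, retained = keep))
  }
  X <- feature_matrix(features)[, keep, drop = FALSE]
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[!is.finite(rho)] <- 0  # zero-variance columns: undefined -> weak
  off <- rho[upper.tri(rho)]
  list(fraction_weak = mean(off > -0.5 & off < 0.5),
       n_pairs = length(off), retained = keep)
}
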