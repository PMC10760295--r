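# Synthetic slide and cohort generator. Slides are built from the same
# geometric vocabulary the analysis assumes: a stroma region containing
# non-overlapping elliptical DCIS ducts, each filled with circular
# nuclei placed by a hard-core point process. Cohorts attach
# proportional-hazards outcome times whose log-hazard is a linear
# function of named slide-level morphometric summaries, so parameter
# recovery by the downstream survival stage is a testable property.
#
# Randomness: R's default Mersenne-Twister generator with inversion
# normals, seeded explicitly via the `seed` field; identical parameters
# and seed give identical output on every platform.

#' Parameters for one synthetic slide
#'
#' Defaults emulate the duct-count and size regime of screen-detected
#' DCIS series: duct counts per slide follow a truncated negative
#' binomial with median about 36 and a right tail reaching several
#' hundred (range capped at 1-700); duct areas are lognormal with median
#' about 8000 um^2 (about a 100 um diameter duct); nuclei are circles of
#' mean radius 4 um placed at about 5e-3 nuclei per um^2 with an 8 um
#' hard-core spacing. Per-duct area/density distributions are this
#' generator's modeling choice, not published values.
#'
#' @param n_ducts duct count; `NA` draws from the negative-binomial
#'   default (size `nb_size`, mean `nb_mu`, truncated to
#'   `[1, nb_max]`).
#' @param duct_area_log_mean,duct_area_log_sd lognormal parameters of
#'   duct area (um^2 scale; log-mean is log of the median area).
#' @param duct_elongation_range major/minor axis ratio range (uniform).
#' @param nuclear_density_mean expected nuclei per um^2 of duct area.
#' @param nucleus_radius_mean,nucleus_radius_sd nucleus radius (um),
#'   normal truncated to `[2, 8]`.
#' @param hardcore_spacing minimum nucleus center-to-center distance
#'   (um) within a duct.
#' @param stroma_area stroma region area in um^2; `NA` sizes a square
#'   stroma to 8x the expected total duct area (placement headroom).
#' @param boundary_noise relative radial roughening of duct outlines
#'   (0 = exact ellipses).
#' @param n_vertices vertices per duct polygon.
#' @param nb_size,nb_mu,nb_max negative-binomial duct-count defaults.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return object of class `slide_sim_params`.
#' @export
slide_sim_params <- function(n_ducts = NA, duct_area_log_mean = log(8000),
                             duct_area_log_sd = 0.9,
                             duct_elongation_range = c(1, 3),
                             nuclear_density_mean = 5e-3,
                             nucleus_radius_mean = 4,
                             nucleus_radius_sd = 0.5,
                             hardcore_spacing = 8,
                             stroma_area = NA,
                             boundary_noise = 0,
                             n_vertices = 256L,
                             nb_size = 0.9, nb_mu = 55, nb_max = 700L,
                             seed = NULL) {
  p <- list(n_ducts = n_ducts, duct_area_log_mean = duct_area_log_mean,
            duct_area_log_sd = duct_area_log_sd,
            duct_elongation_range = duct_elongation_range,
            nuclear_density_mean = nuclear_density_mean,
            nucleus_radius_mean = nucleus_radius_mean,
            nucleus_radius_sd = nucleus_radius_sd,
            hardcore_spacing = hardcore_spacing,
            stroma_area = stroma_area, boundary_noise = boundary_noise,
            n_vertices = as.integer(n_vertices),
            nb_size = nb_size, nb_mu = nb_mu, nb_max = as.integer(nb_max),
            seed = seed)
  stopifnot(is.na(p$n_ducts) || p$n_ducts >= 0,
            p$duct_area_log_sd >= 0, p$nuclear_density_mean > 0,
            p$nucleus_radius_mean > 0, p$hardcore_spacing >= 0,
            length(p$duct_elongation_range) == 2L,
            p$duct_elongation_range[1] >= 1,
            diff(p$duct_elongation_range) >= 0,
            is.na(p$stroma_area) || p$stroma_area > 0)
  structure(p, class = "slide_sim_params")
}

#' Draw duct counts from the default slide distribution
#'
#' Negative binomial truncated to `[1, nb_max]`; the shipped size/mean
#' give a median of about 36 ducts per slide with a tail past 600.
#'
#' @param n number of draws.
#' @param params a [slide_sim_params()] (for nb_size/nb_mu/nb_max).
#' @return integer vector.
#' @export
sample_duct_count <- function(n, params = slide_sim_params()) {
  x <- stats::rnbinom(n, size = params$nb_size, mu = params$nb_mu)
  pmax(1L, pmin(as.integer(x), params$nb_max))
}

#' Simulate one slide
#'
#' Places `n_ducts` randomly oriented elliptical ducts without overlap
#' inside a square stroma region, then fills each duct with circular
#' nuclei by hard-core dart throwing at the duct's Poisson-sampled
#' target count. Every nucleus centroid is inside its parent duct
#' polygon and all nucleus centers within a duct respect the hard-core
#' spacing. Identical parameters and seed reproduce the slide exactly.
#'
#' @param params a [slide_sim_params()].
#' @param slide_id identifier for the generated slide.
#' @return a [slide_objects] table (microns; polygons attached).
#' @export
simulate_slide <- function(params = slide_sim_params(),
                           slide_id = "synthetic_slide") {
  stopifnot(inherits(params, "slide_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n_ducts <- params$n_ducts
  if (is.na(n_ducts)) n_ducts <- sample_duct_count(1L, params)
  n_ducts <- as.integer(n_ducts)

  areas <- if (n_ducts > 0)
    stats::rlnorm(n_ducts, params$duct_area_log_mean, params$duct_area_log_sd)
  else numeric(0)
  elong <- stats::runif(n_ducts, params$duct_elongation_range[1],
                        params$duct_elongation_range[2])
  a_ax <- sqrt(areas * elong / pi)   # semi-major
  b_ax <- sqrt(areas / (pi * elong)) # semi-minor
  theta <- stats::runif(n_ducts, 0, pi)

  stroma_area <- params$stroma_area
  if (is.na(stroma_area))
    stroma_area <- max(8 * sum(areas), 1e5)
  side <- sqrt(stroma_area)
  stroma_poly <- cbind(c(0, side, side, 0), c(0, 0, side, side))

  # duct placement: dart throwing on centers; non-overlap guaranteed
  # conservatively through bounding circles (semi-major axes)
  ord <- order(a_ax, decreasing = TRUE)  # large ducts first pack better
  cx <- cy <- numeric(n_ducts)
  for (i in ord) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      x <- stats::runif(1, a_ax[i], side - a_ax[i])
      y <- stats::runif(1, a_ax[i], side - a_ax[i])
      prev <- ord[seq_len(match(i, ord) - 1L)]
      if (!length(prev) ||
          all((x - cx[prev])^2 + (y - cy[prev])^2 >
                (a_ax[i] + a_ax[prev])^2)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n_ducts, " ducts without overlap; ",
           "increase stroma_area")
  }

  rows <- vector("list", 1L + 2L * n_ducts)
  polys <- vector("list", 1L + 2L * n_ducts)
  rows[[1]] <- data.frame(object_id = "stroma_1", class = "stroma",
                          area = poly_area(stroma_poly),
                          perimeter = poly_perimeter(stroma_poly),
                          centroid_x = side / 2, centroid_y = side / 2,
                          parent_duct_id = NA_character_,
                          stringsAsFactors = FALSE)
  polys[[1]] <- list(stroma_poly)

  nuc_idx <- 0L
  for (i in seq_len(n_ducts)) {
    poly <- ellipse_polygon(cx[i], cy[i], a_ax[i], b_ax[i], theta[i],
                            params$n_vertices)
    if (params$boundary_noise > 0) {
      r <- 1 + stats::rnorm(nrow(poly), 0, params$boundary_noise)
      r <- pmax(r, 0.5)
      ctr <- c(cx[i], cy[i])
      poly <- sweep(sweep(poly, 2, ctr) * r, 2, ctr, `+`)
    }
    A <- poly_area(poly)
    ctr <- poly_centroid(poly)
    duct_id <- sprintf("duct_%d", i)
    rows[[2 * i]] <- data.frame(object_id = duct_id, class = "duct",
                                area = A, perimeter = poly_perimeter(poly),
                                centroid_x = ctr[1], centroid_y = ctr[2],
                                parent_duct_id = NA_character_,
                                stringsAsFactors = FALSE)
    polys[[2 * i]] <- list(poly)

    # nuclei: hard-core dart throwing inside the duct polygon
    k_target <- stats::rpois(1, params$nuclear_density_mean * A)
    if (k_target > 0) {
      pts <- hardcore_in_ellipse(k_target, cx[i], cy[i], a_ax[i], b_ax[i],
                                 theta[i], params$hardcore_spacing, poly)
      k <- nrow(pts)
      if (k > 0) {
        rad <- pmin(pmax(stats::rnorm(k, params$nucleus_radius_mean,
                                      params$nucleus_radius_sd), 2), 8)
        rows[[2 * i + 1L]] <- data.frame(
          object_id = sprintf("nucleus_%d", nuc_idx + seq_len(k)),
          class = "nucleus",
          area = pi * rad^2, perimeter = 2 * pi * rad,
          centroid_x = pts[, 1], centroid_y = pts[, 2],
          parent_duct_id = duct_id, stringsAsFactors = FALSE)
        polys[[2 * i + 1L]] <- replicate(k, NULL, simplify = FALSE)
        nuc_idx <- nuc_idx + k
      }
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  obj <- do.call(rbind, rows[keep])
  obj$polygon <- do.call(c, polys[keep])
  slide_objects(slide_id, obj, microns_per_pixel = 1, qc_pass = TRUE)
}

# Hard-core dart throwing of up to k points inside an ellipse (and
# strictly inside its polygon discretization). Candidate darts are
# proposed in vectorized batches; acceptance is greedy in proposal
# order, which preserves seed determinism. Saturation simply yields
# fewer points; callers treat the realized count as the truth.
hardcore_in_ellipse <- function(k, cx, cy, a, b, theta, spacing, poly) {
  ct <- cos(theta); st <- sin(theta)
  margin <- 0.98  # keep centers off the polygonized boundary
  px <- py <- numeric(0)
  sp2 <- spacing^2
  batches <- 0L
  while (length(px) < k && batches < 8L) {
    batches <- batches + 1L
    m <- max(4L * (k - length(px)), 32L)
    u <- sqrt(stats::runif(m)) * margin
    phi <- stats::runif(m, 0, 2 * pi)
    x0 <- a * u * cos(phi); y0 <- b * u * sin(phi)
    x <- cx + x0 * ct - y0 * st
    y <- cy + x0 * st + y0 * ct
    ok <- points_in_polygon(x, y, poly)
    x <- x[ok]; y <- y[ok]
    for (j in seq_along(x)) {
      if (length(px) >= k) break
      if (length(px) && any((x[j] - px)^2 + (y[j] - py)^2 < sp2)) next
      px <- c(px, x[j]); py <- c(py, y[j])
    }
  }
  cbind(px, py)
}

#' Render a synthetic slide to a class-label mask
#'
#' Rasterizes the slide's polygons (and nucleus circles) onto a pixel
#' grid with the class encoding used by [mask_to_objects()] (1 stroma,
#' 2 duct, 3 nucleus). Later classes overwrite earlier ones, so nuclei
#' sit on top of their ducts, ducts on top of stroma.
#'
#' @param slide a [slide_objects] table with polygons.
#' @param microns_per_pixel pixel size of the rendered mask.
#' @param classes which classes to render.
#' @return a `label_mask`.
#' @export
render_mask <- function(slide, microns_per_pixel = 2,
                        classes = c("stroma", "duct", "nucleus")) {
  stopifnot(inherits(slide, "slide_objects"))
  o <- slide$objects
  mpp <- microns_per_pixel
  xmax <- max(o$centroid_x, vapply(o$polygon, function(p)
    if (is.null(p)) -Inf else max(p[, 1]), numeric(1)))
  ymax <- max(o$centroid_y, vapply(o$polygon, function(p)
    if (is.null(p)) -Inf else max(p[, 2]), numeric(1)))
  nc <- ceiling(xmax / mpp) + 2L
  nr <- ceiling(ymax / mpp) + 2L
  pix <- matrix(0L, nr, nc)
  fill <- function(poly, code) {
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    cs <- max(1L, floor(xr[1] / mpp)):min(nc, ceiling(xr[2] / mpp) + 1L)
    rs <- max(1L, floor(yr[1] / mpp)):min(nr, ceiling(yr[2] / mpp) + 1L)
    g <- expand.grid(r = rs, c = cs)
    inside <- points_in_polygon((g$c - 0.5) * mpp, (g$r - 0.5) * mpp, poly)
    pix[cbind(g$r[inside], g$c[inside])] <<- code
  }
  for (cls in intersect(c("stroma", "duct", "nucleus"), classes)) {
    code <- match(cls, OBJECT_CLASSES)
    for (i in which(o$class == cls)) {
      poly <- o$polygon[[i]]
      if (is.null(poly) && cls == "nucleus") {
        r <- o$perimeter[i] / (2 * pi)
        poly <- ellipse_polygon(o$centroid_x[i], o$centroid_y[i], r, r,
                                0, 32L)
      }
      if (!is.null(poly)) fill(poly, code)
    }
  }
  label_mask(slide$slide_id, pix, mpp)
}

#' Parameters for a synthetic cohort
#'
#' Patients draw a slide archetype (a [slide_sim_params()] template),
#' a slide, and an event time from a Weibull proportional-hazards model
#' whose log-hazard is linear in named, cohort-standardized slide
#' summaries. Supported summary names: `log_total_duct_area`,
#' `total_nuclei`, `duct_stroma_ratio`, `n_ducts`, `mean_duct_area`.
#' Censoring is uniform on `censoring_years_range`.
#'
#' @param n_patients cohort size.
#' @param archetypes named list of [slide_sim_params()] templates.
#' @param archetype_mixture mixture weights (same length, sums to 1).
#' @param risk_coefficients named numeric vector of log-hazard effects
#'   per SD of each named summary.
#' @param baseline_shape,baseline_scale Weibull baseline hazard in
#'   years (shape 1 = exponential; the default scale puts roughly a
#'   third of patients at an observed event under default censoring).
#' @param censoring_years_range uniform censoring window `[lo, hi]`.
#' @param seed integer seed.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 100L,
                              archetypes = list(base = slide_sim_params()),
                              archetype_mixture = NULL,
                              risk_coefficients =
                                c(log_total_duct_area = 0.35,
                                  total_nuclei = 0.25,
                                  duct_stroma_ratio = 0.2),
                              baseline_shape = 1.2, baseline_scale = 25,
                              censoring_years_range = c(5, 20),
                              seed = NULL) {
  risk_coefficients <- unlist(risk_coefficients)  # tolerate YAML maps
  if (is.null(archetype_mixture))
    archetype_mixture <- rep(1 / length(archetypes), length(archetypes))
  archetype_mixture <- unlist(archetype_mixture)
  censoring_years_range <- unlist(censoring_years_range)
  stopifnot(n_patients >= 1, length(archetypes) >= 1,
            length(archetype_mixture) == length(archetypes),
            abs(sum(archetype_mixture) - 1) < 1e-8,
            baseline_shape > 0, baseline_scale > 0,
            length(censoring_years_range) == 2L,
            censoring_years_range[1] <= censoring_years_range[2])
  known <- c("log_total_duct_area", "total_nuclei", "duct_stroma_ratio",
             "n_ducts", "mean_duct_area")
  bad <- setdiff(names(risk_coefficients), known)
  if (length(bad))
    stop("risk_coefficients name unknown summaries: ",
         paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  structure(list(n_patients = as.integer(n_patients),
                 archetypes = archetypes,
                 archetype_mixture = archetype_mixture,
                 risk_coefficients = risk_coefficients,
                 baseline_shape = baseline_shape,
                 baseline_scale = baseline_scale,
                 censoring_years_range = censoring_years_range,
                 seed = seed),
            class = "cohort_sim_params")
}

# Slide-level summaries the risk model can reference.
risk_summaries <- function(slide) {
  o <- slide$objects
  d <- o$class == "duct"
  stroma <- sum(o$area[o$class == "stroma"])
  tot <- sum(o$area[d])
  c(log_total_duct_area = log(max(tot, 1)),
    total_nuclei = sum(o$class == "nucleus"),
    duct_stroma_ratio = tot / max(stroma, 1e-12),
    n_ducts = sum(d),
    mean_duct_area = if (any(d)) mean(o$area[d]) else 0)
}

#' Simulate a cohort of slides with linked survival outcomes
#'
#' @param params a [cohort_sim_params()].
#' @return list with `slides` (named list of [slide_objects]), `cohort`
#'   (validated cohort data.frame), and `archetype` (the archetype each
#'   patient drew).
#' @details Event time T follows a Weibull PH model:
#'   `T = scale * (-log(U) / exp(risk))^(1/shape)` with
#'   `risk = sum(coef * z)` over the cohort-standardized summaries.
#'   The observed follow-up is `min(T, C)` with uniform censoring C;
#'   `case_control` is "case" iff the event is observed, and the
#'   5-level status bins observed event times at 5/10/15 years.
#'   Clinicopathological covariates (grade 1-3, binary ER/HER2/COX-2)
#'   are drawn independently of morphometry, so their null behavior in
#'   multivariate models is known.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_patients
  arch <- sample(names(params$archetypes), n, replace = TRUE,
                 prob = params$archetype_mixture)
  slide_seeds <- sample.int(.Machine$integer.max - 1L, n)
  slides <- vector("list", n)
  summaries <- matrix(0, n, 5,
    dimnames = list(NULL, c("log_total_duct_area", "total_nuclei",
                            "duct_stroma_ratio", "n_ducts",
                            "mean_duct_area")))
  for (i in seq_len(n)) {
    p <- params$archetypes[[arch[i]]]
    p$seed <- slide_seeds[i]
    slides[[i]] <- simulate_slide(p, slide_id = sprintf("slide_%03d", i))
    summaries[i, ] <- risk_summaries(slides[[i]])
  }
  names(slides) <- vapply(slides, `[[`, "", "slide_id")

  z <- scale(summaries)
  z[, apply(summaries, 2, stats::sd) == 0] <- 0
  coefs <- params$risk_coefficients
  risk <- if (length(coefs))
    as.numeric(z[, names(coefs), drop = FALSE] %*% coefs)
  else rep(0, n)

  u <- stats::runif(n)
  t_event <- params$baseline_scale *
    (-log(u) / exp(risk))^(1 / params$baseline_shape)
  cens <- stats::runif(n, params$censoring_years_range[1],
                       params$censoring_years_range[2])
  event <- t_event <= cens
  followup <- pmin(t_event, cens)
  lv <- c("event_0_5", "event_5_10", "event_10_15", "event_gt15", "no_event")
  status <- ifelse(!event, "no_event",
    as.character(cut(t_event, c(0, 5, 10, 15, Inf), labels = lv[1:4],
                     right = FALSE)))
  cohort <- data.frame(
    patient_id = sprintf("pt_%03d", seq_len(n)),
    slide_id = names(slides),
    case_control = ifelse(event, "case", "control"),
    followup_years = followup,
    event_years = ifelse(event, t_event, NA_real_),
    iibc_status5 = status,
    grade = sample(1:3, n, replace = TRUE, prob = c(0.25, 0.45, 0.3)),
    er = stats::rbinom(n, 1, 0.75),
    her2 = stats::rbinom(n, 1, 0.25),
    cox2 = stats::rbinom(n, 1, 0.4),
    stringsAsFactors = FALSE)
  cohort <- read_cohort_table(cohort)
  list(slides = slides, cohort = cohort, archetype = arch)
}

#' Read simulation parameters from a YAML config
#'
#' Every [slide_sim_params()] / [cohort_sim_params()] field can be set;
#' unspecified fields take the documented defaults. A `cohort:` block
#' defines the cohort layer with an `archetypes:` map of slide blocks.
#'
#' @param path YAML file.
#' @return `slide_sim_params` or `cohort_sim_params` depending on
#'   whether a `cohort:` block is present.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  slide_from <- function(lst) do.call(slide_sim_params, lst)
  if (!is.null(cfg$cohort)) {
    cc <- cfg$cohort
    arch <- lapply(cc$archetypes, slide_from)
    do.call(cohort_sim_params, c(
      list(archetypes = arch),
      cc[setdiff(names(cc), c("archetypes"))]))
  } else {
    slide_from(cfg)
  }
}
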