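#' Default superior sagittal sinus seed points
#'
#' The rostral and caudal measurement sites in stereotaxic bregma offsets
#' (mm): rostral (0.00, -1.07, -0.22), caudal (0.00, -0.53, -5.55).
#'
#' @return Tibble with columns `location`, `RL`, `VD`, `RC`.
#' @export
default_sss_seeds <- function() {
  tibble(location = c("rostral", "caudal"),
         RL = c(0, 0), VD = c(-1.07, -0.53), RC = c(-0.22, -5.55))
}

# deterministic quasi-uniform directions on the unit sphere
# (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# gradient-magnitude volume by central differences (mm^-1 scaled),
# replicated edges
gradient_magnitude <- function(v) {
  sp <- voxel_spacing(v)
  a <- v$data
  d <- dim(a)
  g2 <- array(0, dim = d)
  for (axis in 1:3) {
    ip <- pmin(slice.index(a, axis) + 1, d[axis])
    im <- pmax(slice.index(a, axis) - 1, 1)
    idx <- arrayInd(seq_along(a), d)
    hi <- idx; hi[, axis] <- ip
    lo <- idx; lo[, axis] <- im
    diffa <- (a[hi] - a[lo]) / ((ip - im) * sp[axis])
    g2 <- g2 + array(diffa, dim = d)^2
  }
  volume_image(sqrt(g2), v$affine, "OTHER")
}

#' Sphere-growing estimate of vessel caliber
#'
#' Grows a sphere from a seed point inside the vessel lumen until the mean
#' image gradient magnitude over the sphere surface reaches its first local
#' maximum, which marks the vessel boundary; the sphere's physical diameter
#' estimates the vessel diameter. The gradient is computed by central
#' differences on the image grid and sampled trilinearly at quasi-uniform
#' points on each sphere; the radius profile is lightly smoothed (3-point
#' moving average) before the first strict local maximum is selected, with
#' ties broken toward smaller radii. If no interior local maximum exists
#' the global argmax is returned with `converged = FALSE`.
#'
#' @param image A [volume_image()] (typically a contrast difference image
#'   in atlas space).
#' @param seed Seed location as a bregma offset `c(RL, VD, RC)` in mm.
#' @param frame A [bregma_frame()].
#' @param r_min Smallest radius (mm); default one voxel.
#' @param r_max Largest radius (mm).
#' @param step Radius increment (mm); default a quarter of the smallest
#'   voxel spacing.
#' @param n_points Surface sample points per sphere (>= 200 recommended).
#' @param profile_smoothing Moving-average window (odd; 1 disables).
#' @return An object of class `diameter_measurement`: list with `diameter`
#'   (mm), `converged`, `seed_offset`, and `radius_profile` (tibble of
#'   radius vs mean surface gradient).
#' @export
sphere_grow_diameter <- function(image, seed, frame,
                                 r_min = NULL, r_max = 2,
                                 step = NULL, n_points = 300L,
                                 profile_smoothing = 3L) {
  stopifnot(inherits(image, "volume_image"), inherits(frame, "bregma_frame"))
  sp <- voxel_spacing(image)
  if (is.null(r_min)) r_min <- min(sp)
  if (is.null(step)) step <- 0.25 * min(sp)
  stopifnot(r_max > r_min, r_min > 0, step > 0)
  seed_world <- bregma_offset_to_world(seed, frame)
  seed_vox <- world_to_voxel(image$affine, seed_world)
  d <- dim(image$data)
  if (any(seed_vox < 0) || any(seed_vox > d - 1))
    stop("seed lies outside the image", call. = FALSE)
  gmag <- gradient_magnitude(image)
  dirs <- fibonacci_sphere(n_points)
  radii <- seq(r_min, r_max, by = step)
  prof <- vapply(radii, function(r) {
    pts_world <- sweep(dirs * r, 2, seed_world, "+")
    vox <- world_to_voxel(image$affine, pts_world)
    mean(cpp_sample_trilinear(gmag$data, vox), na.rm = TRUE)
  }, 0)
  smoothed <- smooth_profile(prof, profile_smoothing)
  sel <- first_local_max(smoothed)
  converged <- !is.na(sel)
  if (!converged) {
    if (all(!is.finite(smoothed)) || diff(range(smoothed,
                                                finite = TRUE)) == 0) {
      sel <- NA_integer_
      diameter <- NA_real_
    } else {
      sel <- which.max(smoothed)
      diameter <- 2 * radii[sel]
    }
  } else {
    diameter <- 2 * radii[sel]
  }
  structure(
    list(diameter = diameter, converged = converged,
         seed_offset = c(RL = seed[[1]], VD = seed[[2]], RC = seed[[3]]),
         radius_profile = tibble(radius = radii, gradient = prof,
                                 smoothed = smoothed)),
    class = "diameter_measurement"
  )
}

smooth_profile <- function(x, window) {
  if (window <= 1) return(x)
  half <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi], na.rm = TRUE)
  }, 0)
}

# first interior strict local maximum: x[i-1] < x[i] >= x[i+1]
first_local_max <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_integer_)
  for (i in 2:(n - 1)) {
    if (is.finite(x[i - 1]) && is.finite(x[i]) && is.finite(x[i + 1]) &&
        x[i - 1] < x[i] && x[i] >= x[i + 1])
      return(i)
  }
  NA_integer_
}

#' @export
print.diameter_measurement <- function(x, ...) {
  cat(sprintf("<diameter_measurement> %.3f mm at seed (%.2f, %.2f, %.2f)%s\n",
              x$diameter, x$seed_offset[1], x$seed_offset[2],
              x$seed_offset[3],
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Measure sinus diameter across a study
#'
#' Applies [sphere_grow_diameter()] at the rostral and caudal seed points to
#' every supplied atlas-space scan. Non-converged measurements are flagged
#' for review rather than dropped.
#'
#' @param scans Named list of atlas-space [volume_image()] (typically
#'   contrast difference images), or a tibble with columns `subject`, `day`,
#'   `scan` (list column).
#' @param frame A [bregma_frame()].
#' @param seeds Seed tibble as [default_sss_seeds()].
#' @param ... Passed to [sphere_grow_diameter()].
#' @return Tibble with columns `subject`, `day`, `location`, `diameter`,
#'   `converged`.
#' @export
measure_study_sss <- function(scans, frame, seeds = default_sss_seeds(),
                              ...) {
  if (!is.data.frame(scans)) {
    scans <- tibble(subject = names(scans) %||%
                      paste0("scan_", seq_along(scans)),
                    day = NA_character_, scan = unname(scans))
  }
  rows <- list()
  for (i in seq_len(nrow(scans))) {
    for (j in seq_len(nrow(seeds))) {
      m <- sphere_grow_diameter(scans$scan[[i]],
                                c(seeds$RL[j], seeds$VD[j], seeds$RC[j]),
                                frame, ...)
      rows[[length(rows) + 1]] <- tibble(
        subject = scans$subject[i], day = scans$day[i],
        location = seeds$location[j], diameter = m$diameter,
        converged = m$converged)
    }
  }
  dplyr::bind_rows(rows)
}

#' Group comparison of sinus diameters across days
#'
#' One-way ANOVA of diameter across day groups (per location), followed by
#' all pairwise two-tailed pooled t-tests; only pairs at or below `alpha`
#' are listed as significant.
#'
#' @param table Tibble with columns `day`, `diameter` and optionally
#'   `location` (analysed separately per location).
#' @param alpha Significance level for pairwise reporting.
#' @return An object of class `diameter_anova`: list with `anova` (per
#'   location F, df, p), `pairwise` (all pairs) and `significant_pairs`.
#' @export
diameter_group_analysis <- function(table, alpha = 0.05) {
  stopifnot(all(c("day", "diameter") %in% names(table)))
  if (!"location" %in% names(table)) table$location <- "all"
  locs <- unique(table$location)
  an <- list(); pw <- list()
  for (loc in locs) {
    d <- table[table$location == loc & is.finite(table$diameter), ]
    groups <- split(d$diameter, d$day)
    groups <- groups[vapply(groups, length, 0L) >= 2]
    if (length(groups) < 2)
      stop("need at least two day groups with >= 2 observations (location ",
           loc, ")", call. = FALSE)
    dd <- data.frame(diameter = unlist(groups),
                     day = rep(names(groups), lengths(groups)))
    fit <- aov(diameter ~ day, data = dd)
    s <- summary(fit)[[1]]
    an[[loc]] <- tibble(location = loc, F = s$`F value`[1],
                        df1 = s$Df[1], df2 = s$Df[2],
                        p = s$`Pr(>F)`[1])
    days <- names(groups)
    for (a in seq_along(days)) {
      for (b in seq_along(days)) {
        if (b <= a) next
        ts <- pooled_t_stat(groups[[days[b]]], groups[[days[a]]])
        pw[[length(pw) + 1]] <- tibble(
          location = loc, day_1 = days[a], day_2 = days[b],
          n_1 = ts$n_y, n_2 = ts$n_x,
          mean_1 = mean(groups[[days[a]]]), mean_2 = mean(groups[[days[b]]]),
          t = ts$t, df = ts$df, p = ts$p)
      }
    }
  }
  pairwise <- dplyr::bind_rows(pw)
  structure(
    list(anova = dplyr::bind_rows(an), pairwise = pairwise,
         significant_pairs = dplyr::filter(pairwise, .data$p <= alpha),
         alpha = alpha),
    class = "diameter_anova"
  )
}

#' @export
print.diameter_anova <- function(x, ...) {
  cat("<diameter_anova>\n")
  print(x$anova)
  cat(sprintf("%d significant pair(s) at alpha = %g\n",
              nrow(x$significant_pairs), x$alpha))
  if (nrow(x$significant_pairs)) print(x$significant_pairs)
  invisible(x)
}

#' @describeIn diameter_group_analysis Tidy pairwise comparisons.
#' @param x A `diameter_anova`.
#' @param ... Unused.
#' @export
tidy.diameter_anova <- function(x, ...) {
  x$pairwise
}

#' @describeIn diameter_group_analysis Per-location ANOVA summary.
#' @export
glance.diameter_anova <- function(x, ...) {
  x$anova
}

#' Pooled two-sample t-test from printed summary statistics
#'
#' Computes the classical pooled-variance two-tailed t-test from
#' (n, mean, SD) triples, enabling checks against published summary tables
#' without per-subject data.
#'
#' @param n1,mean1,sd1 First group summaries.
#' @param n2,mean2,sd2 Second group summaries.
#' @return Tibble with `t` (positive when `mean2 > mean1`), `df`, `p`.
#' @export
summary_stat_ttest <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean2 - mean1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}
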