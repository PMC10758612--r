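# Seeded synthetic 3D vessel phantoms: branching bright tubes on a darker
# background with nearby distractor tubes and additive Gaussian noise.
# They emulate the statistical structure of contrast-enhanced abdominal
# angiography at desk scale: sparse elongated foreground, bright lumen,
# adjacent non-target vessels, isotropic voxels.

#' Phantom specification
#'
#' @param extent Volume extents, length 1 (cube) or 3.
#' @param n_branches Number of vessel branches (>= 1; the first is the
#'   main trunk, the rest sprout from random points on earlier branches).
#' @param radius_range Min/max tube radius in voxels (radii taper linearly
#'   toward the distal end to emulate peripheral thinning).
#' @param curvature Waypoint jitter scale as a fraction of the extent;
#'   0 gives straight tubes.
#' @param lumen_mean,lumen_sd Intensity of vessel lumen voxels.
#' @param background_mean,background_sd Background intensity.
#' @param distractor_count Nearby non-target tubes (excluded from the
#'   label), emulating adjacent vessels of similar appearance.
#' @param distractor_mean Lumen intensity of distractor tubes (dimmer than
#'   the target, as for less-enhanced neighbouring vessels).
#' @param noise_sd Additive Gaussian noise on the whole volume.
#' @param taper Distal radius as a fraction of the proximal radius.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(extent = 64L, n_branches = 3L,
                         radius_range = c(1.5, 3), curvature = 0.15,
                         lumen_mean = 0.8, lumen_sd = 0.05,
                         background_mean = 0.2, background_sd = 0.05,
                         distractor_count = 2L, distractor_mean = 0.55,
                         noise_sd = 0.05, taper = 0.5, seed = 1L) {
  if (length(extent) == 1L) extent <- rep(extent, 3L)
  extent <- as.integer(extent)
  if (any(radius_range < 1)) stop("phantom_spec: radii must be >= 1 voxel")
  if (max(radius_range) > min(extent) / 4)
    stop("phantom_spec: max radius exceeds a quarter of the volume extent")
  structure(list(extent = extent, n_branches = as.integer(n_branches),
                 radius_range = radius_range, curvature = curvature,
                 lumen_mean = lumen_mean, lumen_sd = lumen_sd,
                 background_mean = background_mean, background_sd = background_sd,
                 distractor_count = as.integer(distractor_count),
                 distractor_mean = distractor_mean, noise_sd = noise_sd,
                 taper = taper, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Rasterize a tapering tube along a polyline
#'
#' Marks every voxel whose distance to some polyline segment (with the
#' projection parameter inside the segment, i.e. flat end caps) is at most
#' the linearly interpolated radius.
#'
#' @param mask Logical/integer 3D array to draw into.
#' @param pts `n x 3` matrix of polyline points (voxel coordinates).
#' @param radii Radius at each point (length `n`).
#' @return The updated mask.
#' @export
rasterize_tube <- function(mask, pts, radii) {
  ext <- dim(mask)
  for (s in seq_len(nrow(pts) - 1L)) {
    p1 <- pts[s, ]; p2 <- pts[s + 1L, ]
    r1 <- radii[s]; r2 <- radii[s + 1L]
    rmax <- max(r1, r2)
    lo <- pmax(floor(pmin(p1, p2) - rmax), 1)
    hi <- pmin(ceiling(pmax(p1, p2) + rmax), ext)
    if (any(lo > hi)) next
    gx <- seq(lo[1], hi[1]); gy <- seq(lo[2], hi[2]); gz <- seq(lo[3], hi[3])
    g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    dvec <- p2 - p1
    len2 <- sum(dvec^2)
    if (len2 == 0) next
    t <- ((g[, 1] - p1[1]) * dvec[1] + (g[, 2] - p1[2]) * dvec[2] +
            (g[, 3] - p1[3]) * dvec[3]) / len2
    inside <- t >= 0 & t <= 1
    if (!any(inside)) next
    gi <- g[inside, , drop = FALSE]
    ti <- t[inside]
    px <- p1[1] + ti * dvec[1]; py <- p1[2] + ti * dvec[2]; pz <- p1[3] + ti * dvec[3]
    dist <- sqrt((gi[, 1] - px)^2 + (gi[, 2] - py)^2 + (gi[, 3] - pz)^2)
    rad <- r1 + ti * (r2 - r1)
    hit <- gi[dist <= rad, , drop = FALSE]
    if (nrow(hit) > 0)
      mask[hit] <- TRUE
  }
  mask
}

# one smooth random curve: waypoints from a jittered directed walk,
# densified with cubic spline interpolation
random_curve <- function(start, direction, length_total, extent, curvature,
                         n_way = 5L, samples_per_voxel = 1) {
  direction <- direction / sqrt(sum(direction^2))
  step <- length_total / (n_way - 1L)
  pts <- matrix(0, n_way, 3)
  pts[1, ] <- start
  dirc <- direction
  for (i in 2:n_way) {
    jit <- stats::rnorm(3, sd = curvature * mean(extent) / n_way)
    dirc <- dirc + jit / max(step, 1e-8)
    dirc <- dirc / sqrt(sum(dirc^2))
    pts[i, ] <- pts[i - 1, ] + dirc * step
  }
  u <- seq_len(n_way)
  nu <- max(8L, ceiling(length_total * samples_per_voxel))
  uu <- seq(1, n_way, length.out = nu)
  dense <- cbind(stats::spline(u, pts[, 1], xout = uu)$y,
                 stats::spline(u, pts[, 2], xout = uu)$y,
                 stats::spline(u, pts[, 3], xout = uu)$y)
  dense
}

draw_tree <- function(mask, spec, n_tubes) {
  ext <- dim(mask)
  curves <- list()
  for (b in seq_len(n_tubes)) {
    if (b == 1L || length(curves) == 0L) {
      start <- stats::runif(3, 0.2, 0.8) * ext
      dirn <- stats::rnorm(3)
      len <- stats::runif(1, 0.5, 0.9) * mean(ext)
      r0 <- stats::runif(1, mean(spec$radius_range), spec$radius_range[2])
    } else {
      parent <- curves[[sample.int(length(curves), 1)]]
      at <- sample.int(nrow(parent$pts), 1)
      start <- parent$pts[at, ]
      dirn <- stats::rnorm(3)
      len <- stats::runif(1, 0.25, 0.6) * mean(ext)
      r0 <- stats::runif(1, spec$radius_range[1], mean(spec$radius_range))
    }
    pts <- random_curve(start, dirn, len, ext, spec$curvature)
    radii <- seq(r0, max(spec$radius_range[1], r0 * spec$taper),
                 length.out = nrow(pts))
    mask <- rasterize_tube(mask, pts, radii)
    curves[[length(curves) + 1L]] <- list(pts = pts)
  }
  list(mask = mask, curves = curves)
}

#' Generate one synthetic vessel phantom
#'
#' The label is the union of swept tapering tubes along random smooth
#' branching curves; the image carries lumen intensity inside the label,
#' distractor-tube intensity on nearby non-target tubes (not in the
#' label), background elsewhere, plus additive Gaussian noise. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param hu If `TRUE`, intensities are mapped to a CT-like scale
#'   `hu_scale * I + hu_offset` instead of `[0, 1]`.
#' @param hu_scale,hu_offset CT-mode intensity mapping.
#' @return List with `image` (numeric 3D array), `label` (integer 3D
#'   array in {0, 1}), and `spec`.
#' @export
generate_phantom <- function(spec, hu = FALSE, hu_scale = 400, hu_offset = -100) {
  stopifnot(inherits(spec, "phantom_spec"))
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)
  ext <- spec$extent
  lab <- array(FALSE, ext)
  tree <- draw_tree(lab, spec, spec$n_branches)
  lab <- tree$mask
  dis <- array(FALSE, ext)
  if (spec$distractor_count > 0) {
    dspec <- spec
    dspec$radius_range <- pmax(spec$radius_range * 0.7, 1)
    dis <- draw_tree(dis, dspec, spec$distractor_count)$mask
  }
  fg_frac <- mean(lab)
  if (fg_frac <= 0 || fg_frac >= 0.05)
    stop(sprintf("generate_phantom: foreground fraction %.4f outside (0, 0.05); adjust the spec",
                 fg_frac))
  img <- array(stats::rnorm(prod(ext), spec$background_mean, spec$background_sd), ext)
  ndis <- sum(dis & !lab)
  if (ndis > 0)
    img[dis & !lab] <- stats::rnorm(ndis, spec$distractor_mean, spec$lumen_sd)
  img[lab] <- stats::rnorm(sum(lab), spec$lumen_mean, spec$lumen_sd)
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(prod(ext), 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  if (hu) img <- img * hu_scale + hu_offset
  list(image = img, label = array(as.integer(lab), ext), spec = spec)
}

save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Deterministic k-fold partition of case ids
#'
#' Folds are disjoint, exhaustive, and their sizes differ by at most one.
#'
#' @param case_ids Character or integer vector of case identifiers.
#' @param folds Number of folds (default 3).
#' @param seed Seed for the shuffle.
#' @return Integer vector of fold assignments (1..folds), named by case.
#' @export
assign_folds <- function(case_ids, folds = 3L, seed = 1L) {
  n <- length(case_ids)
  if (n < folds) stop(sprintf("assign_folds: %d cases cannot fill %d folds", n, folds))
  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  f <- integer(n)
  f[perm] <- rep_len(seq_len(folds), n)
  names(f) <- as.character(case_ids)
  f
}

#' Generate a phantom dataset with fold assignments
#'
#' Per-case seeds derive from the base spec's seed, so the whole dataset
#' is reproducible. Optionally writes paired NIfTI files (isotropic 1 mm
#' spacing) and a JSON manifest.
#'
#' @param spec Base [phantom_spec()]; case `i` uses `spec$seed + i`.
#' @param n_cases Number of cases.
#' @param folds Number of cross-validation folds.
#' @param dir Optional output directory for
#'   `case-XXX_image.nii.gz` / `case-XXX_label.nii.gz` and
#'   `manifest.json`.
#' @return List with `cases` (list of phantom lists, when `dir` is NULL),
#'   `manifest` data.frame (`case_id`, `seed`, `fold`), and `dir`.
#' @export
make_dataset <- function(spec, n_cases, folds = 3L, dir = NULL) {
  ids <- sprintf("case-%03d", seq_len(n_cases))
  fold <- assign_folds(ids, folds = folds, seed = spec$seed)
  manifest <- data.frame(case_id = ids, seed = spec$seed + seq_len(n_cases),
                         fold = as.integer(fold), stringsAsFactors = FALSE)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    cs <- spec
    cs$seed <- manifest$seed[i]
    ph <- generate_phantom(cs)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_volume(ph$image, file.path(dir, paste0(ids[i], "_image.nii.gz")))
      write_volume(ph$label, file.path(dir, paste0(ids[i], "_label.nii.gz")))
    } else {
      cases[[i]] <- ph
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    cases <- NULL
  }
  list(cases = cases, manifest = manifest, dir = dir)
}
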