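#' Specification of a synthetic fluorescence field
#'
#' Bundles the geometric and photometric parameters of one simulated
#' microscopy field. Per-cell signal amplitudes are drawn from class-dependent
#' lognormal distributions (reporter and antibody channels separately for
#' reporter-positive and reporter-negative cells), cells are rendered as
#' non-overlapping disks across a z-stack with a Gaussian intensity profile
#' along z, and a constant background plus optional Poisson and Gaussian
#' noise is added before clipping to the 16-bit range.
#'
#' The defaults emulate a confocal field of cultured cells in which roughly
#' 40--50% of cells express the target: 60 cells per 256x256 field (so the
#' at-least-20-negative-cells rule for specificity ratios is comfortably
#' met), a 3-fold antibody signal ratio between positive and negative cells,
#' and a photometrically small constant background.
#'
#' @param height_px,width_px Field size in pixels.
#' @param n_cells Number of cells to place. The number of positive cells is
#'   exactly `round(positive_fraction * n_cells)`.
#' @param positive_fraction Fraction of cells that are reporter-positive,
#'   in \[0, 1\].
#' @param radius_range Length-2 numeric, min and max cell radius in pixels.
#' @param min_separation_px Minimum gap between disk edges, pixels.
#' @param n_z Number of z planes.
#' @param z_profile_sigma Standard deviation (in planes) of the Gaussian
#'   intensity profile along z, centered on each cell's focal plane. Use
#'   `Inf` for a flat profile (every plane at full amplitude).
#' @param reporter_logmean_pos,reporter_logsd_pos,reporter_logmean_neg,reporter_logsd_neg
#'   Lognormal log-scale location and spread of per-cell reporter amplitudes
#'   by class (arbitrary intensity units).
#' @param antibody_logmean_pos,antibody_logsd_pos,antibody_logmean_neg,antibody_logsd_neg
#'   Same for the antibody channel. The ratio
#'   `exp(antibody_logmean_pos - antibody_logmean_neg)` is the generative
#'   antibody specificity of the simulated staining.
#' @param background_level Constant background intensity added everywhere.
#' @param gaussian_noise_sd Standard deviation of additive Gaussian read
#'   noise (0 disables).
#' @param poisson_scaling Photons per intensity unit for Poisson shot noise
#'   (0 disables).
#' @param bit_depth Image bit depth; only 16 is supported.
#'
#' @return An object of class `field_spec` (a validated list).
#' @seealso [generate_field()]
#' @export
field_spec <- function(height_px = 256, width_px = 256,
                       n_cells = 60, positive_fraction = 0.4,
                       radius_range = c(4, 7), min_separation_px = 2,
                       n_z = 5, z_profile_sigma = 1.5,
                       reporter_logmean_pos = log(3000), reporter_logsd_pos = 0.3,
                       reporter_logmean_neg = log(150), reporter_logsd_neg = 0.3,
                       antibody_logmean_pos = log(6000), antibody_logsd_pos = 0.25,
                       antibody_logmean_neg = log(2000), antibody_logsd_neg = 0.25,
                       background_level = 50, gaussian_noise_sd = 50,
                       poisson_scaling = 0, bit_depth = 16) {
  spec <- list(
    height_px = height_px, width_px = width_px,
    n_cells = n_cells, positive_fraction = positive_fraction,
    radius_range = as.numeric(radius_range),
    min_separation_px = min_separation_px,
    n_z = n_z, z_profile_sigma = z_profile_sigma,
    reporter_logmean_pos = reporter_logmean_pos,
    reporter_logsd_pos = reporter_logsd_pos,
    reporter_logmean_neg = reporter_logmean_neg,
    reporter_logsd_neg = reporter_logsd_neg,
    antibody_logmean_pos = antibody_logmean_pos,
    antibody_logsd_pos = antibody_logsd_pos,
    antibody_logmean_neg = antibody_logmean_neg,
    antibody_logsd_neg = antibody_logsd_neg,
    background_level = background_level,
    gaussian_noise_sd = gaussian_noise_sd,
    poisson_scaling = poisson_scaling,
    bit_depth = bit_depth
  )
  class(spec) <- "field_spec"
  validate_field_spec(spec)
  spec
}

validate_field_spec <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  ok <- function(cond, msg) if (!cond) stop("invalid field spec: ", msg, call. = FALSE)
  ok(is_count(spec$height_px, 1) && is_count(spec$width_px, 1), "field size must be positive integers")
  ok(is_count(spec$n_cells, 1), "n_cells must be >= 1")
  ok(is_number(spec$positive_fraction, 0) && spec$positive_fraction <= 1,
     "positive_fraction must be in [0, 1]")
  ok(length(spec$radius_range) == 2 && all(spec$radius_range > 0) &&
       spec$radius_range[1] <= spec$radius_range[2],
     "radius_range must be (min, max) with 0 < min <= max")
  ok(is_number(spec$min_separation_px, 0), "min_separation_px must be >= 0")
  ok(is_count(spec$n_z, 1), "n_z must be >= 1")
  ok(is_number(spec$z_profile_sigma, 0) &&
       (spec$z_profile_sigma > 0 || is.infinite(spec$z_profile_sigma)),
     "z_profile_sigma must be > 0 (Inf for a flat profile)")
  for (p in grep("_logsd_", names(spec), value = TRUE)) {
    ok(is_number(spec[[p]], 0), paste(p, "must be >= 0"))
  }
  ok(is_number(spec$background_level, 0), "background_level must be >= 0")
  ok(is_number(spec$gaussian_noise_sd, 0), "gaussian_noise_sd must be >= 0")
  ok(is_number(spec$poisson_scaling, 0), "poisson_scaling must be >= 0")
  ok(identical(as.numeric(spec$bit_depth), 16), "only bit_depth = 16 is supported")
  invisible(spec)
}

MAX_PLACEMENT_ATTEMPTS <- 10000L
INTENSITY_MAX <- 65535L

#' Generate a synthetic multi-channel fluorescence field
#'
#' Places `n_cells` non-overlapping disks by rejection sampling, assigns each
#' a class (`positive`/`negative`; exactly `round(positive_fraction *
#' n_cells)` positives), draws per-cell reporter and antibody amplitudes from
#' the class-dependent lognormals, and renders a z-stack per channel: each
#' cell's disk carries its amplitude attenuated by a Gaussian z profile
#' centered on a randomly chosen focal plane (one of the integer plane
#' indices, so the maximum projection recovers the full amplitude). A
#' constant background is added to every pixel, then optional Poisson shot
#' noise on signal plus background, then additive Gaussian noise, then
#' rounding and clipping to \[0, 65535\].
#'
#' The whole construction is driven by a single RNG stream seeded from
#' `seed`, so a given `(spec, seed)` pair always yields a bit-identical
#' field.
#'
#' @param spec A [field_spec()].
#' @param seed Integer seed for the field's private RNG stream.
#' @return An object of class `synthetic_field`: a list with `channels` (a
#'   named list of `height x width x n_z` integer arrays, `reporter` and
#'   `antibody`), `label_mask` (`height x width` integer matrix, 0 =
#'   background, k = cell k), `truth` (data frame: `cell_id`, `row`, `col`
#'   (0-based centroids), `radius`, `class`, `reporter_amp`,
#'   `antibody_amp`), `spec` and `seed`.
#' @examples
#' f <- generate_field(field_spec(n_cells = 30, height_px = 160, width_px = 160), seed = 1)
#' table(f$truth$class)
#' @export
generate_field <- function(spec, seed) {
  validate_field_spec(spec)
  with_local_seed(seed, {
    H <- spec$height_px; W <- spec$width_px; n <- spec$n_cells

    n_pos <- as.integer(round(spec$positive_fraction * n))
    classes <- sample(c(rep("positive", n_pos), rep("negative", n - n_pos)))

    placement <- place_disks(n, H, W, spec$radius_range, spec$min_separation_px)

    rep_amp <- stats::rlnorm(
      n,
      meanlog = ifelse(classes == "positive", spec$reporter_logmean_pos, spec$reporter_logmean_neg),
      sdlog   = ifelse(classes == "positive", spec$reporter_logsd_pos, spec$reporter_logsd_neg)
    )
    ab_amp <- stats::rlnorm(
      n,
      meanlog = ifelse(classes == "positive", spec$antibody_logmean_pos, spec$antibody_logmean_neg),
      sdlog   = ifelse(classes == "positive", spec$antibody_logsd_pos, spec$antibody_logsd_neg)
    )

    focal <- sample.int(spec$n_z, n, replace = TRUE)

    # linear pixel indices of each cell's disk (H x W column-major)
    disk_idx <- lapply(seq_len(n), function(i) {
      disk_pixels(placement$row[i], placement$col[i], placement$radius[i], H, W)
    })

    label_mask <- matrix(0L, H, W)
    for (i in seq_len(n)) label_mask[disk_idx[[i]]] <- i

    # per-cell z attenuation weights, n x n_z
    if (is.infinite(spec$z_profile_sigma)) {
      zw <- matrix(1, n, spec$n_z)
    } else {
      zgrid <- matrix(seq_len(spec$n_z), n, spec$n_z, byrow = TRUE)
      zw <- exp(-(zgrid - focal)^2 / (2 * spec$z_profile_sigma^2))
    }

    render <- function(amps) {
      stack <- array(0, dim = c(H, W, spec$n_z))
      for (k in seq_len(spec$n_z)) {
        plane <- matrix(spec$background_level, H, W)
        for (i in seq_len(n)) {
          plane[disk_idx[[i]]] <- plane[disk_idx[[i]]] + amps[i] * zw[i, k]
        }
        if (spec$poisson_scaling > 0) {
          plane <- stats::rpois(length(plane), spec$poisson_scaling * plane) /
            spec$poisson_scaling
          dim(plane) <- c(H, W)
        }
        if (spec$gaussian_noise_sd > 0) {
          plane <- plane + stats::rnorm(length(plane), 0, spec$gaussian_noise_sd)
        }
        stack[, , k] <- plane
      }
      stack <- round(stack)
      stack[stack < 0] <- 0
      stack[stack > INTENSITY_MAX] <- INTENSITY_MAX
      storage.mode(stack) <- "integer"
      stack
    }

    truth <- data.frame(
      cell_id = seq_len(n),
      row = placement$row, col = placement$col,
      radius = placement$radius,
      class = classes,
      reporter_amp = rep_amp,
      antibody_amp = ab_amp,
      stringsAsFactors = FALSE
    )

    structure(
      list(
        channels = list(reporter = render(rep_amp), antibody = render(ab_amp)),
        label_mask = label_mask,
        truth = truth,
        spec = spec,
        seed = as.integer(seed)
      ),
      class = "synthetic_field"
    )
  })
}

# Rejection-sample disk centers (0-based continuous coordinates) so that
# every pair satisfies dist >= r_i + r_j + min_sep. Bounded total attempts.
place_disks <- function(n, H, W, radius_range, min_sep) {
  rows <- cols <- radii <- numeric(n)
  attempts <- 0L
  for (i in seq_len(n)) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    if (H - 1 - 2 * r < 0 || W - 1 - 2 * r < 0) {
      stop("field too crowded: a radius-", round(r, 1), " cell does not fit in ",
           H, "x", W, call. = FALSE)
    }
    repeat {
      attempts <- attempts + 1L
      if (attempts > MAX_PLACEMENT_ATTEMPTS) {
        stop("field too crowded: could not place ", n, " cells in ", H, "x", W,
             " after ", MAX_PLACEMENT_ATTEMPTS, " attempts", call. = FALSE)
      }
      cand_r <- stats::runif(1, r, H - 1 - r)
      cand_c <- stats::runif(1, r, W - 1 - r)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      d2 <- (rows[j] - cand_r)^2 + (cols[j] - cand_c)^2
      if (all(d2 >= (radii[j] + r + min_sep)^2)) break
    }
    rows[i] <- cand_r; cols[i] <- cand_c; radii[i] <- r
  }
  list(row = rows, col = cols, radius = radii)
}

# Linear (column-major) indices of pixels whose 0-based centers lie within
# `radius` of the 0-based centroid (row0, col0).
disk_pixels <- function(row0, col0, radius, H, W) {
  i <- max(0, floor(row0 - radius)):min(H - 1, ceiling(row0 + radius))
  j <- max(0, floor(col0 - radius)):min(W - 1, ceiling(col0 + radius))
  ii <- rep(i, times = length(j))
  jj <- rep(j, each = length(i))
  keep <- (ii - row0)^2 + (jj - col0)^2 <= radius^2
  (jj[keep]) * H + ii[keep] + 1L
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses a `height x width x n_z` stack to a single plane by taking the
#' per-pixel maximum across z. All quantification in this package operates
#' on such raw maximum projections. A plain matrix is treated as a
#' single-plane stack and returned unchanged.
#'
#' @param stack A 3-d array (`H x W x Z`, `Z >= 1`) or an `H x W` matrix.
#' @return An `H x W` matrix with the input's storage mode.
#' @export
max_projection <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    stop("`stack` must be an H x W x Z array with Z >= 1", call. = FALSE)
  }
  planes <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  Reduce(pmax, planes)
}

#' Write / read a synthetic field to a directory of plain image files
#'
#' `write_field()` stores each channel as a multi-page 16-bit TIFF (one page
#' per z plane), the label mask as a single-page 16-bit TIFF, the truth
#' table as CSV and the spec plus seed as JSON. `read_field()` reverses the
#' operation; the round trip is lossless for channels and mask.
#'
#' @param field A `synthetic_field`.
#' @param directory Output directory (created if absent).
#' @return `write_field()` invisibly returns the vector of files written;
#'   `read_field()` returns a `synthetic_field`.
#' @export
write_field <- function(field, directory) {
  stopifnot(inherits(field, "synthetic_field"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    reporter = file.path(directory, "reporter.tif"),
    antibody = file.path(directory, "antibody.tif"),
    label_mask = file.path(directory, "label_mask.tif"),
    truth = file.path(directory, "truth.csv"),
    spec = file.path(directory, "spec.json")
  )
  for (ch in c("reporter", "antibody")) {
    stack <- field$channels[[ch]]
    pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k] / INTENSITY_MAX)
    tiff::writeTIFF(pages, paths[[ch]], bits.per.sample = 16L)
  }
  tiff::writeTIFF(field$label_mask / INTENSITY_MAX, paths[["label_mask"]],
                  bits.per.sample = 16L)
  utils::write.csv(field$truth, paths[["truth"]], row.names = FALSE)
  spec_out <- unclass(field$spec)
  jsonlite::write_json(list(spec = spec_out, seed = field$seed), paths[["spec"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_field
#' @export
read_field <- function(directory) {
  need <- c("reporter.tif", "antibody.tif", "label_mask.tif", "truth.csv", "spec.json")
  for (f in need) {
    if (!file.exists(file.path(directory, f))) {
      stop("missing field file: ", file.path(directory, f), call. = FALSE)
    }
  }
  read_stack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    out <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) out[, , k] <- pages[[k]]
    storage.mode(out) <- "integer"
    out
  }
  meta <- jsonlite::read_json(file.path(directory, "spec.json"), simplifyVector = TRUE)
  spec <- meta$spec
  spec$radius_range <- as.numeric(spec$radius_range)
  class(spec) <- "field_spec"
  validate_field_spec(spec)
  mask <- tiff::readTIFF(file.path(directory, "label_mask.tif"), as.is = TRUE)
  storage.mode(mask) <- "integer"
  truth <- utils::read.csv(file.path(directory, "truth.csv"), stringsAsFactors = FALSE)
  structure(
    list(
      channels = list(
        reporter = read_stack(file.path(directory, "reporter.tif")),
        antibody = read_stack(file.path(directory, "antibody.tif"))
      ),
      label_mask = mask,
      truth = truth,
      spec = spec,
      seed = as.integer(meta$seed)
    ),
    class = "synthetic_field"
  )
}

#' @export
print.synthetic_field <- function(x, ...) {
  d <- dim(x$channels$reporter)
  cat("<synthetic_field> ", d[1], "x", d[2], " px, ", d[3], " z planes, ",
      nrow(x$truth), " cells (", sum(x$truth$class == "positive"),
      " positive), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
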