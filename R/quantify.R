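#' Ground-truth labels and classes of a synthetic field
#'
#' For synthetic fields the simulator's truth table plays the role that the
#' independent reporter (e.g. an anti-GFP co-stain) plays for real images:
#' it defines which cells are positive. Returns the field's label mask
#' unchanged together with the true class of every label.
#'
#' @param field A `synthetic_field`.
#' @return A list with `labels` (H x W integer mask) and `classes` (character
#'   vector named by cell id, values `"positive"`/`"negative"`).
#' @export
labels_from_truth <- function(field) {
  if (!inherits(field, "synthetic_field") || is.null(field$truth) ||
      is.null(field$label_mask)) {
    stop("`field` must be a synthetic_field with truth and label_mask", call. = FALSE)
  }
  classes <- field$truth$class
  names(classes) <- field$truth$cell_id
  list(labels = field$label_mask, classes = classes)
}

#' Segment reporter-positive cells in a maximum projection
#'
#' Thresholds the reporter projection, labels 8-connected foreground
#' components and discards components smaller than `min_area`. This is an
#' explicit stand-in for manual ROI outlining and is validated only against
#' synthetic ground truth.
#'
#' @param image H x W numeric matrix (a maximum projection), or an
#'   H x W x Z stack, which is max-projected first.
#' @param method `"otsu"` for Otsu's threshold on the 16-bit histogram, or a
#'   single number for a fixed threshold. A constant (single-valued) image
#'   under Otsu yields no foreground rather than an arbitrary split.
#' @param min_area Minimum component area in pixels (default 20).
#' @return H x W integer label mask; labels are numbered 1..K in raster
#'   (row-major) order of each component's first pixel. K = 0 (all zeros) is
#'   a valid result.
#' @export
segment_reporter <- function(image, method = "otsu", min_area = 20) {
  image <- max_projection(image)
  if (length(image) == 0) stop("`image` must be nonempty", call. = FALSE)
  if (is.numeric(method)) {
    thr <- method
  } else if (identical(method, "otsu")) {
    vals <- unique(as.vector(image))
    if (length(vals) < 2L) {
      return(matrix(0L, nrow(image), ncol(image)))
    }
    thr <- EBImage::otsu(EBImage::Image(image / 65535),
                         range = c(0, 1), levels = 65536L) * 65535
  } else {
    stop("`method` must be \"otsu\" or a numeric threshold", call. = FALSE)
  }
  label_components(image >= thr, min_area = min_area)
}

# 8-connected component labeling of a logical matrix, relabeled 1..K in
# raster (row-major) order of each component's first pixel.
label_components <- function(foreground, min_area = 0) {
  H <- nrow(foreground); W <- ncol(foreground)
  fg <- which(foreground)                     # column-major linear indices
  out <- matrix(0L, H, W)
  if (length(fg) == 0L) return(out)

  ri <- (fg - 1L) %% H + 1L
  ci <- (fg - 1L) %/% H + 1L
  pos <- integer(H * W); pos[fg] <- seq_along(fg)   # pixel -> vertex id

  edge_to <- function(dr, dc) {
    ok <- ri + dr >= 1L & ri + dr <= H & ci + dc >= 1L & ci + dc <= W
    nb <- fg[ok] + dr + dc * H
    keep <- pos[nb] > 0L
    cbind(pos[fg[ok][keep]], pos[nb[keep]])
  }
  edges <- rbind(edge_to(1L, 0L), edge_to(0L, 1L), edge_to(1L, 1L), edge_to(-1L, 1L))

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  sizes <- tabulate(comp)
  raster <- (ri - 1L) * W + ci                 # row-major scan order
  first_pix <- vapply(seq_len(max(comp)),
                      function(k) min(raster[comp == k]), numeric(1))
  keep <- sizes >= min_area
  new_id <- integer(max(comp))
  new_id[keep][order(first_pix[keep])] <- seq_len(sum(keep))
  out[fg] <- new_id[comp]
  out
}

#' Per-cell mean intensities from labeled projections
#'
#' Computes, for every label, the mean intensity over exactly that label's
#' pixels in each channel's maximum projection. No background subtraction or
#' normalization is applied: measurements are taken on the raw projections.
#'
#' @param labels H x W integer label mask (0 = background).
#' @param channels Named list of H x W matrices (or H x W x Z stacks, which
#'   are max-projected first) sharing the mask's dimensions.
#' @param field_id Identifier recorded with every measurement.
#' @param classes Optional character vector of cell classes named by label
#'   id (as from [labels_from_truth()]); unnamed labels become `"unknown"`.
#' @return A data frame with one row per label: `field_id`, `cell_id`,
#'   `cell_class`, `area_px`, and one `mean_<channel>` column per channel.
#' @export
mean_intensities <- function(labels, channels, field_id = "field", classes = NULL) {
  stopifnot(is.matrix(labels))
  channels <- lapply(channels, max_projection)
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dim(labels))) {
      stop("channel '", nm, "' does not share the label mask's dimensions",
           call. = FALSE)
    }
  }
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0L) {
    out <- data.frame(field_id = character(), cell_id = integer(),
                      cell_class = character(), area_px = integer())
    for (nm in names(channels)) out[[paste0("mean_", nm)]] <- numeric()
    return(out)
  }
  in_cell <- labels > 0
  lab <- factor(labels[in_cell], levels = ids)
  area <- as.integer(table(lab))
  out <- data.frame(
    field_id = field_id,
    cell_id = as.integer(ids),
    cell_class = if (is.null(classes)) "unknown" else {
      cl <- classes[as.character(ids)]
      cl[is.na(cl)] <- "unknown"
      unname(cl)
    },
    area_px = area,
    stringsAsFactors = FALSE
  )
  for (nm in names(channels)) {
    sums <- tapply(as.numeric(channels[[nm]][in_cell]), lab, sum)
    out[[paste0("mean_", nm)]] <- as.numeric(sums) / area
  }
  out
}

#' Classify cells as reporter-positive by their reporter mean
#'
#' For real images with no ground truth: a cell is `positive` iff its mean
#' reporter intensity is at or above the threshold. With
#' `reporter_threshold = NULL` the threshold is chosen by Otsu's criterion
#' over the per-cell reporter means (maximizing between-class variance over
#' midpoints of consecutive sorted means).
#'
#' @param measurements Data frame from [mean_intensities()].
#' @param reporter_threshold Intensity threshold, or `NULL` for automatic.
#' @param reporter_col Column holding the reporter means.
#' @return The measurements with `cell_class` set; zero rows in, zero rows out.
#' @export
classify_cells <- function(measurements, reporter_threshold = NULL,
                           reporter_col = "mean_reporter") {
  if (nrow(measurements) == 0L) return(measurements)
  if (!reporter_col %in% names(measurements)) {
    stop("reporter channel column '", reporter_col, "' not present", call. = FALSE)
  }
  m <- measurements[[reporter_col]]
  if (is.null(reporter_threshold)) reporter_threshold <- otsu_1d(m)
  measurements$cell_class <- ifelse(m >= reporter_threshold, "positive", "negative")
  measurements
}

# Otsu's threshold for a numeric vector: evaluate between-class variance at
# midpoints between consecutive distinct sorted values. Degenerate input
# (fewer than 2 distinct values) -> +Inf, i.e. nothing is called positive.
otsu_1d <- function(x) {
  v <- sort(unique(x))
  if (length(v) < 2L) return(Inf)
  cand <- (v[-1] + v[-length(v)]) / 2
  score <- vapply(cand, function(t) {
    lo <- x < t
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) return(-Inf)
    w0 * (1 - w0) * (mean(x[!lo]) - mean(x[lo]))^2
  }, numeric(1))
  cand[which.max(score)]
}

#' Quantify a synthetic field end to end
#'
#' Convenience wrapper: maximum-projects both channels, takes the
#' ground-truth labels and classes, and returns the per-cell measurement
#' table.
#'
#' @param field A `synthetic_field`.
#' @param field_id Identifier for the output rows.
#' @return Per-cell measurements as from [mean_intensities()].
#' @export
quantify_field <- function(field, field_id = "field") {
  lt <- labels_from_truth(field)
  mean_intensities(lt$labels, field$channels, field_id = field_id,
                   classes = lt$classes)
}
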