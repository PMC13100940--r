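test_that("truth labels carry the true class for every cell", {
  f <- generate_field(small_field_spec(), seed = 31)
  lt <- labels_from_truth(f)
  expect_identical(lt$labels, f$label_mask)
  expect_identical(unname(lt$classes[as.character(f$truth$cell_id)]),
                   f$truth$class)
  f0 <- generate_field(small_field_spec(positive_fraction = 0), seed = 31)
  expect_true(all(labels_from_truth(f0)$classes == "negative"))
  expect_error(labels_from_truth(list()), "synthetic_field")
})

test_that("mean intensities match a brute-force pixel loop", {
  f <- generate_field(small_field_spec(n_cells = 12, positive_fraction = 0.5),
                      seed = 41)
  proj <- max_projection(f$channels$antibody)
  m <- mean_intensities(f$label_mask, list(antibody = f$channels$antibody))
  for (k in seq_len(nrow(m))) {
    id <- m$cell_id[k]
    px <- proj[f$label_mask == id]
    expect_equal(m$mean_antibody[k], sum(as.numeric(px)) / length(px))
    expect_identical(m$area_px[k], length(px))
  }
})

test_that("mean intensities: constant channel, relabeling invariance, linear scaling", {
  f <- generate_field(small_field_spec(n_cells = 10, positive_fraction = 0.3),
                      seed = 43)
  const <- matrix(7, nrow(f$label_mask), ncol(f$label_mask))
  m <- mean_intensities(f$label_mask, list(c1 = const))
  expect_true(all(m$mean_c1 == 7))

  proj <- max_projection(f$channels$antibody)
  m1 <- mean_intensities(f$label_mask, list(ab = proj))
  # permute the label ids
  ids <- sort(unique(f$label_mask[f$label_mask > 0]))
  perm <- setNames(sample(ids), ids)
  relabeled <- f$label_mask
  relabeled[f$label_mask > 0] <- perm[as.character(f$label_mask[f$label_mask > 0])]
  m2 <- mean_intensities(relabeled, list(ab = proj))
  m2_back <- m2[match(perm[as.character(m1$cell_id)], m2$cell_id), ]
  expect_equal(m2_back$mean_ab, m1$mean_ab)
  expect_identical(m2_back$area_px, m1$area_px)

  m3 <- mean_intensities(f$label_mask, list(ab = proj * 2.5))
  expect_equal(m3$mean_ab, m1$mean_ab * 2.5)

  bad <- matrix(0, 3, 3)
  expect_error(mean_intensities(f$label_mask, list(ab = bad)), "dimensions")
})

test_that("fixed-threshold segmentation recovers two clean disks", {
  img <- matrix(0, 40, 40)
  mk_disk <- function(r0, c0, rad) {
    for (i in 1:40) for (j in 1:40)
      if ((i - r0)^2 + (j - c0)^2 <= rad^2) img[i, j] <<- 1000
  }
  mk_disk(10, 10, 4); mk_disk(30, 30, 5)
  seg <- segment_reporter(img, method = 500, min_area = 5)
  expect_identical(max(seg), 2L)
  expect_identical(sort(as.integer(table(seg[seg > 0]))),
                   sort(c(sum((row(img) - 10)^2 + (col(img) - 10)^2 <= 16),
                          sum((row(img) - 30)^2 + (col(img) - 30)^2 <= 25))))
})

test_that("otsu on a constant image yields no foreground", {
  seg <- segment_reporter(matrix(500, 30, 30), method = "otsu")
  expect_true(all(seg == 0L))
})

test_that("component labels use 8-connectivity and raster numbering", {
  img <- matrix(0, 6, 6)
  img[2, 2] <- 1; img[3, 3] <- 1          # diagonal pair: one component
  img[5, 5] <- 1                          # separate component
  seg <- segment_reporter(img, method = 0.5, min_area = 1)
  expect_identical(max(seg), 2L)
  expect_identical(seg[2, 2], seg[3, 3])
  expect_identical(seg[2, 2], 1L)         # first in raster order
  expect_identical(seg[5, 5], 2L)
})

test_that("segmentation recovers >= 95% of true positives at high SNR", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    f <- generate_field(small_field_spec(), seed = 200 + s)
    seg <- segment_reporter(f$channels$reporter)
    pos_ids <- f$truth$cell_id[f$truth$class == "positive"]
    for (id in pos_ids) {
      truth_px <- which(f$label_mask == id)
      labs <- seg[truth_px]
      labs <- labs[labs > 0]
      if (length(labs)) {
        cand <- as.integer(names(which.max(table(labs))))
        seg_px <- which(seg == cand)
        iou <- length(intersect(truth_px, seg_px)) /
          length(union(truth_px, seg_px))
        if (iou >= 0.5) hits <- hits + 1L
      }
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("threshold classification behaves at the extremes and recovers truth via otsu", {
  f <- generate_field(small_field_spec(), seed = 51)
  m <- quantify_field(f)
  truth_class <- m$cell_class
  m$cell_class <- NULL
  expect_true(all(classify_cells(m, reporter_threshold = 0)$cell_class == "positive"))
  expect_true(all(classify_cells(m, reporter_threshold = 1e9)$cell_class == "negative"))

  agree <- vapply(1:10, function(s) {
    f <- generate_field(small_field_spec(), seed = 300 + s)
    m <- quantify_field(f)
    truth_class <- m$cell_class
    mean(classify_cells(m)$cell_class == truth_class)
  }, numeric(1))
  expect_gte(mean(agree), 0.95)

  empty <- m[0, ]
  expect_identical(nrow(classify_cells(empty)), 0L)
})
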