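test_that("binarize marks dark pixels as foreground and validates the threshold", {
  img <- gray_image(matrix(c(0L, 79L, 80L, 255L), 2, 2), "t")
  mask <- binarize(img, 80)
  expect_identical(as.vector(mask), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(binarize(gray_image(matrix(0L, 3, 3)), 80)))
  expect_false(any(binarize(gray_image(matrix(255L, 3, 3)), 80)))
  # threshold 0: nothing is strictly below 0
  expect_false(any(binarize(img, 0)))
  expect_error(binarize(img, 256), class = "ovocount_parameter_error")
  expect_error(binarize(img, -1), class = "ovocount_parameter_error")
})

test_that("labeling matches the solid-block and diagonal-touch contracts", {
  mask <- matrix(FALSE, 6, 6)
  mask[2:4, 2:4] <- TRUE
  comp <- label_components(mask, 8)
  expect_equal(nrow(comp), 1L)
  expect_equal(comp$pixel_area, 9L)
  expect_equal(comp$box_area, 9L)
  expect_equal(c(comp$top, comp$left, comp$bottom, comp$right),
               c(1L, 1L, 4L, 4L))

  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(nrow(label_components(diag2, 8)), 1L)
  expect_equal(nrow(label_components(diag2, 4)), 2L)

  expect_equal(nrow(label_components(matrix(FALSE, 5, 5), 8)), 0L)
})

test_that("labeling equals a brute-force flood fill on random masks (both connectivities)", {
  set.seed(42)
  for (i in 1:200) {
    mask <- matrix(runif(144) < runif(1, 0.2, 0.7), 12, 12)
    for (conn in c(4, 8)) {
      expect_identical(package_partition(mask, conn),
                       oracle_components(mask, conn))
    }
  }
})

test_that("components are ordered by bounding-box top-left scan position", {
  mask <- matrix(FALSE, 10, 10)
  mask[7:8, 1:2] <- TRUE     # lowest
  mask[1:2, 8:9] <- TRUE     # top-most
  mask[4:5, 4:5] <- TRUE     # middle
  comp <- label_components(mask, 8)
  expect_equal(comp$top, c(0L, 3L, 6L))
})

test_that("box-area classification follows the [min, max] band with default 80/800/1400", {
  p <- detection_params()
  expect_equal(p$bw_threshold, 80L)
  expect_equal(p$min_box_area, 800L)
  expect_equal(p$max_box_area, 1400L)

  img <- gray_image(light_matrix(120, 160), "cls")
  img[] <- paint_block(unclass(img), 5:34, 5:34)       # 30x30 = 900: confident
  img[] <- paint_block(unclass(img), 50:69, 5:24)      # 20x20 = 400: rejected
  img[] <- paint_block(unclass(img), 5:64, 60:99)      # 60x40 = 2400: uncertain
  res <- count_eggs(gray_image(unclass(img), "cls"))
  st <- res$objects$status[order(res$objects$box_area)]
  expect_equal(st, c("rejected", "confident", "uncertain"))
  expect_equal(res$objects$estimated_count[res$objects$status == "rejected"], 0L)
  expect_equal(res$objects$estimated_count[res$objects$status == "confident"], 1L)
})

test_that("reference area is the confident median with the documented fallback", {
  p <- detection_params()
  obj <- data.frame(status = rep("confident", 3),
                    pixel_area = c(900, 1000, 1100))
  expect_equal(reference_egg_area(obj, p), 1000L)
  expect_equal(reference_egg_area(obj[2, ], p), 1000L)
  obj1 <- data.frame(status = "confident", pixel_area = 950)
  expect_equal(reference_egg_area(obj1, p), 950L)
  # no confident object: 0.7 x (800 + 1400) / 2 = 770
  none <- data.frame(status = "uncertain", pixel_area = 5000)
  expect_equal(reference_egg_area(none, p), 770L)
})

test_that("cluster estimates round half up with a floor of one", {
  expect_equal(estimate_cluster(2000, 1000), 2L)
  expect_equal(estimate_cluster(2600, 1000), 3L)
  expect_equal(estimate_cluster(2500, 1000), 3L)   # exact .5 rounds up
  expect_equal(estimate_cluster(700, 1000), 1L)
  expect_equal(estimate_cluster(100, 1000), 1L)
  expect_error(estimate_cluster(2000, 0), class = "ovocount_parameter_error")
  expect_error(estimate_cluster(2000, -5), class = "ovocount_parameter_error")
})

test_that("count_eggs composes the pipeline: blank image, exact strip, merged pair", {
  expect_equal(count_eggs(gray_image(light_matrix(50, 50)))$total_estimate, 0L)

  # isolated default-sized synthetic eggs are counted exactly
  out <- generate_strip(strip_spec(n_eggs = 12, cluster_fraction = 0, seed = 5))
  res <- count_eggs(out$image)
  expect_equal(res$total_estimate, 12L)

  # two touching eggs merged into one component of ~2x the confident median
  img <- light_matrix(150, 220)
  img <- paint_block(img, 10:39, 10:39)     # three confident 900 px eggs
  img <- paint_block(img, 10:39, 60:89)
  img <- paint_block(img, 10:39, 110:139)
  img <- paint_block(img, 80:109, 10:69)    # merged blob: 30 x 60 = 1800 px
  res2 <- count_eggs(gray_image(img, "merged"))
  expect_equal(res2$n_uncertain, 1L)
  expect_equal(res2$reference_area, 900L)
  unc <- res2$objects[res2$objects$status == "uncertain", ]
  expect_equal(unc$estimated_count, 2L)
  expect_equal(res2$total_estimate, 5L)
})

test_that("total estimate decomposes over statuses and pixel areas are conserved", {
  out <- generate_strip(strip_spec(n_eggs = 40, cluster_fraction = 0.2, seed = 11))
  res <- count_eggs(out$image)
  obj <- res$objects
  expect_equal(res$total_estimate,
               sum(obj$estimated_count[obj$status == "confident"]) +
                 sum(obj$estimated_count[obj$status == "uncertain"]))
  expect_gte(res$total_estimate, res$n_confident)
  mask <- binarize(out$image, 80)
  expect_equal(sum(obj$pixel_area), sum(mask))
})

test_that("classification is monotone in the box-area bounds", {
  out <- generate_strip(strip_spec(n_eggs = 30, cluster_fraction = 0.1, seed = 21))
  base <- count_eggs(out$image)
  wider <- count_eggs(out$image, detection_params(max_box_area = 2000))
  lower <- count_eggs(out$image, detection_params(min_box_area = 400))
  conf_ids <- base$objects$object_id[base$objects$status == "confident"]
  # raising max never demotes a confident object to uncertain
  expect_true(all(wider$objects$status[conf_ids] == "confident"))
  # lowering min never demotes a confident object to rejected
  expect_false(any(lower$objects$status[conf_ids] == "rejected"))
})

test_that("histogram estimation equals foreground pixels over reference area", {
  blank <- gray_image(light_matrix(30, 30))
  expect_equal(estimate_by_histogram(blank, detection_params(), 900), 0L)

  # 10 disjoint blobs of exactly 1000 px each, reference 1000 -> 10
  img <- light_matrix(100, 300)
  for (k in 0:9) {
    rs <- 5 + (k %% 2) * 50; cs <- 5 + (k %/% 2) * 55
    img <- paint_block(img, rs:(rs + 19), cs:(cs + 49))  # 20 x 50 = 1000 px
  }
  gi <- gray_image(img, "blobs")
  expect_equal(estimate_by_histogram(gi, detection_params(), 1000), 10L)

  # seeded synthetic strip: equals an independent pixel count over reference
  out <- generate_strip(strip_spec(n_eggs = 25, seed = 9))
  fg <- sum(unclass(out$image) < 80)              # independent pixel count
  expect_equal(estimate_by_histogram(out$image, detection_params(), 900),
               as.integer(floor(fg / 900 + 0.5)))
  expect_error(estimate_by_histogram(gi, detection_params(), 0),
               class = "ovocount_parameter_error")
})

test_that("raft mode counts each large component once and never exceeds micro totals", {
  expect_equal(count_rafts(gray_image(light_matrix(40, 40)))$total_estimate, 0L)

  # three disjoint blobs all above max_box_area count as 3 rafts, not ratios
  img <- light_matrix(200, 300)
  img <- paint_block(img, 10:69, 10:59)
  img <- paint_block(img, 10:69, 100:149)
  img <- paint_block(img, 100:159, 10:59)
  res <- count_rafts(gray_image(img, "rafts"))
  expect_equal(res$total_estimate, 3L)
  expect_true(all(res$objects$status == "confident"))

  # raft totals are bounded by micro totals (micro splits clusters)
  for (s in 1:5) {
    out <- generate_strip(strip_spec(n_eggs = 30, cluster_fraction = 0.3,
                                     seed = 30 + s))
    micro <- count_eggs(out$image)
    raft <- count_rafts(out$image, detection_params(mode = "raft"))
    expect_lte(raft$total_estimate, micro$total_estimate)
  }
  expect_error(count_rafts(gray_image(light_matrix(5, 5)), detection_params()),
               class = "ovocount_parameter_error")
})

test_that("parameter validation rejects inconsistent detection settings", {
  expect_error(detection_params(bw_threshold = 300), class = "ovocount_parameter_error")
  expect_error(detection_params(min_box_area = 1400, max_box_area = 800),
               class = "ovocount_parameter_error")
  expect_error(detection_params(connectivity = 6), class = "ovocount_parameter_error")
})

test_that("results CSV export has the documented per-object and per-image schema", {
  out <- generate_strip(strip_spec(n_eggs = 15, seed = 3))
  res <- count_eggs(out$image)
  fo <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  write_results_csv(list(res), fo, fs)
  obj <- read.csv(fo); summ <- read.csv(fs)
  expect_equal(names(obj), c("image_id", "object_id", "top", "left", "bottom",
                             "right", "box_area", "pixel_area", "status",
                             "estimated_count"))
  expect_equal(names(summ), c("image_id", "n_confident", "n_uncertain",
                              "n_rejected", "reference_area", "total_estimate"))
  expect_equal(summ$total_estimate, res$total_estimate)
  expect_equal(nrow(obj), nrow(res$objects))
})
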