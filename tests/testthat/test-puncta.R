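test_that("normalize_image rescales linearly and handles edge cases", {
  expect_equal(normalize_image(matrix(c(0, 20, 10, 40), 2)),
               matrix(c(0, 0.5, 0.25, 1), 2))
  expect_equal(normalize_image(matrix(7, 3, 3)), matrix(0, 3, 3))
  x <- matrix(seq(0, 1, length.out = 9), 3)
  expect_equal(normalize_image(x), x)
  expect_error(normalize_image(matrix(c(1, NA), 1)), "non-finite")
})

test_that("Phansalkar threshold matches its closed form on flat patches", {
  # constant 0.5 patch: m = 0.5, s = 0 -> t = 0.5*(1 + 2*exp(-5) - 0.25)
  x <- matrix(0.5, 40, 40)
  t_expected <- 0.5 * (1 + 2 * exp(-5) - 0.25)
  tmap <- phansalkar_threshold_map(x)
  expect_lt(max(abs(tmap - t_expected)), 1e-6)
  # every pixel (0.5) exceeds its own threshold (~0.3817): the
  # all-foreground outcome on constant bright images is the formula's
  # consequence
  expect_true(all(phansalkar_threshold(x)))
  expect_lt(t_expected, 0.5)
  expect_equal(t_expected, 0.381737947, tolerance = 1e-9)

  # all-zero image: t = 0 everywhere, strict ">" gives an empty mask
  expect_false(any(phansalkar_threshold(matrix(0, 40, 40))))

  # radius must fit the image
  expect_error(phansalkar_threshold(matrix(0.2, 10, 10)),
               "radius larger")
})

test_that("a Gaussian spot on dim background is isolated by the threshold", {
  n <- 101
  d2 <- outer((1:n - 51)^2, (1:n - 51)^2, "+")
  x <- 0.1 + 0.8 * exp(-d2 / (2 * 1.5^2))
  mask <- phansalkar_threshold(x)
  expect_true(mask[51, 51])
  expect_false(any(mask[1:20, 1:20]))          # far background suppressed
  expect_true(all(which(mask) %in% which(d2 <= 15^2)))
})

test_that("nuclei are detected at disk centers within half a pixel", {
  img <- matrix(0, 200, 200)
  centers <- rbind(c(50, 60), c(120, 40), c(160, 150))
  for (k in 1:3) {
    d2 <- outer((1:200 - centers[k, 1])^2, (1:200 - centers[k, 2])^2, "+")
    img[d2 <= 12^2] <- 0.9
  }
  seeds <- detect_nuclei(img)
  expect_equal(nrow(seeds$centers), 3L)
  ord <- order(seeds$centers[, 1])
  expect_true(all(abs(seeds$centers[ord, ] - centers[order(centers[, 1]), ])
                  <= 0.5))

  expect_equal(nrow(detect_nuclei(matrix(0, 50, 50))$centers), 0L)

  # two overlapping disks merge into one component -> one seed
  img2 <- matrix(0, 100, 100)
  for (ctr in list(c(50, 40), c(50, 55))) {
    d2 <- outer((1:100 - ctr[1])^2, (1:100 - ctr[2])^2, "+")
    img2[d2 <= 12^2] <- 0.9
  }
  expect_equal(nrow(detect_nuclei(img2)$centers), 1L)
})

test_that("seeded watershed recovers the planted cytoplasm masks", {
  sim <- gen_cell_image(n_cells = 3, puncta_per_cell = 4, snr = 10,
                        size = c(300, 300), seed = 21)
  seg <- segment_cytoplasm(normalize_image(sim$image[, , 2]),
                           sim$truth$nuclei_centers)
  expect_equal(seg$n_cells, 3L)
  lm <- seg$label_map
  tm <- sim$truth$label_map
  # labels partition the foreground: one label per pixel by construction
  expect_true(all(lm[tm == 0] %in% 0:3))
  for (k in 1:3) {
    inside <- lm[tm == k]
    best <- as.integer(names(which.max(table(inside))))
    expect_gte(mean(inside == best), 0.90)
  }
  # every seed lies inside its own region
  at_seed <- lm[cbind(round(sim$truth$nuclei_centers[, 1]),
                      round(sim$truth$nuclei_centers[, 2]))]
  expect_equal(at_seed, 1:3)
})

test_that("a seed outside the foreground yields an empty region + warning", {
  sim <- gen_cell_image(n_cells = 1, puncta_per_cell = 3,
                        size = c(200, 200), seed = 22)
  seeds <- rbind(sim$truth$nuclei_centers, c(5, 5))  # corner = background
  expect_warning(
    seg <- segment_cytoplasm(normalize_image(sim$image[, , 2]), seeds),
    "outside the foreground")
  expect_equal(sum(seg$label_map == 2L), 0L)
  expect_error(segment_cytoplasm(matrix(0.5, 50, 50),
                                 matrix(numeric(0), 0, 2)), "no seeds")
})

test_that("particle area filter and bookkeeping identity hold", {
  mask <- matrix(FALSE, 50, 50)
  mask[10, 10] <- TRUE                       # area 1 -> rejected
  mask[20, 20:22] <- TRUE                    # area 3 -> kept, cell 1
  mask[40, 40:42] <- TRUE                    # area 3, centroid on background
  labels <- matrix(0L, 50, 50)
  labels[1:30, 1:30] <- 1L
  res <- detect_and_assign_puncta(mask, list(label_map = labels,
                                             n_cells = 1L))
  expect_equal(unname(res$per_cell_counts), 1L)
  expect_equal(res$discarded_background, 1L)
  expect_equal(sum(res$per_cell_counts) + res$discarded_background,
               nrow(res$puncta_records))
  expect_error(detect_and_assign_puncta(mask, matrix(0L, 10, 10)),
               "different shapes")
})

test_that("the full pipeline is deterministic for a fixed image", {
  sim <- gen_cell_image(n_cells = 2, puncta_per_cell = 5,
                        size = c(256, 256), seed = 30)
  r1 <- quantify_puncta(sim$image)
  r2 <- quantify_puncta(sim$image)
  expect_identical(r1$per_cell_counts, r2$per_cell_counts)
  expect_identical(r1$segmentation$label_map, r2$segmentation$label_map)
  expect_identical(r1$puncta$puncta_records, r2$puncta$puncta_records)
})

test_that("detection matching scores precision and recall sensibly", {
  truth <- data.frame(row = c(10, 40), col = c(10, 40))
  det <- data.frame(row = c(10.8, 40.4, 90), col = c(9.5, 40.2, 90))
  ev <- evaluate_puncta(det, truth, tolerance = 3)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 1)
  ev0 <- evaluate_puncta(det[0, ], truth)
  expect_equal(ev0$recall, 0)
})

test_that("condition comparison tests per-replicate means", {
  same <- list(BSA = c(5, 6, 7, 8), PA = c(5, 6, 7, 8))
  cc <- compare_conditions(same)
  expect_equal(cc$difference, 0)
  expect_equal(cc$p_value, 1)

  diffg <- compare_conditions(list(BSA = c(8.1, 7.9, 8.2, 8.0),
                                   PA = c(4.0, 4.2, 3.9, 4.1)))
  expect_gt(diffg$difference, 0)
  expect_lt(diffg$p_value, 0.05)

  # identical constant groups / degenerate variance limits
  expect_equal(compare_conditions(list(a = c(8, 8), b = c(4, 4)))$p_value, 0)
  expect_equal(compare_conditions(list(a = c(8, 8), b = c(8, 8)))$p_value, 1)

  expect_error(compare_conditions(list(a = 1, b = c(1, 2))), "2 replicates")
  expect_error(compare_conditions(list(a = 1:2)), "two conditions")
})
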