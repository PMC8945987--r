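test_that("quantification generator respects planted labels and fractions", {
  sim <- gen_quant_table(200, frac_up = 0.25, frac_down = 0.15, seed = 3)
  expect_equal(nrow(sim$records), 200L)
  expect_equal(sum(sim$truth$planted_label == "up"), 50L)
  expect_equal(sum(sim$truth$planted_label == "down"), 30L)
  expect_true(all(sim$truth$true_log2_effect[sim$truth$planted_label == "up"] >= 1))
  expect_true(all(sim$truth$true_log2_effect[sim$truth$planted_label == "down"] <= -1))
  expect_true(all(sim$truth$true_log2_effect[sim$truth$planted_label == "null"] == 0))
  expect_true(all(sim$records$peptide_count >= 1))
  expect_true(all(sim$records$ratio > 0))

  # determinism and seed isolation
  sim2 <- gen_quant_table(200, frac_up = 0.25, frac_down = 0.15, seed = 3)
  expect_identical(sim, sim2)

  expect_error(gen_quant_table(10, frac_up = 0.7, frac_down = 0.5),
               "fractions")
  expect_error(gen_quant_table(10, n_replicates = 1), "n_replicates")
})

test_that("noise-free tables hit the degenerate t-test limits", {
  sim <- gen_quant_table(100, frac_up = 0.3, frac_down = 0.3, rep_sd = 0,
                         seed = 9)
  nonnull <- sim$truth$planted_label != "null"
  expect_true(all(sim$records$p_value[nonnull] < 1e-6))
  expect_true(all(sim$records$p_value[!nonnull] == 1))
  expect_equal(sim$records$ratio, 2^sim$truth$true_log2_effect,
               tolerance = 1e-9)
})

test_that("null-only tables stay near ratio 1", {
  sim <- gen_quant_table(100, frac_up = 0, frac_down = 0, rep_sd = 0.1,
                         seed = 1)
  expect_true(all(sim$truth$planted_label == "null"))
  expect_true(all(abs(log2(sim$records$ratio)) < 0.5))
})

test_that("motif-protein generator self-validates against the scanner", {
  prot <- gen_motif_proteins(n_per_class = 20, length = 120, seed = 3)
  expect_equal(nrow(prot), 100L)
  # confusion matrix of planted class vs scanned class is diagonal
  scanned <- vapply(seq_len(nrow(prot)), function(i) {
    hits <- scan_sequence(prot$sequence[i], prot$protein_id[i])
    if (nrow(hits) == 0L) "none"
    else if (nrow(hits) == 1L) hits$motif_class
    else "multiple"
  }, character(1))
  expect_identical(scanned, prot$planted_class)
  # and positions match
  with_motif <- prot$planted_class != "none"
  starts <- vapply(which(with_motif), function(i)
    scan_sequence(prot$sequence[i])$start, integer(1))
  expect_identical(starts, prot$planted_start[with_motif])

  expect_identical(gen_motif_proteins(5, length = 60, seed = 2),
                   gen_motif_proteins(5, length = 60, seed = 2))
  expect_error(gen_motif_proteins(1, length = 4), "length")
})

test_that("cell-image generator books truth correctly and is bit-stable", {
  sim <- gen_cell_image(n_cells = 3, puncta_per_cell = c(2, 5, 8),
                        size = c(256, 256), seed = 2)
  expect_equal(dim(sim$image), c(256L, 256L, 2L))
  expect_equal(nrow(sim$truth$nuclei_centers), 3L)
  expect_equal(as.vector(table(sim$truth$puncta$cell)), c(2L, 5L, 8L))
  expect_true(all(sim$image >= 0 & sim$image <= 1))

  # puncta centers lie inside their cell's cytoplasm mask
  lm <- sim$truth$label_map
  at <- lm[cbind(round(sim$truth$puncta$row), round(sim$truth$puncta$col))]
  expect_identical(at, sim$truth$puncta$cell)

  # cytoplasm masks are disjoint by construction (one label per pixel) and
  # pairwise separated
  d <- as.matrix(dist(sim$truth$nuclei_centers))
  expect_true(all(d[upper.tri(d)] > 2 * 34))

  sim2 <- gen_cell_image(n_cells = 3, puncta_per_cell = c(2, 5, 8),
                         size = c(256, 256), seed = 2)
  expect_identical(sim$image, sim2$image)

  blank <- gen_cell_image(n_cells = 0, size = c(64, 64), seed = 1)
  expect_equal(nrow(blank$truth$nuclei_centers), 0L)
  expect_equal(nrow(blank$truth$puncta), 0L)
  expect_true(all(blank$truth$label_map == 0L))

  expect_error(gen_cell_image(50, size = c(128, 128), seed = 1,
                              max_tries = 50),
               "could not place")
  expect_error(gen_cell_image(1, snr = 0), "snr")
})

test_that("round-trips through TSV, FASTA and TIFF preserve the data", {
  dir <- withr::local_tempdir()

  sim <- gen_quant_table(50, seed = 4)
  tsv <- write_quant_table(sim$records, file.path(dir, "q.tsv"))
  back <- read_quant_table(tsv, treatment = "PA")
  expect_equal(back$ratio, sim$records$ratio, tolerance = 1e-12)
  expect_equal(back$protein_id, sim$records$protein_id)

  prot <- gen_motif_proteins(3, length = 80, seed = 5)
  fa <- write_proteins_fasta(prot, file.path(dir, "p.fasta"))
  seqs <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(seqs), setNames(prot$sequence, prot$protein_id))

  img <- gen_cell_image(2, 3, size = c(128, 128), seed = 6)$image
  tif <- write_image_tiff(img, file.path(dir, "i.tiff"))
  back_img <- read_image_tiff(tif)
  expect_equal(dim(back_img), dim(img))
  expect_true(max(abs(back_img - img)) < 1 / 65535)  # 16-bit quantization

  js <- write_truth_json(list(a = 1:3, b = "x"), file.path(dir, "t.json"))
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE),
               list(a = 1:3, b = "x"))
})
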