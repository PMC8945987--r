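# Per-cell quantification of fluorescent CMA-reporter puncta from
# two-channel images: nuclei provide seeds, the cytoplasm is segmented by a
# nucleus-seeded watershed on the gradient of the smoothed reporter channel,
# puncta are binarized by Phansalkar local thresholding and assigned to the
# cell containing their centroid.

#' Phansalkar local-threshold parameters
#'
#' Defaults follow the widely used Auto Local Threshold implementation
#' (k = 0.25, r = 0.5, p = 2, q = 10, radius 15 px), intended for images
#' normalized to \[0, 1\].
#'
#' @param k,r,p,q Formula constants (see [phansalkar_threshold()]).
#' @param radius Neighborhood radius in pixels (circular window).
#' @return A `phansalkar_params` list.
#' @export
phansalkar_params <- function(k = 0.25, r = 0.5, p = 2.0, q = 10.0,
                              radius = 15L) {
  stopifnot(radius >= 1, r > 0)
  structure(list(k = k, r = r, p = p, q = q, radius = as.integer(radius)),
            class = "phansalkar_params")
}

#' Min-max normalize an image to \[0, 1\]
#'
#' Linear rescale with the minimum mapped to 0 and the maximum to 1; a
#' constant image maps to all zeros.  The input array is not modified.
#'
#' @param image 2-D numeric array with finite values.
#' @return Numeric matrix in \[0, 1\].
#' @export
normalize_image <- function(image) {
  if (!all(is.finite(image))) stop("image contains non-finite values")
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(array(0, dim(image)))
  (image - lo) / (hi - lo)
}

# mirror-pad a matrix by `pad` pixels on every side
.mirror_pad <- function(x, pad) {
  nr <- nrow(x); nc <- ncol(x)
  if (pad >= nr || pad >= nc)
    stop("neighborhood radius larger than image half-extent")
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1L))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1L))
  x[ri, ci]
}

#' Phansalkar local adaptive thresholding
#'
#' For each pixel, let `m` and `s` be the mean and standard deviation of the
#' intensities in the circular neighborhood of the given radius (the image
#' is mirror-padded at its borders).  The local threshold is
#' `t = m * (1 + p * exp(-q * m) + k * ((s / r) - 1))` and a pixel is
#' foreground iff its intensity is strictly greater than `t`.  The
#' exponential term boosts the threshold in dim regions, which suits
#' low-contrast bright spots; note that on a constant bright image every
#' pixel exceeds its own (lower) threshold, so the mask is all-foreground --
#' a direct consequence of the formula.
#'
#' @param image Numeric matrix normalized to \[0, 1\].
#' @param params A [phansalkar_params()] object.
#' @return Logical matrix (TRUE = foreground).
#' @export
phansalkar_threshold <- function(image, params = phansalkar_params()) {
  image > phansalkar_threshold_map(image, params)
}

#' @rdname phansalkar_threshold
#' @return `phansalkar_threshold_map` returns the per-pixel threshold `t`
#'   itself (numeric matrix).
#' @export
phansalkar_threshold_map <- function(image, params = phansalkar_params()) {
  stopifnot(min(image) >= 0, max(image) <= 1)
  rad <- params$radius
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  nw <- sum(brush)
  pad <- .mirror_pad(image, rad)
  crop <- function(z) z[(rad + 1L):(rad + nrow(image)),
                        (rad + 1L):(rad + ncol(image)), drop = FALSE]
  conv <- function(z) crop(as.matrix(EBImage::filter2(z, brush / nw,
                                                      boundary = "replicate")))
  m <- conv(pad)
  ex2 <- conv(pad^2)
  s <- sqrt(pmax(ex2 - m^2, 0))
  m * (1 + params$p * exp(-params$q * m) + params$k * ((s / params$r) - 1))
}

#' Detect nuclei in the DAPI channel
#'
#' Global Otsu threshold, connected components, and an area filter; returns
#' one seed (centroid) per retained component.  Touching nuclei merged into
#' one component yield a single seed.
#'
#' @param nuclei_channel Numeric matrix (normalized internally).
#' @param min_area Minimum component area in pixels.
#' @return List with `centers` (n x 2 matrix of row/col centroids), `areas`
#'   and `mask` (labelled integer matrix, relabelled 1..n).
#' @export
detect_nuclei <- function(nuclei_channel, min_area = 50L) {
  x <- normalize_image(nuclei_channel)
  if (all(x == 0))
    return(list(centers = matrix(numeric(0), 0L, 2L), areas = integer(0),
                mask = matrix(0L, nrow(x), ncol(x))))
  th <- EBImage::otsu(EBImage::Image(x))
  lab <- EBImage::bwlabel(x > th)
  lab <- matrix(as.integer(lab), nrow(x), ncol(x))
  areas <- tabulate(lab)
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(x), ncol(x))
  centers <- matrix(numeric(0), 0L, 2L)
  for (i in seq_along(keep)) {
    px <- which(lab == keep[i])
    out[px] <- i
    rows <- (px - 1L) %% nrow(x) + 1L
    cols <- (px - 1L) %/% nrow(x) + 1L
    centers <- rbind(centers, c(mean(rows), mean(cols)))
  }
  rownames(centers) <- NULL
  list(centers = centers, areas = areas[keep], mask = out)
}

#' Seeded-watershed segmentation of the cell cytoplasm
#'
#' The reporter channel is Gaussian-smoothed (`sigma`), the foreground is
#' taken as the pixels above the global Otsu threshold of the smoothed
#' channel, and a marker-controlled watershed is run on the Sobel gradient
#' magnitude of the smoothed channel, flooding one basin per nucleus seed
#' and restricted to the foreground.  Ties on gradient plateaus are broken
#' deterministically by queue insertion order.
#'
#' Before the Otsu threshold is computed the intensities are capped at
#' their 95th percentile: the rare, very bright punctum pixels otherwise
#' dominate the between-class variance and push the threshold above the
#' diffuse cytoplasm level.  The threshold is still applied to the uncapped
#' smoothed channel.
#'
#' @param reporter_channel Numeric matrix (normalized internally).
#' @param seeds n x 2 matrix of seed centroids (row, col), e.g. from
#'   [detect_nuclei()], or the list returned by [detect_nuclei()].
#' @param sigma Gaussian smoothing sd in pixels (default 2).
#' @param seed_radius Radius of the disk stamped around each seed centroid
#'   to initialise its basin.
#' @return List (`segmentation_result`): `label_map` (integer matrix, 0 =
#'   background, k = cell k), `n_cells`, and `seed_of` (n x 2 matrix of the
#'   seed centroid per label).
#' @export
segment_cytoplasm <- function(reporter_channel, seeds, sigma = 2,
                              seed_radius = 3L) {
  if (is.list(seeds)) seeds <- seeds$centers
  if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 2L)
  if (!nrow(seeds)) stop("no seeds supplied")
  x <- normalize_image(reporter_channel)
  sm <- as.matrix(EBImage::gblur(x, sigma = sigma))
  cap <- stats::quantile(sm, 0.95)
  smc <- pmin(pmax(sm, 0), cap)
  th <- if (cap > 0) EBImage::otsu(EBImage::Image(smc / cap)) * cap else 0
  fg <- sm > th
  if (!any(fg)) stop("empty foreground: no cytoplasm above Otsu threshold")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L) / 8
  gx <- as.matrix(EBImage::filter2(sm, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(sm, t(kx), boundary = "replicate"))
  grad <- sqrt(gx^2 + gy^2)
  seed_lab <- matrix(0L, nrow(x), ncol(x))
  for (k in seq_len(nrow(seeds)))
    seed_lab[.disk_pixels(seeds[k, ], seed_radius, dim(x))] <- k
  lost <- setdiff(seq_len(nrow(seeds)), unique(seed_lab[fg & seed_lab > 0L]))
  if (length(lost))
    warning("seed(s) outside the foreground yield empty regions: ",
            paste(lost, collapse = ", "))
  labels <- seeded_watershed_cpp(grad, seed_lab, fg)
  list(label_map = labels, n_cells = nrow(seeds), seed_of = seeds)
}

#' Detect puncta in a binary mask and assign them to cells
#'
#' Particles are the connected components of the mask, optionally separated
#' by an intensity watershed first (the equivalent of the binary watershed
#' step applied before particle counting in interactive image-analysis
#' workflows): when `intensity` is supplied, each mask component is split
#' into one particle per intensity peak deeper than `split_tolerance`, so
#' touching puncta are counted individually.  Particles are then filtered
#' by area and each retained particle is assigned to the cell whose label
#' covers its (unweighted) centroid pixel; particles whose centroid falls
#' on background are discarded and tallied.
#'
#' @param mask Logical matrix from [phansalkar_threshold()].
#' @param labels A segmentation result from [segment_cytoplasm()] or a plain
#'   integer label matrix.
#' @param min_area,max_area Particle area bounds in pixels (inclusive).
#' @param intensity Optional intensity surface (same shape as `mask`) used
#'   to split touching particles at intensity saddles; `NULL` disables
#'   splitting.
#' @param split_tolerance Minimum peak prominence (intensity units) for a
#'   peak to found its own particle during splitting.
#' @param threshold_map Optional per-pixel threshold map (e.g. from
#'   [phansalkar_threshold_map()]).  When given together with `intensity`,
#'   a particle is kept only if its intensity peak rises at least
#'   `split_tolerance` above the local threshold, which rejects particles
#'   that barely crossed the threshold on noise.
#' @return List (`puncta_result`): `per_cell_counts` (named integer vector
#'   over labels 1..n_cells), `discarded_background`, and `puncta_records`
#'   (data frame `row`, `col`, `area`, `cell`; `cell` 0 = discarded).
#' @export
detect_and_assign_puncta <- function(mask, labels, min_area = 2L,
                                     max_area = 100L, intensity = NULL,
                                     split_tolerance = 0.1,
                                     threshold_map = NULL) {
  label_map <- if (is.list(labels)) labels$label_map else labels
  n_cells <- if (is.list(labels)) labels$n_cells else max(label_map)
  if (!all(dim(mask) == dim(label_map)))
    stop("mask and label map have different shapes")
  if (is.null(intensity)) {
    comp <- EBImage::bwlabel(mask)
  } else {
    if (!all(dim(intensity) == dim(mask)))
      stop("intensity and mask have different shapes")
    surf <- intensity
    surf[!mask] <- 0
    comp <- EBImage::watershed(EBImage::Image(surf),
                               tolerance = split_tolerance, ext = 1L)
  }
  comp <- matrix(as.integer(comp), nrow(mask), ncol(mask))
  areas <- tabulate(comp)
  keep <- which(areas >= min_area & areas <= max_area)
  if (!is.null(threshold_map) && !is.null(intensity) && length(keep)) {
    px <- which(comp %in% keep)
    excess <- tapply(intensity[px] - threshold_map[px],
                     factor(comp[px], levels = keep), max)
    keep <- keep[!is.na(excess) & excess >= split_tolerance]
  }
  recs <- data.frame(row = numeric(0), col = numeric(0), area = integer(0),
                     cell = integer(0))
  if (length(keep)) {
    px <- which(comp %in% keep)
    rows <- (px - 1L) %% nrow(mask) + 1L
    cols <- (px - 1L) %/% nrow(mask) + 1L
    id <- factor(comp[px], levels = keep)
    cr <- tapply(rows, id, mean)
    cc <- tapply(cols, id, mean)
    cell <- label_map[cbind(pmin(pmax(round(cr), 1L), nrow(mask)),
                            pmin(pmax(round(cc), 1L), ncol(mask)))]
    recs <- data.frame(row = as.numeric(cr), col = as.numeric(cc),
                       area = areas[keep], cell = as.integer(cell))
    rownames(recs) <- NULL
  }
  counts <- tabulate(recs$cell[recs$cell > 0L], nbins = n_cells)
  names(counts) <- as.character(seq_len(n_cells))
  list(per_cell_counts = counts,
       discarded_background = sum(recs$cell == 0L),
       puncta_records = recs)
}

#' Full puncta-per-cell quantification pipeline
#'
#' Runs nucleus detection, seeded-watershed cytoplasm segmentation,
#' Gaussian pre-smoothing plus Phansalkar thresholding of the reporter
#' channel, and particle detection/assignment.  Deterministic for a fixed
#' input image.
#'
#' Two smoothing scales are used on the reporter channel: the binarization
#' mask comes from a strongly smoothed copy (`presmooth_sigma`), which
#' suppresses pixel noise below the Phansalkar margin, while touching
#' particles are separated on a lightly smoothed copy (`split_sigma`) that
#' preserves the intensity saddle between nearby spots.
#'
#' The mask is cleaned by a small morphological opening (`open_size`)
#' before particle analysis, which removes speckle and thin bridges that
#' would otherwise inflate watershed basins.  The effective split tolerance
#' is never taken below 5 times the estimated noise standard deviation of
#' the split surface (pixel noise is estimated robustly from the residual
#' of the reporter channel against its smoothed copy over the segmented
#' cytoplasm), so noise maxima neither split the mask nor pass the
#' prominence test.
#'
#' A cell whose Phansalkar mask covers more than `max_mask_fraction` of its
#' cytoplasm is flagged as having no countable discrete foci and reports a
#' count of zero: on an image without localized bright objects, min-max
#' normalization stretches noise over the full intensity scale, the
#' threshold margin turns negative over the diffuse signal, and the mask
#' degenerates to (nearly) all-foreground — the formula's documented
#' behaviour on constant bright regions, not evidence of puncta.  Flagged
#' cells are listed in the `qc` element of the result.
#'
#' @param image rows x cols x channels array (e.g. from
#'   [read_image_tiff()] or [gen_cell_image()]).
#' @param nuclei_channel,reporter_channel Channel indices (1-based).
#' @param params [phansalkar_params()] for the binarization.
#' @param presmooth_sigma Gaussian sd (px) applied to the reporter channel
#'   before thresholding, to suppress pixel noise at spot scale.
#' @param split_sigma Gaussian sd (px) of the surface used to split
#'   touching particles at intensity saddles (0 disables splitting).
#' @param split_tolerance Peak prominence required to found a particle
#'   during splitting (normalized intensity units).
#' @param seg_sigma Smoothing sd for the cytoplasm segmentation surface.
#' @param min_area,max_area Particle area bounds (px).
#' @param nucleus_min_area Minimum nucleus component area (px).
#' @param max_mask_fraction Largest tolerated fraction of a cell's
#'   cytoplasm covered by the puncta mask before the cell is flagged as
#'   having no countable foci (see Details).
#' @param open_size Diameter (px) of the disc used to morphologically open
#'   the mask before particle analysis (0 disables).
#' @return List with `segmentation` ([segment_cytoplasm()] result), `mask`
#'   (binary puncta mask), `puncta` ([detect_and_assign_puncta()] result),
#'   `per_cell_counts` for convenience, and `qc` (per-cell mask coverage
#'   and the labels of flagged cells).
#' @export
quantify_puncta <- function(image, nuclei_channel = 1L, reporter_channel = 2L,
                            params = phansalkar_params(),
                            presmooth_sigma = 2.5, split_sigma = 1,
                            split_tolerance = 0.1, seg_sigma = 2,
                            min_area = 2L, max_area = 100L,
                            nucleus_min_area = 50L,
                            max_mask_fraction = 0.5, open_size = 3L) {
  nuc <- normalize_image(image[, , nuclei_channel])
  rep_ch <- normalize_image(image[, , reporter_channel])
  seeds <- detect_nuclei(nuc, min_area = nucleus_min_area)
  if (!nrow(seeds$centers))
    return(list(segmentation = NULL, mask = NULL,
                puncta = list(per_cell_counts = integer(0),
                              discarded_background = 0L,
                              puncta_records = NULL),
                per_cell_counts = integer(0)))
  seg <- segment_cytoplasm(rep_ch, seeds, sigma = seg_sigma)
  blur <- function(s) if (s > 0)
    pmin(pmax(as.matrix(EBImage::gblur(rep_ch, sigma = s)), 0), 1)
  else rep_ch
  mask_surf <- blur(presmooth_sigma)
  tmap <- phansalkar_threshold_map(mask_surf, params)
  mask <- mask_surf > tmap
  if (open_size > 0) {
    op <- EBImage::opening(mask, EBImage::makeBrush(as.integer(open_size),
                                                    shape = "disc"))
    mask <- matrix(as.integer(op) > 0, nrow(mask), ncol(mask))
  }
  split_surf <- if (split_sigma > 0) blur(split_sigma) else NULL
  # robust pixel-noise estimate (residual over the cytoplasm) -> noise sd
  # on the split surface
  cyto_px <- seg$label_map > 0L
  sigma_raw <- if (any(cyto_px))
    stats::mad(rep_ch[cyto_px] - mask_surf[cyto_px]) else 0
  sigma_split <- sigma_raw / (2 * max(split_sigma, 0.5) * sqrt(pi))
  tol_eff <- max(split_tolerance, 5 * sigma_split)
  pr <- detect_and_assign_puncta(mask, seg, min_area = min_area,
                                 max_area = max_area,
                                 intensity = split_surf,
                                 split_tolerance = tol_eff,
                                 threshold_map = tmap)
  mask_frac <- vapply(seq_len(seg$n_cells), function(k) {
    px <- seg$label_map == k
    if (any(px)) mean(mask[px]) else 0
  }, numeric(1))
  flagged <- which(mask_frac > max_mask_fraction)
  if (length(flagged)) {
    drop <- pr$puncta_records$cell %in% flagged
    pr$puncta_records <- pr$puncta_records[!drop, , drop = FALSE]
    pr$per_cell_counts[flagged] <- 0L
  }
  list(segmentation = seg, mask = mask, puncta = pr,
       per_cell_counts = pr$per_cell_counts,
       qc = list(mask_fraction = mask_frac, flagged_cells = flagged,
                 split_tolerance = tol_eff))
}

#' Match detected puncta against ground truth
#'
#' A detection counts as correct when a true punctum lies within
#' `tolerance` pixels of its centroid; a true punctum counts as recovered
#' when some detection lies within `tolerance`.  Matching is
#' nearest-within-radius (not one-to-one), so two spots merged into a
#' single detected particle still count as recovered.
#'
#' @param detected Data frame with `row`, `col` (e.g. `puncta_records`).
#' @param truth Data frame with `row`, `col` (e.g. generator truth).
#' @param tolerance Matching radius in pixels.
#' @return List with `precision`, `recall`, `n_detected`, `n_true`.
#' @export
evaluate_puncta <- function(detected, truth, tolerance = 3) {
  n_d <- nrow(detected); n_t <- nrow(truth)
  if (n_d == 0L || n_t == 0L)
    return(list(precision = if (n_d) 0 else NA_real_,
                recall = if (n_t) 0 else NA_real_,
                n_detected = n_d, n_true = n_t))
  d2 <- outer(detected$row, truth$row, "-")^2 +
    outer(detected$col, truth$col, "-")^2
  list(precision = mean(apply(d2, 1L, min) <= tolerance^2),
       recall = mean(apply(d2, 2L, min) <= tolerance^2),
       n_detected = n_d, n_true = n_t)
}

#' Compare puncta counts between conditions
#'
#' Two-sided unpaired t-test on per-replicate mean counts (not pooled
#' cells), mirroring a design where each replicate contributes one mean
#' puncta-per-cell value.
#'
#' @param counts_by_condition Named list of two numeric vectors of
#'   per-replicate means, each of length >= 2.
#' @param var_equal Use the classical equal-variance t statistic (default).
#' @return List with `means` (named), `difference` (first minus second),
#'   `t`, `df` and `p_value`.
#' @export
compare_conditions <- function(counts_by_condition, var_equal = TRUE) {
  if (length(counts_by_condition) != 2L)
    stop("exactly two conditions are required")
  if (any(vapply(counts_by_condition, length, 1L) < 2L))
    stop("at least 2 replicates per condition are required")
  a <- counts_by_condition[[1L]]; b <- counts_by_condition[[2L]]
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate limit: identical replicates within each group
    same <- mean(a) == mean(b)
    tt <- list(statistic = if (same) 0 else Inf * sign(mean(a) - mean(b)),
               parameter = length(a) + length(b) - 2L,
               p.value = if (same) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
  }
  list(means = stats::setNames(c(mean(a), mean(b)),
                               names(counts_by_condition)),
       difference = mean(a) - mean(b),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
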