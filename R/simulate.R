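# Synthetic-data generators: SILAC quantification tables, motif-bearing
# protein sequences, and two-channel benchmark cell images, each with full
# ground truth so every downstream stage can be validated against planted
# values.

# run expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a SILAC protein quantification table with planted regulation
#'
#' Each protein receives a true log2 effect (0 for "null" proteins;
#' magnitude drawn uniformly from `effect_range` with the planted sign for
#' "up"/"down" proteins) and `n_replicates` replicate log2-ratios drawn
#' around that effect with standard deviation `rep_sd`.  The reported linear
#' ratio is `2^mean(log2 replicates)` and the p-value is a two-sided
#' one-sample t-test of the replicates against 0, so ratio and p-value are
#' jointly realistic.  With `rep_sd = 0` the ratio equals `2^effect` exactly
#' and the p-value is set to 0 for non-null and 1 for null proteins (the
#' degenerate-noise limit of the t-test).
#'
#' A fraction of proteins is given single-peptide identifications and
#' non-"high" confidence tiers so that the identification-quality filters
#' have something to remove; set `frac_single_peptide = 0` and
#' `frac_high = 1` to generate tables where only ratio and p-value decide
#' the outcome.
#'
#' @param n_proteins Number of proteins.
#' @param frac_up,frac_down Fractions of planted up-/downregulated proteins
#'   (`frac_up + frac_down <= 1`).
#' @param n_replicates Replicates per protein (>= 2; default 3, matching a
#'   technical-triplicate design).
#' @param rep_sd Replicate standard deviation in log2 units.
#' @param seed Integer seed (RNG state is restored on exit).
#' @param treatment Treatment label (`"PA"` or `"SA"`).
#' @param effect_range Range of |true log2 effect| for regulated proteins;
#'   the default `c(1, 3)` plants at least two-fold changes.
#' @param frac_high Fraction of proteins with "high" FDR confidence.
#' @param frac_single_peptide Fraction identified by a single peptide.
#' @return List with `records` (data frame as in [read_quant_table()], plus
#'   the replicate log2-ratios as a `"replicates"` attribute) and `truth`
#'   (data frame `protein_id`, `planted_label`, `true_log2_effect`).
#' @export
gen_quant_table <- function(n_proteins, frac_up = 0.2, frac_down = 0.2,
                            n_replicates = 3L, rep_sd = 0.2, seed = NULL,
                            treatment = "PA", effect_range = c(1, 3),
                            frac_high = 0.9, frac_single_peptide = 0.05) {
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1)
    stop("invalid fractions: frac_up + frac_down must be <= 1")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  stopifnot(effect_range[1] >= 1, rep_sd >= 0)
  .with_seed(seed, {
    n_up <- round(n_proteins * frac_up)
    n_down <- round(n_proteins * frac_down)
    label <- sample(rep(c("up", "down", "null"),
                        c(n_up, n_down, n_proteins - n_up - n_down)))
    effect <- numeric(n_proteins)
    effect[label == "up"] <- stats::runif(n_up, effect_range[1], effect_range[2])
    effect[label == "down"] <- -stats::runif(n_down, effect_range[1],
                                             effect_range[2])
    reps <- matrix(stats::rnorm(n_proteins * n_replicates, mean = effect,
                                sd = rep_sd),
                   nrow = n_proteins)
    m <- rowMeans(reps)
    s <- apply(reps, 1L, stats::sd)
    tstat <- m / (s / sqrt(n_replicates))
    p <- 2 * stats::pt(-abs(tstat), df = n_replicates - 1L)
    p[s == 0] <- ifelse(m[s == 0] != 0, 0, 1)
    id <- sprintf("SYN%05d", seq_len(n_proteins))
    records <- data.frame(
      protein_id = id,
      gene_symbol = sprintf("Gene%05d", seq_len(n_proteins)),
      ratio = 2^m,
      p_value = p,
      peptide_count = ifelse(stats::runif(n_proteins) < frac_single_peptide,
                             1L, 2L + stats::rpois(n_proteins, 4)),
      confidence = ifelse(stats::runif(n_proteins) < frac_high, "high",
                          sample(c("medium", "low"), n_proteins,
                                 replace = TRUE)),
      treatment = treatment,
      stringsAsFactors = FALSE)
    attr(records, "replicates") <- reps
    truth <- data.frame(protein_id = id, planted_label = label,
                        true_log2_effect = effect, stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

# residues outside every motif residue class (no F/I/L/V, K/R, D/E, S/T/Y,
# Q), so no accidental KFERQ-like window can form on the background
.SAFE_ALPHABET <- c("A", "G", "M", "P", "W", "C")

# draw one pentapeptide of the requested motif class
.sample_motif_window <- function(class) {
  cl <- kferq_residue_classes()
  h <- sample(1:2, 1L); b <- 3L - h  # hydrophobic/basic counts
  flank <- switch(class,
    "canonical" = ,
    "acetyl" = c(sample(cl$hydrophobic, h, replace = TRUE),
                 sample(cl$basic, b, replace = TRUE),
                 sample(cl$acidic, 1L)),
    "phospho" = ,
    "phospho+acetyl" = c(sample(cl$hydrophobic, h, replace = TRUE),
                         sample(cl$basic, b, replace = TRUE),
                         sample(cl$phospho_mimic, 1L)),
    stop("unknown motif class: ", class))
  anchor <- if (class %in% c("acetyl", "phospho+acetyl")) "K" else "Q"
  flank <- sample(flank)
  if (sample(c(TRUE, FALSE), 1L)) paste(c(anchor, flank), collapse = "")
  else paste(c(flank, anchor), collapse = "")
}

#' Simulate protein sequences with planted KFERQ-like motifs
#'
#' Generates `n_per_class` sequences for each requested class.  The
#' background alphabet is restricted to residues outside every motif residue
#' class (A, G, M, P, W, C), so a sequence contains exactly the planted
#' motif and nothing else; `"none"` sequences carry no insertion.  Each
#' sequence is re-scanned with [scan_sequence()] and resampled until the
#' observed hits equal the planted hits, so the generator self-validates.
#'
#' @param n_per_class Sequences per class.
#' @param classes Subset of `c("canonical", "phospho", "acetyl",
#'   "phospho+acetyl", "none")`.
#' @param length Sequence length (>= 5).
#' @param seed Integer seed (RNG state restored on exit).
#' @return Data frame with `protein_id`, `sequence`, `planted_class`
#'   (`"none"` for motif-free sequences) and `planted_start` (1-based
#'   window start, `NA` for `"none"`).
#' @export
gen_motif_proteins <- function(n_per_class = 20L,
                               classes = c("canonical", "phospho", "acetyl",
                                           "phospho+acetyl", "none"),
                               length = 120L, seed = NULL) {
  classes <- match.arg(classes, several.ok = TRUE)
  if (length < 5L) stop("length must be >= 5 to hold a pentapeptide")
  .with_seed(seed, {
    rows <- list()
    i <- 0L
    for (class in classes) for (k in seq_len(n_per_class)) {
      i <- i + 1L
      id <- sprintf("%s_%03d", gsub("[^a-z]", "", class), k)
      for (try in 1:50) {
        seq <- paste(sample(.SAFE_ALPHABET, length, replace = TRUE),
                     collapse = "")
        if (class == "none") {
          start <- NA_integer_
        } else {
          start <- sample(length - 4L, 1L)
          substr(seq, start, start + 4L) <- .sample_motif_window(class)
        }
        hits <- scan_sequence(seq, id)
        ok <- if (class == "none") nrow(hits) == 0L
        else nrow(hits) == 1L && hits$start == start &&
          hits$motif_class == class
        if (ok) break
        if (try == 50L) stop("self-validation failed for class ", class)
      }
      rows[[i]] <- data.frame(protein_id = id, sequence = seq,
                              planted_class = class, planted_start = start,
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# pixel-set disk mask indices around a center (row, col)
.disk_pixels <- function(center, radius, dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dim[2], ceiling(center[2] + radius))
  rows <- r0:r1; cols <- c0:c1
  g <- expand.grid(row = rows, col = cols)
  keep <- (g$row - center[1])^2 + (g$col - center[2])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  (g$col - 1L) * dim[1] + g$row  # linear indices (column-major)
}

#' Simulate a two-channel benchmark cell image with ground truth
#'
#' Channel 1 contains nuclei as uniform disks; channel 2 contains a faint
#' diffuse cytoplasm signal over each cell disk plus Gaussian reporter
#' puncta of known sub-pixel positions.  Additive Gaussian noise with
#' standard deviation `noise_sd` is applied to both channels and intensities
#' are clipped to \[0, 1\].  The puncta amplitude is `snr * noise_sd`, so
#' `snr` is the peak spot amplitude in units of the noise standard
#' deviation.  Cells are placed by rejection sampling with non-overlapping
#' cytoplasm disks; puncta are placed inside the cytoplasm with a minimum
#' pairwise separation of `min_sep` pixels.
#'
#' @param n_cells Number of cells (0 gives a blank image and empty truth).
#' @param puncta_per_cell Single count or vector of length `n_cells`.
#' @param spot_sigma Gaussian spot standard deviation in pixels.
#' @param snr Peak spot amplitude / noise standard deviation (> 0).
#' @param size Image size `c(rows, cols)`.
#' @param seed Integer seed (RNG state restored on exit).
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param cyto_level Diffuse cytoplasm intensity; kept of the order of the
#'   noise floor, as for a dark non-activated reporter background.
#' @param nucleus_level Nucleus disk intensity in channel 1.
#' @param bg_level Background pedestal in both channels.
#' @param nucleus_radius,cell_radius Disk radii in pixels.
#' @param min_sep Minimum distance between puncta of one cell (default
#'   `4 * spot_sigma`).
#' @param max_tries Placement attempts per cell / punctum before failing.
#' @return List with `image` (rows x cols x 2 array, channel 1 = nuclei,
#'   channel 2 = reporter) and `truth`: `nuclei_centers` (matrix row, col),
#'   `label_map` (integer matrix of true cytoplasm masks, 0 = background),
#'   `puncta` (data frame `cell`, `row`, `col`), and `snr`.
#' @export
gen_cell_image <- function(n_cells, puncta_per_cell = 8L, spot_sigma = 1.5,
                           snr = 10, size = c(512L, 512L), seed = NULL,
                           noise_sd = 0.02, cyto_level = 0.02,
                           nucleus_level = 0.8, bg_level = 0,
                           nucleus_radius = 12, cell_radius = 34,
                           min_sep = 4 * spot_sigma, max_tries = 5000L) {
  if (snr <= 0) stop("snr must be > 0")
  if (length(puncta_per_cell) == 1L)
    puncta_per_cell <- rep(as.integer(puncta_per_cell), n_cells)
  if (n_cells > 0L && length(puncta_per_cell) != n_cells)
    stop("puncta_per_cell must have length 1 or n_cells")
  .with_seed(seed, {
    dim <- as.integer(size)
    ch1 <- matrix(bg_level, dim[1], dim[2])
    ch2 <- matrix(bg_level, dim[1], dim[2])
    label_map <- matrix(0L, dim[1], dim[2])
    # place cell centers with disjoint cytoplasm disks; a dead-end layout
    # (earlier cells blocking all remaining room) is restarted wholesale
    centers <- NULL
    for (restart in seq_len(20L)) {
      centers <- matrix(numeric(0), 0L, 2L)
      for (k in seq_len(n_cells)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cand <- c(stats::runif(1, cell_radius + 1, dim[1] - cell_radius),
                    stats::runif(1, cell_radius + 1, dim[2] - cell_radius))
          if (!nrow(centers) ||
              min(sqrt((centers[, 1] - cand[1])^2 +
                       (centers[, 2] - cand[2])^2)) > 2 * cell_radius + 1) {
            centers <- rbind(centers, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) break
      }
      if (nrow(centers) == n_cells) break
    }
    if (is.null(centers) || nrow(centers) < n_cells)
      stop("could not place ", n_cells, " non-overlapping cells in a ",
           dim[1], "x", dim[2], " image")
    puncta <- data.frame(cell = integer(0), row = numeric(0), col = numeric(0))
    amp <- snr * noise_sd
    for (k in seq_len(n_cells)) {
      ctr <- centers[k, ]
      ch1[.disk_pixels(ctr, nucleus_radius, dim)] <- nucleus_level
      cyto <- .disk_pixels(ctr, cell_radius, dim)
      label_map[cyto] <- k
      ch2[cyto] <- ch2[cyto] + cyto_level
      # puncta inside the cytoplasm, pairwise separation >= min_sep
      pts <- matrix(numeric(0), 0L, 2L)
      for (j in seq_len(puncta_per_cell[k])) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          a <- stats::runif(1, 0, 2 * pi)
          r <- sqrt(stats::runif(1)) * (cell_radius - 3)
          cand <- ctr + r * c(cos(a), sin(a))
          if (!nrow(pts) ||
              min(sqrt((pts[, 1] - cand[1])^2 +
                       (pts[, 2] - cand[2])^2)) >= min_sep) {
            pts <- rbind(pts, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place ", puncta_per_cell[k],
                      " puncta with separation ", min_sep, " in cell ", k)
      }
      if (nrow(pts))
        puncta <- rbind(puncta, data.frame(cell = k, row = pts[, 1],
                                           col = pts[, 2]))
      # render Gaussian spots in a local window
      w <- ceiling(4 * spot_sigma)
      for (j in seq_len(nrow(pts))) {
        rows <- max(1L, floor(pts[j, 1] - w)):min(dim[1], ceiling(pts[j, 1] + w))
        cols <- max(1L, floor(pts[j, 2] - w)):min(dim[2], ceiling(pts[j, 2] + w))
        d2 <- outer((rows - pts[j, 1])^2, (cols - pts[j, 2])^2, "+")
        ch2[rows, cols] <- ch2[rows, cols] + amp * exp(-d2 / (2 * spot_sigma^2))
      }
    }
    ch1 <- ch1 + matrix(stats::rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
    ch2 <- ch2 + matrix(stats::rnorm(prod(dim), 0, noise_sd), dim[1], dim[2])
    img <- array(c(pmin(pmax(ch1, 0), 1), pmin(pmax(ch2, 0), 1)),
                 dim = c(dim[1], dim[2], 2L))
    rownames(centers) <- NULL
    list(image = img,
         truth = list(nuclei_centers = centers, label_map = label_map,
                      puncta = puncta, snr = snr))
  })
}

#' Write a quantification table as a Proteome Discoverer-style TSV
#'
#' @param records Records from [gen_quant_table()] or [read_quant_table()].
#' @param path Output TSV path.
#' @param column_map Header mapping as in [pd_column_map()].
#' @return Invisibly, `path`.
#' @export
write_quant_table <- function(records, path, column_map = pd_column_map()) {
  out <- records[, names(column_map)]
  names(out) <- unname(column_map)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write synthetic protein sequences as FASTA
#'
#' @param proteins Data frame from [gen_motif_proteins()].
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_proteins_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(stats::setNames(proteins$sequence,
                                                  proteins$protein_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write / read a two-channel image as multi-page TIFF
#'
#' @param image rows x cols x channels array with values in \[0, 1\].
#' @param path TIFF path.
#' @return `write_image_tiff` invisibly returns `path`; `read_image_tiff`
#'   returns a rows x cols x channels array.
#' @export
write_image_tiff <- function(image, path) {
  pages <- lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
  array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
}

#' Write ground truth as a JSON sidecar file
#'
#' @param truth Truth object from a generator.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
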