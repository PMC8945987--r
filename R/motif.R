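# KFERQ-like motif scanning and classification.
#
# A KFERQ-like motif is a pentapeptide targeting signal recognised by HSC70
# for lysosomal delivery via LAMP2A.  The canonical composition rule used
# here: a glutamine (Q) anchor at either end of the window, with the four
# flanking residues made up of 1-2 hydrophobic (F/I/L/V), 1-2 basic (K/R)
# and exactly 1 acidic (D/E) residue.  Non-canonical classes arise by
# post-translational "activation": a phosphorylatable S/T/Y can stand in for
# the acidic residue (phospho-activated), and an acetylated terminal lysine
# can stand in for the Q anchor (acetyl-activated); a window may require both
# modifications at once (phospho+acetyl).

.AA <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

#' Residue classes used by the KFERQ-like motif rule
#'
#' @return Named list of character vectors: `hydrophobic` (F, I, L, V),
#'   `basic` (K, R), `acidic` (D, E), `phospho_mimic` (S, T, Y — can act as
#'   acidic when phosphorylated), `anchor` (Q) and `acetyl_anchor` (K — can
#'   act as the Q anchor when acetylated).
#' @export
kferq_residue_classes <- function() {
  list(hydrophobic   = c("F", "I", "L", "V"),
       basic         = c("K", "R"),
       acidic        = c("D", "E"),
       phospho_mimic = c("S", "T", "Y"),
       anchor        = "Q",
       acetyl_anchor = "K")
}

# per-code 0/1 class indicators, indexed by position in .AA
.cls <- local({
  cl <- list(h = c("F","I","L","V"), b = c("K","R"),
             a = c("D","E"), s = c("S","T","Y"))
  lapply(cl, function(x) as.integer(.AA %in% x))
})
.Q_CODE <- match("Q", .AA)
.K_CODE <- match("K", .AA)

.MOTIF_CLASSES <- c("canonical", "phospho", "acetyl", "phospho+acetyl")

# windows (character vector of 5-mers) -> n x 5 integer code matrix
.window_codes <- function(windows) {
  if (any(nchar(windows) != 5L))
    stop("pentapeptide windows must have exactly 5 residues")
  m <- matrix(match(unlist(strsplit(windows, "", fixed = TRUE)), .AA),
              ncol = 5L, byrow = TRUE)
  m
}

# n x 5 code matrix -> integer class: 1 canonical, 2 phospho, 3 acetyl,
# 4 phospho+acetyl, 0 none.  NA codes (nonstandard residues) give NA.
.classify_codes <- function(idx) {
  n <- nrow(idx)
  bad <- rowSums(is.na(idx)) > 0L
  if (any(bad)) idx[bad, ] <- 1L  # classify dummies, blank out later

  count_excl <- function(v) {
    sc <- matrix(v[idx], nrow = n)
    tot <- rowSums(sc)
    list(e1 = tot - sc[, 1L], e5 = tot - sc[, 5L])
  }
  H <- count_excl(.cls$h); B <- count_excl(.cls$b)
  A <- count_excl(.cls$a); S <- count_excl(.cls$s)
  qa <- cbind(idx[, 1L] == .Q_CODE, idx[, 5L] == .Q_CODE)
  ka <- cbind(idx[, 1L] == .K_CODE, idx[, 5L] == .K_CODE)

  comp_can <- function(h, b, a, s) h >= 1L & h <= 2L & b >= 1L & b <= 2L &
    a == 1L & s == 0L & (h + b + a) == 4L
  comp_pho <- function(h, b, a, s) h >= 1L & h <= 2L & b >= 1L & b <= 2L &
    a == 0L & s == 1L & (h + b) == 3L

  can <- (qa[, 1L] & comp_can(H$e1, B$e1, A$e1, S$e1)) |
         (qa[, 2L] & comp_can(H$e5, B$e5, A$e5, S$e5))
  pho <- (qa[, 1L] & comp_pho(H$e1, B$e1, A$e1, S$e1)) |
         (qa[, 2L] & comp_pho(H$e5, B$e5, A$e5, S$e5))
  # for an acetyl anchor the terminal K stops counting as a basic flanker
  ace <- (ka[, 1L] & comp_can(H$e1, B$e1, A$e1, S$e1)) |
         (ka[, 2L] & comp_can(H$e5, B$e5, A$e5, S$e5))
  dua <- (ka[, 1L] & comp_pho(H$e1, B$e1, A$e1, S$e1)) |
         (ka[, 2L] & comp_pho(H$e5, B$e5, A$e5, S$e5))

  out <- integer(n)
  out[dua] <- 4L
  out[ace] <- 3L
  out[pho] <- 2L
  out[can] <- 1L
  out[bad] <- NA_integer_
  out
}

#' Classify pentapeptide windows into KFERQ-like motif classes
#'
#' Applies the composition rule for CMA-targeting motifs.  A window is
#' `"canonical"` when a Q anchor sits at either end and the four flanking
#' residues comprise 1-2 hydrophobic (F/I/L/V), 1-2 basic (K/R) and exactly
#' one acidic (D/E) residue.  It is `"phospho"` when not canonical but
#' treating exactly one flanking S/T/Y as acidic completes the rule,
#' `"acetyl"` when treating a terminal K as the Q anchor completes it, and
#' `"phospho+acetyl"` when both relaxations are needed at once.  Priority is
#' canonical > phospho > acetyl > phospho+acetyl > `"none"`.
#'
#' @param windows Character vector of 5-residue windows (standard one-letter
#'   amino-acid codes).
#' @return Character vector, one of `"canonical"`, `"phospho"`, `"acetyl"`,
#'   `"phospho+acetyl"`, `"none"` per window.
#' @examples
#' classify_pentapeptide(c("KFERQ", "KFSRQ", "KFERK", "KFSRK", "AAAAA"))
#' @export
classify_pentapeptide <- function(windows) {
  windows <- toupper(as.character(windows))
  idx <- .window_codes(windows)
  if (anyNA(idx))
    stop("nonstandard residue in window(s): ",
         paste(unique(windows[rowSums(is.na(idx)) > 0L]), collapse = ", "))
  cls <- .classify_codes(idx)
  c("none", .MOTIF_CLASSES)[cls + 1L]
}

# anchor end and required modifications for one classified window.
# Positions are 1-based offsets within the window; the N-terminal anchor is
# preferred when both ends qualify.
.hit_details <- function(window, cls) {
  res <- strsplit(window, "", fixed = TRUE)[[1]]
  classes <- kferq_residue_classes()
  cnt <- function(fl, set) sum(fl %in% set)
  comp <- function(fl, phospho) {
    h <- cnt(fl, classes$hydrophobic); b <- cnt(fl, classes$basic)
    a <- cnt(fl, classes$acidic);      s <- cnt(fl, classes$phospho_mimic)
    if (phospho) h >= 1 && h <= 2 && b >= 1 && b <= 2 && a == 0 && s == 1
    else         h >= 1 && h <= 2 && b >= 1 && b <= 2 && a == 1 && s == 0
  }
  anchors <- c(1L, 5L)
  need_k  <- cls %in% c("acetyl", "phospho+acetyl")
  need_s  <- cls %in% c("phospho", "phospho+acetyl")
  for (a in anchors) {
    anchor_res <- if (need_k) "K" else "Q"
    if (res[a] != anchor_res) next
    fl <- res[-a]
    if (!comp(fl, need_s)) next
    mods <- character(0)
    if (need_s) {
      sty <- setdiff(which(res %in% classes$phospho_mimic), a)[1L]
      mods <- c(mods, sprintf("phospho@%d", sty))
    }
    if (need_k) mods <- c(mods, sprintf("acetyl@%d", a))
    return(list(anchor_end = if (a == 1L) "N" else "C",
                mods = paste(mods, collapse = ",")))
  }
  stop("internal error: no anchor found for classified window ", window)
}

#' Scan a protein sequence for KFERQ-like motifs
#'
#' Evaluates every 5-residue window of the sequence with
#' [classify_pentapeptide()].  Overlapping hits are allowed.  Windows
#' containing nonstandard residues (e.g. X, U) are skipped when
#' `nonstandard = "skip"` (the default) or raise an error.
#'
#' @param sequence Single amino-acid string, length >= 5.
#' @param protein_id Identifier carried into the result.
#' @param nonstandard `"skip"` or `"error"`.
#' @return A data frame with one row per hit: `protein_id`, `start` (1-based
#'   offset of the window), `window`, `motif_class`, `anchor_end` (`"N"` or
#'   `"C"`), and `required_mods` (comma-separated `modification@offset`
#'   entries with offsets 1-based within the window; empty for canonical
#'   motifs).
#' @examples
#' scan_sequence("MKFERQAAAA", "demo")
#' @export
scan_sequence <- function(sequence, protein_id = "protein",
                          nonstandard = c("skip", "error")) {
  nonstandard <- match.arg(nonstandard)
  sequence <- toupper(as.character(sequence)[1L])
  n <- nchar(sequence)
  if (n < 5L) stop("sequence shorter than 5 residues")
  starts <- seq_len(n - 4L)
  windows <- substring(sequence, starts, starts + 4L)
  idx <- .window_codes(windows)
  if (anyNA(idx) && nonstandard == "error")
    stop("nonstandard residue in sequence ", protein_id)
  cls <- .classify_codes(idx)
  hit <- which(!is.na(cls) & cls > 0L)
  if (!length(hit))
    return(data.frame(protein_id = character(0), start = integer(0),
                      window = character(0), motif_class = character(0),
                      anchor_end = character(0), required_mods = character(0),
                      stringsAsFactors = FALSE))
  cls_chr <- .MOTIF_CLASSES[cls[hit]]
  det <- Map(.hit_details, windows[hit], cls_chr)
  data.frame(protein_id = protein_id,
             start = starts[hit],
             window = windows[hit],
             motif_class = cls_chr,
             anchor_end = vapply(det, `[[`, "", "anchor_end"),
             required_mods = vapply(det, `[[`, "", "mods"),
             stringsAsFactors = FALSE)
}

#' Scan a set of protein sequences
#'
#' @param sequences Named character vector of amino-acid sequences, or an
#'   `AAStringSet`.  Sequences shorter than 5 residues yield no hits.
#' @param nonstandard Passed to [scan_sequence()].
#' @return Data frame of hits (see [scan_sequence()]), one block per protein.
#' @export
scan_proteins <- function(sequences, nonstandard = c("skip", "error")) {
  nonstandard <- match.arg(nonstandard)
  if (methods::is(sequences, "XStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("protein", seq_along(sequences))
  res <- lapply(names(sequences), function(id) {
    if (nchar(sequences[[id]]) < 5L) return(NULL)
    scan_sequence(sequences[[id]], id, nonstandard)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- scan_sequence("AAAAA", "x")[0, ]
  rownames(out) <- NULL
  out
}

#' Read a protein FASTA file and scan it for KFERQ-like motifs
#'
#' Accessions are parsed from UniProt-style headers
#' (`sp|ACCESSION|NAME ...` or `tr|ACCESSION|NAME ...`); otherwise the first
#' whitespace-delimited token of the header is used.
#'
#' @param path FASTA file.
#' @inheritParams scan_proteins
#' @return Data frame of hits as in [scan_proteins()].
#' @export
scan_fasta <- function(path, nonstandard = c("skip", "error")) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- parse_fasta_accession(names(seqs))
  scan_proteins(seqs, nonstandard = nonstandard)
}

#' @rdname scan_fasta
#' @param headers Character vector of FASTA header lines (without `>`).
#' @export
parse_fasta_accession <- function(headers) {
  acc <- sub("^(sp|tr)\\|([^|]+)\\|.*$", "\\2", headers)
  first_tok <- sub("\\s.*$", "", headers)
  ifelse(grepl("^(sp|tr)\\|", headers), acc, first_tok)
}

#' Per-protein motif profile and exclusive category
#'
#' Collapses per-window hits to one row per protein.  The exclusive category
#' is used for whole-proteome breakdowns so that category percentages sum to
#' ~100%.  With `fold_dual = TRUE` (default) the dual phospho+acetyl window
#' class counts as evidence of both a phospho- and an acetyl-activated motif
#' before the category is assigned; with `fold_dual = FALSE` it is kept as
#' its own class and surfaces in combination labels.
#'
#' Category mapping: a single class maps to itself (`"canonical"`,
#' `"phospho"`, `"acetyl"`); phospho + acetyl without canonical maps to
#' `"phospho&acetyl"`; canonical together with both others maps to
#' `"all three"`; the remaining combinations are labelled explicitly
#' (`"canonical&phospho"`, `"canonical&acetyl"`, ...).  Proteins without
#' hits map to `"no motif"`.
#'
#' @param hits Hit data frame from [scan_proteins()].
#' @param protein_ids Optional vector of all protein ids to report (so that
#'   proteins with zero hits appear as `"no motif"`); defaults to the ids
#'   present in `hits`.
#' @param fold_dual Fold the dual class into both parent classes (default).
#' @return Data frame with `protein_id`, `class_set` (`"+"`-separated sorted
#'   classes, `""` when none) and `category`.
#' @export
categorize_proteins <- function(hits, protein_ids = NULL, fold_dual = TRUE) {
  if (is.null(protein_ids)) protein_ids <- unique(hits$protein_id)
  sets <- split(hits$motif_class, factor(hits$protein_id, levels = protein_ids))
  rows <- lapply(protein_ids, function(id) {
    cs <- sort(unique(sets[[id]]))
    data.frame(protein_id = id,
               class_set = paste(cs, collapse = "+"),
               category = .category_of(cs, fold_dual),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.category_of <- function(class_set, fold_dual = TRUE) {
  if (!length(class_set)) return("no motif")
  stopifnot(all(class_set %in% .MOTIF_CLASSES))
  if (fold_dual && "phospho+acetyl" %in% class_set)
    class_set <- setdiff(union(class_set, c("phospho", "acetyl")),
                         "phospho+acetyl")
  has <- .MOTIF_CLASSES %in% class_set
  names(has) <- .MOTIF_CLASSES
  if (length(class_set) == 1L) return(class_set)
  if (has["canonical"] && has["phospho"] && has["acetyl"]) return("all three")
  if (has["phospho"] && has["acetyl"] && !has["canonical"])
    return("phospho&acetyl")
  paste(class_set, collapse = "&")
}

#' Motif/regulation breakdown of a filtered protein set
#'
#' Joins per-protein motif profiles with up/down regulation calls and
#' reports the three whole-set summaries used for CMA substrate screens:
#' (i) the percentage of proteins carrying at least one KFERQ-like motif,
#' (ii) among motif-containing proteins, the percentage up- and
#' downregulated, and (iii) the percentage of each exclusive motif category
#' among motif-containing proteins.  Percentages are rounded to integers.
#'
#' @param profiles Data frame from [categorize_proteins()].
#' @param calls Data frame with `protein_id` and `call`
#'   (`"up"`/`"down"`/`"unchanged"`), e.g. from [call_regulation()].
#' @return A list with elements `n_proteins`, `n_with_motif`,
#'   `pct_with_motif`, `regulation` (counts and integer percentages of
#'   up/down among motif-containing proteins) and `categories` (counts and
#'   integer percentages per exclusive category).  When no protein carries a
#'   motif, `regulation` and `categories` are `NULL` and `has_motif_proteins`
#'   is `FALSE`.
#' @export
motif_breakdown <- function(profiles, calls) {
  m <- merge(profiles, calls, by = "protein_id")
  if (!nrow(m)) stop("profiles and calls share no protein_id")
  n <- nrow(m)
  with_motif <- m[m$category != "no motif", , drop = FALSE]
  nm <- nrow(with_motif)
  out <- list(n_proteins = n, n_with_motif = nm,
              pct_with_motif = as.integer(round(100 * nm / n)),
              has_motif_proteins = nm > 0L)
  if (nm == 0L) {
    out$regulation <- NULL
    out$categories <- NULL
    return(out)
  }
  ud <- with_motif[with_motif$call %in% c("up", "down"), , drop = FALSE]
  n_up <- sum(ud$call == "up"); n_down <- sum(ud$call == "down")
  out$regulation <- list(
    n_up = n_up, n_down = n_down,
    pct_up = as.integer(round(100 * n_up / max(nrow(ud), 1L))),
    pct_down = as.integer(round(100 * n_down / max(nrow(ud), 1L))))
  tab <- table(with_motif$category)
  out$categories <- data.frame(
    category = names(tab),
    n = as.integer(tab),
    pct = as.integer(round(100 * as.integer(tab) / nm)),
    stringsAsFactors = FALSE)
  out
}

#' Export gene-symbol lists for STRING network analysis
#'
#' Writes the up- and downregulated gene symbols (optionally restricted to
#' motif-containing proteins) as single-column text files suitable for
#' pasting into the STRING web interface.
#'
#' @param calls Data frame with `protein_id`, `gene_symbol` and `call`.
#' @param path_prefix Output prefix; `<prefix>_up.txt` and
#'   `<prefix>_down.txt` are written.
#' @param profiles Optional profiles from [categorize_proteins()]; when
#'   given, only proteins with `category != "no motif"` are exported.
#' @return Invisibly, a named list of the two file paths.
#' @export
export_string_list <- function(calls, path_prefix, profiles = NULL) {
  stopifnot(all(c("protein_id", "gene_symbol", "call") %in% names(calls)))
  if (!is.null(profiles)) {
    keep <- profiles$protein_id[profiles$category != "no motif"]
    calls <- calls[calls$protein_id %in% keep, , drop = FALSE]
  }
  paths <- list(up = paste0(path_prefix, "_up.txt"),
                down = paste0(path_prefix, "_down.txt"))
  for (dir in names(paths)) {
    genes <- calls$gene_symbol[calls$call == dir]
    genes <- genes[!is.na(genes) & nzchar(genes)]
    writeLines(unique(genes), paths[[dir]])
  }
  invisible(paths)
}

#' Exhaustive census of all pentapeptides by motif class
#'
#' Enumerates all 20^5 = 3,200,000 windows over the standard amino-acid
#' alphabet and tabulates the motif classes assigned by
#' [classify_pentapeptide()].  Useful as a global consistency check of the
#' composition rule (the canonical count has a closed combinatorial form).
#'
#' @return Named integer vector of counts for `canonical`, `phospho`,
#'   `acetyl`, `phospho+acetyl` and `none`.
#' @export
pentapeptide_census <- function() {
  n <- 20L^5L
  k <- 0:(n - 1L)
  idx <- cbind(k %/% 160000L %% 20L, k %/% 8000L %% 20L, k %/% 400L %% 20L,
               k %/% 20L %% 20L, k %% 20L) + 1L
  cls <- .classify_codes(idx)
  counts <- tabulate(cls + 1L, nbins = 5L)
  stats::setNames(counts, c("none", .MOTIF_CLASSES))[c(.MOTIF_CLASSES, "none")]
}
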