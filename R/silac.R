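# SILAC lysosome-proteome filtering and regulation calling.
#
# The pipeline starts from a Proteome Discoverer-style protein
# quantification export (one row per protein, linear treatment/control
# abundance ratio plus a p-value, peptide count and FDR-confidence tier)
# and applies three filters: high-confidence identification with at least
# two peptides, p <= 0.05, and a two-fold change (ratio >= 2 or <= 0.5,
# boundaries inclusive).  Surviving proteins are called up- or
# downregulated by which side of the fold threshold they fall on.

#' Filtering criteria for SILAC quantification tables
#'
#' @param min_peptides Minimum peptide count (default 2, i.e. "more than one
#'   peptide").
#' @param max_p Largest acceptable p-value (default 0.05, inclusive).
#' @param fold_threshold Linear fold-change threshold, applied two-sided:
#'   kept if `ratio >= fold_threshold` or `ratio <= 1/fold_threshold`
#'   (default 2, boundaries inclusive).
#' @param require_confidence Confidence tiers accepted (default `"high"`).
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(min_peptides = 2L, max_p = 0.05,
                            fold_threshold = 2.0,
                            require_confidence = "high") {
  stopifnot(fold_threshold >= 1, max_p > 0, max_p < 1, min_peptides >= 1)
  structure(list(min_peptides = as.integer(min_peptides), max_p = max_p,
                 fold_threshold = fold_threshold,
                 require_confidence = tolower(require_confidence)),
            class = "filter_criteria")
}

#' Default column mapping for Proteome Discoverer protein exports
#'
#' Maps the internal record fields to the column headers of the delimited
#' export.  Override individual entries to match a local export layout.
#'
#' @return Named character vector with entries `protein_id`, `gene_symbol`,
#'   `ratio`, `p_value`, `peptide_count`, `confidence`.
#' @export
pd_column_map <- function() {
  c(protein_id   = "Accession",
    gene_symbol  = "Gene Symbol",
    ratio        = "Abundance Ratio",
    p_value      = "Abundance Ratio P-Value",
    peptide_count = "# Peptides",
    confidence   = "Protein FDR Confidence")
}

#' Read a SILAC protein quantification table
#'
#' Reads a TSV/CSV export, renames columns according to `column_map`, and
#' drops rows whose ratio or p-value cannot be parsed (these are counted in
#' the `"qc"` attribute of the result rather than silently treated as
#' passing downstream filters).
#'
#' @param path Delimited text file; the separator is inferred from the
#'   extension (`.csv` = comma, otherwise tab) unless `sep` is given.
#' @param column_map Named character vector as in [pd_column_map()].
#' @param treatment Label attached to every record (e.g. `"PA"` or `"SA"`).
#' @param sep Optional field separator.
#' @return Data frame of records with columns `protein_id`, `gene_symbol`,
#'   `ratio`, `p_value`, `peptide_count`, `confidence`, `treatment`, and a
#'   `"qc"` attribute (`n_read`, `n_dropped`).
#' @export
read_quant_table <- function(path, column_map = pd_column_map(),
                             treatment = "PA", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (!nrow(raw)) stop("empty table: ", path)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols))
    stop("mapped column(s) not in table: ", paste(missing_cols, collapse = ", "))
  df <- data.frame(
    protein_id = as.character(raw[[column_map[["protein_id"]]]]),
    gene_symbol = as.character(raw[[column_map[["gene_symbol"]]]]),
    ratio = suppressWarnings(as.numeric(raw[[column_map[["ratio"]]]])),
    p_value = suppressWarnings(as.numeric(raw[[column_map[["p_value"]]]])),
    peptide_count = suppressWarnings(
      as.integer(raw[[column_map[["peptide_count"]]]])),
    confidence = tolower(as.character(raw[[column_map[["confidence"]]]])),
    treatment = treatment,
    stringsAsFactors = FALSE)
  ok <- !is.na(df$ratio) & df$ratio > 0 &
    !is.na(df$p_value) & df$p_value >= 0 & df$p_value <= 1 &
    !is.na(df$peptide_count) & df$peptide_count >= 1
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc") <- list(n_read = nrow(df), n_dropped = sum(!ok))
  out
}

#' Apply the SILAC quality and regulation filters
#'
#' Keeps a record iff its confidence tier is accepted, its peptide count is
#' at least `min_peptides`, its p-value is at most `max_p`, and its ratio is
#' beyond the two-sided fold threshold (`>= fold_threshold` or
#' `<= 1/fold_threshold`).  Row order is preserved and the operation is
#' idempotent.
#'
#' @param records Data frame of records (see [read_quant_table()]).
#' @param criteria A [filter_criteria()] object.
#' @return The subset of `records` passing all filters.
#' @export
apply_filters <- function(records, criteria = filter_criteria()) {
  if (!nrow(records)) return(records)
  keep <- tolower(records$confidence) %in% criteria$require_confidence &
    records$peptide_count >= criteria$min_peptides &
    records$p_value <= criteria$max_p &
    (records$ratio >= criteria$fold_threshold |
       records$ratio <= 1 / criteria$fold_threshold)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call up/down regulation from abundance ratios
#'
#' `"up"` if `ratio >= fold_threshold`, `"down"` if
#' `ratio <= 1/fold_threshold`, otherwise `"unchanged"`; boundaries are
#' inclusive, so the two-fold convention satisfies
#' `call(r) == "up"  <=>  call(1/r) == "down"`.
#'
#' @param records Data frame with `protein_id` and positive `ratio`.
#' @param criteria A [filter_criteria()] object.
#' @return Data frame with `protein_id`, `gene_symbol` (if present),
#'   `treatment` (if present) and `call`.
#' @export
call_regulation <- function(records, criteria = filter_criteria()) {
  if (any(records$ratio <= 0)) stop("non-positive ratio")
  call <- ifelse(records$ratio >= criteria$fold_threshold, "up",
                 ifelse(records$ratio <= 1 / criteria$fold_threshold,
                        "down", "unchanged"))
  out <- data.frame(protein_id = records$protein_id, call = call,
                    stringsAsFactors = FALSE)
  for (extra in c("gene_symbol", "treatment"))
    if (extra %in% names(records)) out[[extra]] <- records[[extra]]
  out
}

#' Summarize regulation calls
#'
#' Counts and percentages of up- and downregulated proteins, per treatment
#' when a `treatment` column is present.  Percentages are computed over
#' up + down calls only (proteins inside the fold band are excluded), so
#' `pct_up + pct_down = 100` up to rounding.
#'
#' @param calls Data frame from [call_regulation()].
#' @return Data frame with one row per treatment: `treatment`, `n_up`,
#'   `n_down`, `n_unchanged`, `pct_up`, `pct_down` (integer percentages).
#' @export
summarize_regulation <- function(calls) {
  if (!nrow(calls)) stop("no regulation calls to summarize")
  if (!"treatment" %in% names(calls)) calls$treatment <- "all"
  res <- lapply(split(calls, calls$treatment), function(g) {
    n_up <- sum(g$call == "up"); n_down <- sum(g$call == "down")
    reg <- n_up + n_down
    data.frame(treatment = g$treatment[1L],
               n_up = n_up, n_down = n_down,
               n_unchanged = sum(g$call == "unchanged"),
               pct_up = if (reg) as.integer(round(100 * n_up / reg)) else NA_integer_,
               pct_down = if (reg) as.integer(round(100 * n_down / reg)) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
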