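test_that("reference pentapeptides classify into the expected classes", {
  expect_equal(
    classify_pentapeptide(c("KFERQ", "KFSRQ", "KFERK", "KFSRK",
                            "AAAAA", "QQQQQ", "QFERK")),
    c("canonical", "phospho", "acetyl", "phospho+acetyl",
      "none", "none", "canonical"))
  # anchor may sit at either end
  expect_equal(classify_pentapeptide(c("QRFEK", "QKFSR")),
               c("canonical", "phospho"))
  # nonstandard residues are an error
  expect_error(classify_pentapeptide("KFXRQ"), "nonstandard")
  expect_error(classify_pentapeptide("KFER"), "5 residues")
})

test_that("classifier matches the substitution oracle on random windows", {
  w <- random_anchored_pentapeptides(2000, seed = 42)
  expect_equal(classify_pentapeptide(w),
               vapply(w, oracle_classify, character(1), USE.NAMES = FALSE))
})

test_that("class priority is total and hydrophobic swaps preserve class", {
  w <- random_anchored_pentapeptides(500, seed = 7)
  cls <- classify_pentapeptide(w)
  # substituting one hydrophobic residue for another never changes class
  hyd <- c("F", "I", "L", "V")
  set.seed(8)
  for (i in seq_along(w)) {
    res <- strsplit(w[i], "")[[1]]
    pos <- which(res %in% hyd)
    if (!length(pos)) next
    j <- pos[1L]
    res[j] <- sample(setdiff(hyd, res[j]), 1L)
    expect_identical(classify_pentapeptide(paste(res, collapse = "")), cls[i])
  }
})

test_that("scan_sequence enumerates windows and reports 1-based hits", {
  hits <- scan_sequence("MKFERQAAAA", "p1")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$window, "KFERQ")
  expect_equal(hits$motif_class, "canonical")
  expect_equal(hits$required_mods, "")

  expect_equal(nrow(scan_sequence("QQQQQQQ")), 0L)
  expect_error(scan_sequence("MKQ"), "shorter than 5")

  # phospho hit carries its required modification
  hp <- scan_sequence("AAKFSRQAA", "p2")
  expect_equal(hp$motif_class, "phospho")
  expect_match(hp$required_mods, "^phospho@")
  ha <- scan_sequence("AAKFERKAA", "p3")
  expect_equal(ha$motif_class, "acetyl")
  expect_match(ha$required_mods, "^acetyl@")
})

test_that("hits are shift-equivariant under safe-alphabet padding", {
  base <- "MKFERQAAVKILDEQPW"
  h0 <- scan_sequence(base, "x")
  pad <- paste(rep("AGMPW", 3), collapse = "")
  h1 <- scan_sequence(paste0(pad, base), "x")
  expect_equal(nrow(h0), nrow(h1))
  expect_equal(h1$start, h0$start + nchar(pad))
  expect_equal(h1$window, h0$window)
  expect_equal(h1$motif_class, h0$motif_class)
})

test_that("UniProt accessions are parsed from FASTA headers", {
  expect_equal(parse_fasta_accession(
    c("sp|P12345|NAME_MOUSE some protein", "tr|Q9ABC1|X", "myprot extra")),
    c("P12345", "Q9ABC1", "myprot"))
})

test_that("per-protein categories follow the exclusive mapping", {
  mk <- function(classes) data.frame(protein_id = "p",
                                     motif_class = classes,
                                     stringsAsFactors = FALSE)
  cat_of <- function(classes, ...)
    categorize_proteins(mk(classes), ...)$category
  expect_equal(cat_of("canonical"), "canonical")
  expect_equal(cat_of(c("phospho", "acetyl")), "phospho&acetyl")
  expect_equal(cat_of(c("canonical", "phospho", "acetyl")), "all three")
  expect_equal(cat_of(c("canonical", "phospho")), "canonical&phospho")
  # dual class folds into both parents by default ...
  expect_equal(cat_of("phospho+acetyl"), "phospho&acetyl")
  expect_equal(cat_of(c("canonical", "phospho+acetyl")), "all three")
  # ... but is kept as its own label when folding is off
  expect_equal(cat_of("phospho+acetyl", fold_dual = FALSE), "phospho+acetyl")
  # proteins without hits are "no motif"
  prof <- categorize_proteins(mk("canonical"), protein_ids = c("p", "q"))
  expect_equal(prof$category[prof$protein_id == "q"], "no motif")
})

test_that("motif_breakdown reports the three panels with integer percents", {
  profiles <- data.frame(
    protein_id = sprintf("p%02d", 1:10),
    class_set = "canonical",
    category = c(rep("canonical", 8), "no motif", "no motif"),
    stringsAsFactors = FALSE)
  calls <- data.frame(protein_id = sprintf("p%02d", 1:10),
                      call = rep(c("up", "down"), 5),
                      stringsAsFactors = FALSE)
  bd <- motif_breakdown(profiles, calls)
  expect_equal(bd$n_proteins, 10L)
  expect_equal(bd$n_with_motif, 8L)
  expect_equal(bd$pct_with_motif, 80L)
  expect_equal(bd$regulation$pct_up + bd$regulation$pct_down, 100L)
  expect_equal(sum(bd$categories$pct), 100L)

  # all motif-free: panels (ii)/(iii) are explicit empties, not zeros
  profiles$category <- "no motif"
  bd0 <- motif_breakdown(profiles, calls)
  expect_false(bd0$has_motif_proteins)
  expect_null(bd0$regulation)
  expect_null(bd0$categories)

  expect_error(motif_breakdown(profiles,
                               data.frame(protein_id = "zz", call = "up")),
               "no protein_id")
})

test_that("STRING export writes one gene symbol per line for up and down", {
  calls <- data.frame(protein_id = c("a", "b", "c", "d"),
                      gene_symbol = c("Ide", "Grb10", "Lamp2", "Hspa8"),
                      call = c("up", "down", "up", "unchanged"),
                      stringsAsFactors = FALSE)
  profiles <- data.frame(protein_id = c("a", "b", "c", "d"),
                         category = c("canonical", "phospho", "no motif",
                                      "acetyl"),
                         stringsAsFactors = FALSE)
  prefix <- file.path(withr::local_tempdir(), "string")
  paths <- export_string_list(calls, prefix, profiles = profiles)
  expect_equal(readLines(paths$up), "Ide")       # c is motif-free, dropped
  expect_equal(readLines(paths$down), "Grb10")
})
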