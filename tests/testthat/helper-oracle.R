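# Independent brute-force motif-rule checker used as the test oracle.
# Deliberately implemented by literal substitution-and-recheck (not by
# composition counting, which is what the package's classifier does):
# a window is phospho-activated iff replacing one S/T/Y by an acidic
# residue makes it canonical, acetyl-activated iff replacing a terminal K
# by Q makes it canonical, and dual iff both substitutions are needed.

oracle_is_canonical <- function(res) {
  for (a in c(1L, 5L)) {
    if (res[a] != "Q") next
    fl <- res[-a]
    h <- sum(fl %in% c("F", "I", "L", "V"))
    b <- sum(fl %in% c("K", "R"))
    acid <- sum(fl %in% c("D", "E"))
    if (h >= 1 && h <= 2 && b >= 1 && b <= 2 && acid == 1 &&
        h + b + acid == 4)
      return(TRUE)
  }
  FALSE
}

oracle_classify <- function(window) {
  res <- strsplit(window, "", fixed = TRUE)[[1]]
  if (oracle_is_canonical(res)) return("canonical")
  sty <- which(res %in% c("S", "T", "Y"))
  for (i in sty) {
    r2 <- res; r2[i] <- "D"
    if (oracle_is_canonical(r2)) return("phospho")
  }
  for (a in c(1L, 5L)) {
    if (res[a] != "K") next
    r2 <- res; r2[a] <- "Q"
    if (oracle_is_canonical(r2)) return("acetyl")
  }
  for (a in c(1L, 5L)) {
    if (res[a] != "K") next
    for (i in setdiff(sty, a)) {
      r2 <- res; r2[a] <- "Q"; r2[i] <- "D"
      if (oracle_is_canonical(r2)) return("phospho+acetyl")
    }
  }
  "none"
}

# closed-form count of canonical pentapeptides: anchor at either end, four
# flanking positions holding h hydrophobic, b basic and one acidic residue
# with (h, b) in {(1,2), (2,1)}; multinomial placement times residue choices
closed_form_canonical_count <- function() {
  2 * sum(vapply(list(c(1, 2), c(2, 1)), function(hb) {
    arrangements <- factorial(4) / (factorial(hb[1]) * factorial(hb[2]))
    arrangements * 4^hb[1] * 2^hb[2] * 2
  }, numeric(1)))
}

random_pentapeptides <- function(n, seed) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(aa, 5, replace = TRUE), collapse = ""), character(1))
}

# enriched sampler: half the windows get a Q or K forced onto an end so the
# rare motif classes are actually exercised
random_anchored_pentapeptides <- function(n, seed) {
  w <- random_pentapeptides(n, seed)
  set.seed(seed + 1L)
  force_anchor <- sample(c(TRUE, FALSE), n, replace = TRUE)
  anchor <- sample(c("Q", "K"), n, replace = TRUE)
  at_end <- sample(c(1L, 5L), n, replace = TRUE)
  substr(w[force_anchor], at_end[force_anchor], at_end[force_anchor]) <-
    anchor[force_anchor]
  w
}
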