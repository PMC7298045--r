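# Independent oracles used across the suite. These deliberately re-derive
# results by brute force / closed form and never call the code paths they
# check.

# exhaustive affine-gap global-alignment DP (gap of length L costs
# open + L * ext); tractable for sequences up to a few dozen residues
nw_oracle_score <- function(a, b, open = 11, ext = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62", envir = environment())
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- sub[a[i - 1], b[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# funnel rule evaluated without sorting shortcuts: filter, then scan for the
# best row by explicit pairwise comparison
funnel_oracle <- function(panel, parent_kd, fold = 2) {
  keep <- panel[panel$kd_pM <= fold * parent_kd, , drop = FALSE]
  if (nrow(keep) == 0L) return(NA_character_)
  better <- function(i, j) {
    ei <- keep$epimatrix_hc[i] + keep$epimatrix_lc[i]
    ej <- keep$epimatrix_hc[j] + keep$epimatrix_lc[j]
    if (ei != ej) return(ei < ej)
    if (keep$tagg[i] != keep$tagg[j]) return(keep$tagg[i] > keep$tagg[j])
    if (keep$fab_tm[i] != keep$fab_tm[j]) return(keep$fab_tm[i] > keep$fab_tm[j])
    keep$name[i] < keep$name[j]
  }
  best <- 1L
  for (i in seq_len(nrow(keep))[-1]) if (better(i, best)) best <- i
  keep$name[best]
}

# brute-force per-position rare-residue scan of one chain
rare_scan_oracle <- function(query, germline, profile_tab, threshold = 0.01) {
  stopifnot(length(query) == length(germline))
  count <- 0L
  for (p in seq_along(query)) {
    if (query[p] == germline[p] || query[p] == "X" || germline[p] == "X") next
    f <- profile_tab$frequency[profile_tab$position == p &
                                 profile_tab$residue == query[p]]
    if (length(f) == 1L && f < threshold) count <- count + 1L
  }
  count
}

# independent closed-form three-state signal (re-derived, kept separate from
# the package implementation)
three_state_signal_oracle <- function(c, dG1, m1, dG2, m2, bn, bu, yI,
                                      temperature = 298.15) {
  RT <- 8.314e-3 * temperature
  K1 <- exp(-(dG1 - m1 * c) / RT)
  K2 <- exp(-(dG2 - m2 * c) / RT)
  Z <- 1 + K1 + K1 * K2
  (1 / Z) * (bn[1] + bn[2] * c) + (K1 / Z) * yI +
    (K1 * K2 / Z) * (bu[1] + bu[2] * c)
}

make_parent_panel <- function() {
  p <- parent_sequences()
  list(name = "PCa75", VH = p$VH, VL = p$VL)
}
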