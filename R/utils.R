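#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef predict rnorm sd mad setNames optim approx
#' @importFrom utils read.delim write.table read.csv write.csv head tail
NULL

# gas constant in kJ/(mol K); energies throughout are kJ/mol
.R_KJ <- 8.314e-3

# canonical amino-acid alphabet (one-letter); 'X' tolerated as unknown
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Exponential with a clipped argument
#'
#' Guards equilibrium-constant evaluations against overflow; arguments are
#' clipped to +/-500 before exponentiation.
#' @param x numeric vector.
#' @return `exp(pmin(pmax(x, -500), 500))`
#' @keywords internal
guarded_exp <- function(x) exp(pmin(pmax(x, -500), 500))

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_residues <- function(residues, what = "sequence") {
  if (length(residues) < 1L) stop_input("%s must contain at least one residue", what)
  bad <- setdiff(unique(residues), c(.AA20, "X"))
  if (length(bad) > 0L)
    stop_input("%s contains non-canonical residues: %s", what,
               paste(bad, collapse = ", "))
  invisible(TRUE)
}

# split a sequence string into residues
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# corrected Akaike information criterion from a Gaussian RSS
aicc_from_rss <- function(rss, n, n_par) {
  k <- n_par + 1  # + residual variance
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
}
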