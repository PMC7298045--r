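#' Antibody chain sequence
#'
#' Lightweight container for one variable-domain amino-acid sequence with
#' 1-based sequential numbering.
#'
#' @param id character label.
#' @param chain one of `"heavy"`, `"kappa"`, `"lambda"`.
#' @param residues either a single string or a character vector of one-letter
#'   codes; the 20 canonical amino acids plus `"X"` are allowed.
#' @param region_annotations optional named map position -> region label
#'   (FR1..FR4, CDR1..CDR3).
#' @return object of class `antibody_sequence`.
#' @export
antibody_sequence <- function(id, chain = c("heavy", "kappa", "lambda"),
                              residues, region_annotations = NULL) {
  chain <- match.arg(chain)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- seq_chars(residues)
  check_residues(residues, sprintf("sequence '%s'", id))
  structure(list(id = id, chain = chain, residues = residues,
                 region_annotations = region_annotations),
            class = "antibody_sequence")
}

#' Germline reference sequence
#'
#' @param allele_name non-empty allele label (e.g. `"IGHV3-23*01"`).
#' @inheritParams antibody_sequence
#' @return object of class `germline_reference`.
#' @export
germline_reference <- function(allele_name, chain = c("heavy", "kappa", "lambda"),
                               residues) {
  if (!nzchar(allele_name)) stop_input("allele_name must be non-empty")
  chain <- match.arg(chain)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- seq_chars(residues)
  check_residues(residues, sprintf("germline '%s'", allele_name))
  structure(list(allele_name = allele_name, chain = chain, residues = residues),
            class = "germline_reference")
}

#' @export
print.antibody_sequence <- function(x, ...) {
  cat(sprintf("<antibody_sequence> %s [%s] %d aa\n%s\n",
              x$id, x$chain, length(x$residues),
              paste(x$residues, collapse = "")))
  invisible(x)
}

#' @export
print.germline_reference <- function(x, ...) {
  cat(sprintf("<germline_reference> %s [%s] %d aa\n%s\n",
              x$allele_name, x$chain, length(x$residues),
              paste(x$residues, collapse = "")))
  invisible(x)
}

as_string <- function(x) paste(x$residues, collapse = "")

#' Read antibody sequences from FASTA
#'
#' Record ids are expected to carry the chain class as a suffix token matched
#' by `chain_regex` (default: trailing `_VH`/`_VL`/`_heavy`/`_kappa`/`_lambda`,
#' case-insensitive). VH maps to heavy, VL to kappa unless the id says lambda.
#'
#' @param path FASTA file.
#' @param chain_regex regex with one capture group extracting the chain token.
#' @return list of [antibody_sequence] objects.
#' @export
read_antibody_fasta <- function(path,
                                chain_regex = "_(VH|VL|heavy|kappa|lambda)$") {
  set <- Biostrings::readAAStringSet(path)
  lapply(seq_along(set), function(i) {
    id <- names(set)[i]
    token <- regmatches(id, regexpr(chain_regex, id, ignore.case = TRUE))
    if (length(token) == 0L)
      stop_input("cannot infer chain class from record id '%s'", id)
    token <- toupper(sub("^_", "", token))
    chain <- switch(token, VH = "heavy", HEAVY = "heavy",
                    VL = "kappa", KAPPA = "kappa", LAMBDA = "lambda")
    antibody_sequence(id, chain, as.character(set[[i]]))
  })
}

#' Write antibody sequences to FASTA
#'
#' @param seqs list of [antibody_sequence] or [germline_reference] objects.
#' @param path output file.
#' @export
write_antibody_fasta <- function(seqs, path) {
  strings <- vapply(seqs, as_string, character(1))
  names(strings) <- vapply(seqs, function(s)
    if (inherits(s, "germline_reference")) s$allele_name else s$id,
    character(1))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(strings), path)
  invisible(path)
}
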