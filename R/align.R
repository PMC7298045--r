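#' Global alignment of a variable domain to its germline reference
#'
#' Needleman-Wunsch global alignment (via [Biostrings::pairwiseAlignment])
#' with BLOSUM62 substitution scores and affine gap penalties. Antibody
#' V-domains aligned against their own germline precursor are nearly gap-free,
#' so the scoring scheme has little leverage; it is exposed for completeness.
#'
#' @param query an [antibody_sequence].
#' @param reference a [germline_reference] of the same chain class.
#' @param gap_opening,gap_extension affine gap penalties (positive costs;
#'   a gap of length L costs `gap_opening + L * gap_extension`).
#' @param substitution_matrix name of a substitution matrix known to
#'   Biostrings, default `"BLOSUM62"`.
#' @return object of class `germline_alignment`: aligned query/reference
#'   character vectors (with `"-"` gaps), per-column 1-based query and
#'   reference position maps (`NA` at gaps), and the alignment score.
#' @export
align_to_germline <- function(query, reference,
                              gap_opening = 11, gap_extension = 1,
                              substitution_matrix = "BLOSUM62") {
  stopifnot(inherits(query, "antibody_sequence"),
            inherits(reference, "germline_reference"))
  q_chain <- if (query$chain == "heavy") "heavy" else "light"
  r_chain <- if (reference$chain == "heavy") "heavy" else "light"
  if (q_chain != r_chain)
    stop_input("chain mismatch: query is %s, reference is %s",
               query$chain, reference$chain)
  if (length(query$residues) < 1L || length(reference$residues) < 1L)
    stop_input("empty sequence")

  pa <- Biostrings::pairwiseAlignment(
    pattern = as_string(query), subject = as_string(reference),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension)

  aq <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  ar <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  qpos <- cumsum(aq != "-"); qpos[aq == "-"] <- NA_integer_
  rpos <- cumsum(ar != "-"); rpos[ar == "-"] <- NA_integer_

  structure(list(query = query, reference = reference,
                 aligned_query = aq, aligned_reference = ar,
                 query_pos = as.integer(qpos), ref_pos = as.integer(rpos),
                 score = Biostrings::score(pa)),
            class = "germline_alignment")
}

#' @export
print.germline_alignment <- function(x, ...) {
  cat(sprintf("<germline_alignment> %s vs %s  score %.1f\n",
              x$query$id, x$reference$allele_name, x$score))
  cat("Q: ", paste(x$aligned_query, collapse = ""), "\n", sep = "")
  cat("R: ", paste(x$aligned_reference, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Enumerate somatic hypermutations from a germline alignment
#'
#' One record per mismatch column of the alignment; gap columns and columns
#' involving `'X'` are skipped. Records are ordered by query position.
#'
#' @param alignment a `germline_alignment` from [align_to_germline()].
#' @return data.frame of class `shm_records` with columns `position` (1-based
#'   query numbering), `germline_residue`, `observed_residue`, `region`.
#' @export
identify_shm <- function(alignment) {
  stopifnot(inherits(alignment, "germline_alignment"))
  aq <- alignment$aligned_query
  ar <- alignment$aligned_reference
  keep <- aq != "-" & ar != "-" & aq != ar & aq != "X" & ar != "X"
  pos <- alignment$query_pos[keep]
  regions <- alignment$query$region_annotations
  region_col <- if (is.null(regions)) rep(NA_character_, length(pos))
                else as.character(regions[as.character(pos)])
  out <- data.frame(
    position = pos,
    germline_residue = ar[keep],
    observed_residue = aq[keep],
    region = region_col,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("shm_records", "data.frame")
  out
}

#' Tab-separated alignment report
#'
#' Writes one row per alignment column: query position, germline residue,
#' query residue and a match flag.
#'
#' @param alignment a `germline_alignment`.
#' @param path output path; when `NULL` the data.frame is returned unwritten.
#' @return the report data.frame, invisibly when written.
#' @export
alignment_report <- function(alignment, path = NULL) {
  rep <- data.frame(
    position = alignment$query_pos,
    germline_residue = alignment$aligned_reference,
    query_residue = alignment$aligned_query,
    match = alignment$aligned_query == alignment$aligned_reference,
    stringsAsFactors = FALSE
  )
  if (is.null(path)) return(rep)
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
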