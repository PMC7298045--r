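new_profile <- function(chain, table, n_sequences, partial = FALSE) {
  stopifnot(all(c("position", "residue", "frequency") %in% names(table)))
  if (!"n_obs" %in% names(table)) table$n_obs <- n_sequences
  structure(list(chain = chain, table = table,
                 n_sequences = n_sequences, partial = partial),
            class = "positional_frequency_profile")
}

#' @export
print.positional_frequency_profile <- function(x, ...) {
  cat(sprintf("<positional_frequency_profile> %s chain, %d positions, n = %d%s\n",
              x$chain, length(unique(x$table$position)), x$n_sequences,
              if (x$partial) " (partial fixture)" else ""))
  invisible(x)
}

#' Build a positional amino-acid frequency profile from a repertoire
#'
#' Computes, for every position of a pre-aligned equal-length repertoire, the
#' frequency of each residue among non-gap, non-`X` observations. This is a
#' descriptive count profile: no pseudocounts by default (frequencies are used
#' as rarity evidence, not as probabilistic scores); `pseudocount` adds
#' Laplace smoothing over the 20 canonical residues when set.
#'
#' @param repertoire list of [antibody_sequence] objects of one chain class,
#'   or a character matrix (rows = sequences, columns = positions) as produced
#'   by [generate_repertoire()].
#' @param chain chain class the repertoire is declared to be.
#' @param pseudocount Laplace pseudocount per residue, default 0.
#' @param min_coverage positions with fewer non-gap observations than this
#'   are dropped from the profile (reported as unknown downstream).
#' @return a `positional_frequency_profile`.
#' @export
build_profile <- function(repertoire, chain = c("heavy", "kappa", "lambda"),
                          pseudocount = 0, min_coverage = 10) {
  chain <- match.arg(chain)
  if (is.matrix(repertoire)) {
    mat <- repertoire
  } else {
    if (length(repertoire) < 1L) stop_input("empty repertoire")
    chains <- vapply(repertoire, `[[`, character(1), "chain")
    if (!all(chains == chain))
      stop_input("repertoire contains sequences of chain other than '%s'", chain)
    lens <- vapply(repertoire, function(s) length(s$residues), integer(1))
    if (length(unique(lens)) != 1L)
      stop_input("repertoire sequences must have equal (pre-aligned) length")
    mat <- do.call(rbind, lapply(repertoire, `[[`, "residues"))
  }
  if (nrow(mat) < 1L) stop_input("empty repertoire")

  n_seq <- nrow(mat)
  min_coverage <- max(min_coverage, 1L)
  rows <- lapply(seq_len(ncol(mat)), function(p) {
    col <- mat[, p]
    col <- col[col %in% .AA20]
    n_obs <- length(col)
    if (n_obs < min_coverage) return(NULL)
    counts <- table(factor(col, levels = .AA20))
    if (pseudocount > 0) {
      freq <- (as.numeric(counts) + pseudocount) / (n_obs + 20 * pseudocount)
      keep <- rep(TRUE, 20L)
    } else {
      freq <- as.numeric(counts) / n_obs
      keep <- counts > 0
    }
    data.frame(position = p, residue = .AA20[keep],
               frequency = freq[keep], n_obs = n_obs,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    stop_input("no position reaches min_coverage = %d", min_coverage)
  rownames(tab) <- NULL
  new_profile(chain, tab, n_sequences = n_seq, partial = FALSE)
}

profile_lookup <- function(profile, position, residue) {
  tab <- profile$table
  hit <- tab$position == position & tab$residue == residue
  if (!any(hit)) return(NA_real_)
  tab$frequency[which(hit)[1L]]
}

profile_modal <- function(profile, position) {
  tab <- profile$table[profile$table$position == position, , drop = FALSE]
  if (nrow(tab) == 0L)
    return(list(residue = NA_character_, frequency = NA_real_))
  i <- which.max(tab$frequency)
  list(residue = tab$residue[i], frequency = tab$frequency[i])
}

#' Flag rare somatic hypermutations against a frequency profile
#'
#' An SHM is flagged rare (an rSHM / "unusual residue") when the observed
#' residue's positional frequency is strictly below `threshold` (default 1%).
#' Positions absent from the profile yield status `"unknown"` rather than a
#' silent omission; for a partial (fixture) profile an observed residue with
#' no entry at a covered position is also `"unknown"`.
#'
#' @param shm_list `shm_records` from [identify_shm()] (or a data.frame with
#'   the same columns).
#' @param profile a `positional_frequency_profile`.
#' @param threshold rarity threshold as a fraction, default 0.01; strict `<`.
#' @return data.frame of class `rshm_flags`: one row per SHM with
#'   `observed_frequency`, `modal_residue`, `modal_frequency`, `is_rare`,
#'   `threshold`, `status` (`"ok"` / `"unknown"`).
#' @export
flag_rare <- function(shm_list, profile, threshold = 0.01) {
  stopifnot(inherits(profile, "positional_frequency_profile"))
  n <- nrow(shm_list)
  out <- data.frame(
    position = shm_list$position,
    germline_residue = shm_list$germline_residue,
    observed_residue = shm_list$observed_residue,
    observed_frequency = rep(NA_real_, n),
    modal_residue = rep(NA_character_, n),
    modal_frequency = rep(NA_real_, n),
    is_rare = rep(NA, n),
    threshold = rep(threshold, n),
    status = rep("unknown", n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    pos <- shm_list$position[i]
    f <- profile_lookup(profile, pos, shm_list$observed_residue[i])
    modal <- profile_modal(profile, pos)
    out$modal_residue[i] <- modal$residue
    out$modal_frequency[i] <- modal$frequency
    covered <- any(profile$table$position == pos)
    if (covered && is.na(f) && !profile$partial) f <- 0  # seen never at a covered position
    if (!is.na(f)) {
      out$observed_frequency[i] <- f
      out$is_rare[i] <- f < threshold
      out$status[i] <- "ok"
    }
  }
  class(out) <- c("rshm_flags", "data.frame")
  out
}

#' Count unusual (rare-SHM) residues per chain for an antibody panel
#'
#' For each antibody, aligns VH/VL to the matching germline, identifies SHM,
#' flags them against the per-chain profiles and counts flagged-rare positions
#' per chain. Zero-count antibodies are reported like any other.
#'
#' @param panel list of antibodies, each a list with elements `name`, `VH`,
#'   `VL` ([antibody_sequence]s).
#' @param profiles list with elements `heavy` and `light`
#'   (`positional_frequency_profile`s); either may be `NULL` (counts `NA`).
#' @param germlines list with elements `VH` and `VL` ([germline_reference]s).
#' @param threshold rarity threshold, default 0.01.
#' @return data.frame: `name`, `heavy_count`, `light_count`, `heavy_unknown`,
#'   `light_unknown` (numbers of SHM whose frequency is unknown).
#' @export
count_unusual <- function(panel, profiles, germlines, threshold = 0.01) {
  one_chain <- function(query, ref, profile) {
    shm <- identify_shm(align_to_germline(query, ref))
    if (is.null(profile))
      return(c(count = NA_integer_, unknown = nrow(shm)))
    flags <- flag_rare(shm, profile, threshold)
    c(count = sum(flags$is_rare, na.rm = TRUE),
      unknown = sum(flags$status == "unknown"))
  }
  rows <- lapply(panel, function(ab) {
    h <- one_chain(ab$VH, germlines$VH, profiles$heavy)
    l <- one_chain(ab$VL, germlines$VL, profiles$light)
    data.frame(name = ab$name,
               heavy_count = h[["count"]], light_count = l[["count"]],
               heavy_unknown = h[["unknown"]], light_unknown = l[["unknown"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist / load a frequency profile as tab-separated text
#'
#' Round-trips bit-exactly: frequencies are written with full precision.
#' @param profile a `positional_frequency_profile`.
#' @param path TSV path.
#' @export
write_profile_tsv <- function(profile, path) {
  tab <- profile$table
  tab$chain <- profile$chain
  tab <- tab[, c("chain", "position", "residue", "frequency", "n_obs")]
  tab$frequency <- sprintf("%.17g", tab$frequency)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param partial whether the loaded profile is a partial fixture.
#' @export
read_profile_tsv <- function(path, partial = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  chain <- unique(tab$chain)
  stopifnot(length(chain) == 1L)
  n_seq <- if (all(tab$n_obs == 0L)) 0L else max(tab$n_obs)
  new_profile(chain, tab[, c("position", "residue", "frequency", "n_obs")],
              n_sequences = n_seq, partial = partial || n_seq == 0L)
}
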