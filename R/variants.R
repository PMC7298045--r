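#' Enumerate germline-reversion variants
#'
#' Generates all `2^k` reversion subsets of `k` flagged SHM positions
#' (the parent itself is the empty subset), in deterministic order: by subset
#' size, then lexicographically by chain/position tokens, truncated to
#' `max_combinations`.
#'
#' @param parent list with `VH`, `VL` ([antibody_sequence]s) and `name`.
#' @param flagged_positions data.frame with columns `chain` (`"H"`/`"L"`),
#'   `position`, `from_residue` (parent residue), `to_residue` (germline
#'   residue to revert to).
#' @param max_combinations cap on the number of variants returned (>= 1).
#' @return list of `variant_spec` objects: `name`, `reversions` (data.frame
#'   subset of `flagged_positions`), `VH`, `VL` (reverted sequences).
#' @export
enumerate_reversions <- function(parent, flagged_positions,
                                 max_combinations = Inf) {
  stopifnot(max_combinations >= 1)
  fp <- flagged_positions
  k <- nrow(fp)
  # validate against parent before any enumeration
  for (i in seq_len(k)) {
    seqobj <- if (fp$chain[i] == "H") parent$VH else parent$VL
    have <- seqobj$residues[fp$position[i]]
    if (is.na(have) || have != fp$from_residue[i])
      stop_input("parent %s chain position %d carries '%s', not '%s'",
                 fp$chain[i], fp$position[i], have, fp$from_residue[i])
  }
  token <- sprintf("%s:%s%d%s", fp$chain, fp$from_residue, fp$position,
                   fp$to_residue)
  subsets <- if (k == 0L) list(integer(0)) else {
    s <- unlist(lapply(0:k, function(m) utils::combn(k, m, simplify = FALSE)),
                recursive = FALSE)
    keys <- vapply(s, function(idx) paste(sort(token[idx]), collapse = "."),
                   character(1))
    sizes <- lengths(s)
    s[order(sizes, keys)]
  }
  if (is.finite(max_combinations) && length(subsets) > max_combinations)
    subsets <- subsets[seq_len(max_combinations)]

  lapply(subsets, function(idx) {
    rev_tab <- fp[idx, , drop = FALSE]
    vh <- parent$VH; vl <- parent$VL
    for (i in seq_len(nrow(rev_tab))) {
      if (rev_tab$chain[i] == "H")
        vh$residues[rev_tab$position[i]] <- rev_tab$to_residue[i]
      else
        vl$residues[rev_tab$position[i]] <- rev_tab$to_residue[i]
    }
    name <- if (length(idx) == 0L) parent$name else
      paste0(parent$name, "+", paste(sort(token[idx]), collapse = "."))
    vh$id <- paste0(name, "_VH"); vl$id <- paste0(name, "_VL")
    structure(list(name = name, reversions = rev_tab, VH = vh, VL = vl),
              class = "variant_spec")
  })
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("<variant_spec> %s (%d reversion%s)\n", x$name,
              nrow(x$reversions), if (nrow(x$reversions) == 1) "" else "s"))
  invisible(x)
}

#' Multi-attribute lead-selection funnel
#'
#' Applies the screening funnel used to pick the lead from a germline-reversion
#' panel: (1) discard variants whose KD exceeds `kd_fold_limit` times the
#' parent KD (binding must be retained); (2) among survivors minimise the
#' combined (heavy + light) EpiMatrix immunogenicity score; ties broken by
#' (3) maximum aggregation-onset temperature Tagg, (4) maximum Fab Tm,
#' (5) variant name. The rule order is configurable via `rule_order`, a
#' permutation of `c("epimatrix", "tagg", "fab_tm")`.
#'
#' @param panel data.frame with columns `name`, `epimatrix_hc`,
#'   `epimatrix_lc`, `fab_tm`, `tagg`, `kd_pM` (one row per variant; the
#'   parent may be included as a row).
#' @param parent_kd parent KD in pM (reference for the retention filter).
#' @param kd_fold_limit KD retention limit as a fold over the parent, default 2.
#' @param rule_order order of ranking criteria after the KD filter.
#' @return list of class `lead_selection`: `lead` (name, or `NA` for
#'   "no lead"), `ranked` (full panel with `rank`, `kd_pass`,
#'   `epimatrix_combined`), `survivors` (per-step survivor name lists).
#' @export
select_lead <- function(panel, parent_kd, kd_fold_limit = 2.0,
                        rule_order = c("epimatrix", "tagg", "fab_tm")) {
  needed <- c("name", "epimatrix_hc", "epimatrix_lc", "fab_tm", "tagg", "kd_pM")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols) > 0L)
    stop_input("panel lacks columns: %s", paste(missing_cols, collapse = ", "))
  stopifnot(all(is.finite(panel$kd_pM)), all(panel$kd_pM > 0))
  rule_order <- match.arg(rule_order, c("epimatrix", "tagg", "fab_tm"),
                          several.ok = TRUE)

  panel <- as.data.frame(panel)
  panel$epimatrix_combined <- panel$epimatrix_hc + panel$epimatrix_lc
  panel$kd_pass <- panel$kd_pM <= kd_fold_limit * parent_kd

  keys <- list(epimatrix = panel$epimatrix_combined,  # minimise
               tagg = -panel$tagg,                    # maximise
               fab_tm = -panel$fab_tm)                # maximise
  ord_args <- c(list(!panel$kd_pass), keys[rule_order], list(panel$name))
  ord <- do.call(order, ord_args)
  ranked <- panel[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  rownames(ranked) <- NULL

  surv1 <- ranked$name[ranked$kd_pass]
  survivors <- list(kd_filter = surv1)
  pool <- ranked[ranked$kd_pass, , drop = FALSE]
  for (rule in rule_order) {
    if (nrow(pool) == 0L) { survivors[[rule]] <- character(0); next }
    val <- switch(rule, epimatrix = pool$epimatrix_combined,
                  tagg = -pool$tagg, fab_tm = -pool$fab_tm)
    pool <- pool[val == min(val), , drop = FALSE]
    survivors[[rule]] <- pool$name
  }
  lead <- if (length(surv1) == 0L) NA_character_ else ranked$name[1L]
  structure(list(lead = lead, ranked = ranked, survivors = survivors,
                 parent_kd = parent_kd, kd_fold_limit = kd_fold_limit,
                 rule_order = rule_order),
            class = "lead_selection")
}

#' @export
print.lead_selection <- function(x, ...) {
  cat(sprintf("<lead_selection> lead: %s (KD filter kept %d/%d)\n",
              ifelse(is.na(x$lead), "no lead", x$lead),
              length(x$survivors$kd_filter), nrow(x$ranked)))
  invisible(x)
}

#' Read / write a variant attribute panel as CSV
#'
#' Column layout follows the published attribute table: variant name, the
#' residues at the four SHM positions, EpiMatrix heavy/light scores, Fab Tm,
#' Tagg and KD.
#' @param path CSV path.
#' @return data.frame with standardised column names (`name`,
#'   `epimatrix_hc`, `epimatrix_lc`, `fab_tm`, `tagg`, `kd_pM`, plus the
#'   residue columns `hc_14`, `hc_20`, `hc_81`, `lc_1`).
#' @export
read_panel_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_panel_csv
#' @param panel data.frame to write.
#' @export
write_panel_csv <- function(panel, path) {
  write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
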