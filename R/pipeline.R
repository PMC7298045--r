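#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are rejected.
#'
#' @param query_fasta,germline_fasta optional FASTA paths; when `NULL` the
#'   packaged parent/germline fixtures are used.
#' @param profile_tsv optional frequency-profile TSV; default is the packaged
#'   printed-frequency fixture.
#' @param panel_csv optional variant attribute CSV; default is the packaged
#'   published panel.
#' @param rshm_threshold rarity threshold, default 0.01.
#' @param kd_fold_limit KD retention limit for the funnel, default 2.
#' @param rule_order funnel ranking order after the KD filter.
#' @param enumerate_positions `"all_shm"` (revert every SHM, as in the
#'   published panel) or `"rare_only"`.
#' @param fit_assays logical; also simulate-and-fit the assay bundle for the
#'   parent and selected lead.
#' @param noise_level assay noise level passed to [generate_assay_suite()].
#' @param seed RNG seed for all simulated assays.
#' @param output_dir optional directory for the JSON/CSV reports.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(query_fasta = NULL, germline_fasta = NULL,
                            profile_tsv = NULL, panel_csv = NULL,
                            rshm_threshold = 0.01, kd_fold_limit = 2.0,
                            rule_order = c("epimatrix", "tagg", "fab_tm"),
                            enumerate_positions = c("all_shm", "rare_only"),
                            fit_assays = FALSE, noise_level = "default",
                            seed = 1L, output_dir = NULL) {
  enumerate_positions <- match.arg(enumerate_positions)
  stopifnot(rshm_threshold > 0, rshm_threshold < 1, kd_fold_limit >= 1)
  for (p in c(query_fasta, germline_fasta, profile_tsv, panel_csv))
    if (!is.null(p) && !file.exists(p)) stop_input("input not readable: %s", p)
  structure(list(query_fasta = query_fasta, germline_fasta = germline_fasta,
                 profile_tsv = profile_tsv, panel_csv = panel_csv,
                 rshm_threshold = rshm_threshold,
                 kd_fold_limit = kd_fold_limit, rule_order = rule_order,
                 enumerate_positions = enumerate_positions,
                 fit_assays = fit_assays, noise_level = noise_level,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the end-to-end lead-selection pipeline
#'
#' Sequences -> germline alignment -> SHM -> rSHM flags -> reversion panel ->
#' attribute table -> lead-selection funnel (-> optional assay fits). The
#' result is a pure function of (inputs, config, seed); stage failures are
#' recorded per stage with all completed results preserved.
#'
#' @param config a [pipeline_config].
#' @return list of class `lead_report`: `schema_version`, `stages` (status
#'   per stage), `shm`, `flags`, `panel`, `selection`, `lead`, `fits`,
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(schema_version = "1.0", stages = list(), provenance = list())
  run_stage <- function(name, fn) {
    res <- tryCatch(list(ok = TRUE, value = fn()),
                    error = function(e) list(ok = FALSE, message = conditionMessage(e)))
    report$stages[[name]] <<- if (res$ok) "ok" else paste("failed:", res$message)
    if (res$ok) res$value else NULL
  }

  seqs <- run_stage("sequences", function() {
    if (is.null(config$query_fasta)) {
      list(parent = parent_sequences(), germ = germline_references(),
           source = "packaged fixtures")
    } else {
      qs <- read_antibody_fasta(config$query_fasta)
      gs <- read_antibody_fasta(config$germline_fasta)
      pick <- function(lst, chain) lst[[which(vapply(lst, `[[`, character(1), "chain") ==
                                                 chain)[1]]]
      gl <- function(s) germline_reference(s$id, s$chain, s$residues)
      list(parent = list(VH = pick(qs, "heavy"),
                         VL = pick(qs, setdiff(c("kappa", "lambda"),
                                               "heavy")[1])),
           germ = list(VH = gl(pick(gs, "heavy")), VL = gl(pick(gs, "kappa"))),
           source = config$query_fasta)
    }
  })
  if (is.null(seqs)) return(finish_report(report, config))

  shm <- run_stage("shm", function() {
    list(heavy = identify_shm(align_to_germline(seqs$parent$VH, seqs$germ$VH)),
         light = identify_shm(align_to_germline(seqs$parent$VL, seqs$germ$VL)))
  })
  if (is.null(shm)) return(finish_report(report, config))
  report$shm <- shm

  flags <- run_stage("rshm_flags", function() {
    profile <- if (is.null(config$profile_tsv)) printed_frequency_profile()
               else read_profile_tsv(config$profile_tsv)
    list(heavy = flag_rare(shm$heavy, profile, config$rshm_threshold),
         light = NULL)  # no light-chain frequencies are published
  })
  report$flags <- flags
  report$provenance$frequencies <- "packaged printed-frequency fixture unless overridden"

  panel_attrs <- run_stage("panel_attributes", function() {
    if (is.null(config$panel_csv)) variant_panel_table()
    else read_panel_csv(config$panel_csv)
  })
  report$panel <- panel_attrs
  report$provenance$attributes <-
    "EpiMatrix scores, Fab Tm, Tagg and KD are supplied inputs (published panel), never computed"

  variants <- run_stage("enumerate", function() {
    use <- shm$heavy
    if (config$enumerate_positions == "rare_only" && !is.null(flags$heavy))
      use <- use[which(flags$heavy$is_rare), , drop = FALSE]
    fp <- rbind(
      data.frame(chain = "H", position = use$position,
                 from_residue = use$observed_residue,
                 to_residue = use$germline_residue,
                 stringsAsFactors = FALSE),
      data.frame(chain = "L", position = shm$light$position,
                 from_residue = shm$light$observed_residue,
                 to_residue = shm$light$germline_residue,
                 stringsAsFactors = FALSE))
    enumerate_reversions(list(name = "PCa75", VH = seqs$parent$VH,
                              VL = seqs$parent$VL), fp)
  })
  report$n_enumerated <- length(variants)

  selection <- run_stage("select_lead", function() {
    if (is.null(panel_attrs) || nrow(panel_attrs) == 0L)
      return(structure(list(lead = NA_character_, ranked = panel_attrs,
                            survivors = list()), class = "lead_selection"))
    parent_kd <- panel_attrs$kd_pM[panel_attrs$name == "PCa75"][1]
    if (is.na(parent_kd)) parent_kd <- min(panel_attrs$kd_pM)
    select_lead(panel_attrs, parent_kd, config$kd_fold_limit,
                config$rule_order)
  })
  report$selection <- selection
  report$lead <- if (!is.null(selection)) selection$lead else NA_character_

  if (isTRUE(config$fit_assays)) {
    report$fits <- run_stage("assay_fits", function() {
      fit_one <- function(key) {
        suite <- generate_assay_suite(key, config$noise_level, config$seed)
        sel <- select_unfolding_model(suite$icd)
        list(icd_model = sel$model,
             icd = if (sel$model == "three_state") sel$three_state else sel$two_state,
             dsc = if (!is.null(suite$dsc)) fit_dsc(suite$dsc, 2) else NULL,
             dsf = dsf_tm(suite$dsf),
             tagg = if (!is.null(suite$scattering))
               detect_aggregation_onset(suite$scattering) else NULL,
             kinetics = if (!is.null(suite$sensorgram))
               fit_1to1_global(suite$sensorgram) else NULL,
             stress = if (!is.null(suite$aggregates))
               passes_stress_criterion(suite$aggregates$`40C`) else NULL)
      }
      list(PCa75 = fit_one("PCa75"), PCa62 = fit_one("PCa62"))
    })
  }
  finish_report(report, config)
}

finish_report <- function(report, config) {
  report$config <- unclass(config)
  class(report) <- "lead_report"
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_lead_report(report, file.path(config$output_dir, "lead_report.json"))
    if (!is.null(report$selection) && !is.null(report$selection$ranked))
      write.csv(report$selection$ranked,
                file.path(config$output_dir, "ranked_panel.csv"),
                row.names = FALSE)
  }
  report
}

#' @export
print.lead_report <- function(x, ...) {
  cat("<lead_report>\n")
  for (s in names(x$stages)) cat(sprintf("  %-18s %s\n", s, x$stages[[s]]))
  cat("  lead:", ifelse(is.na(x$lead), "no lead", x$lead), "\n")
  invisible(x)
}

#' Serialise a lead report to JSON
#'
#' Deterministic given (inputs, config, seed): no timestamps are included.
#'
#' @param report a `lead_report`.
#' @param path JSON output path.
#' @export
write_lead_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "lead_selection")) x <- unclass(x)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  out <- strip(unclass(report))
  out$config$output_dir <- NULL  # machine-local path, not analysis content
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
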