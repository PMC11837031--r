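#' Configuration for an end-to-end synthetic pipeline run
#'
#' Collects the synthesis, QC and statistical parameters of [run_pipeline()].
#' The defaults reproduce the reference study conditions: a 213-subject
#' memory-clinic-sized cohort, IQR fence multiplier 1.5, slow-variance
#' threshold 75%, FDR level 0.05.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed driving every random stage.
#' @param wmh_burden,atrophy Phantom parameters, see [make_phantom()].
#' @param planted_beta,null_idp_names Cohort ground truth, see
#'   [cohort_truth()]; the default plants a handful of moderate effects and
#'   leaves the rest null.
#' @param iqm_outlier_ids Scans given planted IQM outliers.
#' @param exclusions Scan/subject ids excluded after (out-of-scope) visual
#'   inspection; dropped before association.
#' @param k IQR fence multiplier.
#' @param svar_threshold Slow-variance percentage threshold.
#' @param q Hierarchical FDR level.
#' @param outcomes Outcomes to screen.
#' @param out_dir Output directory; tables and the run manifest are written
#'   here.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 213, seed = 1,
                            wmh_burden = 0.02, atrophy = 0.1,
                            planted_beta = NULL, null_idp_names = NULL,
                            iqm_outlier_ids = c("scan_03", "scan_17"),
                            exclusions = character(),
                            k = 1.5, svar_threshold = 75, q = 0.05,
                            outcomes = c("age", "ace_total", "diagnosis"),
                            out_dir = tempfile("idpscreen_run_")) {
  if (is.null(planted_beta)) {
    planted_beta <- list(
      gm_temporal_lobe_volume = c(age = -0.5, ace_total = 0.55,
                                  diagnosis = -1.2),
      psmd = c(age = 0.45, ace_total = -0.4, diagnosis = 0.8),
      nbm_l_volume = c(age = -0.3, ace_total = 0.25, diagnosis = -0.6)
    )
  }
  if (is.null(null_idp_names)) {
    null_idp_names <- setdiff(default_idp_names(), names(planted_beta))
  }
  stopifnot(k >= 0, svar_threshold >= 0, svar_threshold <= 100,
            q > 0, q < 1)
  structure(list(
    n_subjects = n_subjects, seed = as.integer(seed),
    wmh_burden = wmh_burden, atrophy = atrophy,
    planted_beta = planted_beta, null_idp_names = null_idp_names,
    iqm_outlier_ids = iqm_outlier_ids, exclusions = exclusions,
    k = k, svar_threshold = svar_threshold, q = q,
    outcomes = outcomes, out_dir = out_dir
  ), class = "pipeline_config")
}

# The 110 IDP names the default atlas emits, with their modality tags.
default_idp_names <- function() {
  modality_of_default_idps()$idp_name
}

modality_of_default_idps <- function() {
  rois <- c("hippocampus_l", "hippocampus_r", "amygdala_l", "amygdala_r",
            paste0(rep(cortical_roi_names(), each = 2L), c("_l", "_r")))
  tibble::tibble(
    idp_name = c(paste0("gm_", lobe_names(), "_lobe_volume"),
                 paste0(wm_atlas_tract_names(), "_wmh_volume"),
                 c("nbm_l_volume", "nbm_r_volume"),
                 "psmd",
                 paste0(tractography_tract_names(), "_tract_volume"),
                 paste0(rep(rois, each = 2L), c("_md", "_mo"))),
    modality = c(rep("T1", 4L), rep("T2-FLAIR", 48L), rep("T1", 2L),
                 "dMRI", rep("dMRI", 27L), rep("dMRI", 28L))
  )
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the full workflow with zero external inputs: (1) generate a
#' phantom and extract its 110 supplementary IDPs, verifying determinism;
#' (2) generate a cohort with planted effects and an IQM table with planted
#' outliers; (3) flag scans by the IQR rule and decompose a synthetic BOLD
#' series with the DSE/S-var criterion; (4) drop excluded subjects and run
#' the hierarchical-FDR association screen. All tables are written as TSV
#' under `config$out_dir` together with a JSON run manifest recording the
#' seed and per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return An invisible list: `idps_phantom`, `flag_report`, `flag_summary`,
#'   `dse`, `screen`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  say("stage 1/4: phantom synthesis and IDP extraction")
  ph <- make_phantom(seed = seed, wmh_burden = config$wmh_burden,
                     atrophy = config$atrophy)
  idps_phantom <- extract_all(ph$subject, ph$atlas, subject_id = "phantom01")
  write_tsv_table(idps_phantom, file.path(config$out_dir,
                                          "phantom_idps.tsv"))

  say("stage 2/4: cohort and IQM synthesis (n = %d)", config$n_subjects)
  truth <- cohort_truth(planted_beta = config$planted_beta,
                        null_idp_names = config$null_idp_names)
  labels <- modality_of_default_idps()
  all_names <- c(names(config$planted_beta), config$null_idp_names)
  modality_labels <- stats::setNames(
    labels$modality[match(all_names, labels$idp_name)], all_names)
  modality_labels[is.na(modality_labels)] <- "T1"
  cohort <- make_cohort(config$n_subjects, truth,
                        modality_labels = modality_labels, seed = seed + 1L)
  iqm <- make_iqm_table(n_scans = max(config$n_subjects, 5),
                        outlier_ids = config$iqm_outlier_ids,
                        seed = seed + 2L)

  say("stage 3/4: quality control")
  flags <- iqr_flags(iqm, k = config$k)
  flag_summary <- summarize_flags(flags, exclusions = config$exclusions)
  bold <- make_bold(seed = seed + 3L, shape = c(12L, 12L, 12L), n_time = 60L,
                    spike_timepoints = 30L)
  dse <- dse_decompose(bold)
  svar <- svar_criterion(dse, config$svar_threshold)
  write_tsv_table(flags, file.path(config$out_dir, "flag_report.tsv"))
  write_tsv_table(flag_summary, file.path(config$out_dir,
                                          "flag_summary.tsv"))

  # excluded scan ids map to subject ids positionally (scan_07 -> sub_0007)
  excluded_subjects <- sprintf(
    "sub_%04d", as.integer(sub("scan_", "", config$exclusions)))
  idps_used <- dplyr::filter(cohort$idps,
                             !(.data$subject_id %in% excluded_subjects))
  phen_used <- dplyr::filter(cohort$phenotypes,
                             !(.data$subject_id %in% excluded_subjects))

  say("stage 4/4: association screen (%d subjects after exclusions)",
      nrow(phen_used))
  screen <- run_association_screen(idps_used, phen_used,
                                   outcomes = config$outcomes, q = config$q)
  write_tsv_table(screen$results, file.path(config$out_dir,
                                            "associations.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("idpscreen")),
    seed = seed,
    parameters = config[c("n_subjects", "wmh_burden", "atrophy", "k",
                          "svar_threshold", "q")],
    counts = list(
      phantom_idps = nrow(idps_phantom),
      cohort_subjects = config$n_subjects,
      scans_flagged = sum(flags$flagged),
      subjects_excluded = length(config$exclusions),
      subjects_screened = nrow(phen_used),
      idp_fits = nrow(screen$results),
      idps_rejected = sum(screen$results$rejected, na.rm = TRUE),
      svar_flagged_timepoints = length(svar$timepoints)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(idps_phantom = idps_phantom, flag_report = flags,
                 flag_summary = flag_summary, dse = dse, svar = svar,
                 screen = screen, manifest = manifest,
                 out_dir = config$out_dir))
}
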