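#' Ground-truth description of a synthetic cohort
#'
#' Declares which IDPs carry planted effects and how strong they are, on the
#' standardised scale the association screen estimates. `planted_beta` maps
#' IDP names to named effect vectors with any of the elements `age`,
#' `ace_total` (standardised linear effects) and `diagnosis` (log-odds per
#' SD in the proportional-odds latent). Every other IDP in
#' `null_idp_names` is generated independently of all phenotypes.
#'
#' @param planted_beta Named list: IDP name -> named numeric vector of
#'   effects.
#' @param null_idp_names Character vector of IDPs with no planted effect;
#'   must be disjoint from `names(planted_beta)`.
#' @param noise_sd Residual SD of each planted IDP; `NULL` (default) uses
#'   the unit-variance completion `sqrt(1 - sum(linear betas^2))` so the
#'   planted linear betas are exactly the standardised regression slopes.
#' @return A `cohort_truth` list.
#' @export
cohort_truth <- function(planted_beta = list(), null_idp_names = character(),
                         noise_sd = NULL) {
  if (length(planted_beta) > 0 &&
      (is.null(names(planted_beta)) || any(names(planted_beta) == ""))) {
    stop("`planted_beta` must be a named list", call. = FALSE)
  }
  overlap <- intersect(names(planted_beta), null_idp_names)
  if (length(overlap) > 0) {
    stop("IDP(s) both planted and null: ", paste(overlap, collapse = ", "),
         call. = FALSE)
  }
  allowed <- c("age", "ace_total", "diagnosis")
  for (nm in names(planted_beta)) {
    b <- planted_beta[[nm]]
    if (is.null(names(b)) || !all(names(b) %in% allowed)) {
      stop(sprintf("effects for `%s` must be named among: %s", nm,
                   paste(allowed, collapse = ", ")), call. = FALSE)
    }
    lin <- b[names(b) %in% c("age", "ace_total")]
    if (is.null(noise_sd) && sum(lin^2) >= 1) {
      stop(sprintf("linear effects for `%s` imply variance > 1; give noise_sd",
                   nm), call. = FALSE)
    }
  }
  structure(list(planted_beta = planted_beta,
                 null_idp_names = null_idp_names,
                 noise_sd = noise_sd),
            class = "cohort_truth")
}

#' Simulate a cohort of IDPs and phenotypes with planted effects
#'
#' Generates a phenotype table (age, sex, head size, ACE-III total, ordered
#' diagnosis) and a long-format IDP table in which the IDPs named in
#' `truth$planted_beta` carry the stated standardised effects and all others
#' are pure noise. Linear effects are planted by construction:
#' `IDP = beta_age * z_age + beta_ace * z_ace + s * noise` with `s` chosen so
#' the IDP has unit variance, making the planted beta the population
#' standardised regression coefficient. Diagnosis is drawn from a
#' proportional-odds latent `sum(beta_diag * IDP) + logistic noise` with
#' fixed cutpoints (-1.1, 1.1), which give all three levels
#' (no dementia-related diagnosis < MCI < dementia) substantial mass.
#'
#' Age is drawn as 78 +/- 6.2 years and ACE-III centred near 74 with SD 17
#' (clamped to 0-100), emulating a memory-clinic population; the default
#' cohort size elsewhere in the package is 213 subjects.
#'
#' @param n Number of subjects (>= 10).
#' @param truth A [cohort_truth()] object.
#' @param modality_labels Named character vector mapping every IDP name to a
#'   modality family; unnamed default assigns all planted + null IDPs round-
#'   robin over the six scan modalities.
#' @param seed Integer seed.
#' @return A list with `idps` (tibble: `subject_id`, `idp_name`, `modality`,
#'   `value`) and `phenotypes` (tibble: `subject_id`, `age`, `sex`,
#'   `head_size`, `ace_total`, `diagnosis` as an ordered factor).
#' @examples
#' truth <- cohort_truth(
#'   planted_beta = list(idp_signal = c(age = 0.5)),
#'   null_idp_names = paste0("idp_null_", 1:5))
#' cohort <- make_cohort(50, truth, seed = 1)
#' head(cohort$phenotypes)
#' @export
make_cohort <- function(n, truth, modality_labels = NULL, seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  idp_names <- c(names(truth$planted_beta), truth$null_idp_names)
  if (length(idp_names) == 0) stop("no IDPs declared in `truth`",
                                   call. = FALSE)
  modalities <- c("T1", "T2-FLAIR", "swMRI", "dMRI", "ASL", "rfMRI")
  if (is.null(modality_labels)) {
    modality_labels <- stats::setNames(
      rep_len(modalities, length(idp_names)), idp_names)
  }
  unknown <- setdiff(names(modality_labels), idp_names)
  if (length(unknown) > 0) {
    stop("modality label for unknown IDP name(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(idp_names %in% names(modality_labels))) {
    stop("every IDP needs a modality label", call. = FALSE)
  }

  withr::with_seed(seed, {
    z_age <- stats::rnorm(n)
    z_ace <- stats::rnorm(n)
    sex <- stats::rbinom(n, 1, 0.5)
    head_size <- stats::rnorm(n, 1, 0.08)

    vals <- matrix(NA_real_, n, length(idp_names),
                   dimnames = list(NULL, idp_names))
    for (nm in idp_names) {
      b <- truth$planted_beta[[nm]]
      b_age <- if (!is.null(b) && "age" %in% names(b)) b[["age"]] else 0
      b_ace <- if (!is.null(b) && "ace_total" %in% names(b)) b[["ace_total"]] else 0
      s <- truth$noise_sd %||% sqrt(max(1 - b_age^2 - b_ace^2, 0))
      vals[, nm] <- b_age * z_age + b_ace * z_ace + s * stats::rnorm(n)
    }

    eta <- rep(0, n)
    for (nm in names(truth$planted_beta)) {
      b <- truth$planted_beta[[nm]]
      if ("diagnosis" %in% names(b)) eta <- eta + b[["diagnosis"]] * vals[, nm]
    }
    latent <- eta + stats::rlogis(n)
    diagnosis <- cut(latent, breaks = c(-Inf, -1.1, 1.1, Inf),
                     labels = c("no_drd", "mci", "dementia"),
                     ordered_result = TRUE)
  })

  subject_id <- sprintf("sub_%04d", seq_len(n))
  phen <- tibble::tibble(
    subject_id = subject_id,
    age = 78 + 6.2 * z_age,
    sex = sex,
    head_size = head_size,
    ace_total = as.integer(pmin(pmax(round(74 + 17 * z_ace), 0), 100)),
    diagnosis = diagnosis
  )
  idps <- tibble::as_tibble(as.data.frame(vals)) |>
    dplyr::mutate(subject_id = subject_id, .before = 1) |>
    tidyr::pivot_longer(-"subject_id", names_to = "idp_name",
                        values_to = "value") |>
    dplyr::mutate(modality = unname(modality_labels[.data$idp_name]),
                  .after = "idp_name") |>
    dplyr::arrange(.data$subject_id, .data$idp_name)

  list(idps = idps, phenotypes = phen)
}

#' Simulate an image-quality-metric table with planted outliers
#'
#' Draws `n_metrics` metrics for `n_scans` scans from a common unimodal
#' distribution and then pushes, for every scan in `outlier_ids`, one
#' metric value far beyond the 1.5-IQR fences of the remaining scans, so the
#' IQR flagging rule is guaranteed to pick it up.
#'
#' @param n_scans Number of scans (>= 5); ids are `scan_01`, `scan_02`, ...
#' @param n_metrics Number of metrics per scan.
#' @param outlier_ids Character or integer vector of scans to plant an
#'   outlier in; integers index into the scan sequence.
#' @param seed Integer seed.
#' @param modality Modality label stored in the table.
#' @return A tibble (`scan_id`, `modality`, `metric`, `value`).
#' @export
make_iqm_table <- function(n_scans, n_metrics = 6, outlier_ids = character(),
                           seed = 1, modality = "T1") {
  if (n_scans < 5) {
    stop("`n_scans` must be at least 5 for meaningful quartiles",
         call. = FALSE)
  }
  scan_ids <- sprintf("scan_%02d", seq_len(n_scans))
  if (is.numeric(outlier_ids)) outlier_ids <- scan_ids[outlier_ids]
  if (!all(outlier_ids %in% scan_ids)) {
    stop("`outlier_ids` must be a subset of the generated scan ids",
         call. = FALSE)
  }
  metrics <- sprintf("iqm_%02d", seq_len(n_metrics))
  withr::with_seed(seed, {
    tab <- tidyr::expand_grid(scan_id = scan_ids, metric = metrics) |>
      dplyr::mutate(modality = modality, .after = "scan_id") |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(value = stats::rnorm(dplyr::n(),
                                         mean = stats::runif(1, -2, 2),
                                         sd = stats::runif(1, 0.5, 2))) |>
      dplyr::ungroup()
    for (sid in outlier_ids) {
      m <- sample(metrics, 1)
      others <- tab$value[tab$metric == m & tab$scan_id != sid]
      q <- stats::quantile(others, c(0.25, 0.75), type = 7, names = FALSE)
      # well beyond the upper fence of the remaining scans
      tab$value[tab$metric == m & tab$scan_id == sid] <-
        q[2] + 1.5 * (q[2] - q[1]) + 3 * (max(others) - min(others)) + 1
    }
  })
  tab
}

#' Simulate a 4D time series with planted global-intensity spikes
#'
#' Baseline i.i.d. Gaussian noise with a constant added to every voxel at
#' the listed timepoints, producing the abrupt whole-image shifts the DSE
#' fast-variance component is sensitive to.
#'
#' @param seed Integer seed.
#' @param shape Spatial grid shape.
#' @param n_time Number of timepoints (>= 10).
#' @param spike_timepoints Integer timepoints (1-based) receiving a spike.
#' @param spike_amplitude Added intensity at spike timepoints, in noise-SD
#'   units.
#' @return A 4D array of dimension `c(shape, n_time)`.
#' @export
make_bold <- function(seed, shape = c(16L, 16L, 16L), n_time = 100L,
                      spike_timepoints = integer(), spike_amplitude = 5) {
  shape <- as.integer(shape)
  n_time <- as.integer(n_time)
  if (n_time < 10) stop("`n_time` must be at least 10", call. = FALSE)
  spike_timepoints <- as.integer(spike_timepoints)
  if (length(spike_timepoints) > 0 &&
      (min(spike_timepoints) < 1 || max(spike_timepoints) > n_time)) {
    stop("`spike_timepoints` must lie within [1, n_time]", call. = FALSE)
  }
  withr::with_seed(seed, {
    bold <- array(stats::rnorm(prod(shape) * n_time), c(shape, n_time))
  })
  for (t in spike_timepoints) {
    bold[, , , t] <- bold[, , , t] + spike_amplitude
  }
  bold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
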