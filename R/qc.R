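#' Interquartile-range outlier flagging of image-quality metrics
#'
#' For every metric within every modality, computes the quartiles Q1 and Q3
#' over scans (linear interpolation between order statistics, quantile type
#' 7) and flags a scan on that metric when its value falls below
#' `Q1 - k * IQR` or above `Q3 + k * IQR`. A scan is flagged overall when it
#' is an outlier on at least one metric. Flagging marks scans for visual
#' inspection only; exclusion is a separate human decision recorded via
#' [summarize_flags()].
#'
#' A metric that is identical across scans has zero IQR and produces no
#' flags (no value differs from the common value).
#'
#' @param iqm Long-format tibble/data.frame of image-quality metrics with
#'   columns `scan_id`, `modality`, `metric`, `value` (finite).
#' @param k Fence multiplier; default 1.5.
#' @return A `flag_report` tibble with one row per scan and modality:
#'   `scan_id`, `modality`, `flagged`, `flagged_metrics` (list column),
#'   `n_flagged`.
#' @examples
#' iqm <- make_iqm_table(n_scans = 20, n_metrics = 4, outlier_ids = "scan_03",
#'                       seed = 1)
#' iqr_flags(iqm)
#' @export
iqr_flags <- function(iqm, k = 1.5) {
  iqm <- tibble::as_tibble(iqm)
  req <- c("scan_id", "modality", "metric", "value")
  if (!all(req %in% names(iqm))) {
    stop("`iqm` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(iqm$value))) {
    stop("IQM values must be finite", call. = FALSE)
  }
  if (k < 0) stop("`k` must be non-negative", call. = FALSE)
  n_scans <- dplyr::summarise(dplyr::group_by(iqm, .data$modality),
                              n = dplyr::n_distinct(.data$scan_id))
  if (any(n_scans$n < 5)) {
    stop("need at least 5 scans per modality for meaningful quartiles",
         call. = FALSE)
  }

  per_metric <- iqm |>
    dplyr::group_by(.data$modality, .data$metric) |>
    dplyr::mutate(
      q1 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
      outlier = .data$value < .data$q1 - k * (.data$q3 - .data$q1) |
                .data$value > .data$q3 + k * (.data$q3 - .data$q1)
    ) |>
    dplyr::ungroup()

  report <- per_metric |>
    dplyr::group_by(.data$scan_id, .data$modality) |>
    dplyr::summarise(
      flagged = any(.data$outlier),
      flagged_metrics = list(.data$metric[.data$outlier]),
      n_flagged = sum(.data$outlier),
      .groups = "drop"
    )
  class(report) <- c("flag_report", class(report))
  report
}

#' DSE variance decomposition of a 4D time series
#'
#' Splits the temporal variance of a voxelwise mean-centred 4D series into
#' fast (D), slow (S) and edge (E) components. For each voxel time series
#' \eqn{y_t}, the half-differences \eqn{(y_{t+1} - y_t)/2} carry the fast
#' variance, the half-sums \eqn{(y_{t+1} + y_t)/2} the slow variance, and the
#' two endpoints \eqn{y_1^2/2, y_T^2/2} the edge variance; averaged over
#' mask voxels these satisfy the exact conservation identity
#' \eqn{\sum_t A_t = \sum_t D_t + \sum_t S_t + E}. A high slow share
#' indicates residual structured noise.
#'
#' Per-timepoint percentages are expressed relative to the whole-series mean
#' A-var, so white noise gives D and S shares that fluctuate around 50%.
#' Global percentages are relative to total A-var and sum to 100 exactly.
#'
#' @param bold 4D numeric array (x, y, z, t) with at least 3 timepoints.
#' @param brain_mask Binary `volume_grid` (or 3D array) selecting voxels;
#'   must be nonempty. Default: all voxels.
#' @return A `dse_result` list: `timepoints` (tibble `t`, `a_var`),
#'   `transitions` (tibble `t`, `d_var`, `s_var`, `pct_d`, `pct_s`; row `t`
#'   covers the transition `t -> t + 1`), `edge` (`e_first`, `e_last`),
#'   `global` (named percentages `pct_d`, `pct_s`, `pct_e`), `totals`.
#' @examples
#' bold <- make_bold(seed = 1, shape = c(8, 8, 8), n_time = 40,
#'                   spike_timepoints = 20)
#' dse <- dse_decompose(bold)
#' dse$global
#' @export
dse_decompose <- function(bold, brain_mask = NULL) {
  if (!is.array(bold) || length(dim(bold)) != 4L) {
    stop("`bold` must be a 4D array", call. = FALSE)
  }
  n_t <- dim(bold)[4]
  if (n_t < 3) stop("need at least 3 timepoints", call. = FALSE)
  if (is.null(brain_mask)) {
    keep <- rep(TRUE, prod(dim(bold)[1:3]))
  } else {
    mask <- if (is_volume_grid(brain_mask)) brain_mask$data else brain_mask
    if (!identical(dim(mask), dim(bold)[1:3])) {
      stop("mask shape does not match the spatial dimensions of `bold`",
           call. = FALSE)
    }
    keep <- as.vector(mask) == 1
    if (!any(keep)) stop("brain mask is empty", call. = FALSE)
  }

  y <- matrix(bold, ncol = n_t)[keep, , drop = FALSE]
  y <- y - rowMeans(y)                       # centre each voxel's series

  a_var <- colMeans(y^2)
  d <- (y[, -1, drop = FALSE] - y[, -n_t, drop = FALSE]) / 2
  s <- (y[, -1, drop = FALSE] + y[, -n_t, drop = FALSE]) / 2
  d_var <- colMeans(d^2)
  s_var <- colMeans(s^2)
  e_first <- mean(y[, 1]^2) / 2
  e_last <- mean(y[, n_t]^2) / 2

  total_a <- sum(a_var)
  a_bar <- mean(a_var)
  pct <- function(x, denom) if (denom > 0) 100 * x / denom else 0 * x

  structure(list(
    timepoints = tibble::tibble(t = seq_len(n_t), a_var = a_var),
    transitions = tibble::tibble(
      t = seq_len(n_t - 1L), d_var = d_var, s_var = s_var,
      pct_d = pct(d_var, a_bar), pct_s = pct(s_var, a_bar)),
    edge = c(e_first = e_first, e_last = e_last),
    global = c(pct_d = pct(sum(d_var), total_a),
               pct_s = pct(sum(s_var), total_a),
               pct_e = pct(e_first + e_last, total_a)),
    totals = c(a = total_a, d = sum(d_var), s = sum(s_var),
               e = e_first + e_last),
    n_voxels = sum(keep)
  ), class = "dse_result")
}

#' @export
print.dse_result <- function(x, ...) {
  cat(sprintf(
    "<dse_result: %d timepoints, %d voxels; %%D = %.1f, %%S = %.1f, %%E = %.1f>\n",
    nrow(x$timepoints), x$n_voxels,
    x$global["pct_d"], x$global["pct_s"], x$global["pct_e"]))
  invisible(x)
}

#' Slow-variance criterion on a DSE decomposition
#'
#' Lists the transitions whose slow-variance share exceeds `threshold_pct`
#' (default 75%, the conventional cut-off for residual structured noise) and
#' reports a scan-level flag if any does.
#'
#' @param dse A `dse_result` from [dse_decompose()].
#' @param threshold_pct Percentage threshold (strict inequality).
#' @return A list with `timepoints` (integer indices of flagged transitions)
#'   and `flagged` (logical scalar).
#' @export
svar_criterion <- function(dse, threshold_pct = 75) {
  stopifnot(inherits(dse, "dse_result"))
  hit <- dse$transitions$t[dse$transitions$pct_s > threshold_pct]
  list(timepoints = hit, flagged = length(hit) > 0)
}

#' Summarise flag reports into per-modality percentages
#'
#' Combines automated flags with the separately supplied exclusion decisions
#' (visual inspection is a human step) into the conventional per-modality
#' "% flagged / % excluded" table.
#'
#' @param reports A `flag_report` tibble from [iqr_flags()] (rows may be
#'   pooled over several runs).
#' @param exclusions Character vector of `scan_id`s excluded after
#'   inspection.
#' @return A tibble per modality: `n_total`, `n_flagged`, `pct_flagged`,
#'   `n_excluded`, `pct_excluded` (percentages of `n_total`, one decimal
#'   scale as conventionally reported, not rounded).
#' @examples
#' iqm <- make_iqm_table(30, 5, outlier_ids = c("scan_02", "scan_11"), seed = 2)
#' summarize_flags(iqr_flags(iqm), exclusions = "scan_02")
#' @export
summarize_flags <- function(reports, exclusions = character()) {
  reports <- tibble::as_tibble(reports)
  if (nrow(reports) == 0) {
    warning("empty flag report")
    return(tibble::tibble(modality = character(), n_total = integer(),
                          n_flagged = integer(), pct_flagged = numeric(),
                          n_excluded = integer(), pct_excluded = numeric()))
  }
  reports |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_flagged = sum(.data$flagged),
      n_excluded = sum(.data$scan_id %in% exclusions),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_flagged = 100 * .data$n_flagged / .data$n_total,
      pct_excluded = 100 * .data$n_excluded / .data$n_total
    ) |>
    dplyr::select("modality", "n_total", "n_flagged", "pct_flagged",
                  "n_excluded", "pct_excluded")
}
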