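#' Mass-univariate association screen with hierarchical FDR
#'
#' Joins a long-format IDP table to a phenotype table, quantile-normalises
#' every numeric variable (IDPs, age, ACE-III total, head size; sex stays a
#' binary indicator), fits one model per IDP and outcome, and corrects each
#' outcome's p-values with the two-stage hierarchical FDR over modality
#' families.
#'
#' Outcome-specific models:
#' \describe{
#'   \item{`age`}{linear: `age ~ idp + sex + head_size + ace_total`}
#'   \item{`ace_total`}{linear: `ace_total ~ idp + age + sex + head_size`}
#'   \item{`diagnosis`}{proportional-odds: `diagnosis ~ idp + age + sex +
#'     head_size`}
#' }
#' Cognition enters the age model as a covariate so that age effects are not
#' simply relabelled impairment effects in a population where the two are
#' strongly coupled.
#'
#' An optional `volume_covariates` mapping (IDP name -> name of its matched
#' ROI/tract volume IDP) adds that normalised volume as an extra covariate to
#' the mapped IDPs' models, the sensitivity variant separating microstructure
#' from plain atrophy.
#'
#' @param idps Tibble with `subject_id`, `idp_name`, `modality`, `value`.
#' @param phenotypes Tibble with `subject_id`, `age`, `sex`, `head_size`,
#'   `ace_total`, `diagnosis` (ordered factor).
#' @param outcomes Subset of `c("age", "ace_total", "diagnosis")`.
#' @param q Hierarchical FDR level.
#' @param volume_covariates Optional named character vector, IDP ->
#'   volume-IDP.
#' @param min_n Minimum complete cases for a fit; IDPs below it are skipped
#'   with a message collected in the result.
#' @param p_type Passed to [fit_ordinal_assoc()].
#' @return An `idp_screen` list: `results` (tibble over outcomes x IDPs:
#'   `outcome`, `idp_name`, `modality`, `beta`, `se`, `statistic`, `p_raw`,
#'   `p_adj`, `rejected`, `n_used`), `hierarchy` (named list of
#'   `hier_fdr_result` per outcome), `skipped` (tibble), `q`.
#' @examples
#' truth <- cohort_truth(
#'   planted_beta = list(sig = c(age = 0.6)),
#'   null_idp_names = paste0("null_", 1:11))
#' cohort <- make_cohort(120, truth, seed = 7)
#' scr <- run_association_screen(cohort$idps, cohort$phenotypes,
#'                               outcomes = "age")
#' dplyr::filter(scr$results, rejected)
#' @export
run_association_screen <- function(idps, phenotypes,
                                   outcomes = c("age", "ace_total",
                                                "diagnosis"),
                                   q = 0.05, volume_covariates = NULL,
                                   min_n = 20, p_type = c("wald", "lr")) {
  p_type <- match.arg(p_type)
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  idps <- tibble::as_tibble(idps)
  phenotypes <- tibble::as_tibble(phenotypes)
  stopifnot(all(c("subject_id", "idp_name", "modality", "value") %in%
                  names(idps)),
            all(c("subject_id", "age", "sex", "head_size") %in%
                  names(phenotypes)))
  if ("diagnosis" %in% outcomes && !is.ordered(phenotypes$diagnosis)) {
    stop("`phenotypes$diagnosis` must be an ordered factor", call. = FALSE)
  }

  modality_of <- idps |>
    dplyr::distinct(.data$idp_name, .data$modality)
  if (anyDuplicated(modality_of$idp_name) > 0) {
    stop("an IDP carries more than one modality tag", call. = FALSE)
  }

  wide <- idps |>
    dplyr::select("subject_id", "idp_name", "value") |>
    tidyr::pivot_wider(names_from = "idp_name", values_from = "value")
  dat <- dplyr::inner_join(phenotypes, wide, by = "subject_id")
  if (nrow(dat) < min_n) {
    stop("fewer than `min_n` subjects after joining tables", call. = FALSE)
  }

  idp_names <- modality_of$idp_name
  norm_idp <- lapply(stats::setNames(idp_names, idp_names), function(nm) {
    v <- dat[[nm]]
    if (sum(!is.na(v)) >= 3 && length(unique(stats::na.omit(v))) > 1) {
      quantile_normalise(v)
    } else {
      rep(NA_real_, length(v))
    }
  })
  z_age <- quantile_normalise(dat$age)
  z_head <- quantile_normalise(dat$head_size)
  z_ace <- if ("ace_total" %in% names(dat)) quantile_normalise(dat$ace_total)
           else NULL
  sex <- dat$sex

  if (!is.null(volume_covariates)) {
    bad <- setdiff(c(names(volume_covariates),
                     unname(volume_covariates)), idp_names)
    if (length(bad) > 0) {
      stop("`volume_covariates` references unknown IDP(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  fit_one <- function(outcome, nm) {
    mod <- modality_of$modality[modality_of$idp_name == nm]
    x <- norm_idp[[nm]]
    covs <- switch(outcome,
      age = data.frame(sex = sex, head_size = z_head,
                       ace_total = z_ace %||% stop("ace_total required")),
      ace_total = data.frame(age = z_age, sex = sex, head_size = z_head),
      diagnosis = data.frame(age = z_age, sex = sex, head_size = z_head))
    if (!is.null(volume_covariates) && nm %in% names(volume_covariates)) {
      covs$roi_volume <- norm_idp[[volume_covariates[[nm]]]]
    }
    y <- switch(outcome, age = z_age, ace_total = z_ace,
                diagnosis = dat$diagnosis)
    n_ok <- sum(stats::complete.cases(cbind(data.frame(y = y, x = x), covs)))
    if (n_ok < min_n) {
      return(list(skip = tibble::tibble(
        outcome = outcome, idp_name = nm,
        reason = sprintf("only %d complete cases (min_n = %d)", n_ok, min_n))))
    }
    fit <- tryCatch({
      if (outcome == "diagnosis") {
        fit_ordinal_assoc(y, x, covs, idp_name = nm, modality = mod,
                          p_type = p_type)
      } else {
        fit_linear_assoc(y, x, covs, idp_name = nm, modality = mod)
      }
    }, error = function(e) {
      list(skip = tibble::tibble(outcome = outcome, idp_name = nm,
                                 reason = conditionMessage(e)))
    })
    if (is.data.frame(fit)) {
      list(fit = dplyr::mutate(fit, outcome = outcome, .before = 1))
    } else {
      fit
    }
  }

  all_fits <- purrr::map(outcomes, function(oc) {
    purrr::map(idp_names, function(nm) fit_one(oc, nm))
  })
  flat <- purrr::flatten(all_fits)
  results <- purrr::map_dfr(flat, "fit")
  skipped <- purrr::map_dfr(flat, "skip")

  hierarchy <- list()
  corrected <- list()
  for (oc in outcomes) {
    res_oc <- dplyr::filter(results, .data$outcome == oc)
    if (nrow(res_oc) == 0) next
    fam <- split(res_oc$p_raw, res_oc$modality)
    hier <- hierarchical_fdr(fam, q = q)
    key <- res_oc |>
      dplyr::group_by(.data$modality) |>
      dplyr::mutate(index = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::left_join(
        dplyr::rename(hier$tests, modality = "family"),
        by = c("modality", "index", "p_raw")) |>
      dplyr::select(-"index")
    hierarchy[[oc]] <- hier
    corrected[[oc]] <- key
  }
  results <- dplyr::bind_rows(corrected)

  structure(list(results = results, hierarchy = hierarchy,
                 skipped = skipped, q = q,
                 n_subjects = nrow(dat), outcomes = outcomes),
            class = "idp_screen")
}

#' @export
print.idp_screen <- function(x, ...) {
  cat(sprintf("<idp_screen: %d subjects, %d IDP fits over %s; q = %g>\n",
              x$n_subjects, nrow(x$results),
              paste(x$outcomes, collapse = "/"), x$q))
  for (oc in names(x$hierarchy)) {
    h <- x$hierarchy[[oc]]
    cat(sprintf("  %-10s %d/%d modalities selected, %d IDPs rejected\n",
                oc, h$r_selected, h$m_families, sum(h$tests$rejected)))
  }
  if (nrow(x$skipped) > 0) {
    cat(sprintf("  (%d fits skipped)\n", nrow(x$skipped)))
  }
  invisible(x)
}
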