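#' Tidiers for screen and FDR results
#'
#' `tidy()` on an `idp_screen` returns the per-IDP association table
#' (outcome, IDP, modality, beta, se, p-values, rejection flag); on a
#' `hier_fdr_result` it returns the per-test table with family labels.
#' `glance()` gives one-row-per-outcome (or one-row) summaries: counts of
#' selected families and rejected tests.
#'
#' @param x An `idp_screen` or `hier_fdr_result`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @exportS3Method generics::tidy
tidy.idp_screen <- function(x, ...) x$results

#' @rdname tidy.idp_screen
#' @exportS3Method generics::glance
glance.idp_screen <- function(x, ...) {
  purrr::map_dfr(names(x$hierarchy), function(oc) {
    h <- x$hierarchy[[oc]]
    tibble::tibble(outcome = oc, n_idps = nrow(h$tests),
                   m_families = h$m_families, r_selected = h$r_selected,
                   stage2_level = h$stage2_level,
                   n_rejected = sum(h$tests$rejected),
                   q = h$q, n_subjects = x$n_subjects)
  })
}

#' @rdname tidy.idp_screen
#' @exportS3Method generics::tidy
tidy.hier_fdr_result <- function(x, ...) x$tests

#' @rdname tidy.idp_screen
#' @exportS3Method generics::glance
glance.hier_fdr_result <- function(x, ...) {
  tibble::tibble(m_families = x$m_families, r_selected = x$r_selected,
                 stage2_level = x$stage2_level,
                 n_tests = nrow(x$tests), n_rejected = sum(x$tests$rejected),
                 q = x$q)
}

#' @export
generics::tidy

#' @export
generics::glance
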