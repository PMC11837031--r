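#' Simes omnibus p-value
#'
#' Combines a family of p-values into one omnibus p-value:
#' `min_i m * p_(i) / i` over the sorted p-values, capped at 1. Valid as a
#' family-level test under independence or positive dependence, and the
#' family screen used by the hierarchical FDR procedure.
#'
#' @param pvec Numeric vector of p-values in \[0, 1\]; nonempty.
#' @return A single p-value.
#' @examples
#' simes_p(c(0.01, 0.03, 0.04))
#' @export
simes_p <- function(pvec) {
  if (length(pvec) == 0) stop("`pvec` is empty", call. = FALSE)
  if (any(is.na(pvec)) || any(pvec < 0 | pvec > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvec)
  min(1, min(m * sort(pvec) / seq_len(m)))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard BH: sort the m p-values, find the largest i with
#' `p_(i) <= i * level / m`, and reject all hypotheses with p-values up to
#' that order statistic. Adjusted p-values are the usual step-up
#' `cummin`-from-the-top values, so `reject` is equivalent to
#' `p_adj <= level`.
#'
#' @param pvec Numeric vector of p-values in \[0, 1\].
#' @param level FDR level in (0, 1).
#' @return A tibble in input order: `p_raw`, `p_adj`, `reject`. Empty input
#'   gives an empty tibble.
#' @examples
#' bh_reject(c(0.001, 0.02, 0.03, 0.9), 0.05)
#' @export
bh_reject <- function(pvec, level = 0.05) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)",
                                     call. = FALSE)
  if (length(pvec) == 0) {
    return(tibble::tibble(p_raw = numeric(), p_adj = numeric(),
                          reject = logical()))
  }
  if (any(is.na(pvec)) || any(pvec < 0 | pvec > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvec)
  ord <- order(pvec)
  p_sorted <- pvec[ord]
  adj_sorted <- rev(cummin(rev(pmin(1, m * p_sorted / seq_len(m)))))
  p_adj <- numeric(m)
  p_adj[ord] <- adj_sorted
  k <- which(p_sorted <= seq_len(m) * level / m)
  thresh <- if (length(k) > 0) p_sorted[max(k)] else -Inf
  tibble::tibble(p_raw = pvec, p_adj = p_adj, reject = pvec <= thresh)
}

#' Two-stage hierarchical FDR over modality families
#'
#' Stage 1 computes a Simes omnibus p-value for each family (here: each scan
#' modality) and applies BH across the `m` family p-values at level `q`,
#' selecting `R` families. Stage 2 applies BH within each selected family at
#' the adjusted, more stringent level `q * R / m`; unselected families have
#' no rejections. This controls the expected FDR within selected families at
#' `q` while keeping interpretation within modality.
#'
#' Reported within-family adjusted p-values are the stage-2 BH-adjusted
#' values scaled by `m / R` (capped at 1), so `rejected` is equivalent to
#' `p_adj <= q`.
#'
#' @param p_by_family Named list: family -> numeric vector of member
#'   p-values in \[0, 1\].
#' @param q Target FDR level; default 0.05.
#' @return A `hier_fdr_result` list with `family` (tibble: `family`,
#'   `n_tests`, `simes_p`, `selected`), `tests` (tibble: `family`, `index`,
#'   `p_raw`, `p_adj`, `rejected`), `q`, `m_families`, `r_selected`,
#'   `stage2_level`.
#' @examples
#' hierarchical_fdr(list(A = c(0.001, 0.2), B = c(0.9, 0.95),
#'                       C = c(0.8, 0.9)), q = 0.05)
#' @export
hierarchical_fdr <- function(p_by_family, q = 0.05) {
  if (!is.list(p_by_family) || length(p_by_family) == 0 ||
      is.null(names(p_by_family)) || anyDuplicated(names(p_by_family))) {
    stop("`p_by_family` must be a nonempty uniquely named list",
         call. = FALSE)
  }
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)

  fam_names <- names(p_by_family)
  simes <- vapply(p_by_family, simes_p, numeric(1))
  m <- length(fam_names)
  stage1 <- bh_reject(unname(simes), q)
  selected <- stage1$reject
  r <- sum(selected)
  level2 <- if (r > 0) q * r / m else NA_real_

  tests <- purrr::map_dfr(seq_along(fam_names), function(i) {
    p <- p_by_family[[i]]
    if (selected[i]) {
      res <- bh_reject(p, level2)
      tibble::tibble(family = fam_names[i], index = seq_along(p),
                     p_raw = p, p_adj = pmin(1, res$p_adj * m / r),
                     rejected = res$reject)
    } else {
      tibble::tibble(family = fam_names[i], index = seq_along(p),
                     p_raw = p, p_adj = NA_real_, rejected = FALSE)
    }
  })

  structure(list(
    family = tibble::tibble(
      family = fam_names,
      n_tests = lengths(p_by_family),
      simes_p = unname(simes),
      selected = selected),
    tests = tests,
    q = q, m_families = m, r_selected = r, stage2_level = level2
  ), class = "hier_fdr_result")
}

#' @export
print.hier_fdr_result <- function(x, ...) {
  cat(sprintf(
    "<hier_fdr_result: %d/%d families selected at q = %g; stage-2 level %s; %d rejections>\n",
    x$r_selected, x$m_families, x$q,
    if (is.na(x$stage2_level)) "-" else signif(x$stage2_level, 3),
    sum(x$tests$rejected)))
  print(x$family)
  invisible(x)
}

#' Empirical FDR of the hierarchical procedure under simulation
#'
#' Simulates replicate screens of independent tests grouped into families,
#' with a known subset of non-null tests, runs [hierarchical_fdr()] on each,
#' and records the false-discovery proportion (FDP) among within-family
#' detections (0 when nothing is rejected). Null p-values are two-sided
#' normal p-values of N(0, 1) draws (uniform); non-null tests draw their z
#' from N(`effect_z`, 1).
#'
#' @param n_rep Number of replicates.
#' @param n_families Number of families.
#' @param n_tests Tests per family.
#' @param n_nonnull_per_family Number of non-null tests in each of the first
#'   `n_signal_families` families.
#' @param n_signal_families Families carrying signal.
#' @param effect_z Mean of the non-null z distribution.
#' @param q Target FDR level.
#' @param seed Integer seed.
#' @return A tibble with one row per replicate: `fdp`, `n_rejected`,
#'   `n_false`; the empirical FDR is `mean(fdp)`.
#' @examples
#' sim <- simulate_hierarchical_fdr(n_rep = 50, seed = 1)
#' mean(sim$fdp)
#' @export
simulate_hierarchical_fdr <- function(n_rep = 2000, n_families = 6,
                                      n_tests = 50,
                                      n_nonnull_per_family = 10,
                                      n_signal_families = 2,
                                      effect_z = 3, q = 0.05, seed = 1) {
  stopifnot(n_signal_families <= n_families,
            n_nonnull_per_family <= n_tests)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_rep), function(rep) {
      fams <- lapply(seq_len(n_families), function(f) {
        mu <- rep(0, n_tests)
        if (f <= n_signal_families) {
          mu[seq_len(n_nonnull_per_family)] <- effect_z
        }
        z <- stats::rnorm(n_tests, mean = mu)
        list(p = 2 * stats::pnorm(-abs(z)), null = mu == 0)
      })
      names(fams) <- paste0("fam", seq_len(n_families))
      res <- hierarchical_fdr(lapply(fams, `[[`, "p"), q = q)
      nulls <- unlist(lapply(fams, `[[`, "null"), use.names = FALSE)
      rej <- res$tests$rejected
      n_rej <- sum(rej)
      n_false <- sum(rej & nulls)
      tibble::tibble(rep = rep, n_rejected = n_rej, n_false = n_false,
                     fdp = if (n_rej > 0) n_false / n_rej else 0)
    })
  })
}
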