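test_that("phantom generation is seed-deterministic and well-formed", {
  a <- make_phantom(seed = 11)
  b <- make_phantom(seed = 11)
  expect_identical(a$subject$gm_pve$data, b$subject$gm_pve$data)
  expect_identical(a$subject$wmh_mask$data, b$subject$wmh_mask$data)
  expect_identical(a$ground_truth, b$ground_truth)

  s <- a$subject
  expect_true(all(s$gm_pve$data >= 0 & s$gm_pve$data <= 1))
  expect_true(all(s$wmh_mask$data %in% c(0, 1)))
  expect_true(all(s$mo_map$data >= -1 & s$mo_map$data <= 1))
  shapes <- vapply(c(list(s$gm_pve, s$wmh_mask, s$csf_map, s$md_map),
                     s$structure_masks, a$atlas$lobar_masks,
                     a$atlas$wm_tract_masks),
                   function(g) paste(dim(g$data), collapse = "x"),
                   character(1))
  expect_length(unique(shapes), 1L)
  # every atlas mask nonempty
  expect_true(all(vapply(a$atlas$wm_tract_masks,
                         function(g) sum(g$data) > 0, logical(1))))
  # WMH restricted to the brain support (where GM/CSF live)
  expect_true(all(s$gm_pve$data[s$wmh_mask$data == 1] > 0))
})

test_that("zero lesion burden yields zero WMH-tract overlap everywhere", {
  ph <- make_phantom(seed = 1, wmh_burden = 0)
  wmh_truth <- dplyr::filter(ph$ground_truth,
                             grepl("_wmh_volume$", idp_name))
  expect_equal(nrow(wmh_truth), 48L)
  expect_true(all(wmh_truth$value == 0))
})

test_that("ground-truth volumes equal the brute-force voxel oracle", {
  ph <- make_phantom(seed = 2, wmh_burden = 0.05, shape = c(16, 16, 16))
  s <- ph$subject
  at <- ph$atlas
  vox <- s$gm_pve$voxel_size
  gm_corr <- s$gm_pve$data * (1 - s$wmh_mask$data)

  for (lb in c("frontal", "temporal")) {
    expect_equal(
      ph$ground_truth$value[
        ph$ground_truth$idp_name == paste0("gm_", lb, "_lobe_volume")],
      oracle_volume(gm_corr * at$lobar_masks[[lb]]$data, vox))
  }
  some_tracts <- names(at$wm_tract_masks)[c(1, 17, 48)]
  for (tr in some_tracts) {
    expect_equal(
      ph$ground_truth$value[
        ph$ground_truth$idp_name == paste0(tr, "_wmh_volume")],
      oracle_overlap_count(s$wmh_mask$data, at$wm_tract_masks[[tr]]$data) *
        prod(vox))
  }
  expect_equal(
    ph$ground_truth$value[ph$ground_truth$idp_name == "nbm_l_volume"],
    oracle_volume(gm_corr * at$nbm_masks$nbm_l$data, vox))
})

test_that("degenerate phantom parameters are rejected", {
  expect_error(make_phantom(seed = 1, shape = c(8, 16, 16)), ">= 16")
  expect_error(make_phantom(seed = 1, wmh_burden = 1.5), "\\[0, 1\\]")
})

test_that("cohort tables have the contracted shape and determinism", {
  truth <- cohort_truth(planted_beta = list(sig = c(age = 0.5)),
                        null_idp_names = c("n1", "n2"))
  co <- make_cohort(10, truth, seed = 4)
  expect_equal(nrow(co$phenotypes), 10L)
  expect_equal(nrow(co$idps), 30L)
  expect_true(is.ordered(co$phenotypes$diagnosis))
  expect_identical(levels(co$phenotypes$diagnosis),
                   c("no_drd", "mci", "dementia"))
  expect_true(all(co$phenotypes$ace_total >= 0 &
                    co$phenotypes$ace_total <= 100))
  co2 <- make_cohort(10, truth, seed = 4)
  expect_identical(co, co2)
})

test_that("a planted linear effect is recovered within 3 standard errors", {
  truth <- cohort_truth(planted_beta = list(sig = c(age = 0.5)),
                        null_idp_names = "n1")
  co <- make_cohort(2000, truth, seed = 9)
  wide <- tidyr::pivot_wider(co$idps, names_from = "idp_name",
                             values_from = "value",
                             id_cols = "subject_id")
  dat <- dplyr::inner_join(co$phenotypes, wide, by = "subject_id")
  fit <- lm(scale(age) ~ sig, data = dat)
  est <- coef(summary(fit))["sig", ]
  expect_lt(abs(est[["Estimate"]] - 0.5), 3 * est[["Std. Error"]])
})

test_that("declaring an IDP both planted and null is rejected", {
  expect_error(cohort_truth(planted_beta = list(a = c(age = 0.2)),
                            null_idp_names = "a"), "both planted and null")
  expect_error(cohort_truth(planted_beta = list(a = c(bogus = 0.2))),
               "named among")
  truth <- cohort_truth(planted_beta = list(a = c(age = 0.2)))
  expect_error(make_cohort(5, truth), "at least 10")
})

test_that("IQM tables plant detectable outliers and are reproducible", {
  tab <- make_iqm_table(30, 5, outlier_ids = 3, seed = 6)
  expect_identical(tab, make_iqm_table(30, 5, outlier_ids = 3, seed = 6))
  flags <- iqr_flags(tab)
  expect_true(flags$flagged[flags$scan_id == "scan_03"])

  # without planted outliers the flag fraction stays small
  clean <- make_iqm_table(100, 5, seed = 7)
  frac <- mean(iqr_flags(clean)$flagged)
  expect_gte(frac, 0)
  expect_lt(frac, 0.3)

  expect_error(make_iqm_table(4), "at least 5")
  expect_error(make_iqm_table(10, outlier_ids = "scan_99"), "subset")
})

test_that("BOLD series carry spikes where requested", {
  bold <- make_bold(seed = 2, shape = c(8, 8, 8), n_time = 10)
  expect_equal(dim(bold), c(8, 8, 8, 10))
  expect_identical(bold, make_bold(seed = 2, shape = c(8, 8, 8), n_time = 10))
  expect_error(make_bold(seed = 1, n_time = 5), "at least 10")
  expect_error(make_bold(seed = 1, n_time = 20, spike_timepoints = 25),
               "within")

  # spike at t = 20: fast variance maximal at the transitions into/out of it
  spiked <- make_bold(seed = 3, shape = c(8, 8, 8), n_time = 40,
                      spike_timepoints = 20)
  d <- dse_decompose(spiked)
  top2 <- d$transitions$t[order(-d$transitions$pct_d)][1:2]
  expect_setequal(top2, c(19, 20))

  # homogeneous noise: fast share fluctuates around its null 50% share
  calm <- dse_decompose(make_bold(seed = 4, shape = c(8, 8, 8), n_time = 100))
  expect_lt(abs(calm$global[["pct_d"]] - 50), 5)
})
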