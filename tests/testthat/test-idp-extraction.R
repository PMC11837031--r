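test_that("lesion masking equals the elementwise rule and never adds GM", {
  gm <- random_grid(1)
  wmh <- random_mask(2)
  out <- lesion_mask_gm(gm, wmh)
  expect_equal(out$data, gm$data * (1 - wmh$data))
  expect_true(all(out$data <= gm$data))

  # identity when no lesions; forced arithmetic when GM is full
  zero <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_identical(lesion_mask_gm(gm, zero)$data, gm$data)
  full <- volume_grid(array(1, c(16, 16, 16)), c(2, 2, 2))
  k <- sum(wmh$data)
  expect_equal(sum(lesion_mask_gm(full, wmh)$data) * voxel_volume(full),
               (prod(dim(full$data)) - k) * voxel_volume(full))

  small <- volume_grid(array(0, c(16, 16, 17)), c(2, 2, 2))
  expect_error(lesion_mask_gm(gm, small), "shape mismatch")
})

test_that("CSF masking removes exactly the above-threshold voxels", {
  m <- random_mask(3)
  csf <- random_grid(4)
  out <- csf_mask_structure(m, csf, 0.5)
  expect_equal(out$data, m$data * (1 - (csf$data > 0.5)))
  expect_true(all(out$data <= m$data))

  zero <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_identical(csf_mask_structure(m, zero)$data, m$data)

  # csf = 1 on exactly half the structure halves the volume
  half <- array(0, c(16, 16, 16))
  str_mask <- array(0, c(16, 16, 16))
  str_mask[1:4, 1, 1] <- 1
  half[1:2, 1, 1] <- 1
  out <- csf_mask_structure(volume_grid(str_mask, c(2, 2, 2)),
                            volume_grid(half, c(2, 2, 2)), 0.5)
  expect_equal(sum(out$data), 2)

  # boundary: exactly-at-threshold voxels survive (strict >)
  at <- volume_grid(array(0.5, c(16, 16, 16)), c(2, 2, 2))
  expect_identical(csf_mask_structure(m, at, 0.5)$data, m$data)
  expect_error(csf_mask_structure(m, csf, 0), "\\(0, 1\\]")
})

test_that("mislocalisation detection counts overlap fractions correctly", {
  inside <- random_mask(5, p = 0.2)
  csf_all <- volume_grid(array(1, c(16, 16, 16)), c(2, 2, 2))
  csf_none <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_true(detect_mislocalised(inside, csf_all))
  expect_false(detect_mislocalised(inside, csf_none))

  # 50% overlap: below the full-overlap default, at a 0.5 threshold flagged
  m <- array(0, c(16, 16, 16)); m[1:4, 1, 1] <- 1
  c2 <- array(0, c(16, 16, 16)); c2[1:2, 1, 1] <- 1
  mg <- volume_grid(m, c(2, 2, 2)); cg <- volume_grid(c2, c(2, 2, 2))
  expect_false(detect_mislocalised(mg, cg, 1))
  expect_true(detect_mislocalised(mg, cg, 0.5))

  empty <- volume_grid(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_error(detect_mislocalised(empty, cg), "empty")
})

test_that("volume operators match forced arithmetic and the voxel oracle", {
  shape <- c(16, 16, 16)
  vox1 <- c(1, 1, 1)
  # 100-voxel lobe of solid GM at 2 mm -> 800 mm^3
  lobe <- array(0, shape); lobe[1:10, 1:10, 1] <- 1
  gm1 <- volume_grid(array(1, shape), c(2, 2, 2))
  masks <- lapply(c(frontal = 1, parietal = 2, temporal = 3, occipital = 4),
                  function(i) volume_grid(lobe, c(2, 2, 2)))
  out <- lobar_gm_volumes(gm1, masks)
  expect_equal(out$value, rep(800, 4))
  expect_equal(out$modality, rep("T1", 4))

  gm0 <- volume_grid(array(0, shape), c(2, 2, 2))
  expect_true(all(lobar_gm_volumes(gm0, masks)$value == 0))
  expect_error(lobar_gm_volumes(gm1, masks[1:3]), "missing lobe")

  # NBM: gm = 0.5 over a 100-voxel mask at 1 mm -> 50 mm^3
  nbm <- list(nbm_l = volume_grid(lobe, vox1), nbm_r = volume_grid(lobe, vox1))
  gmh <- volume_grid(array(0.5, shape), vox1)
  expect_equal(nbm_volumes(nbm, gmh)$value, c(50, 50))
  expect_error(nbm_volumes(nbm["nbm_l"], gmh), "missing hemisphere")

  # random weighted sums against the triple-loop oracle
  gm <- random_grid(10)
  m <- random_mask(11)
  got <- lobar_gm_volumes(gm, list(frontal = m, parietal = m, temporal = m,
                                   occipital = m))$value[1]
  expect_equal(got, oracle_volume(gm$data * m$data, gm$voxel_size))
})

test_that("tract-wise WMH volumes count overlaps per tract", {
  shape <- c(16, 16, 16)
  tract_names <- wm_atlas_tract_names()
  empty_masks <- stats::setNames(
    rep(list(volume_grid(array(c(1, rep(0, prod(shape) - 1)), shape),
                         c(2, 2, 2))), 48), tract_names)
  wmh0 <- volume_grid(array(0, shape), c(2, 2, 2))
  out <- tractwise_wmh_volumes(wmh0, empty_masks)
  expect_equal(nrow(out), 48L)
  expect_true(all(out$value == 0))
  expect_true(all(out$modality == "T2-FLAIR"))

  # constructed 10-voxel overlap at 2 mm isotropic -> 80 mm^3
  wmh <- array(0, shape); wmh[1:10, 1, 1] <- 1
  tr <- array(0, shape); tr[1:10, 1, ] <- 1
  out <- tractwise_wmh_volumes(
    volume_grid(wmh, c(2, 2, 2)),
    list(a = volume_grid(tr, c(2, 2, 2))))
  expect_equal(out$value, 80)

  dup <- stats::setNames(empty_masks[1:2], c("x", "x"))
  expect_error(tractwise_wmh_volumes(wmh0, dup), "uniquely named")

  # random masks vs the overlap-counting oracle
  w <- random_mask(12); t2 <- random_mask(13)
  got <- tractwise_wmh_volumes(w, list(t = t2))$value
  expect_equal(got, oracle_overlap_count(w$data, t2$data) * 8)
})

test_that("PSMD follows the declared percentile rule and its invariances", {
  shape <- c(16, 16, 16)
  sk <- array(0, shape); sk[1:100] <- 1        # linear indexing
  skg <- volume_grid(sk, c(2, 2, 2))
  md <- array(0, shape); md[1:100] <- 1:100
  mdg <- volume_grid(md, c(2, 2, 2))

  expect_equal(psmd(mdg, skg), oracle_psmd(md, sk))

  const <- volume_grid(array(5, shape), c(2, 2, 2))
  expect_equal(psmd(const, skg), 0)

  # translation invariance and positive homogeneity
  md2 <- volume_grid(md + 7, c(2, 2, 2))
  expect_equal(psmd(md2, skg), psmd(mdg, skg))
  md3 <- volume_grid(md * 3.5, c(2, 2, 2))
  expect_equal(psmd(md3, skg), 3.5 * psmd(mdg, skg))

  empty <- volume_grid(array(0, shape), c(2, 2, 2))
  expect_error(psmd(mdg, empty), "empty")

  # random values against the sort-and-interpolate oracle
  r <- random_grid(14, lo = 0.0005, hi = 0.002)
  m <- random_mask(15)
  expect_equal(psmd(r, m), oracle_psmd(r$data, m$data))
})

test_that("tract volumes binarise densities with a strict threshold", {
  shape <- c(16, 16, 16)
  zero <- volume_grid(array(0, shape), c(2, 2, 2))
  expect_equal(tract_volume(zero), 0)

  d <- array(0, shape); d[1:20] <- 0.01
  expect_equal(tract_volume(volume_grid(d, c(2, 2, 2))), 160)

  at_thr <- volume_grid(array(0.005, shape), c(2, 2, 2))
  expect_equal(tract_volume(at_thr), 0)

  neg <- volume_grid(array(-0.1, shape), c(2, 2, 2))
  expect_error(tract_volume(neg), "negative|\\[0, 1\\]")
})

test_that("regional diffusion is the PVE-weighted mean, missing when empty", {
  shape <- c(16, 16, 16)
  # two-voxel ROI with MD (1, 3) and weights (1, 3) -> 2.5
  md <- array(0, shape); md[1, 1, 1] <- 1; md[2, 1, 1] <- 3
  gm <- array(0, shape); gm[1, 1, 1] <- 0.25; gm[2, 1, 1] <- 0.75
  roi <- array(0, shape); roi[1:2, 1, 1] <- 1
  out <- regional_diffusion(volume_grid(md), volume_grid(md * 0),
                            list(r = volume_grid(roi)), volume_grid(gm))
  expect_equal(out$value[out$idp_name == "r_md"], 2.5)

  # constant metric: weighted mean is that constant for any positive weights
  mdc <- volume_grid(array(4.2, shape))
  gmr <- random_grid(16, vox = c(1, 1, 1))
  roi_m <- random_mask(17, vox = c(1, 1, 1))
  out <- regional_diffusion(mdc, mdc, list(r = roi_m), gmr)
  expect_equal(out$value, c(4.2, 4.2))

  # random fields vs the loop oracle
  mo <- random_grid(18, vox = c(1, 1, 1), lo = -0.5, hi = 0.9)
  out <- regional_diffusion(gmr, mo, list(r = roi_m), gmr)
  expect_equal(out$value[2],
               oracle_weighted_mean(mo$data, gmr$data * roi_m$data))

  # zero total weight -> missing, not zero
  gm0 <- volume_grid(array(0, shape))
  out <- regional_diffusion(mdc, mdc, list(r = roi_m), gm0)
  expect_true(all(is.na(out$value)))
})

test_that("extract_all emits the full deterministic supplementary IDP set", {
  ph <- make_phantom(seed = 21, wmh_burden = 0.04)
  idps <- extract_all(ph$subject, ph$atlas, subject_id = "s1")
  expect_equal(nrow(idps), 110L)
  expect_equal(anyDuplicated(idps$idp_name), 0L)
  expect_identical(extract_all(ph$subject, ph$atlas, subject_id = "s1"), idps)

  # modality composition of the default configuration
  counts <- table(idps$modality)
  expect_equal(unname(counts[c("T1", "T2-FLAIR", "dMRI")]),
               c(6L, 48L, 56L), ignore_attr = TRUE)

  # every volume IDP agrees with the generator's counted truth
  m <- dplyr::inner_join(idps, ph$ground_truth, by = c("idp_name", "modality"),
                         suffix = c("", "_truth"))
  expect_equal(nrow(m), 110L)
  expect_equal(m$value, m$value_truth)

  # lobar volumes cannot exceed the total corrected GM volume
  gm_corr <- lesion_mask_gm(ph$subject$gm_pve, ph$subject$wmh_mask)
  total_gm <- sum(gm_corr$data) * voxel_volume(gm_corr)
  lobar_sum <- sum(idps$value[grepl("_lobe_volume$", idps$idp_name)])
  expect_lte(lobar_sum, total_gm)
})

test_that("mislocalised structures yield missing regional IDPs", {
  ph <- make_phantom(seed = 22)
  # drown the left hippocampus in CSF so it fully overlaps thresholded CSF
  csf <- ph$subject$csf_map$data
  csf[ph$subject$structure_masks$hippocampus_l$data == 1] <- 0.95
  ph$subject$csf_map <- volume_grid(csf, ph$subject$csf_map$voxel_size)
  idps <- extract_all(ph$subject, ph$atlas)
  expect_equal(nrow(idps), 110L)
  expect_true(all(is.na(
    idps$value[idps$idp_name %in% c("hippocampus_l_md", "hippocampus_l_mo")])))
  expect_false(anyNA(
    idps$value[idps$idp_name %in% c("hippocampus_r_md", "hippocampus_r_mo")]))
})
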