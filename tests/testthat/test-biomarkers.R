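test_that("epithelial depth is the mask height in micrometres", {
  s <- flat_surfaces(1, 2, top = 11, boundary = 27)
  rm <- build_region_masks(s, matrix(61L, 1, 2), n_z = 80)
  expect_equal(as.numeric(epithelial_depth_map(rm)), c(160, 160))

  # loss A-line: the full visualized depth counts as epithelium
  s2 <- surface_set(matrix(11L, 1, 1), matrix(NA_integer_, 1, 1))
  rm2 <- build_region_masks(s2, matrix(61L, 1, 1), n_z = 80)
  expect_equal(as.numeric(epithelial_depth_map(rm2)), 500)

  # no tissue -> missing
  s3 <- surface_set(matrix(NA_integer_, 1, 1), matrix(NA_integer_, 1, 1))
  rm3 <- build_region_masks(s3, matrix(NA_integer_, 1, 1), n_z = 80)
  expect_true(is.na(epithelial_depth_map(rm3)[1, 1]))
})

test_that("loss percentage counts loss A-lines among artifact-free tissue", {
  mk <- function(loss_idx, top_na = integer(0)) {
    top <- matrix(11L, 10, 10)
    top[top_na] <- NA
    bnd <- matrix(27L, 10, 10)
    bnd[loss_idx] <- NA
    bnd[is.na(top)] <- NA
    build_region_masks(surface_set(top, bnd), matrix(61L, 10, 10), 80)
  }
  masks0 <- full_masks(10, 10)
  expect_equal(loss_of_boundary_pct(mk(integer(0)), masks0), 0)
  expect_equal(loss_of_boundary_pct(mk(1:50), masks0), 50)

  # 10 flagged of 100 tissue A-lines, 15 artifact A-lines of which 5 are
  # flagged: 100 * 5 / 85
  rm <- mk(1:10)
  art <- matrix(FALSE, 10, 10)
  art[6:20] <- TRUE                      # covers 5 of the flagged cells
  masks <- enface_masks(matrix(TRUE, 10, 10), artifact = art)
  expect_equal(loss_of_boundary_pct(rm, masks), 100 * 5 / 85)

  # all-artifact denominator errors
  expect_error(loss_of_boundary_pct(mk(1:10),
               enface_masks(matrix(TRUE, 10, 10),
                            artifact = matrix(TRUE, 10, 10))), "no tissue")
})

test_that("stratification is the normalized attenuation contrast", {
  expect_equal(round(stratification(1.22, 3.71), 2), -0.51)
  expect_equal(stratification(2.4, 2.4), 0)
  expect_equal(stratification(1.5, 0), 1)
  expect_true(is.na(stratification(0, 0)))
  expect_error(stratification(-1, 2), ">= 0")
})

test_that("stratification stays in [-1, 1] and negates under argument swap", {
  set.seed(13)
  a <- runif(500, 0, 10); b <- runif(500, 0, 10)
  s <- stratification(a, b)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(stratification(b, a), -s)
})

test_that("the full pipeline recovers a noiseless contralateral phantom", {
  sp <- phantom_preset("contralateral", seed = 3, n_frames = 8, n_y = 64,
                       n_z = 200)
  sp$speckle <- FALSE
  ph <- generate_phantom(sp)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
  contact <- ph$truth$masks$contact
  expect_true(all(maps$depth_um[contact] == 160))
  expect_true(all(is.na(maps$depth_um[!contact])))
  expect_equal(maps$loss_pct, 0)
  vs <- volume_summary(maps, ph$truth$masks, role = "contralateral")
  expect_equal(vs$mu_epi, 1.20, tolerance = 0.005)
  expect_equal(vs$mu_stroma, 3.97, tolerance = 0.005)
  expect_equal(vs$es_strat, (1.20 - 3.97) / (1.20 + 3.97), tolerance = 0.01)
  expect_equal(vs$ie_strat, 0, tolerance = 0.005)
})

test_that("equal-attenuation layers give zero epithelial-stromal stratification", {
  # mu high enough that the signal decays below the floor well above the
  # noise-floor estimation window of the 2 mm grid
  sp <- phantom_spec(n_frames = 4, n_y = 32, n_z = 200, surface_z_um = 100,
                     epi_depth_um = 160, mu_epi_mm = 3.5, mu_stroma_mm = 3.5,
                     backscatter_epi = 1, backscatter_stroma = 1,
                     speckle = FALSE, taper_frames = 0, contact_frames = 2:3,
                     seed = 4)
  ph <- generate_phantom(sp)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
  vs <- volume_summary(maps, ph$truth$masks, role = "contralateral")
  expect_equal(vs$es_strat, 0, tolerance = 0.01)
})

test_that("artifact A-lines are missing in every map", {
  sp <- phantom_preset("contralateral", seed = 5, n_frames = 8, n_y = 48,
                       n_z = 200)
  ph <- generate_phantom(sp)
  art <- matrix(FALSE, 8, 48); art[4, 10:20] <- TRUE
  masks <- enface_masks(ph$truth$masks$contact, artifact = art)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, masks)
  for (nm in c("depth_um", "mu_overall", "mu_epi", "mu_stroma",
               "es_strat", "ie_strat"))
    expect_true(all(is.na(maps[[nm]][art])), info = nm)
})

test_that("volume summary takes medians over the retained A-lines only", {
  sp <- phantom_preset("contralateral", seed = 6, n_frames = 12, n_y = 40,
                       n_z = 200)
  sp$speckle <- FALSE
  ph <- generate_phantom(sp)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
  vs <- volume_summary(maps, ph$truth$masks, role = "contralateral")
  # uniform phantom: medians equal the uniform values
  expect_equal(vs$depth_um, 160)

  # planting extreme values in artifact-only A-lines leaves medians unchanged
  art <- matrix(FALSE, 12, 40); art[6, 1:10] <- TRUE
  masks2 <- enface_masks(ph$truth$masks$contact, artifact = art)
  maps2 <- compute_biomarkers(ph$volume, ph$truth$surfaces, masks2)
  vs2 <- volume_summary(maps2, masks2, role = "contralateral")
  maps3 <- maps2
  for (nm in c("depth_um", "mu_overall", "mu_epi", "mu_stroma",
               "es_strat", "ie_strat"))
    maps3[[nm]][art] <- 1e9
  vs3 <- volume_summary(maps3, masks2, role = "contralateral")
  for (nm in c("depth_um", "mu_overall", "mu_epi", "mu_stroma",
               "es_strat", "ie_strat"))
    expect_identical(vs3[[nm]], vs2[[nm]], info = nm)

  # odd-count median
  expect_equal(stats::median(c(100, 160, 700)), 160)
  expect_error(volume_summary(maps, enface_masks(matrix(FALSE, 12, 40)),
                              role = "lesion"), "retained")
})

test_that("lesion restriction limits the summary to the labelled area", {
  sp <- phantom_preset("observation_lesion", seed = 8, n_frames = 16,
                       n_y = 64, n_z = 200)
  ph <- generate_phantom(sp)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
  vs <- volume_summary(maps, ph$truth$masks, restrict_to_lesion = TRUE,
                       role = "lesion")
  eroded <- erode_central(ph$truth$masks$contact)
  keep <- eroded & !ph$truth$masks$artifact & ph$truth$masks$lesion
  expect_equal(vs$n_alines, sum(keep))
  expect_equal(vs$depth_um, stats::median(maps$depth_um[keep], na.rm = TRUE))
})

test_that("biomarker maps export to a directory of files", {
  sp <- phantom_preset("contralateral", seed = 9, n_frames = 6, n_y = 32,
                       n_z = 200)
  ph <- generate_phantom(sp)
  maps <- compute_biomarkers(ph$volume, ph$truth$surfaces, ph$truth$masks)
  d <- file.path(tempdir(), "maps_out")
  write_biomarkers(maps, d)
  expect_true(file.exists(file.path(d, "depth_um.tif")))
  expect_true(file.exists(file.path(d, "es_strat.csv")))
  expect_true(file.exists(file.path(d, "loss_mask.tif")))
  expect_true(file.exists(file.path(d, "biomarkers.png")))
})
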