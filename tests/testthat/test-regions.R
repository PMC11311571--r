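test_that("noise floor is the smoothed bottom-region mean over tissue A-lines", {
  frame <- matrix(-80, 60, 12)
  top <- rep(5L, 12)
  expect_equal(noise_floor(frame, top), -80)

  # A-lines without a surface are excluded
  frame2 <- matrix(-50, 60, 20)
  frame2[, 1:10] <- -70
  top2 <- c(rep(5L, 10), rep(NA_integer_, 10))
  expect_equal(noise_floor(frame2, top2), -70)

  expect_error(noise_floor(frame, rep(NA_integer_, 12)), "no A-line")
})

test_that("noise floor matches a brute-force Gaussian convolution oracle", {
  set.seed(3)
  frame <- matrix(ifelse((row(matrix(0, 60, 10)) + col(matrix(0, 60, 10))) %% 2 == 0,
                         -60, -80), 60, 10)
  top <- rep(3L, 10)
  # independent oracle: direct 5x5 convolution of the bottom-25-row region
  # with reflected borders
  k1 <- exp(-(-2:2)^2 / 2); k <- outer(k1, k1); k <- k / sum(k)
  pad <- function(m, r) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- c(r:1, 1:nr, nr:(nr - r + 1)); ci <- c(r:1, 1:nc, nc:(nc - r + 1))
    m[ri, ci]
  }
  region <- frame[36:60, ]
  mp <- pad(region, 2)
  sm <- matrix(0, 25, 10)
  for (i in 1:25) for (j in 1:10)
    sm[i, j] <- sum(k * mp[i:(i + 4), j:(j + 4)])
  expect_equal(noise_floor(frame, top), mean(sm), tolerance = 1e-12)
})

test_that("noise floor ignores how surface-free columns are arranged", {
  set.seed(8)
  frame <- matrix(rnorm(50 * 16, -70, 4), 50, 16)
  top <- c(rep(4L, 8), rep(NA_integer_, 8))
  f1 <- noise_floor(frame, top)
  # permute the excluded columns' contents
  frame2 <- frame
  frame2[, 9:16] <- frame[, c(12:16, 9:11)]
  expect_equal(noise_floor(frame2, top), f1)
})

test_that("visualized bottom follows the 6 dB rule with a sustained-drop filter", {
  nz <- 100
  aline <- c(rep(-40, 60), rep(-80, nz - 60))
  expect_equal(visualized_bottom(aline, floor_db = -80, epi_top = 1), 61)

  # everywhere above threshold -> capped 25 px above the end
  expect_equal(visualized_bottom(rep(-40, nz), -80, 1), nz - 24)

  # a single-pixel dip is ignored (k = 3), a 3-px dip is not
  dip1 <- rep(-40, nz); dip1[30] <- -80
  expect_equal(visualized_bottom(dip1, -80, 1), nz - 24)
  dip3 <- rep(-40, nz); dip3[30:32] <- -80
  expect_equal(visualized_bottom(dip3, -80, 1), 30)

  # below threshold already at the top -> empty region signalled
  expect_equal(visualized_bottom(rep(-80, nz), -80, 5), 5)
})

test_that("region masks implement the layer rules and the loss assumption", {
  # top 11, boundary 27, bottom 61 (1-based): |E| = 16 px, S spans 27..60
  s <- flat_surfaces(1, 4, top = 11, boundary = 27)
  rm <- build_region_masks(s, matrix(61L, 1, 4), n_z = 80)
  E <- region_array(rm, "E"); S <- region_array(rm, "S")
  expect_equal(sum(E[, 1, 1]), 16)
  expect_equal(which(S[, 1, 1]), 27:60)
  expect_false(any(E & S))

  # boundary missing: whole visualized depth is epithelium, loss flagged
  s2 <- surface_set(matrix(11L, 1, 2), matrix(NA_integer_, 1, 2))
  rm2 <- build_region_masks(s2, matrix(51L, 1, 2), n_z = 80)
  expect_equal(sum(region_array(rm2, "E")[, 1, 1]), 40)
  expect_equal(sum(region_array(rm2, "S")), 0)
  expect_true(all(rm2$loss))

  # odd epithelium splits favour the upper half: |E| = 15 -> UE 8, LE 7
  s3 <- flat_surfaces(1, 1, top = 11, boundary = 26)
  rm3 <- build_region_masks(s3, matrix(61L, 1, 1), n_z = 80)
  expect_equal(sum(region_array(rm3, "UE")), 8)
  expect_equal(sum(region_array(rm3, "LE")), 7)

  expect_error(surface_set(matrix(20L, 1, 1), matrix(20L, 1, 1)), "strictly")
})

test_that("mask partition invariants hold on randomized cases", {
  set.seed(11)
  for (rep in 1:5) {
    nf <- 2; ny <- 12; nz <- 60
    top <- matrix(sample(5:15, nf * ny, TRUE), nf, ny)
    bnd <- top + matrix(sample(2:20, nf * ny, TRUE), nf, ny)
    bnd[sample(length(bnd), 5)] <- NA
    top[sample(length(top), 3)] <- NA
    bnd[is.na(top)] <- NA
    bots <- matrix(36L + sample(0:5, nf * ny, TRUE), nf, ny)
    s <- surface_set(top, bnd)
    rm <- build_region_masks(s, bots, nz)
    E <- region_array(rm, "E"); S <- region_array(rm, "S")
    UE <- region_array(rm, "UE"); LE <- region_array(rm, "LE")
    V <- region_array(rm, "visualized")
    expect_false(any(E & S))
    expect_identical(UE | LE, E)
    expect_false(any(UE & LE))
    expect_true(all((E | S) <= V))
    # loss <=> top present and boundary missing; loss implies S empty
    expect_identical(rm$loss, !is.na(top) & is.na(bnd))
    for (f in 1:nf) for (y in 1:ny) {
      if (isTRUE(rm$loss[f, y])) expect_equal(sum(S[, y, f]), 0)
      if (!is.na(top[f, y]) && !is.na(bnd[f, y]) && bnd[f, y] < bots[f, y])
        expect_equal(sum(E[, y, f]) + sum(S[, y, f]), bots[f, y] - top[f, y])
    }
  }
})

test_that("azimuthal erosion retains the centred half of each contact run", {
  m <- matrix(FALSE, 10, 1); m[1:4, 1] <- TRUE
  expect_equal(which(erode_central(m)[, 1]), 2:3)

  m2 <- matrix(FALSE, 120, 1); m2[1:100, 1] <- TRUE
  expect_equal(which(erode_central(m2)[, 1]), 26:75)

  expect_equal(sum(erode_central(matrix(FALSE, 10, 3))), 0)

  # a single-frame strip still contributes
  m3 <- matrix(FALSE, 10, 1); m3[5, 1] <- TRUE
  expect_equal(which(erode_central(m3)[, 1]), 5)
})

test_that("erosion is dominated by idempotence and never grows the mask", {
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(40 * 6) < 0.6, 40, 6)
    e1 <- erode_central(m)
    e2 <- erode_central(e1)
    expect_true(all(e1 <= m))
    expect_true(all(e2 <= e1))
  }
})

test_that("surfaces and en face masks round-trip through their file formats", {
  set.seed(2)
  top <- matrix(sample(5:10, 12, TRUE), 3, 4)
  bnd <- top + matrix(sample(3:9, 12, TRUE), 3, 4)
  bnd[1, 2] <- NA; top[2, 3] <- NA; bnd[2, 3] <- NA
  s <- surface_set(top, bnd)
  p <- file.path(tempdir(), "surf.json")
  write_surfaces(s, p)
  s2 <- read_surfaces(p)
  expect_identical(s2$epi_top, s$epi_top)
  expect_identical(s2$boundary, s$boundary)

  masks <- enface_masks(matrix(c(TRUE, FALSE), 4, 6),
                        artifact = matrix(runif(24) < 0.2, 4, 6),
                        lesion = matrix(runif(24) < 0.5, 4, 6))
  d <- file.path(tempdir(), "masks")
  write_masks(masks, d)
  m2 <- read_masks(d)
  expect_identical(m2$contact, masks$contact)
  expect_identical(m2$artifact, masks$artifact)
  expect_identical(m2$lesion, masks$lesion)
})
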