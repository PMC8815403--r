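## simple fabricated section: horizontal band(s) over a flat background
flat_section <- function(value = 1, nr = 200, nc = 200, scale = 0.2,
                         bands = list()) {
  img <- matrix(value, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  mask[(nr - 40):(nr - 10), ] <- TRUE
  section_image(img, scale, mask, bands)
}

test_that("ONL normalization sets the background mean to 1", {
  ## constant image becomes all ones
  si <- flat_section(value = 40)
  n <- normalize_by_onl(si)
  expect_true(all(n$img == 1))

  ## scale invariance of the normalization itself
  si2 <- si; si2$img <- si$img * 2.7
  expect_equal(normalize_by_onl(si2)$img, n$img)

  ## synthetic image with ONL mean 40
  set.seed(141)
  si3 <- flat_section(value = 1)
  si3$img <- matrix(rnorm(200 * 200, 100, 5), 200, 200)
  si3$img[si3$onl_mask] <- 40
  expect_equal(mean(normalize_by_onl(si3)$img[si3$onl_mask]), 1)

  ## zero ONL mean errors
  si4 <- flat_section(value = 0)
  expect_error(normalize_by_onl(si4), "zero ONL mean")
})

test_that("ROI averaging along a band recovers a uniform band level", {
  ## band much wider than the 6 um ROI so every ROI pixel sits in the band
  nr <- 300; nc <- 300; scale <- 0.2
  img <- matrix(1, nr, nc)
  img[100:180, ] <- 5                       # 16 um thick band
  mask <- matrix(FALSE, nr, nc); mask[250:290, ] <- TRUE
  band <- cbind(x = seq(20, 280, length.out = 30), y = rep(140, 30))
  si <- section_image(img, scale, mask, list(band))
  nsi <- normalize_by_onl(si)               # background already 1
  got <- band_roi_intensity(nsi, 1, roi_size_um = 6)
  expect_equal(as.numeric(got), 5, tolerance = 0.02)

  ## band below background everywhere: thresholded to zero
  img2 <- img; img2[100:180, ] <- 0.5
  si2 <- section_image(img2, scale, mask, list(band))
  expect_equal(as.numeric(band_roi_intensity(normalize_by_onl(si2), 1)), 0)

  ## above-threshold linearity: doubling the band amplitude doubles the
  ## measure when the ROI lies inside the band
  img3 <- img; img3[100:180, ] <- 10
  si3 <- section_image(img3, scale, mask, list(band))
  expect_equal(as.numeric(band_roi_intensity(normalize_by_onl(si3), 1)),
               2 * as.numeric(got), tolerance = 1e-6)

  ## polyline shorter than one ROI errors
  short <- cbind(x = c(10, 20), y = c(140, 140))  # 2 px = 0.4 um
  expect_error(band_roi_intensity(nsi, short), "shorter than one ROI")
})

test_that("central window sum tracks the profile maximum", {
  ## symmetric triangular profile, hand-summed central region
  prof <- data.frame(offset_um = seq(-2, 2, by = 0.25),
                     intensity = 10 - 4 * abs(seq(-2, 2, by = 0.25)))
  ## window 1.1 um: offsets within +/- 0.55 of the peak at 0:
  ## -0.5, -0.25, 0, 0.25, 0.5 -> 8 + 9 + 10 + 9 + 8 = 44
  expect_equal(central_window_sum(prof, 1.1), 44)

  ## window wider than the profile: total = full sum
  expect_equal(central_window_sum(prof, 100), sum(prof$intensity))

  ## lateral shift leaves the total unchanged (window tracks the maximum)
  shifted <- prof
  shifted$intensity <- c(tail(prof$intensity, 5), head(prof$intensity, -5))
  expect_equal(central_window_sum(shifted, 1.1),
               central_window_sum(prof, 1.1))

  expect_error(central_window_sum(prof[0, ], 1.1), "empty profile")
})

test_that("retina summaries and two-stage cohort normalization", {
  expect_equal(summarize_retina(3.7), 3.7)       # single section: identity
  expect_equal(summarize_retina(c(1, 2, 3, 6)), 3)
  expect_error(summarize_retina(numeric()), "no sections")

  ## pair already centered: unchanged after slide normalization
  df <- data.frame(slide = "s1", pair = "p1", value = c(0.8, 1.2))
  expect_equal(normalize_cohort(df)$normalized, c(0.8, 1.2))

  ## pair (2, 6) -> (0.5, 1.5)
  df2 <- data.frame(slide = c("s1", "s1"), pair = "p1", value = c(2, 6))
  expect_equal(normalize_cohort(df2)$normalized, c(0.5, 1.5))

  expect_error(normalize_cohort(df2[0, ]), "empty group")
})

test_that("full quantification chain is invariant to global rescaling", {
  for (seed in c(151, 152)) {
    pair <- simulate_section_pair(seed, wt_amplitude = 250,
                                  ko_amplitude = 325)
    m <- section_band_measure(pair$wt)
    for (k in c(0.5, 2.7, 100)) {
      si <- pair$wt
      si$img <- si$img * k
      expect_equal(section_band_measure(si), m, tolerance = 1e-12)
    }
    ## ROI route too
    nsi <- normalize_by_onl(pair$wt)
    r <- band_roi_intensity(nsi, 1)
    si2 <- pair$wt; si2$img <- si2$img * 3.1
    expect_equal(as.numeric(band_roi_intensity(normalize_by_onl(si2), 1)),
                 as.numeric(r), tolerance = 1e-12)
  }
})

test_that("noiseless synthetic pairs yield the amplitude ratio exactly", {
  pair <- simulate_section_pair(161, wt_amplitude = 200,
                                ko_amplitude = 260, noise_sd = 0)
  amp <- function(si) {
    nsi <- normalize_by_onl(si)
    prof <- band_profile(nsi, 1)
    max(prof$intensity) - 1      # background sits at 1 after normalization
  }
  expect_equal(amp(pair$ko) / amp(pair$wt), 1.3, tolerance = 1e-9)

  ## background-only image: zero after thresholding
  bg <- flat_section(value = 40, bands = list(
    cbind(x = seq(20, 180, length.out = 20), y = rep(50, 20))))
  nbg <- normalize_by_onl(bg)
  expect_equal(as.numeric(band_roi_intensity(nbg, 1)), 0)
  expect_equal(central_window_sum(band_profile(nbg, 1)), 0)
})

test_that("TIFF plus geometry sidecar round-trips a section image", {
  pair <- simulate_section_pair(171)
  path <- withr::local_tempfile(fileext = ".tif")
  write_section_tiff(pair$wt, path)
  back <- read_section_tiff(path)
  expect_equal(back$scale_um_per_px, pair$wt$scale_um_per_px)
  expect_equal(length(back$bands), 2)
  ## 16-bit quantization: within one count
  expect_lt(max(abs(back$img - pair$wt$img)), 1.01)
  ## ONL region agrees
  expect_equal(mean(back$img[back$onl_mask]),
               mean(pair$wt$img[pair$wt$onl_mask]), tolerance = 0.01)
  ## the measure survives the round trip
  expect_equal(section_band_measure(back), section_band_measure(pair$wt),
               tolerance = 0.02)
})

test_that("z-projection averages slices", {
  sl <- list(matrix(1, 4, 4), matrix(3, 4, 4))
  expect_equal(z_project(sl), matrix(2, 4, 4))
  arr <- array(c(1, 2, 3), dim = c(1, 1, 3))
  expect_equal(z_project(arr)[1, 1], 2)
})
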