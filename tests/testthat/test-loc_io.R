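test_that("CSV reader handles units, dialects and malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x,y", "0,100,200", "1,150,250", "2,175,275"), tmp)
  tab <- read_localizations(tmp, units = "nm")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$x, c(100, 150, 175))

  tab_px <- read_localizations(tmp, units = "px", pixel_size = 100)
  expect_equal(tab_px$x, c(10000, 15000, 17500))
  expect_equal(tab_px$y / tab$y, rep(100, 3))

  # ThunderSTORM-like header mapping
  ts <- withr::local_tempfile(fileext = ".csv")
  writeLines(c('frame,"x [nm]","y [nm]","uncertainty [nm]"',
               "0,10,20,8.5", "1,12,22,9.5"), ts)
  tt <- read_localizations(ts, dialect = "thunderstorm_like")
  expect_equal(tt$precision, c(8.5, 9.5))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,x", "0,1"), bad)
  expect_error(read_localizations(bad), class = "qp_format_error")
  writeLines(c("frame,x,y", "0,1,2", "1,oops,3"), bad)
  expect_error(read_localizations(bad), class = "qp_parse_error")
  expect_error(read_localizations(bad, units = "px", pixel_size = -1),
               class = "qp_parameter_error")
})

test_that("writer round trip preserves coordinates, counts and channels", {
  sim <- sim_localization_field(sim_config(seed = 3, n_frames = 2000))
  tab <- sim$table
  tab$channel <- rep_len(c(0L, 1L), nrow(tab))
  tab <- localization_table(as.data.frame(tab), fov = c(10000, 10000))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_localizations(tab, tmp)
  back <- read_localizations(tmp)
  expect_equal(nrow(back), nrow(tab))
  expect_lt(max(abs(back$x - tab$x), abs(back$y - tab$y)), 1e-6)
  expect_identical(as.integer(back$channel), as.integer(tab$channel))

  # empty table -> header-only file that reads back empty
  empty <- localization_table(data.frame(frame = integer(0), x = numeric(0),
                                         y = numeric(0)), fov = c(100, 100))
  write_localizations(empty, tmp)
  expect_equal(nrow(read_localizations(tmp)), 0)
})

test_that("px -> nm -> px unit conversion is an identity", {
  px <- data.frame(frame = 0:4, x = c(1.25, 2.5, 3.125, 10, 0.33),
                   y = c(5, 6.5, 7.75, 8, 9.99))
  nm <- localization_table(transform(px, x = x * 107, y = y * 107),
                           pixel_size = 107)
  expect_equal(nm$x / 107, px$x, tolerance = 1e-9)
  expect_equal(nm$y / 107, px$y, tolerance = 1e-9)
})

test_that("rendering conserves counts; gaussian peak matches the 2D normal", {
  df <- data.frame(frame = 0:49, x = runif(50, 0, 1000), y = runif(50, 0, 1000))
  tab <- localization_table(df, fov = c(1000, 1000))
  img <- render_image(tab, bin_nm = 25, mode = "histogram")
  expect_equal(sum(img), 50)

  one <- localization_table(data.frame(frame = 0, x = 100.5, y = 100.5,
                                       precision = 10), fov = c(201, 201))
  expect_equal(sum(render_image(one, 20, "histogram")), 1)
  g <- render_image(one, bin_nm = 1, mode = "gaussian")
  # unit-integral Gaussian, sigma 10 nm: peak bin ~ 1/(2 pi 10^2) per nm^2
  expect_equal(max(g), 1 / (2 * pi * 100), tolerance = 0.01)
  expect_equal(sum(g), 1, tolerance = 1e-6)
  expect_error(render_image(tab, bin_nm = 0), class = "qp_parameter_error")
})

test_that("ROI polygons: area, containment, simplicity, JSON round trip", {
  r <- roi_rect(10000, 10000)
  expect_equal(r$area_um2, 100)
  expect_true(all(points_in_roi(c(1, 9999), c(1, 9999), r)))
  expect_false(any(points_in_roi(c(-5, 10005), c(50, 50), r)))
  # bow-tie polygon is rejected
  expect_error(roi_polygon(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               class = "qp_parameter_error")
  tmp <- withr::local_tempfile(fileext = ".json")
  tri <- roi_polygon(rbind(c(0, 0), c(3000, 0), c(0, 4000)))
  write_roi(tri, tmp)
  back <- read_roi(tmp)
  expect_equal(back$area_um2, tri$area_um2)
  expect_equal(back$vertices, tri$vertices, ignore_attr = TRUE)
})
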