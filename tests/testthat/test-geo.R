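test_that("mean centre is the planar coordinate average", {
  one <- tibble::tibble(lat = 48.2, lon = 16.4)
  expect_equal(mean_center(one), c(lat = 48.2, lon = 16.4))
  pair <- tibble::tibble(lat = c(40, 50), lon = c(10, 30))
  expect_equal(mean_center(pair), c(lat = 45, lon = 20))
  five <- tibble::tibble(lat = c(40.1, 41.2, 39.7, 40.6, 40.9),
                         lon = c(-3.5, -2.8, -4.1, -3.0, -3.6))
  expect_equal(mean_center(five),
               c(lat = (40.1 + 41.2 + 39.7 + 40.6 + 40.9) / 5,
                 lon = (-3.5 - 2.8 - 4.1 - 3.0 - 3.6) / 5))
})

test_that("great-circle distances match the haversine closed form and an
           independent geodesy oracle", {
  p <- c(lat = 52.5, lon = 13.4)
  expect_equal(great_circle_distance(p, p), 0)
  expect_equal(
    great_circle_distance(c(lat = 90, lon = 0), c(lat = -90, lon = 0)),
    pi * 6371, tolerance = 1e-9
  )
  withr::with_seed(8, {
    for (i in 1:50) {
      a <- c(lat = runif(1, -80, 80), lon = runif(1, -180, 180))
      b <- c(lat = runif(1, -80, 80), lon = runif(1, -180, 180))
      ref <- geosphere::distHaversine(c(a[["lon"]], a[["lat"]]),
                                      c(b[["lon"]], b[["lat"]]),
                                      r = 6371000) / 1000
      expect_equal(great_circle_distance(a, b), ref, tolerance = 5e-3)
    }
  })
})

test_that("geographic model metrics handle bearings and the 50-km rule", {
  t_pts <- tibble::tibble(lat = 50, lon = 20)
  north <- tibble::tibble(lat = 55, lon = 20)
  south <- tibble::tibble(lat = 45, lon = 20)
  m <- geo_model_metrics(t_pts, list(north, south))
  expect_equal(m$min_angle, 180, tolerance = 1e-6)
  expect_gt(m$max_st, 500)
  # a source within 50 km: distance zeroed, angle undefined
  near <- tibble::tibble(lat = 50.2, lon = 20)
  m2 <- geo_model_metrics(t_pts, list(near, south))
  expect_true(is.na(m2$min_angle))
  expect_equal(m2$avg_st, m2$max_st / 2)
  # angle invariant under swapping sources; distances under reordering
  east <- tibble::tibble(lat = 50, lon = 28)
  m3 <- geo_model_metrics(t_pts, list(north, east))
  m3r <- geo_model_metrics(t_pts, list(east, north))
  expect_equal(m3$min_angle, m3r$min_angle)
  expect_equal(sort(c(m3$max_st, m3$avg_st)), sort(c(m3r$max_st, m3r$avg_st)))
})

test_that("synthetic model tables round-trip through the TSV schema and the
           metric layer matches a slow recomputation", {
  models <- synthetic_geo_models(25, seed = 42)
  path <- file.path(tempdir(), "geo.tsv")
  write_geo_models(models, path)
  back <- read_geo_models(path)
  expect_equal(nrow(back), 25)
  expect_equal(back$p_value, models$p_value, tolerance = 1e-12)
  expect_equal(back$eaf[[3]], models$eaf[[3]], tolerance = 1e-12)
  expect_equal(back$target_coords[[7]]$lat, models$target_coords[[7]]$lat,
               tolerance = 1e-12)

  met <- geo_model_table_metrics(back)
  for (i in c(1, 9, 20)) {
    tc <- mean_center(back$target_coords[[i]])
    d <- vapply(back$source_coords[[i]], function(s) {
      great_circle_distance(tc, mean_center(s))
    }, numeric(1))
    expect_equal(met$max_st[i], max(ifelse(d <= 50, 0, d)), tolerance = 1e-9)
  }
  # metric-space summary runs unchanged on geographic metrics
  sm <- summarize_metric_space(met, met$p_value > 0.5,
                               st_breaks = seq(0, 8000, 1000))
  expect_true(is.list(sm) && "rho" %in% names(sm))
})
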