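test_that("quantile classification with ties to the lower bin", {
  cl <- classify_univariate(1:9, n_bins = 3, scheme = "quantile")
  expect_equal(unname(cl$class), rep(1:3, each = 3))
  # a value equal to a bin edge goes to the lower bin
  cl2 <- classify_univariate(c(1, 2, 2, 3, 4, 5), n_bins = 2)
  edge <- cl2$breaks[1]
  expect_true(all(cl2$class[c(1, 2, 2, 3, 4, 5) == edge] == 1))
})

test_that("equal-interval classification uses range-based edges", {
  x <- c(0, 0.2, 0.4, 0.5, 0.7, 1)
  cl <- classify_univariate(x, n_bins = 3, scheme = "equal_interval")
  expect_equal(cl$breaks, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(unname(cl$class), c(1, 1, 2, 2, 3, 3))
})

test_that("constant values collapse to one class with a warning", {
  expect_warning(cl <- classify_univariate(rep(2, 5)), "equal")
  expect_equal(unname(cl$class), rep(1L, 5))
})

test_that("bivariate classes cover the 3x3 grid on a constructed fixture", {
  # 9 districts whose ranks form a full factorial of tertile pairs
  a <- stats::setNames(c(1, 1, 1, 5, 5, 5, 9, 9, 9) + (0:8) * 0.01,
                       paste0("d", 1:9))
  b <- stats::setNames(rep(c(1, 5, 9), 3) + (0:8) * 0.01, paste0("d", 1:9))
  res <- bivariate_choropleth_classes(a, b, n_bins = 3)
  expect_equal(sort(res$table$class),
               sort(paste(rep(1:3, each = 3), rep(1:3, 3), sep = "-")))
  expect_true(all(res$crosstab == 1))
  # identical vectors give only diagonal classes
  res2 <- bivariate_choropleth_classes(a, a)
  expect_true(all(res2$table$class_a == res2$table$class_b))
})

test_that("bivariate marginals equal the univariate classifications", {
  set.seed(23)
  a <- stats::setNames(rnorm(30), sprintf("d%02d", 1:30))
  b <- stats::setNames(rnorm(30), sprintf("d%02d", 1:30))
  res <- bivariate_choropleth_classes(a, b)
  expect_equal(res$table$class_a, unname(classify_univariate(a)$class))
  expect_equal(res$table$class_b, unname(classify_univariate(b)$class))
  # invariance to district ordering
  perm <- sample(30)
  res_p <- bivariate_choropleth_classes(a[perm], b[perm])
  m <- match(res$table$district, res_p$table$district)
  expect_equal(res_p$table$class[m], res$table$class)
  # mismatched district sets are an error naming the difference
  expect_error(bivariate_choropleth_classes(a, b[-1]), "d01")
})

test_that("count_exceeding reports both conventions", {
  res <- count_exceeding(c(0.4, 0.5, 0.6), 0.5)
  expect_equal(res$strictly_above, 1)
  expect_equal(res$at_or_above, 2)
  expect_equal(count_exceeding(numeric(0), 0.5)$strictly_above, 0)
})

test_that("CSV export round-trips and GeoJSON join validates labels", {
  tab <- data.frame(district = paste0("d", 1:4),
                    value = c(0.1, 0.5, 0.4, 0.9),
                    class = c(1L, 2L, 2L, 3L))
  f <- withr::local_tempfile(fileext = ".csv")
  export_map_table(tab, f, "csv")
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back, tab)
  # geojson with one missing geometry errors naming the district
  gj <- withr::local_tempfile(fileext = ".geojson")
  geo <- list(type = "FeatureCollection", features = lapply(1:3, function(i) {
    list(type = "Feature", properties = list(district = paste0("d", i)),
         geometry = list(type = "Point", coordinates = c(i, i)))
  }))
  jsonlite::write_json(geo, gj, auto_unbox = TRUE)
  out <- withr::local_tempfile(fileext = ".geojson")
  expect_error(export_map_table(tab, out, "geojson", geometry_path = gj),
               "d4")
  # complete geometries join cleanly
  geo$features[[4]] <- list(type = "Feature",
                            properties = list(district = "d4"),
                            geometry = list(type = "Point",
                                            coordinates = c(4, 4)))
  jsonlite::write_json(geo, gj, auto_unbox = TRUE)
  export_map_table(tab, out, "geojson", geometry_path = gj)
  rt <- jsonlite::read_json(out)
  expect_equal(length(rt$features), 4)
  expect_equal(rt$features[[2]]$properties$value, 0.5)
  expect_equal(rt$features[[2]]$properties$class, 2L)
})
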