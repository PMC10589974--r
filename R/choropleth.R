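#' Univariate choropleth classification
#'
#' Assigns each district to one of `n_bins` classes. The `quantile` scheme
#' puts bin edges at the empirical quantiles `k/n_bins`; a value tied with a
#' bin edge goes to the lower bin. The `equal_interval` scheme divides the
#' observed range into equal-width bins.
#'
#' @param values numeric vector (optionally named by district).
#' @param n_bins number of classes (default 3, tertiles).
#' @param scheme `"quantile"` or `"equal_interval"`.
#' @return list with `class` (integer vector, 1 = lowest), `breaks`
#'   (interior bin edges), `scheme`.
#' @export
classify_univariate <- function(values, n_bins = 3,
                                scheme = c("quantile", "equal_interval")) {
  scheme <- match.arg(scheme)
  x <- as.numeric(values)
  if (length(x) < n_bins) stop("need at least n_bins districts")
  if (diff(range(x)) == 0) {
    warning("all values equal; single class")
    return(list(class = stats::setNames(rep(1L, length(x)), names(values)),
                breaks = numeric(0), scheme = scheme))
  }
  breaks <- if (scheme == "quantile") {
    unname(stats::quantile(x, probs = seq_len(n_bins - 1) / n_bins))
  } else {
    seq(min(x), max(x), length.out = n_bins + 1)[-c(1, n_bins + 1)]
  }
  cls <- vapply(x, function(v) 1L + sum(v > breaks), 1L)
  list(class = stats::setNames(cls, names(values)), breaks = breaks,
       scheme = scheme)
}

#' Bivariate choropleth classification
#'
#' Classifies two per-district variables independently into `n_bins`
#' quantile classes and returns the joint class pair per district (the
#' standard 3x3 bivariate choropleth legend), together with a
#' cross-tabulation of pair counts. Vectors must cover the same districts
#' (matched by name when named, by position otherwise).
#'
#' @param values_a,values_b numeric vectors over the same districts.
#' @param n_bins classes per axis (default 3).
#' @param scheme passed to [classify_univariate()].
#' @return list with `table` (data.frame: `district`, `value_a`, `value_b`,
#'   `class_a`, `class_b`, `class` as "a-b"), `crosstab` (n_bins x n_bins
#'   counts), `breaks_a`, `breaks_b`.
#' @export
bivariate_choropleth_classes <- function(values_a, values_b, n_bins = 3,
                                         scheme = "quantile") {
  na <- names(values_a); nb <- names(values_b)
  if (!is.null(na) && !is.null(nb)) {
    if (!setequal(na, nb)) {
      stop("district mismatch; only in a: ",
           paste(setdiff(na, nb), collapse = ", "), "; only in b: ",
           paste(setdiff(nb, na), collapse = ", "))
    }
    values_b <- values_b[na]
  } else if (length(values_a) != length(values_b)) {
    stop("district mismatch: vectors of different length")
  }
  districts <- if (!is.null(na)) na else as.character(seq_along(values_a))
  ca <- classify_univariate(values_a, n_bins, scheme)
  cb <- classify_univariate(values_b, n_bins, scheme)
  tab <- data.frame(district = districts,
                    value_a = as.numeric(values_a),
                    value_b = as.numeric(values_b),
                    class_a = unname(ca$class), class_b = unname(cb$class),
                    class = paste(ca$class, cb$class, sep = "-"),
                    row.names = NULL, stringsAsFactors = FALSE)
  crosstab <- table(factor(tab$class_a, levels = seq_len(n_bins)),
                    factor(tab$class_b, levels = seq_len(n_bins)))
  list(table = tab, crosstab = crosstab, breaks_a = ca$breaks,
       breaks_b = cb$breaks)
}

#' Count districts exceeding a threshold
#'
#' Reports both comparison conventions so that statements like "13 districts
#' had prevalence of more than 50%" are unambiguous.
#'
#' @param values numeric vector (NA values are dropped).
#' @param threshold numeric scalar.
#' @return list with `strictly_above`, `at_or_above`, `threshold`, `n`.
#' @export
count_exceeding <- function(values, threshold) {
  x <- values[!is.na(values)]
  list(strictly_above = sum(x > threshold), at_or_above = sum(x >= threshold),
       threshold = threshold, n = length(x))
}

#' Export a choropleth attribute table
#'
#' CSV is always available. For GeoJSON, a geometry file (GeoJSON
#' FeatureCollection whose features carry a district label property) is
#' joined to the table; districts without a geometry are an error.
#'
#' @param table data.frame with a `district` column; class columns should be
#'   integer, value columns numeric.
#' @param path output file path.
#' @param format `"csv"` or `"geojson"`.
#' @param geometry_path for GeoJSON: path to the geometry FeatureCollection.
#' @param label_property name of the feature property holding the district
#'   label (default `"district"`).
#' @return `path`, invisibly.
#' @export
export_map_table <- function(table, path, format = c("csv", "geojson"),
                             geometry_path = NULL,
                             label_property = "district") {
  format <- match.arg(format)
  stopifnot(is.data.frame(table), "district" %in% names(table))
  if (format == "csv") {
    utils::write.csv(table, path, row.names = FALSE)
  } else {
    if (is.null(geometry_path)) stop("geojson export needs geometry_path")
    geo <- jsonlite::read_json(geometry_path)
    if (is.null(geo$features)) stop("geometry file is not a FeatureCollection")
    feat_labels <- vapply(geo$features, function(f) {
      lab <- f$properties[[label_property]]
      if (is.null(lab)) NA_character_ else as.character(lab)
    }, "")
    missing <- setdiff(table$district, feat_labels)
    if (length(missing)) {
      stop("no geometry for district(s): ", paste(missing, collapse = ", "))
    }
    for (k in seq_along(geo$features)) {
      i <- match(feat_labels[k], table$district)
      if (is.na(i)) next
      for (col in setdiff(names(table), "district")) {
        val <- table[[col]][i]
        if (is.integer(val)) val <- as.integer(val)
        geo$features[[k]]$properties[[col]] <- val
      }
    }
    jsonlite::write_json(geo, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
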