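#' Mean centre of a set of coordinates
#'
#' Arithmetic mean of latitudes and of longitudes (planar convention, as in
#' the Mean Center tool of common GIS software).
#'
#' @param points Tibble/data frame with `lat` and `lon` columns (degrees).
#' @return Named numeric vector `c(lat =, lon =)`.
#' @export
mean_center <- function(points) {
  stopifnot(nrow(points) >= 1, all(c("lat", "lon") %in% names(points)))
  c(lat = mean(points$lat), lon = mean(points$lon))
}

#' Great-circle distance in km
#'
#' Haversine formula on a sphere of radius 6371 km.
#'
#' @param a,b Named vectors/lists with `lat` and `lon` in degrees
#'   (vectorized over `b` given as a two-column matrix/data frame).
#' @return Distance in km.
#' @export
great_circle_distance <- function(a, b) {
  rad <- pi / 180
  la1 <- a[["lat"]] * rad; lo1 <- a[["lon"]] * rad
  la2 <- b[["lat"]] * rad; lo2 <- b[["lon"]] * rad
  h <- sin((la2 - la1) / 2)^2 + cos(la1) * cos(la2) * sin((lo2 - lo1) / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(h)))
}

# initial bearing (degrees clockwise from north) from a to b
.initial_bearing <- function(a, b) {
  rad <- pi / 180
  la1 <- a[["lat"]] * rad; la2 <- b[["lat"]] * rad
  dlo <- (b[["lon"]] - a[["lon"]]) * rad
  th <- atan2(sin(dlo) * cos(la2),
              cos(la1) * sin(la2) - sin(la1) * cos(la2) * cos(dlo))
  (th / rad) %% 360
}

#' Optimality metrics of a qpAdm model with real geographic coordinates
#'
#' Group centroids are planar mean centres of the per-individual
#' coordinates; source-target distances are great-circle distances in km;
#' the minimal source-target-source angle is computed from initial bearings
#' at the target, taking each pairwise bearing difference into \[0, 180\]
#' degrees. Distances of at most `negligible_km` (50 km) are treated as 0
#' and such sources are excluded from the angle computation; a model with
#' any such source carries an undefined (`NA`) angle.
#'
#' @param target_points,source_points `target_points`: coordinates of the
#'   target group's individuals (`lat`, `lon`); `source_points`: list of
#'   such tables, one per source.
#' @param negligible_km Distance below which a source is considered
#'   co-located with the target (default 50).
#' @return One-row tibble: `n`, `max_st`, `avg_st` (km), `min_angle`
#'   (degrees or `NA`).
#' @export
geo_model_metrics <- function(target_points, source_points,
                              negligible_km = 50) {
  tc <- mean_center(target_points)
  scs <- lapply(source_points, mean_center)
  d <- vapply(scs, function(s) great_circle_distance(tc, s), numeric(1))
  near <- d <= negligible_km
  d[near] <- 0
  angle <- NA_real_
  if (!any(near) && length(scs) >= 2) {
    bearings <- vapply(scs, function(s) .initial_bearing(tc, s), numeric(1))
    pairs <- utils::combn(length(bearings), 2)
    diffs <- abs(bearings[pairs[1, ]] - bearings[pairs[2, ]])
    diffs <- pmin(diffs, 360 - diffs)
    angle <- min(diffs)
  }
  tibble::tibble(
    n = length(scs), max_st = max(d), avg_st = mean(d), min_angle = angle
  )
}

#' Read a table of qpAdm models with geographic coordinates
#'
#' One row per model: `target`, `sources` (comma-separated labels),
#' `target_coords` and `source_coords` (JSON arrays of \[lat, lon\] pairs;
#' `source_coords` is a JSON array of such arrays, one per source), `eaf`
#' (comma-separated weights), `se` (comma-separated), `p_value`.
#'
#' @param path TSV file.
#' @return Tibble with parsed list columns and an `n` complexity column.
#' @export
read_geo_models <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "")
  need <- c("target", "sources", "target_coords", "source_coords",
            "eaf", "se", "p_value")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  parse_pts <- function(js) {
    m <- jsonlite::fromJSON(js)
    if (is.null(dim(m))) m <- matrix(m, ncol = 2)
    tibble::tibble(lat = m[, 1], lon = m[, 2])
  }
  tibble::tibble(
    target = raw$target,
    sources = strsplit(raw$sources, ","),
    target_coords = lapply(raw$target_coords, parse_pts),
    source_coords = lapply(raw$source_coords, function(js) {
      lst <- jsonlite::fromJSON(js, simplifyMatrix = FALSE)
      lapply(lst, function(m) {
        m <- do.call(rbind, m)
        tibble::tibble(lat = m[, 1], lon = m[, 2])
      })
    }),
    eaf = lapply(strsplit(raw$eaf, ","), as.numeric),
    se = lapply(strsplit(raw$se, ","), as.numeric),
    p_value = as.numeric(raw$p_value)
  ) |>
    dplyr::mutate(n = lengths(.data$sources))
}

#' Optimality metrics for a whole geographic model table
#'
#' @param models Tibble from [read_geo_models()] (or
#'   [synthetic_geo_models()]).
#' @param negligible_km See [geo_model_metrics()].
#' @return `models` with `max_st`, `avg_st`, `min_angle` columns appended.
#' @export
geo_model_table_metrics <- function(models, negligible_km = 50) {
  met <- dplyr::bind_rows(lapply(seq_len(nrow(models)), function(i) {
    geo_model_metrics(models$target_coords[[i]], models$source_coords[[i]],
                      negligible_km)
  }))
  dplyr::bind_cols(models, met[, c("max_st", "avg_st", "min_angle")])
}

#' Generate a synthetic table of geographic qpAdm models
#'
#' Emulates published supplementary model tables: targets and sources are
#' placed at random coordinates within a continental-scale window, each
#' group gets a handful of individuals jittered around its centre, and
#' weights/P-values are drawn with no relation to geography. Useful as a
#' fixture for the geographic analysis layer.
#'
#' @param n_models Number of models.
#' @param seed Integer seed.
#' @param complexity_range Range of model complexities.
#' @param window List with `lat` and `lon` ranges.
#' @return Tibble in the [read_geo_models()] schema (parsed form).
#' @export
synthetic_geo_models <- function(n_models = 50, seed = 1,
                                 complexity_range = c(2, 4),
                                 window = list(lat = c(35, 60),
                                               lon = c(-10, 60))) {
  withr::with_seed(.child_rng(seed, "geo-models"), {
    rows <- lapply(seq_len(n_models), function(i) {
      n <- sample(seq(complexity_range[1], complexity_range[2]), 1)
      centre <- function() {
        c(stats::runif(1, window$lat[1], window$lat[2]),
          stats::runif(1, window$lon[1], window$lon[2]))
      }
      pts <- function(ct) {
        k <- sample(1:6, 1)
        tibble::tibble(lat = ct[1] + stats::rnorm(k, 0, 0.5),
                       lon = ct[2] + stats::rnorm(k, 0, 0.5))
      }
      tc <- centre()
      w <- abs(stats::rnorm(n)); w <- w / sum(w)
      tibble::tibble(
        target = sprintf("T%02d", i),
        sources = list(sprintf("T%02d_s%d", i, seq_len(n))),
        target_coords = list(pts(tc)),
        source_coords = list(lapply(seq_len(n), function(k) pts(centre()))),
        eaf = list(w),
        se = list(abs(stats::rnorm(n, 0, 0.05))),
        p_value = stats::runif(1),
        n = n
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Write a geographic model table in the TSV interchange schema
#' @param models Parsed tibble (as from [synthetic_geo_models()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_geo_models <- function(models, path) {
  enc_pts <- function(df) {
    jsonlite::toJSON(unname(as.matrix(df[, c("lat", "lon")])), digits = NA)
  }
  out <- data.frame(
    target = models$target,
    sources = vapply(models$sources, paste, "", collapse = ","),
    target_coords = vapply(models$target_coords, function(p) {
      as.character(enc_pts(p))
    }, ""),
    source_coords = vapply(models$source_coords, function(lst) {
      as.character(jsonlite::toJSON(
        lapply(lst, function(p) unname(as.matrix(p[, c("lat", "lon")]))),
        digits = NA
      ))
    }, ""),
    eaf = vapply(models$eaf, function(x) paste(x, collapse = ","), ""),
    se = vapply(models$se, function(x) paste(x, collapse = ","), ""),
    p_value = models$p_value
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
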