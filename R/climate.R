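#' Weather-station records
#'
#' A light container for a station's metadata and daily climate series.
#' The daily table needs columns `date` (`Date`), `tmean`, `tmin`, `tmax`
#' (degrees C) and `prcp` (mm/day); a generic CSV with those columns can be
#' read with [read_station_csv()].
#'
#' @param id station identifier.
#' @param latitude decimal degrees, in `[-90, 90]`.
#' @param altitude metres, in `[-100, 6000]`.
#' @param daily daily climate `data.frame` (may be empty for matching-only
#'   use).
#' @return a `"station_record"` list.
#' @export
station_record <- function(id, latitude, altitude, daily = NULL) {
  if (!is.numeric(latitude) || abs(latitude) > 90)
    stop("latitude must be in [-90, 90]")
  if (!is.numeric(altitude) || altitude < -100 || altitude > 6000)
    stop("altitude outside plausible range [-100, 6000] m")
  if (!is.null(daily)) {
    need <- c("date", "tmean", "tmin", "tmax", "prcp")
    miss <- setdiff(need, names(daily))
    if (length(miss)) stop("daily table missing column(s): ",
                           paste(miss, collapse = ", "))
    if (any(daily$prcp < 0, na.rm = TRUE)) stop("negative precipitation")
  }
  structure(list(id = id, latitude = latitude, altitude = altitude,
                 daily = daily), class = "station_record")
}

#' @rdname station_record
#' @param path CSV file with columns `date,tmean,tmin,tmax,prcp`.
#' @export
read_station_csv <- function(id, latitude, altitude, path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  station_record(id, latitude, altitude, d)
}

#' Locality climate summary
#'
#' Builds the eight-variable climate row for one locality from a station's
#' daily series: annual precipitation `AP` (mean of yearly totals, mm/yr),
#' yearly mean daily mean/min/max temperatures (`AMT`, `AMinT`, `AMaxT`),
#' and the same temperature summaries plus mean monthly precipitation
#' restricted to the months in which gravid females occur (`MT`, `MMinT`,
#' `MMaxT`, `MP`).
#'
#' @param record a [station_record()] with a daily series covering at least
#'   one full year.
#' @param gravid_months integer months (1-12) with gravid females present.
#' @return named numeric vector
#'   `c(AP, AMT, AMinT, AMaxT, MT, MMinT, MMaxT, MP)`.
#' @export
summarize_climate <- function(record, gravid_months) {
  if (!inherits(record, "station_record")) stop("expected a station_record")
  d <- record$daily
  if (is.null(d) || !nrow(d)) stop("station ", record$id, " has an empty daily series")
  gravid_months <- sort(unique(as.integer(gravid_months)))
  if (!length(gravid_months)) stop("gravid_months must be non-empty")
  if (any(gravid_months < 1L | gravid_months > 12L))
    stop("gravid_months must be calendar months 1-12")
  mo <- as.integer(format(d$date, "%m"))
  yr <- as.integer(format(d$date, "%Y"))
  if (length(unique(mo)) < 12L)
    stop("daily series must cover at least one full year (all 12 months)")
  absent <- setdiff(gravid_months, mo)
  if (length(absent))
    stop("gravid month(s) absent from the series: ",
         paste(month.abb[absent], collapse = ", "))

  g <- mo %in% gravid_months
  # monthly precipitation totals over each gravid month instance
  mp_tot <- tapply(d$prcp[g], interaction(yr[g], mo[g], drop = TRUE), sum)
  c(AP = mean(tapply(d$prcp, yr, sum)),
    AMT = mean(d$tmean), AMinT = mean(d$tmin), AMaxT = mean(d$tmax),
    MT = mean(d$tmean[g]), MMinT = mean(d$tmin[g]), MMaxT = mean(d$tmax[g]),
    MP = mean(mp_tot))
}

#' PCA reduction of climate variables
#'
#' Principal component analysis on the correlation matrix (variables are
#' standardized: the eight climate variables mix mm and degrees C),
#' unrotated.  Components with eigenvalue > 1 are retained.  Loadings are
#' correlation-scale (`eigenvector * sqrt(eigenvalue)`, in `[-1, 1]`); each
#' component's sign is fixed so its largest-magnitude loading is positive.
#' Scores are standardized (mean 0, sd 1) and labeled `CC1`, `CC2`, ...
#'
#' @param M numeric matrix or data frame, rows = localities/species,
#'   columns = climate variables.
#' @param min_eigen retention threshold (default 1, the Kaiser rule).
#' @return a `"component_scores"` list: `loadings` (all components),
#'   `eigenvalues`, `pct_var`, `retained` (count), `scores` (retained
#'   components only).
#' @export
reduce_climate <- function(M, min_eigen = 1) {
  M <- as.matrix(M)
  if (nrow(M) < 3L) stop("PCA needs at least 3 rows, got ", nrow(M))
  if (anyNA(M)) stop("climate matrix contains missing cells")
  sds <- apply(M, 2L, sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(M)[sds == 0], collapse = ", "))
  Z <- scale(M)
  eg <- eigen(cor(M), symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors
  # sign convention: dominant loading positive
  for (j in seq_along(vals)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- vecs %*% diag(sqrt(pmax(vals, 0)), length(vals))
  dimnames(loadings) <- list(colnames(M), paste0("CC", seq_along(vals)))
  retained <- sum(vals > min_eigen)
  scores <- Z %*% vecs[, seq_len(retained), drop = FALSE] %*%
    diag(1 / sqrt(vals[seq_len(retained)]), retained)
  colnames(scores) <- paste0("CC", seq_len(retained))
  rownames(scores) <- rownames(M)
  structure(list(loadings = loadings, eigenvalues = vals,
                 pct_var = 100 * vals / ncol(M), retained = retained,
                 scores = scores),
            class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat("climate PCA:", x$retained, "component(s) retained (eigenvalue > 1)\n")
  for (j in seq_len(x$retained))
    cat(sprintf("  CC%d: eigenvalue %.3f (%.2f%% of variance)\n",
                j, x$eigenvalues[j], x$pct_var[j]))
  print(round(x$loadings[, seq_len(max(x$retained, 1L)), drop = FALSE], 3))
  invisible(x)
}

#' Match a locality to its best climate station
#'
#' Minimizes the combined climatic distance
#' `cost = 111.32 * |dlat_deg| + (tradeoff / 100) * |dalt_m|`,
#' i.e. latitude displacement in km plus altitude displacement converted at
#' `tradeoff` km per 100 m.  The default tradeoff of 100 km per 100 m
#' encodes the empirical equivalence between 100 m of altitude and 100 km
#' of latitude over the Brazilian gradient; recalibrate it for other
#' regions with [calibrate_tradeoff()].  Ties go to the latitude-closer
#' station.
#'
#' @param locality numeric `c(latitude, altitude)` (degrees, metres).
#' @param stations list of [station_record()]s.
#' @param tradeoff km of latitude equivalent to 100 m of altitude.
#' @return the chosen `"station_record"`, with `attr(, "cost")` in km.
#' @export
match_station <- function(locality, stations, tradeoff = 100) {
  if (!length(stations)) stop("empty station list")
  if (inherits(stations, "station_record")) stations <- list(stations)
  if (tradeoff <= 0) stop("tradeoff must be > 0")
  lat <- locality[[1L]]; alt <- locality[[2L]]
  dlat_km <- vapply(stations, function(s) 111.32 * abs(s$latitude - lat), 0)
  dalt <- vapply(stations, function(s) abs(s$altitude - alt), 0)
  cost <- dlat_km + (tradeoff / 100) * dalt
  i <- order(cost, dlat_km)[1L]
  out <- stations[[i]]
  attr(out, "cost") <- cost[i]
  out
}

#' Calibrate the altitude-latitude tradeoff from station scores
#'
#' Regresses the first principal-component score of the stations on
#' latitude (in km) and altitude (in m); the tradeoff is
#' `100 * |beta_alt / beta_lat|` km per 100 m, i.e. how far along the
#' latitudinal gradient one must travel to match the climatic effect of
#' 100 m of elevation.
#'
#' @param stations data frame with columns `latitude` (deg), `altitude`
#'   (m) and `score` (first-component score), at least 10 rows.
#' @param default fallback tradeoff when the latitude effect is ~0.
#' @return tradeoff in km per 100 m.
#' @export
calibrate_tradeoff <- function(stations, default = 100) {
  need <- c("latitude", "altitude", "score")
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop("stations table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(stations) < 10L)
    stop("calibration needs at least 10 stations, got ", nrow(stations))
  lat_km <- stations$latitude * 111.32
  X <- cbind(1, lat_km, stations$altitude)
  qx <- qr(X)
  if (qx$rank < 3L)
    stop("latitude and altitude are collinear; tradeoff not identifiable")
  beta <- unname(qr.coef(qx, stations$score))
  b_lat <- beta[2L]; b_alt <- beta[3L]
  scale_ref <- sd(stations$score) / max(sd(lat_km), .Machine$double.eps)
  if (abs(b_lat) < 1e-8 * max(scale_ref, 1)) {
    warning("latitude coefficient ~ 0; tradeoff undefined, using default ",
            default, " km per 100 m")
    return(default)
  }
  100 * abs(b_alt / b_lat)
}
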