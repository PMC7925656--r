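#' @useDynLib ssvepwave, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd median coef lm cor cor.test fft
#' @importFrom utils read.table write.table packageVersion
#' @importFrom tools md5sum
NULL

# Canonical spherical coordinates (degrees) for the 32-channel extension of
# the international 10-20 system as laid out on an idealized spherical cap
# (BioSemi ordering).  Latitude is measured from the equatorial
# (nasion-inion-preauricular) plane with Cz at +90 deg; longitude 0 points to
# the nasion and increases towards the right ear, in (-180, 180].
.montage32 <- data.frame(
  name = c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3", "CP1", "CP5",
           "P7", "P3", "Pz", "PO3", "O1", "Oz", "O2", "PO4", "P4", "P8",
           "CP6", "CP2", "C4", "T8", "FC6", "FC2", "F4", "F8", "AF4", "Fp2",
           "Fz", "Cz"),
  lat = c(-2, 16, -2, 30, 58, 18, -2, 44, 58, 18, -2, 30, 44, 16, -2, -2,
          -2, 16, 30, -2, 18, 58, 44, -2, 18, 58, 30, -2, 16, -2, 44, 90),
  lon = c(-18, -25, -54, -39, -45, -69, -90, -90, -135, -111, -126, -141,
          180, -155, -162, 180, 162, 155, 141, 126, 111, 135, 90, 90, 69,
          45, 39, 54, 25, 18, 0, 90),
  stringsAsFactors = FALSE
)

#' Construct an electrode montage on a spherical head model
#'
#' A montage is a set of named electrodes with spherical coordinates on a
#' head modelled as a sphere (default radius 9 cm).  Latitude is measured
#' from the equatorial plane through nasion, inion and the preauricular
#' points, so the vertex electrode Cz sits at latitude pi/2; longitude 0
#' points towards the nasion and increases towards the right ear.
#'
#' @param name character vector of channel labels (10-20 nomenclature);
#'   must be unique.
#' @param lat,lon numeric vectors of latitudes and longitudes.
#' @param radius head radius in cm (default 9).
#' @param unit unit of `lat`/`lon`: `"rad"` (default) or `"deg"`.
#' @return An object of class `ssvep_montage`: a data frame with columns
#'   `name`, `lat`, `lon` (radians) and a `radius` attribute.
#' @examples
#' m <- montage(c("A", "B"), lat = c(0, 0), lon = c(0, 90), unit = "deg")
#' great_circle_distance(0, 0, 0, pi / 2)  # quarter circle, 14.14 cm
#' @export
montage <- function(name, lat, lon, radius = 9, unit = c("rad", "deg")) {
  unit <- match.arg(unit)
  name <- as.character(name)
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(name) != length(lat) || length(lat) != length(lon))
    stop("name, lat and lon must have equal length")
  if (length(name) == 0L) stop("montage must contain at least one electrode")
  if (unit == "deg") { lat <- lat * pi / 180; lon <- lon * pi / 180 }
  if (anyDuplicated(name))
    stop("duplicate electrode names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  if (!all(is.finite(lat)) || !all(is.finite(lon)))
    stop("non-finite electrode coordinates")
  if (any(lat < -pi / 2 - 1e-12 | lat > pi / 2 + 1e-12))
    stop("latitude out of range [-pi/2, pi/2]")
  # normalize longitudes into (-pi, pi]
  lon <- pi - (pi - lon) %% (2 * pi)
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("head radius must be a positive number (cm)")
  m <- data.frame(name = name, lat = lat, lon = lon,
                  stringsAsFactors = FALSE)
  attr(m, "radius") <- radius
  class(m) <- c("ssvep_montage", "data.frame")
  m
}

#' Default 32-channel 10-20 montage
#'
#' The built-in montage covers the 32-channel extension of the international
#' 10-20 positioning system on an idealized spherical cap, with standard
#' published angles; no external file is needed.
#'
#' @param radius head radius in cm (default 9).
#' @return An [montage()] object with 32 electrodes.
#' @export
default_montage <- function(radius = 9) {
  montage(.montage32$name, .montage32$lat, .montage32$lon,
          radius = radius, unit = "deg")
}

#' @export
print.ssvep_montage <- function(x, ...) {
  cat(sprintf("<ssvep_montage> %d electrodes on a %.1f cm sphere\n",
              nrow(x), attr(x, "radius")))
  cat(" ", paste(x$name, collapse = " "), "\n")
  invisible(x)
}

#' Head radius of a montage
#' @param m a montage.
#' @return radius in cm.
#' @export
head_radius <- function(m) attr(m, "radius")

#' Great-circle distance between two points on a sphere
#'
#' Computes the on-sphere distance via the haversine formula
#' \deqn{hav(\alpha) = \sin^2((\phi_1-\phi_2)/2) +
#'       \cos\phi_1 \cos\phi_2 \sin^2((\lambda_1-\lambda_2)/2)}
#' \deqn{\Delta\delta = 2 r \arcsin\sqrt{hav(\alpha)}}
#' with latitudes \eqn{\phi} and longitudes \eqn{\lambda} in radians.
#' The haversine form is numerically stable for nearby points, unlike the
#' naive arccos of the dot product.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in radians (vectorized).
#' @param radius sphere radius in cm (default 9, the spherical head model).
#' @return distance(s) in cm, in `[0, pi * radius]`.
#' @export
great_circle_distance <- function(lat1, lon1, lat2, lon2, radius = 9) {
  if (!all(is.finite(c(lat1, lon1, lat2, lon2))))
    stop("non-finite coordinates")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  hav <- sin((lat1 - lat2) / 2)^2 +
    cos(lat1) * cos(lat2) * sin((lon1 - lon2) / 2)^2
  2 * radius * asin(pmin(1, sqrt(hav)))
}

#' Great-circle distances from one electrode to every montage channel
#'
#' @param m a [montage()].
#' @param source channel label present in `m`.
#' @return named numeric vector of distances (cm), one per channel, in
#'   montage order; the source maps to 0.
#' @export
channel_distances <- function(m, source) {
  stopifnot(inherits(m, "ssvep_montage"))
  i <- match(source, m$name)
  if (is.na(i)) stop("unknown source channel: ", source)
  d <- great_circle_distance(m$lat[i], m$lon[i], m$lat, m$lon,
                             radius = attr(m, "radius"))
  names(d) <- m$name
  d
}

#' Distance between two named electrodes
#' @param m a [montage()].
#' @param a,b channel labels.
#' @return distance in cm.
#' @export
electrode_distance <- function(m, a, b) {
  unname(channel_distances(m, a)[match.arg(b, m$name)])
}

# unit position vectors (n x 3), x towards right ear, y towards nasion, z up
.montage_xyz <- function(m) {
  cbind(x = cos(m$lat) * sin(m$lon),
        y = cos(m$lat) * cos(m$lon),
        z = sin(m$lat))
}

#' Read a montage from a columnar text file
#'
#' The file is TSV/CSV with columns `name`, `lat`, `lon`.  A comment line
#' `# unit: deg` or `# unit: rad` before the column header declares the
#' angular unit; it is required.
#'
#' @param path file path.
#' @param radius head radius in cm.
#' @return a [montage()].
#' @export
load_montage <- function(path, radius = 9) {
  if (!file.exists(path)) stop("montage file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("parse error: empty montage file ", path)
  unit <- NA_character_
  hdr <- grep("^#\\s*unit\\s*:", lines, ignore.case = TRUE)
  if (length(hdr) >= 1L) {
    unit <- tolower(trimws(sub("^#\\s*unit\\s*:", "", lines[hdr[1]],
                               ignore.case = TRUE)))
  }
  if (!isTRUE(unit %in% c("deg", "rad")))
    stop("parse error: missing or invalid '# unit: deg|rad' header in ", path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L)
    stop("parse error: no electrode rows in ", path)
  sep <- if (grepl(",", body[1])) "," else ""
  tab <- tryCatch(
    read.table(text = body, header = TRUE, sep = sep,
               stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e)))
  need <- c("name", "lat", "lon")
  if (!all(need %in% names(tab)))
    stop("parse error: montage file must have columns name, lat, lon")
  for (i in seq_len(nrow(tab))) {
    if (!is.finite(suppressWarnings(as.numeric(tab$lat[i]))) ||
        !is.finite(suppressWarnings(as.numeric(tab$lon[i]))))
      stop(sprintf("parse error at data row %d of %s: non-numeric coordinate",
                   i, path))
  }
  dup <- tab$name[duplicated(tab$name)]
  if (length(dup))
    stop(sprintf("parse error at data row %d of %s: duplicate name '%s'",
                 which(duplicated(tab$name))[1], path, dup[1]))
  lim <- if (unit == "deg") 90 else pi / 2
  bad <- which(abs(as.numeric(tab$lat)) > lim + 1e-9)
  if (length(bad))
    stop(sprintf("parse error at data row %d of %s: latitude out of range",
                 bad[1], path))
  montage(tab$name, as.numeric(tab$lat), as.numeric(tab$lon),
          radius = radius, unit = unit)
}

#' Write a montage to a columnar text file (radians)
#' @param m a [montage()].
#' @param path output path.
#' @export
write_montage <- function(m, path) {
  stopifnot(inherits(m, "ssvep_montage"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# unit: rad", con)
  write.table(as.data.frame(m)[, c("name", "lat", "lon")], con,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
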