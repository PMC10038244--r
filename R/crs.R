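# Coordinate reference systems.
#
# The package carries its own small projection engine: a registry of EPSG
# codes covering geographic NAD83/WGS84 and the North Carolina State Plane
# zone (Lambert conformal conic, 2 standard parallels, GRS80), in both US
# survey feet (EPSG:2264) and metres (EPSG:32119). All protocol distances are
# in feet, so EPSG:2264 is the default working CRS. Formulas are the standard
# conformal-conic series (forward and iterative inverse) on the ellipsoid.

.GRS80_A <- 6378137.0
.GRS80_F <- 1 / 298.257222101
.USFT <- 1200 / 3937  # US survey foot in metres

.lccParams <- function(lat1, lat2, lat0, lon0, fe_m, fn_m) {
  list(lat1 = lat1, lat2 = lat2, lat0 = lat0, lon0 = lon0,
       fe = fe_m, fn = fn_m)
}

.CRS_REGISTRY <- list(
  `4326` = list(epsg = 4326L, kind = "geographic", unit = "degree",
                unit_to_m = NA_real_, name = "WGS 84",
                wkt = paste0('GEOGCS["GCS_WGS_1984",DATUM["D_WGS_1984",',
                             'SPHEROID["WGS_1984",6378137.0,298.257223563]],',
                             'PRIMEM["Greenwich",0.0],',
                             'UNIT["Degree",0.0174532925199433],',
                             'AUTHORITY["EPSG","4326"]]')),
  `4269` = list(epsg = 4269L, kind = "geographic", unit = "degree",
                unit_to_m = NA_real_, name = "NAD83",
                wkt = paste0('GEOGCS["GCS_North_American_1983",',
                             'DATUM["D_North_American_1983",',
                             'SPHEROID["GRS_1980",6378137.0,298.257222101]],',
                             'PRIMEM["Greenwich",0.0],',
                             'UNIT["Degree",0.0174532925199433],',
                             'AUTHORITY["EPSG","4269"]]')),
  `2264` = list(epsg = 2264L, kind = "projected", unit = "us-ft",
                unit_to_m = 1200 / 3937,
                name = "NAD83 / North Carolina (ftUS)",
                proj = "lcc",
                params = .lccParams(34 + 20 / 60, 36 + 10 / 60, 33.75, -79,
                                    609601.2192024384, 0),
                wkt = paste0('PROJCS["NAD_1983_StatePlane_North_Carolina_',
                             'FIPS_3200_Feet",GEOGCS["GCS_North_American_1983",',
                             'DATUM["D_North_American_1983",',
                             'SPHEROID["GRS_1980",6378137.0,298.257222101]],',
                             'PRIMEM["Greenwich",0.0],',
                             'UNIT["Degree",0.0174532925199433]],',
                             'PROJECTION["Lambert_Conformal_Conic"],',
                             'PARAMETER["False_Easting",2000000.002616666],',
                             'PARAMETER["False_Northing",0.0],',
                             'PARAMETER["Central_Meridian",-79.0],',
                             'PARAMETER["Standard_Parallel_1",34.33333333333334],',
                             'PARAMETER["Standard_Parallel_2",36.16666666666666],',
                             'PARAMETER["Latitude_Of_Origin",33.75],',
                             'UNIT["Foot_US",0.3048006096012192],',
                             'AUTHORITY["EPSG","2264"]]')),
  `32119` = list(epsg = 32119L, kind = "projected", unit = "m",
                 unit_to_m = 1,
                 name = "NAD83 / North Carolina",
                 proj = "lcc",
                 params = .lccParams(34 + 20 / 60, 36 + 10 / 60, 33.75, -79,
                                     609601.22, 0),
                 wkt = paste0('PROJCS["NAD_1983_StatePlane_North_Carolina_',
                              'FIPS_3200",GEOGCS["GCS_North_American_1983",',
                              'DATUM["D_North_American_1983",',
                              'SPHEROID["GRS_1980",6378137.0,298.257222101]],',
                              'PRIMEM["Greenwich",0.0],',
                              'UNIT["Degree",0.0174532925199433]],',
                              'PROJECTION["Lambert_Conformal_Conic"],',
                              'PARAMETER["False_Easting",609601.22],',
                              'PARAMETER["False_Northing",0.0],',
                              'PARAMETER["Central_Meridian",-79.0],',
                              'PARAMETER["Standard_Parallel_1",34.33333333333334],',
                              'PARAMETER["Standard_Parallel_2",36.16666666666666],',
                              'PARAMETER["Latitude_Of_Origin",33.75],',
                              'UNIT["Meter",1.0],',
                              'AUTHORITY["EPSG","32119"]]')))

#' Look up a supported coordinate reference system
#'
#' @param epsg integer EPSG code
#' @return a list describing the CRS (kind, unit, projection parameters, WKT)
#' @examples
#' crsInfo(2264)$unit
#' @export
crsInfo <- function(epsg) {
  info <- .CRS_REGISTRY[[as.character(as.integer(epsg))]]
  if (is.null(info))
    stop("unknown or unsupported EPSG code: ", epsg,
         " (supported: ", paste(names(.CRS_REGISTRY), collapse = ", "), ")")
  info
}

#' @noRd
crsIsGeographic <- function(epsg) crsInfo(epsg)$kind == "geographic"

# match a WKT string (e.g. from a .prj file) back to a registered EPSG code
#' @noRd
crsFromWKT <- function(wkt) {
  for (info in .CRS_REGISTRY) {
    m <- regmatches(wkt, regexpr('AUTHORITY\\["EPSG","[0-9]+"\\]\\]$', wkt))
    if (length(m) && grepl(paste0('"', info$epsg, '"'), m)) return(info$epsg)
  }
  # fall back to name matching (ESRI-style .prj files lack authorities)
  if (grepl("North_Carolina", wkt) && grepl("Foot", wkt, ignore.case = TRUE))
    return(2264L)
  if (grepl("North_Carolina", wkt)) return(32119L)
  if (grepl("WGS_1984|WGS 84", wkt)) return(4326L)
  if (grepl("North_American_1983|NAD83", wkt)) return(4269L)
  NA_integer_
}

# ---- Lambert conformal conic (2SP), GRS80 ---------------------------------

.lccSetup <- function(p) {
  a <- .GRS80_A
  e2 <- .GRS80_F * (2 - .GRS80_F)
  e <- sqrt(e2)
  rad <- pi / 180
  mfun <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  tfun <- function(phi) tan(pi / 4 - phi / 2) /
    ((1 - e * sin(phi)) / (1 + e * sin(phi)))^(e / 2)
  phi1 <- p$lat1 * rad; phi2 <- p$lat2 * rad; phi0 <- p$lat0 * rad
  m1 <- mfun(phi1); m2 <- mfun(phi2)
  t0 <- tfun(phi0); t1 <- tfun(phi1); t2 <- tfun(phi2)
  n <- (log(m1) - log(m2)) / (log(t1) - log(t2))
  F <- m1 / (n * t1^n)
  rho0 <- a * F * t0^n
  list(a = a, e = e, n = n, F = F, rho0 = rho0,
       lam0 = p$lon0 * rad, fe = p$fe, fn = p$fn, tfun = tfun)
}

# lon/lat degrees -> projected metres
.lccForward <- function(lon, lat, p) {
  s <- .lccSetup(p)
  rad <- pi / 180
  t <- s$tfun(lat * rad)
  rho <- s$a * s$F * t^s$n
  theta <- s$n * (lon * rad - s$lam0)
  cbind(s$fe + rho * sin(theta), s$fn + s$rho0 - rho * cos(theta))
}

# projected metres -> lon/lat degrees
.lccInverse <- function(x, y, p) {
  s <- .lccSetup(p)
  xp <- x - s$fe
  yp <- s$rho0 - (y - s$fn)
  rho <- sign(s$n) * sqrt(xp^2 + yp^2)
  t <- (rho / (s$a * s$F))^(1 / s$n)
  theta <- atan2(sign(s$n) * xp, sign(s$n) * yp)
  lam <- theta / s$n + s$lam0
  phi <- pi / 2 - 2 * atan(t)
  for (i in 1:8) {
    phi <- pi / 2 - 2 * atan(t * ((1 - s$e * sin(phi)) /
                                  (1 + s$e * sin(phi)))^(s$e / 2))
  }
  cbind(lam / pi * 180, phi / pi * 180)
}

# transform an n x 2 coordinate matrix between two registered CRSs
#' @noRd
transformCoords <- function(m, from, to) {
  if (from == to) return(m)
  src <- crsInfo(from); dst <- crsInfo(to)
  # to geographic degrees
  if (src$kind == "projected") {
    ll <- .lccInverse(m[, 1] * src$unit_to_m, m[, 2] * src$unit_to_m,
                      src$params)
  } else ll <- m
  if (dst$kind == "projected") {
    xy <- .lccForward(ll[, 1], ll[, 2], dst$params)
    xy / dst$unit_to_m
  } else ll
}
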