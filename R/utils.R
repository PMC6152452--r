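`%||%` <- function(a, b) if (is.null(a)) b else a

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6,371 km, in metres.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in WGS84 decimal degrees (vectorised).
#' @return Numeric vector of distances in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# One draw from Dirichlet(alpha); guards the all-zero gamma corner case.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
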