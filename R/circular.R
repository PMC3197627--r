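# Small circular-statistics primitives (degrees throughout).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap to [-180, 180)
wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Circular mean of angles in degrees
#' @param x angles (degrees).
#' @return mean angle in [-180, 180).
#' @export
circ_mean_deg <- function(x) {
  x <- x[!is.na(x)]
  wrap_deg(rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x))))))
}

#' Circular standard deviation (degrees)
#' @param x angles (degrees).
#' @return sqrt(-2 log R) in degrees, R the mean resultant length.
#' @export
circ_sd_deg <- function(x) {
  x <- x[!is.na(x)]
  r <- sqrt(mean(sin(deg2rad(x)))^2 + mean(cos(deg2rad(x)))^2)
  rad2deg(sqrt(-2 * log(max(r, 1e-12))))
}

#' Shortest-arc circular difference a - b (degrees)
#' @param a,b angles (degrees).
#' @return difference in [-180, 180).
#' @export
circ_diff_deg <- function(a, b) wrap_deg(a - b)

#' von Mises random angles (degrees)
#'
#' Best-Fisher (1979) rejection sampler; kappa = 0 gives the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (degrees).
#' @param kappa concentration (>= 0).
#' @return angles in [-180, 180).
#' @export
rvonmises_deg <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) abort("kappa must be >= 0")
  if (kappa == 0) return(wrap_deg(runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap_deg(mu + rad2deg(out))
}
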