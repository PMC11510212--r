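# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  # map -180 to +180 so the interval is half-open on the left
  y[y == -180] <- 180
  y
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

vhat <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero vector", call. = FALSE)
  a / n
}

# Deterministic unit vector perpendicular to u.
perp_vector <- function(u) {
  u <- vhat(u)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  vhat(ref - sum(ref * u) * u)
}

# Rotation matrix: angle (degrees) about unit axis, Rodrigues form.
rotation_about <- function(axis, angle_deg) {
  u <- vhat(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

# Minimal rotation carrying unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- vhat(a); b <- vhat(b)
  ax <- vcross(a, b)
  s <- vnorm(ax)
  if (s < 1e-12) {
    if (sum(a * b) > 0) return(diag(3))
    # antiparallel: rotate 180 degrees about any perpendicular
    return(rotation_about(perp_vector(a), 180))
  }
  rotation_about(ax, rad2deg(atan2(s, sum(a * b))))
}

# Signed angle from a to b in the plane perpendicular to axis u
# (right-handed about u), degrees in (-180, 180].
signed_angle_about <- function(a, b, u) {
  u <- vhat(u)
  ap <- a - sum(a * u) * u
  bp <- b - sum(b * u) * u
  if (vnorm(ap) < 1e-9 || vnorm(bp) < 1e-9)
    stop("signed angle undefined: zero projection", call. = FALSE)
  wrap_angle(rad2deg(atan2(sum(vcross(ap, bp) * u), sum(ap * bp))))
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# RNG stream is untouched (generators are pure functions of spec + seed).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_gact <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "gact_error")))
}
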