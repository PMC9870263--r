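# Independent brute-force oracles used across the suite.  These stay off
# the package's code paths: rotations go through explicit axis matrices,
# statistics through textbook formulas, lag search through a double loop.

rot_x <- function(a) {
  a <- a * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- a * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# intrinsic ZYX rotation matrix built by explicit matrix products
euler_zyx_matrix <- function(yaw, pitch, roll) rot_z(yaw) %*% rot_y(pitch) %*% rot_x(roll)

# third-angle (roll) decomposition read off the rotation matrix
matrix_roll_zyx <- function(R) atan2(R[3, 2], R[3, 3]) * 180 / pi

quat_to_matrix <- function(q) {
  q <- unclass(q)
  w <- q[1, 1]; x <- q[1, 2]; y <- q[1, 3]; z <- q[1, 4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# loop-based unwrap: walk the sequence adjusting each value by +-360 until
# it is within 180 of its predecessor
unwrap_oracle <- function(v) {
  out <- v
  for (i in seq_along(v)[-1]) {
    while (out[i] - out[i - 1] > 180) out[i] <- out[i] - 360
    while (out[i] - out[i - 1] < -180) out[i] <- out[i] + 360
    if (i < length(v)) out[i + 1] <- v[i + 1] + (out[i] - v[i])
  }
  out
}

# exhaustive lag sweep, Pearson correlation per overlap
xcorr_oracle <- function(a, b, max_lag) {
  best <- -Inf; best_lag <- NA
  for (L in -max_lag:max_lag) {
    ia <- max(1, 1 + L):min(length(a), length(b) + L)
    if (length(ia) < 3) next
    sa <- a[ia]; sb <- b[ia - L]
    if (sd(sa) == 0 || sd(sb) == 0) next
    r <- cor(sa, sb)
    if (r > best + 1e-12 ||
        (abs(r - best) <= 1e-12 && (abs(L) < abs(best_lag) ||
                                    (abs(L) == abs(best_lag) && L < best_lag)))) {
      best <- r; best_lag <- L
    }
  }
  list(lag = best_lag, cor = best)
}

# textbook Bland-Altman quantities
ba_oracle <- function(sensor, reference) {
  d <- sensor - reference
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(m_dif = m, sd = s, rpc = 1.96 * s, ula = m + 1.96 * s, lla = m - 1.96 * s)
}

# normal-equations OLS of y on x
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  m <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  b <- (sy - m * sx) / n
  r2 <- ((n * sum(x * y) - sx * sy) /
         sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2)))^2
  list(m = m, b = b, r2 = r2)
}

# textbook paired t-test
paired_t_oracle <- function(x2, x1) {
  d <- x2 - x1
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# small noisy session pair for alignment/agreement tests
make_shifted_pair <- function(n = 600, lag = 7, snr = 10, seed = 42, rate = 60) {
  set.seed(seed)
  t <- seq_len(n + abs(lag)) / rate
  # incommensurate frequencies so no integer lag aliases the true one
  x <- 20 * sin(2 * pi * 0.93 * t) + 6 * sin(2 * pi * 1.71 * t + 1) +
    4 * sin(2 * pi * 0.23 * t + 2)
  noise_sd <- sd(x) / snr
  a_full <- x + rnorm(length(x), 0, noise_sd)
  b_full <- x + rnorm(length(x), 0, noise_sd)
  # windows offset so that a[i] = b[i - lag] (a lags b by +lag)
  a0 <- max(0, -lag)
  a <- a_full[(a0 + 1):(a0 + n)]
  b <- b_full[(a0 + lag + 1):(a0 + lag + n)]
  list(a = a, b = b)
}
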