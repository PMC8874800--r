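# shared fixtures, generated in code

# uniformly random rotation matrix, independent of the package's converters
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# elemental rotations for brute-force composition oracles
Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# tiny hand-built session: straight-line controller motion, static head
toy_session <- function(n = 50, fs = 89, vx = 0.2) {
  t <- (seq_len(n) - 1) / fs
  static <- data.frame(x = 0, y = 0, z = 0, gamma = 0, beta = 0, alpha = 0)[rep(1, n), ]
  right <- data.frame(x = 0.2 + vx * t, y = -0.2, z = 0.1,
                      gamma = 0, beta = 0, alpha = 0)
  left <- data.frame(x = rep(-0.2, n), y = -0.2, z = 0.1,
                     gamma = 0, beta = 0, alpha = 0)
  vr_session(t, static, right, left, sample_rate_hz = fs)
}

# noise-free, tremor-free generator parameters for closed-form checks
clean_params <- function(...) {
  subject_params(pos_noise_sd = 0, ang_noise_sd = 0, hmd_ang_noise_sd = 0,
                 tremor_pos_amp = 0, tremor_ang_amp = 0, ...)
}

session_positions <- function(session, device) {
  as.matrix(session[[device]][c("x", "y", "z")])
}

segment_session <- function(session, reps = 5) {
  dt <- 1 / session$sample_rate_hz
  om <- omega_series(session_positions(session, "right"),
                     session_positions(session, "left"), dt)
  build_segments(detect_intervals(om, dt = dt), reps = reps)
}
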