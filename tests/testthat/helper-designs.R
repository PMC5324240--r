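# Generating designs used across the tests: the three parameter-recovery
# study designs (1D discrete, 2D discrete, 1D time-dependent f1) with their
# published true values and empirical confidence bounds.

design_1d <- function() {
  continuous_params(a = -0.05, f1 = 80, b = 5, Q = 1e-6, f = 80,
                    mu0 = 1e-5, theta = 0.1)
}

# printed recovery bounds for the 1D discrete-time study
bounds_1d <- data.frame(
  par = c("a", "f1", "Q", "f", "b", "mu0", "theta"),
  true = c(-5e-2, 80, 1e-6, 80, 5, 1e-5, 0.1),
  lw = c(-5.1884e-02, 7.9619e+01, 8.8716e-07, 7.9855e+01, 4.9827e+00,
         8.3345e-06, 9.7000e-02),
  up = c(-4.8210e-02, 8.0390e+01, 1.1781e-06, 8.0152e+01, 5.0151e+00,
         1.2294e-05, 1.0200e-01))

design_2d <- function() {
  continuous_params(
    a = matrix(c(-0.05, 0.001, 0.001, -0.05), 2, 2, byrow = TRUE),
    f1 = c(100, 200), b = c(2, 5),
    Q = matrix(c(1e-6, 1e-7, 1e-7, 1e-6), 2, 2),
    f = c(100, 200), mu0 = 1e-4, theta = 0.08)
}

bounds_2d <- data.frame(
  par = c("a11", "a12", "a21", "a22", "f1_1", "f1_2",
          "Q11", "Q12", "Q21", "Q22", "f_1", "f_2", "b_1", "b_2",
          "mu0", "theta"),
  true = c(-5e-2, 1e-3, 1e-3, -5e-2, 100, 200,
           1e-6, 1e-7, 1e-7, 1e-6, 100, 200, 2, 5, 1e-4, 8e-2),
  lw = c(-5.0074e-02, 8.4740e-04, 7.2369e-04, -5.0336e-02,
         9.8931e+01, 1.9864e+02,
         9.9703e-07, 9.6407e-08, 9.6407e-08, 9.9672e-07,
         9.9974e+01, 1.9997e+02, 2.0000e+00, 4.9972e+00,
         9.8661e-05, 7.9680e-02),
  up = c(-4.9742e-02, 1.0151e-03, 1.5977e-03, -4.9945e-02,
         1.0250e+02, 2.0038e+02,
         1.0445e-06, 1.1124e-07, 1.1124e-07, 1.0275e-06,
         1.0012e+02, 2.0004e+02, 2.0014e+00, 5.0005e+00,
         1.0202e-04, 8.0120e-02))

design_td <- function() {
  continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 1e-5, f = 80,
                    mu0 = 0.1, theta = 0, slopes = list(f1 = 0.1))
}

bounds_td <- data.frame(
  par = c("a", "f1a", "f1b", "Q", "f", "b", "mu0"),
  true = c(-5e-2, 80, 0.1, 1e-5, 80, 2.5, 0.1),
  lw = c(-5.3315e-02, 7.8839e+01, 8.4886e-02, 1.3449e-06, 3.0810e+01,
         2.4676e+00, 8.4344e-02),
  up = c(-4.5373e-02, 8.1205e+01, 1.1978e-01, 1.8183e-05, 1.1497e+02,
         2.5336e+00, 1.0169e-01))

# flatten a continuous fit of the 2D design into the bounds_2d ordering
flatten_2d <- function(p) {
  c(p$a[1, 1], p$a[1, 2], p$a[2, 1], p$a[2, 2], p$f1,
    p$Q[1, 1], p$Q[1, 2], p$Q[2, 1], p$Q[2, 2], p$f, p$b, p$mu0, p$theta)
}

flatten_1d <- function(p) {
  c(p$a[1, 1], p$f1, p$Q[1, 1], p$f, p$b, p$mu0, p$theta)
}

# tiny deterministic long table (two subjects, two biomarkers)
toy_records <- function() {
  longitudinal_records(data.frame(
    id = c(1, 1, 1, 2, 2),
    event = c(0, 0, 1, 0, 0),
    t1 = c(30, 32, 34, 40, 41),
    t2 = c(32, 34, 35.5, 41, 43),
    DBP = c(80, 82, 85, 78, 77),
    BMI = c(25, 25.5, 26, 27, 27.2)))
}
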