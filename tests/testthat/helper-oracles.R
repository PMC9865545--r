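# Independent numerical oracles, deliberately implemented by routes
# different from the package code.

# Radial diffusion into a cylinder (constant surface concentration),
# solved by explicit finite differences in dimensionless variables
# rho = r/a, tau = D t / a^2. Returns the uptake fraction
# M(tau)/M(inf) = integral of 2 rho c d rho on the requested tau grid.
pde_cylinder_uptake <- function(tau_out, n_r = 201, dtau = 5e-6) {
  drho <- 1 / (n_r - 1)
  rho <- seq(0, 1, length.out = n_r)
  c_now <- numeric(n_r)
  c_now[n_r] <- 1
  tau <- 0
  tau_out <- sort(tau_out)
  out <- numeric(length(tau_out))
  k_out <- 1
  interior <- 2:(n_r - 1)
  while (k_out <= length(tau_out)) {
    step <- min(dtau, tau_out[k_out] - tau)
    if (step > 0) {
      lap <- (c_now[interior + 1] - 2 * c_now[interior] +
                c_now[interior - 1]) / drho^2 +
        (c_now[interior + 1] - c_now[interior - 1]) /
          (2 * drho * rho[interior])
      c_new <- c_now
      c_new[interior] <- c_now[interior] + step * lap
      # r = 0: symmetry limit of the radial Laplacian is 2 * d2c/dr2
      c_new[1] <- c_now[1] + step * 4 * (c_now[2] - c_now[1]) / drho^2
      c_now <- c_new
      tau <- tau + step
    }
    if (abs(tau - tau_out[k_out]) < 1e-12) {
      # trapezoidal mass integral; M(inf) = integral 2 rho d rho = 1
      out[k_out] <- sum(diff(rho) * (rho[-1] * c_now[-1] +
                                       rho[-n_r] * c_now[-n_r]))
      k_out <- k_out + 1
    }
  }
  out
}

# Henderson-Hasselbalch net charge by direct per-group enumeration
# (protonation fraction of every single group summed one at a time).
enumerate_net_charge <- function(counts, pkas, signs, pH) {
  total <- 0
  for (g in seq_along(counts)) {
    for (i in seq_len(counts[g])) {
      frac_prot <- 1 / (1 + 10^(pH - pkas[g]))
      charge <- if (signs[g] > 0) frac_prot else -(1 - frac_prot)
      total <- total + charge
    }
  }
  total
}

# weighing-schedule time grid used across synthetic-data tests
expect_close <- function(x, y, rel) testthat::expect_lt(abs(x - y) / abs(y), rel)
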