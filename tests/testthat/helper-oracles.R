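# Independent least-squares oracle: explicit normal equations, no lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  k <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a <- (sy - k * sx) / n
  resid <- y - (k * x + a)
  ss_tot <- sum((y - sy / n)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(resid^2) / ss_tot
  list(slope = k, intercept = a, r_squared = r2)
}

# Minimal compound-side data frame for leaf_polarity().
side_df <- function(abundance, delta,
                    compound = paste0("c", seq_along(abundance))) {
  data.frame(compound = compound, abundance = abundance, delta = delta,
             stringsAsFactors = FALSE)
}

# A coupling_fit lying exactly on a chosen line, built through the public
# fitting interface from exact points.
exact_identity_fit <- function(k, a, x = c(50, 100, 150)) {
  fit_coupling(x, k * x + a, "identity")
}
exact_log10_fit <- function(k, a, x = c(1, 2, 4)) {
  fit_coupling(x, 10^(k * log10(x) + a), "log10")
}

# Hand-built clustered dataset with a known linear polarity model:
# polarity = b0 + b_asl * asl + b_light * I(HL) + noise.
linear_path_data <- function(b0 = 0.5, b_asl = -2, b_light = 0,
                             sigma = 0, n_plants = 18, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_plants)) {
    light <- if (p <= n_plants / 2) "HL" else "LL"
    for (age in c("young", "mature", "old")) {
      a <- stats::runif(1, 0.05, 0.45)
      rows[[length(rows) + 1L]] <- data.frame(
        plant_id = sprintf("P%02d", p), light = light, age = age,
        asl = a,
        polarity = b0 + b_asl * a + b_light * (light == "HL") +
          stats::rnorm(1, 0, sigma))
    }
  }
  do.call(rbind, rows)
}
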