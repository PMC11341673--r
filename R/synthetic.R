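#' Configuration for the synthetic study generator
#'
#' Builds the full parameter set for [generate_study()]. The defaults
#' emulate the design of a two-species growth-chamber study: 2 species x
#' 2 light levels (HL/LL) x 3 leaf-age classes x 9 replicate plants, with
#' stomatal densities coupled linearly between leaf sides, wax coverages
#' coupled log-linearly, bulk-leaf delta13C set per species and light,
#' and a linear drawdown model `D = d0 + d1 * ASL + d2 * I(HL)` that is
#' inverted to the wax isotopic polarity each leaf imprints. Pepper-like
#' wax is five odd-chain alkanes (C27-C35); broccoli-like wax three C29
#' aliphatics. Instrument noise on per-compound delta13C defaults to
#' 0.1 permil.
#'
#' Per-compound delta offsets are centred so that their abundance-weighted
#' mean is zero; the weighted side mean then equals the generating side
#' target exactly at zero noise.
#'
#' @param seed Integer seed stored in the config; [generate_study()] is
#'   deterministic given the config.
#' @param noise `"default"` for realistic noise levels, `"none"` to zero
#'   every residual and measurement sigma (design spreads such as the
#'   abaxial-density variation are kept, so regressions stay estimable).
#' @param plants_per_treatment Replicate plants per species x light cell;
#'   each plant contributes one leaf per age class.
#' @return A list of class `"synthetic_config"`; see the vignette for the
#'   meaning and units of every field.
#' @export
synthetic_config <- function(seed = 1L, noise = c("default", "none"),
                             plants_per_treatment = 9L) {
  noise <- match.arg(noise)
  stopifnot(plants_per_treatment >= 1L)
  centre <- function(df) {
    df$offset <- df$offset - sum(df$weight * df$offset) / sum(df$weight)
    df
  }
  pepper_compounds <- centre(data.frame(
    compound = c("C27_alkane", "C29_alkane", "C31_alkane",
                 "C33_alkane", "C35_alkane"),
    weight = c(0.10, 0.35, 0.30, 0.15, 0.10),
    offset = c(-1.0, -0.3, 0.2, 0.6, 1.0)))
  broccoli_compounds <- centre(data.frame(
    compound = c("C29_alkane", "C29_ketone", "C29_ol"),
    weight = c(0.50, 0.30, 0.20),
    offset = c(-0.8, 0.4, 0.9)))
  cfg <- list(
    seed = as.integer(seed),
    design = list(
      ages = c("young", "mature", "old"),
      plants_per_treatment = as.integer(plants_per_treatment),
      lights = c("HL", "LL"),
      age_sd_mult = c(young = 1.05, mature = 1.00, old = 0.95)
    ),
    species = list(
      pepper = list(
        sd_k = 0.37, sd_a = -20, sd_sigma = 8,
        sd_ab_mean = c(HL = 300, LL = 130), sd_ab_sd = 15,
        wax_k = 0.90, wax_a = 0.15, wax_sigma = 0.05,
        logw_ab_mean = c(HL = 0.0, LL = 0.3), logw_ab_sd = 0.15,
        delta_leaf = c(HL = -28.26, LL = -33.91),
        compounds = pepper_compounds
      ),
      broccoli = list(
        sd_k = 1.00, sd_a = -150, sd_sigma = 15,
        sd_ab_mean = c(HL = 360, LL = 280), sd_ab_sd = 25,
        wax_k = 1.10, wax_a = -0.20, wax_sigma = 0.07,
        logw_ab_mean = c(HL = 1.0, LL = 0.8), logw_ab_sd = 0.15,
        delta_leaf = c(HL = -27.63, LL = -33.95),
        compounds = broccoli_compounds
      )
    ),
    drawdown = list(d0 = 0.10, d1 = -0.25, d2 = -0.04, d_sigma = 0.01),
    noise = list(compound_sigma = 0.1, plant_sigma = 0.3,
                 delta_leaf_sigma = 0.2),
    wax_offset = -3.0,
    params = disc_params()
  )
  if (noise == "none") {
    for (sp in names(cfg$species)) {
      cfg$species[[sp]]$sd_sigma <- 0
      cfg$species[[sp]]$wax_sigma <- 0
    }
    cfg$drawdown$d_sigma <- 0
    cfg$noise$compound_sigma <- 0
    cfg$noise$plant_sigma <- 0
    cfg$noise$delta_leaf_sigma <- 0
  }
  structure(cfg, class = "synthetic_config")
}

.validate_config <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    if (s$sd_sigma < 0 || s$wax_sigma < 0 || s$sd_ab_sd < 0 ||
        s$logw_ab_sd < 0) {
      stop(sprintf("Negative sigma in species `%s` config.", sp),
           call. = FALSE)
    }
    if (any(s$compounds$weight <= 0)) {
      stop(sprintf("Abundance weights must be positive (species `%s`).",
                   sp), call. = FALSE)
    }
  }
  if (config$drawdown$d_sigma < 0 ||
      any(unlist(config$noise) < 0)) {
    stop("All noise sigmas must be non-negative.", call. = FALSE)
  }
  invisible(config)
}

#' Generate a synthetic two-species study with known ground truth
#'
#' Forward-simulates a full study from a [synthetic_config()]: for every
#' leaf, abaxial stomatal density is drawn (normal, truncated at zero),
#' the adaxial density follows the linear side coupling plus residual
#' noise, the true amphistomy level and drawdown `D` are computed, `D` is
#' inverted to the true wax polarity via [polarity_from_drawdown()], and
#' per-compound delta13C values are laid down as side target + compound
#' offset + plant random intercept + measurement noise. Wax coverages are
#' drawn from the log-linear side coupling.
#'
#' @param config A [synthetic_config()].
#' @return List with `leaves` (contract-named table, see
#'   [read_leaves()]), `compounds` (long per-compound table), and `truth`
#'   (per-leaf true ASL, D and polarity; per-species generating coupling
#'   parameters; drawdown coefficients; truncation count; seed).
#'   Deterministic given the config, including its seed.
#' @examples
#' study <- generate_study(synthetic_config(seed = 42))
#' head(study$leaves)
#' @export
generate_study <- function(config = synthetic_config()) {
  .validate_config(config)
  set.seed(config$seed)
  des <- config$design
  n_trunc <- 0L
  leaf_rows <- list()
  comp_rows <- list()
  truth_rows <- list()
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    for (light in des$lights) {
      for (p in seq_len(des$plants_per_treatment)) {
        plant_id <- sprintf("%s_%s_P%02d", sp, light, p)
        plant_int <- stats::rnorm(1, 0, config$noise$plant_sigma)
        for (age in des$ages) {
          leaf_id <- sprintf("%s_%s", plant_id, age)
          mult <- des$age_sd_mult[[age]]
          sd_ab <- stats::rnorm(1, s$sd_ab_mean[[light]] * mult,
                                s$sd_ab_sd)
          if (sd_ab < 0) { sd_ab <- 0; n_trunc <- n_trunc + 1L }
          sd_ad <- s$sd_k * sd_ab + s$sd_a +
            stats::rnorm(1, 0, s$sd_sigma)
          if (sd_ad < 0) { sd_ad <- 0; n_trunc <- n_trunc + 1L }
          asl_true <- asl(sd_ad, sd_ab)
          d_true <- config$drawdown$d0 +
            config$drawdown$d1 * asl_true +
            config$drawdown$d2 * (light == "HL") +
            stats::rnorm(1, 0, config$drawdown$d_sigma)
          delta_leaf <- s$delta_leaf[[light]] +
            stats::rnorm(1, 0, config$noise$delta_leaf_sigma)
          N <- delta_leaf - config$params$delta_b + config$params$frac_a
          pol_true <- polarity_from_drawdown(d_true, delta_leaf,
                                             config$params)
          if (abs(N / pol_true) <= 1 + 1e-6 && pol_true != 0) {
            stop(sprintf(
              paste0("Config generates non-physical polarity (%.3g ",
                     "permil at N = %.3g) for species `%s`, light %s; ",
                     "check the drawdown coefficients."),
              pol_true, N, sp, light), call. = FALSE)
          }
          mid <- delta_leaf + config$wax_offset
          side_target <- c(adaxial = mid - pol_true / 2,
                           abaxial = mid + pol_true / 2)
          for (side in c("adaxial", "abaxial")) {
            k <- nrow(s$compounds)
            comp_rows[[length(comp_rows) + 1L]] <- data.frame(
              leaf_id = leaf_id, side = side,
              compound = s$compounds$compound,
              abundance = s$compounds$weight,
              delta_permil = side_target[[side]] + s$compounds$offset +
                plant_int +
                stats::rnorm(k, 0, config$noise$compound_sigma),
              stringsAsFactors = FALSE)
          }
          logw_ab <- stats::rnorm(1, s$logw_ab_mean[[light]],
                                  s$logw_ab_sd)
          logw_ad <- s$wax_k * logw_ab + s$wax_a +
            stats::rnorm(1, 0, s$wax_sigma)
          leaf_rows[[length(leaf_rows) + 1L]] <- data.frame(
            leaf_id = leaf_id, species = sp, light = light, age = age,
            plant_id = plant_id,
            sd_ad_mm2 = sd_ad, sd_ab_mm2 = sd_ab,
            w_ad_ug_cm2 = 10^logw_ad, w_ab_ug_cm2 = 10^logw_ab,
            delta_leaf_permil = delta_leaf, stringsAsFactors = FALSE)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            leaf_id = leaf_id, species = sp, light = light, age = age,
            plant_id = plant_id, asl_true = asl_true, d_true = d_true,
            polarity_true = pol_true, delta_leaf_true = delta_leaf,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  leaves <- do.call(rbind, leaf_rows)
  compounds <- do.call(rbind, comp_rows)
  truth_leaves <- do.call(rbind, truth_rows)
  ord <- order(leaves$leaf_id)
  leaves <- leaves[ord, ]
  truth_leaves <- truth_leaves[order(truth_leaves$leaf_id), ]
  rownames(leaves) <- rownames(compounds) <- rownames(truth_leaves) <- NULL
  if (n_trunc > 0L) {
    message(sprintf("generate_study: %d negative draw(s) truncated to 0.",
                    n_trunc))
  }
  truth <- list(
    leaves = truth_leaves,
    coupling = lapply(config$species, function(s) {
      list(sd_k = s$sd_k, sd_a = s$sd_a,
           wax_k = s$wax_k, wax_a = s$wax_a)
    }),
    drawdown = config$drawdown[c("d0", "d1", "d2")],
    n_truncated = n_trunc,
    seed = config$seed
  )
  list(leaves = leaves, compounds = compounds, truth = truth)
}

# Population-level target for the path direct effect: the Eq-A projection
# fitted on noiseless truths at a large design size.
.true_direct_effects <- function(config, plants = 60L) {
  big <- config
  big$seed <- config$seed
  for (sp in names(big$species)) {
    big$species[[sp]]$sd_sigma <- 0
    big$species[[sp]]$wax_sigma <- 0
  }
  big$drawdown$d_sigma <- 0
  big$noise$compound_sigma <- 0
  big$noise$plant_sigma <- 0
  big$noise$delta_leaf_sigma <- 0
  big$design$plants_per_treatment <- as.integer(plants)
  tr <- generate_study(big)$truth$leaves
  vapply(unique(tr$species), function(sp) {
    sub <- tr[tr$species == sp, ]
    age <- factor(sub$age, levels = c("old", "mature", "young"))
    fit <- stats::lm(polarity_true ~ asl_true + (light == "HL") + age,
                     data = sub)
    unname(stats::coef(fit)["asl_true"])
  }, numeric(1))
}

#' Parameter-recovery report for the full pipeline
#'
#' Repeatedly generates synthetic studies, runs the whole estimation
#' pipeline on each (polarity aggregation, drawdown inversion, coupling
#' fits, asymptote, path direct effect), and aggregates estimator bias,
#' RMSE and confidence-interval coverage against the generator's ground
#' truth.
#'
#' Coverage is reported where the pipeline produces an interval: the
#' t-based intervals of the coupling slope/intercept and the bootstrap
#' interval of the path direct effect (whose target is the Equation-A
#' projection of the noiseless generating model, evaluated at a large
#' design size).
#'
#' @param config A [synthetic_config()]; its `seed` seeds the whole
#'   report, with per-replicate seeds derived from it.
#' @param n_seeds Number of generator replicates (>= 10).
#' @param n_boot Bootstrap resamples for the path stage per replicate.
#' @return Data frame with one row per quantity x species: `quantity`
#'   (`"D"`, `"k"`, `"a"`, `"asl_pot"`, `"direct_effect"`), `species`,
#'   `bias`, `rmse`, `coverage` (NA where no interval is produced),
#'   `n_seeds`.
#' @export
recovery_report <- function(config = synthetic_config(), n_seeds = 50L,
                            n_boot = 200L) {
  if (n_seeds < 10L) {
    stop("`n_seeds` must be at least 10.", call. = FALSE)
  }
  species <- names(config$species)
  true_direct <- .true_direct_effects(config)
  acc <- list()
  add <- function(quantity, sp, err, covered = NA) {
    key <- paste(quantity, sp, sep = "|")
    if (is.null(acc[[key]])) {
      acc[[key]] <<- list(err = numeric(0), cov = logical(0))
    }
    acc[[key]]$err <<- c(acc[[key]]$err, err)
    if (!is.na(covered)) acc[[key]]$cov <<- c(acc[[key]]$cov, covered)
  }
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    study <- suppressMessages(generate_study(cfg))
    leaves <- as_leaf_records(study$leaves)
    truth <- study$truth
    pol <- polarity_table(study$compounds, leaves, config$params)
    stopifnot(identical(pol$leaf_id, truth$leaves$leaf_id))
    add("D", "all", mean(pol$drawdown - truth$leaves$d_true))
    for (sp in species) {
      sub <- leaves[leaves$species == sp, ]
      xf <- stats::lm(sd_ad ~ sd_ab, data = sub)
      fit <- fit_coupling(sub$sd_ab, sub$sd_ad, "identity", group = sp)
      ci <- suppressWarnings(stats::confint(xf))
      tr <- truth$coupling[[sp]]
      add("k", sp, fit$slope_k - tr$sd_k,
          ci["sd_ab", 1] <= tr$sd_k && tr$sd_k <= ci["sd_ab", 2])
      add("a", sp, fit$intercept_a - tr$sd_a,
          ci["(Intercept)", 1] <= tr$sd_a &&
            tr$sd_a <= ci["(Intercept)", 2])
      add("asl_pot", sp, asl_pot(fit) - asl_pot(tr$sd_k))
      pd <- merge(patterning_summary(sub),
                  pol[c("leaf_id", "polarity")], by = "leaf_id")
      path <- fit_path_model(pd, cluster = "plant_id", n_boot = n_boot,
                             seed = cfg$seed %% 100000L)
      arow <- path$coefficients[path$coefficients$equation == "A" &
                                  path$coefficients$term == "asl", ]
      add("direct_effect", sp, path$direct_effect - true_direct[[sp]],
          arow$ci_low <= true_direct[[sp]] &&
            true_direct[[sp]] <= arow$ci_high)
    }
  }
  rows <- lapply(names(acc), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    e <- acc[[key]]
    data.frame(quantity = parts[1], species = parts[2],
               bias = mean(e$err), rmse = sqrt(mean(e$err^2)),
               coverage = if (length(e$cov)) mean(e$cov) else NA_real_,
               n_seeds = n_seeds, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
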