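#' Discrimination parameters for isotope-based CO2 inference
#'
#' Bundles the constants used to convert carbon-isotope compositions into
#' CO2 concentrations and gradients: the diffusion fractionation in still
#' air, the isotopic composition of ambient CO2, the reference
#' substomatal-to-ambient CO2 ratio, the boundary composition of CO2 after
#' partial fractionation through the stomatal pore, the (net) carboxylation
#' fractionation, ambient CO2 concentration, and the 13C/12C ratio of the
#' VPDB standard.
#'
#' By default `delta_b` is recomputed from `delta_air`, `frac_a` and
#' `ci_over_ca_ref` via [boundary_delta()]; with the defaults this gives
#' -9.6 permil. Pass `delta_b` explicitly to override.
#'
#' @param frac_a Fractionation by CO2 diffusion in still air, permil.
#'   Must be positive.
#' @param delta_air delta13C of ambient CO2, permil vs VPDB.
#' @param ci_over_ca_ref Reference ratio of substomatal to ambient CO2
#'   concentration, in (0, 1].
#' @param delta_b delta13C of CO2 after diffusion through the stomatal
#'   pore, permil. `NULL` (default) recomputes it from the other
#'   parameters.
#' @param frac_b Net carboxylation fractionation, permil. Must exceed
#'   `frac_a`.
#' @param c_a Ambient CO2 concentration, umol mol^-1.
#' @param r_vpdb 13C/12C isotope ratio of the VPDB standard.
#' @return An object of class `"disc_params"`: a named list of the seven
#'   parameters.
#' @examples
#' p <- disc_params()
#' p$delta_b  # -9.6
#' @export
disc_params <- function(frac_a = 4.4, delta_air = -8.5, ci_over_ca_ref = 0.75,
                        delta_b = NULL, frac_b = 30, c_a = 415,
                        r_vpdb = 0.0111802) {
  stopifnot(is.numeric(frac_a), length(frac_a) == 1L, frac_a > 0)
  stopifnot(is.numeric(ci_over_ca_ref), length(ci_over_ca_ref) == 1L,
            ci_over_ca_ref > 0, ci_over_ca_ref <= 1)
  stopifnot(is.numeric(frac_b), length(frac_b) == 1L, frac_b > frac_a)
  stopifnot(is.numeric(c_a), length(c_a) == 1L, c_a > 0)
  stopifnot(is.numeric(r_vpdb), length(r_vpdb) == 1L, r_vpdb > 0)
  if (is.null(delta_b)) {
    delta_b <- boundary_delta(delta_air, frac_a, ci_over_ca_ref)
  }
  structure(
    list(frac_a = frac_a, delta_air = delta_air,
         ci_over_ca_ref = ci_over_ca_ref, delta_b = delta_b,
         frac_b = frac_b, c_a = c_a, r_vpdb = r_vpdb),
    class = "disc_params"
  )
}

#' @export
print.disc_params <- function(x, ...) {
  cat("Discrimination parameters:\n")
  cat(sprintf("  frac_a (diffusion fractionation): %.3g permil\n", x$frac_a))
  cat(sprintf("  delta_air: %.4g permil; ci/ca ref: %.3g\n",
              x$delta_air, x$ci_over_ca_ref))
  cat(sprintf("  delta_b (post-stomatal CO2): %.4g permil\n", x$delta_b))
  cat(sprintf("  frac_b (carboxylation): %.3g permil; c_a: %.4g umol/mol\n",
              x$frac_b, x$c_a))
  invisible(x)
}

#' delta13C from isotope ratios
#'
#' Converts a sample 13C/12C ratio to the delta notation relative to a
#' standard, scaled to permil:
#' `delta = (r_sample / r_standard - 1) * 1000`.
#'
#' @param r_sample Sample 13C/12C isotope ratio(s); positive.
#' @param r_standard Standard 13C/12C ratio; positive. Defaults to VPDB.
#' @return delta13C in permil, same length as `r_sample`.
#' @examples
#' delta_from_ratios(0.0108, 0.0111802)  # about -34.01
#' @export
delta_from_ratios <- function(r_sample, r_standard = 0.0111802) {
  if (!is.numeric(r_sample) || any(!is.finite(r_sample)) ||
      any(r_sample <= 0)) {
    stop("`r_sample` must be positive and finite.", call. = FALSE)
  }
  if (!is.numeric(r_standard) || any(!is.finite(r_standard)) ||
      any(r_standard <= 0)) {
    stop("`r_standard` must be positive and finite.", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Abundance-weighted mean delta13C of one leaf side
#'
#' The bulk isotopic composition of the wax on one leaf side is estimated
#' as the mean of per-compound delta13C values weighted by compound
#' abundance (peak area or coverage).
#'
#' @param abundance Non-negative compound abundances; total must be > 0.
#' @param delta Per-compound delta13C, permil; same length as `abundance`.
#' @return Weighted mean delta13C, permil. Always lies within
#'   `range(delta)`.
#' @examples
#' weighted_side_delta(c(2, 3, 5), c(-31, -33, -35))  # -33.6
#' @export
weighted_side_delta <- function(abundance, delta) {
  if (length(abundance) == 0L || length(delta) == 0L) {
    stop("At least one compound record is required.", call. = FALSE)
  }
  if (length(abundance) != length(delta)) {
    stop("`abundance` and `delta` must have equal length.", call. = FALSE)
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("Abundances must be finite and non-negative.", call. = FALSE)
  }
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stop("delta values must be finite and > -1000 permil.", call. = FALSE)
  }
  total <- sum(abundance)
  if (total <= 0) {
    stop("Total abundance must be positive.", call. = FALSE)
  }
  sum(abundance * delta) / total
}

#' Isotopic polarity of a leaf's epicuticular wax
#'
#' Computes the abundance-weighted mean delta13C for the adaxial and
#' abaxial wax of one leaf and their difference, the isotopic polarity
#' `delta_ab - delta_ad` (permil). Positive polarity means the adaxial wax
#' is depleted in 13C relative to the abaxial wax.
#'
#' @param ad,ab Data frames of compound records for the adaxial and
#'   abaxial side, with columns `compound`, `abundance`, `delta`.
#' @param shared_only If `TRUE`, restrict both sides to the compounds
#'   present on both before weighting (strict pairing); default uses all
#'   compounds reported per side.
#' @return A list with `delta_ad_weighted`, `delta_ab_weighted`,
#'   `polarity` (permil) and `n_compounds_used` (per-side counts actually
#'   aggregated).
#' @export
leaf_polarity <- function(ad, ab, shared_only = FALSE) {
  for (nm in c("compound", "abundance", "delta")) {
    if (!nm %in% names(ad) || !nm %in% names(ab)) {
      stop(sprintf("Both sides need a `%s` column.", nm), call. = FALSE)
    }
  }
  if (nrow(ad) == 0L || nrow(ab) == 0L) {
    stop("Both leaf sides must have at least one compound record.",
         call. = FALSE)
  }
  if (isTRUE(shared_only)) {
    shared <- intersect(ad$compound, ab$compound)
    if (length(shared) == 0L) {
      stop(sprintf(
        "No shared compounds between sides (adaxial: %s; abaxial: %s).",
        paste(ad$compound, collapse = ", "),
        paste(ab$compound, collapse = ", ")), call. = FALSE)
    }
    ad <- ad[ad$compound %in% shared, , drop = FALSE]
    ab <- ab[ab$compound %in% shared, , drop = FALSE]
  }
  d_ad <- weighted_side_delta(ad$abundance, ad$delta)
  d_ab <- weighted_side_delta(ab$abundance, ab$delta)
  list(delta_ad_weighted = d_ad,
       delta_ab_weighted = d_ab,
       polarity = d_ab - d_ad,
       n_compounds_used = c(adaxial = nrow(ad), abaxial = nrow(ab)))
}

#' delta13C of CO2 after diffusion through the stomatal pore
#'
#' The boundary composition `delta_b = delta_a - frac_a * (1 - ci/ca)`:
#' ambient CO2 partially fractionated by diffusion through the stoma, the
#' partial effect being proportional to the relative CO2 drawdown into the
#' substomatal cavity.
#'
#' @param delta_air delta13C of ambient CO2, permil.
#' @param frac_a Diffusion fractionation in still air, permil.
#' @param ci_over_ca Substomatal-to-ambient CO2 ratio, in \[0, 1\].
#' @return delta_b in permil. With the C3 defaults (-8.5, 4.4, 0.75) this
#'   is -9.6 permil.
#' @examples
#' boundary_delta(-8.5, 4.4, 0.75)  # -9.6
#' @export
boundary_delta <- function(delta_air = -8.5, frac_a = 4.4,
                           ci_over_ca = 0.75) {
  if (any(!is.finite(ci_over_ca)) || any(ci_over_ca < 0) ||
      any(ci_over_ca > 1)) {
    stop("`ci_over_ca` must lie in [0, 1].", call. = FALSE)
  }
  delta_air - frac_a * (1 - ci_over_ca)
}

# Guard band for |N / polarity|; inside it the implied CO2 ratio is
# non-positive or explosive and the input is rejected.
.polarity_guard_eps <- 1e-6

#' Dorsiventral CO2 drawdown from wax isotopic polarity
#'
#' Inverts the leaf-side isotopic polarity of epicuticular wax into the
#' relative CO2 difference between subepidermal tissue of the adaxial and
#' abaxial leaf sides:
#' \deqn{D = \frac{c_{ad} - c_{ab}}{c_{ab}}
#'   = -\left(1 + \frac{\delta_l - \delta_b + a}
#'                     {\delta_{ab} - \delta_{ad}}\right)^{-1}}
#' where `delta_l` is the bulk leaf dry-mass delta13C, `delta_b` the
#' boundary composition and `a` the diffusion fractionation. Zero polarity
#' maps to zero drawdown (continuous extension of the singular point).
#'
#' For the typical leaf regime `N = delta_l - delta_b + frac_a < 0`, the
#' drawdown has the sign of the polarity: adaxially depleted wax
#' (positive polarity) implies higher adaxial CO2.
#'
#' @param delta_leaf Bulk leaf dry-mass delta13C, permil.
#' @param polarity Wax isotopic polarity `delta_ab - delta_ad`, permil.
#' @param params A [disc_params()] object.
#' @return The drawdown D (dimensionless), vectorized over inputs.
#'   Inputs with `|N/polarity| <= 1 + 1e-6` are rejected with an error of
#'   class `"amphistomy_nonphysical"` carrying `N`, `polarity` and `t`.
#' @examples
#' co2_drawdown(-30, 1)    # 1/15
#' co2_drawdown(-30, -1)   # -1/17
#' @export
co2_drawdown <- function(delta_leaf, polarity, params = disc_params()) {
  stopifnot(inherits(params, "disc_params"))
  n <- max(length(delta_leaf), length(polarity))
  delta_leaf <- rep_len(delta_leaf, n)
  polarity <- rep_len(polarity, n)
  N <- delta_leaf - params$delta_b + params$frac_a
  out <- numeric(n)
  nz <- polarity != 0
  t_ratio <- N[nz] / polarity[nz]
  bad <- abs(t_ratio) <= 1 + .polarity_guard_eps
  if (any(bad)) {
    i <- which(nz)[which(bad)[1L]]
    stop(errorCondition(
      sprintf(paste0(
        "Non-physical polarity: |N/polarity| <= 1 at delta_leaf = %.4g, ",
        "polarity = %.4g (N = %.4g, t = %.4g); the implied CO2 ratio is ",
        "non-positive or unbounded."),
        delta_leaf[i], polarity[i], N[i], N[i] / polarity[i]),
      class = c("amphistomy_nonphysical", "error", "condition"),
      N = N[i], polarity = polarity[i], t = N[i] / polarity[i]))
  }
  out[nz] <- -1 / (1 + t_ratio)
  out
}

#' Wax isotopic polarity implied by a CO2 drawdown (forward model)
#'
#' Algebraic inverse of [co2_drawdown()], used by the synthetic-data
#' generator to map a known drawdown back to the polarity it would imprint
#' in the wax: `polarity = -D * N / (1 + D)` with
#' `N = delta_leaf - delta_b + frac_a`.
#'
#' @inheritParams co2_drawdown
#' @param drawdown Relative CO2 difference D, dimensionless; must be
#'   > -1 (the CO2 ratio `1 + D` must stay positive).
#' @return Polarity `delta_ab - delta_ad` in permil; round-trips with
#'   [co2_drawdown()] to within 1e-10 relative error.
#' @export
polarity_from_drawdown <- function(drawdown, delta_leaf,
                                   params = disc_params()) {
  stopifnot(inherits(params, "disc_params"))
  if (any(!is.finite(drawdown)) || any(drawdown <= -1)) {
    stop("`drawdown` must be finite and > -1.", call. = FALSE)
  }
  N <- delta_leaf - params$delta_b + params$frac_a
  -drawdown * N / (1 + drawdown)
}

#' Sensitivity of the inferred CO2 ratio to the boundary composition
#'
#' The boundary composition delta_b is a model simplification; this scans
#' a grid of bulk-leaf delta13C and polarity values, perturbs delta_b by
#' +/- `perturbation` permil, and reports the maximum relative change of
#' the inferred CO2 ratio `c_ad : c_ab = 1 + D`.
#'
#' @param delta_leaf_grid Bulk leaf delta13C values, permil.
#' @param polarity_grid Polarity values, permil (the full cross-product of
#'   the two grids is evaluated).
#' @param params A [disc_params()] object.
#' @param perturbation Size of the delta_b perturbation, permil; both
#'   signs are scanned.
#' @return Maximum over the grid of
#'   `|ratio(delta_b +/- perturbation) - ratio(delta_b)| / ratio(delta_b)`
#'   (a fraction).
#' @examples
#' # for a typical C3 leaf the ratio is insensitive to +/-1 permil in
#' # delta_b: the relative error stays below 1 %
#' boundary_sensitivity(seq(-41, -28, 0.5),
#'                      c(-seq(0.1, 1.5, 0.1), seq(0.1, 1.5, 0.1)))
#' @export
boundary_sensitivity <- function(delta_leaf_grid, polarity_grid,
                                 params = disc_params(),
                                 perturbation = 1) {
  stopifnot(inherits(params, "disc_params"))
  if (length(delta_leaf_grid) == 0L || length(polarity_grid) == 0L) {
    stop("Grids must be non-empty.", call. = FALSE)
  }
  grid <- expand.grid(delta_leaf = delta_leaf_grid,
                      polarity = polarity_grid)
  ratio_with <- function(db) {
    p <- disc_params(frac_a = params$frac_a, delta_air = params$delta_air,
                     ci_over_ca_ref = params$ci_over_ca_ref,
                     delta_b = db, frac_b = params$frac_b,
                     c_a = params$c_a, r_vpdb = params$r_vpdb)
    1 + co2_drawdown(grid$delta_leaf, grid$polarity, p)
  }
  r0 <- ratio_with(params$delta_b)
  r_up <- ratio_with(params$delta_b + perturbation)
  r_dn <- ratio_with(params$delta_b - perturbation)
  max(abs(r_up - r0) / r0, abs(r_dn - r0) / r0)
}

#' Leaf intercellular CO2 from bulk delta13C
#'
#' Back-calculates the leaf internal CO2 concentration from bulk dry-mass
#' delta13C under the simple two-endmember discrimination model with
#' infinite mesophyll conductance:
#' `c_i = c_a * (Delta - frac_a) / (frac_b - frac_a)` with the exact bulk
#' discrimination `Delta = (delta_air - delta_leaf) / (1 + delta_leaf/1000)`.
#'
#' Values of `Delta` outside `[frac_a, frac_b]` (which would imply c_i
#' outside `[0, c_a]`) are clamped to the boundary with a warning.
#'
#' @inheritParams co2_drawdown
#' @return c_i in umol mol^-1, vectorized over `delta_leaf`.
#' @examples
#' ci_from_bulk_delta(-28.26)  # about 258 umol/mol at c_a = 415
#' @export
ci_from_bulk_delta <- function(delta_leaf, params = disc_params()) {
  stopifnot(inherits(params, "disc_params"))
  Delta <- (params$delta_air - delta_leaf) / (1 + delta_leaf / 1000)
  lo <- Delta < params$frac_a
  hi <- Delta > params$frac_b
  if (any(lo | hi)) {
    warning(sprintf(
      "Bulk discrimination outside [%.3g, %.3g] permil for %d value(s); c_i clamped to [0, c_a].",
      params$frac_a, params$frac_b, sum(lo | hi)), call. = FALSE)
    Delta[lo] <- params$frac_a
    Delta[hi] <- params$frac_b
  }
  params$c_a * (Delta - params$frac_a) / (params$frac_b - params$frac_a)
}

#' Per-leaf polarity and drawdown from a compounds table
#'
#' Aggregates a long compounds table (one row per leaf, side and compound)
#' into one row per leaf: abundance-weighted side means, the isotopic
#' polarity, and — when bulk leaf delta13C is supplied via `leaves` — the
#' CO2 drawdown and the adaxial:abaxial CO2 ratio.
#'
#' @param compounds Data frame with columns `leaf_id`, `side`
#'   (`"adaxial"`/`"abaxial"`), `compound`, `abundance`, `delta_permil`.
#' @param leaves Optional data frame with columns `leaf_id` and
#'   `delta_leaf` (bulk dry-mass delta13C, permil); needed for the
#'   drawdown columns.
#' @param params A [disc_params()] object.
#' @param shared_only Restrict each leaf to compounds present on both
#'   sides (see [leaf_polarity()]).
#' @return Data frame ordered by `leaf_id` with columns `leaf_id`,
#'   `delta_ad_weighted`, `delta_ab_weighted`, `polarity`,
#'   `n_compounds_used`, and (with `leaves`) `drawdown` and `ratio`.
#' @export
polarity_table <- function(compounds, leaves = NULL,
                           params = disc_params(), shared_only = FALSE) {
  need <- c("leaf_id", "side", "compound", "abundance", "delta_permil")
  miss <- setdiff(need, names(compounds))
  if (length(miss)) {
    stop(sprintf("`compounds` lacks column(s): %s.",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ids <- sort(unique(as.character(compounds$leaf_id)))
  rows <- lapply(ids, function(id) {
    sub <- compounds[compounds$leaf_id == id, , drop = FALSE]
    ad <- sub[sub$side == "adaxial", , drop = FALSE]
    ab <- sub[sub$side == "abaxial", , drop = FALSE]
    names(ad)[names(ad) == "delta_permil"] <- "delta"
    names(ab)[names(ab) == "delta_permil"] <- "delta"
    pol <- leaf_polarity(ad, ab, shared_only = shared_only)
    data.frame(leaf_id = id,
               delta_ad_weighted = pol$delta_ad_weighted,
               delta_ab_weighted = pol$delta_ab_weighted,
               polarity = pol$polarity,
               n_compounds_used = sum(pol$n_compounds_used),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(leaves)) {
    if (!all(c("leaf_id", "delta_leaf") %in% names(leaves))) {
      stop("`leaves` needs columns `leaf_id` and `delta_leaf`.",
           call. = FALSE)
    }
    idx <- match(out$leaf_id, as.character(leaves$leaf_id))
    if (anyNA(idx)) {
      stop(sprintf("Leaves table lacks leaf_id(s): %s.",
                   paste(out$leaf_id[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    dl <- leaves$delta_leaf[idx]
    out$drawdown <- co2_drawdown(dl, out$polarity, params)
    out$ratio <- 1 + out$drawdown
  }
  rownames(out) <- NULL
  out
}

#' Count leaf-side 13C enrichment directions in a paired compound table
#'
#' For a table of per-compound delta13C measured on both leaf sides (one
#' row per species/sample/compound instance), counts how many instances
#' have the adaxial wax enriched in 13C relative to the abaxial wax
#' (`delta_ad > delta_ab`, i.e. negative polarity). In hypostomatous
#' leaves the adaxial side is expected to be enriched.
#'
#' @param paired Data frame with numeric columns `delta_ad_permil` and
#'   `delta_ab_permil` (one row per compound instance).
#' @return A list with `n_adaxial_enriched`, `n_total`, and the logical
#'   vector `adaxial_enriched`.
#' @export
enrichment_sign_count <- function(paired) {
  need <- c("delta_ad_permil", "delta_ab_permil")
  if (!all(need %in% names(paired))) {
    stop("`paired` needs columns `delta_ad_permil` and `delta_ab_permil`.",
         call. = FALSE)
  }
  enr <- paired$delta_ad_permil > paired$delta_ab_permil
  list(n_adaxial_enriched = sum(enr), n_total = length(enr),
       adaxial_enriched = enr)
}
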