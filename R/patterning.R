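#' Amphistomy level
#'
#' Fraction of stomata on the adaxial (upper) leaf side,
#' `ASL = SD_ad / (SD_ad + SD_ab)`. Ranges from 0 in hypostomatous leaves
#' (no adaxial stomata) to 1 in epistomatous leaves, and equals 0.5 when
#' both sides bear the same stomatal density.
#'
#' @param sd_ad,sd_ab Adaxial and abaxial stomatal densities, mm^-2;
#'   non-negative, not both zero.
#' @return ASL in \[0, 1\], vectorized.
#' @examples
#' asl(0, 200)    # 0, hypostomatous
#' asl(150, 150)  # 0.5
#' @export
asl <- function(sd_ad, sd_ab) {
  n <- max(length(sd_ad), length(sd_ab))
  sd_ad <- rep_len(sd_ad, n)
  sd_ab <- rep_len(sd_ab, n)
  if (any(!is.finite(sd_ad)) || any(!is.finite(sd_ab)) ||
      any(sd_ad < 0) || any(sd_ab < 0)) {
    stop("Stomatal densities must be finite and non-negative.",
         call. = FALSE)
  }
  if (any(sd_ad + sd_ab == 0)) {
    stop("ASL is undefined when both stomatal densities are zero.",
         call. = FALSE)
  }
  sd_ad / (sd_ad + sd_ab)
}

#' Amphiwaxy level
#'
#' Fraction of epicuticular wax deposited on the adaxial leaf side,
#' `AWL = W_ad / (W_ad + W_ab)`, by analogy with the amphistomy level.
#'
#' @param w_ad,w_ab Adaxial and abaxial wax coverage, ug cm^-2; strictly
#'   positive.
#' @return AWL in (0, 1), vectorized.
#' @export
awl <- function(w_ad, w_ab) {
  n <- max(length(w_ad), length(w_ab))
  w_ad <- rep_len(w_ad, n)
  w_ab <- rep_len(w_ab, n)
  if (any(!is.finite(w_ad)) || any(!is.finite(w_ab)) ||
      any(w_ad <= 0) || any(w_ab <= 0)) {
    stop("Wax coverages must be finite and positive.", call. = FALSE)
  }
  w_ad / (w_ad + w_ab)
}

#' Side-coupling regression of adaxial on abaxial measures
#'
#' Ordinary least-squares fit of the adaxial measure on the abaxial one —
#' `y = k * x + a` — either on the raw scale (stomatal density) or after
#' log10 transforming both axes (wax coverage, whose side coupling is
#' log-linear). The slope `k` determines the asymptotic patterning level
#' ([asl_pot()], [awl_pot()]).
#'
#' @param x Abaxial measure per leaf (SD_ab in mm^-2 or W_ab in
#'   ug cm^-2).
#' @param y Adaxial measure per leaf.
#' @param transform `"identity"` (stomatal density) or `"log10"` (wax;
#'   requires all values positive).
#' @param group Optional label describing the stratum the fit belongs to.
#' @param leaf_id Optional leaf identifiers, used in error messages.
#' @return Object of class `"coupling_fit"`: list with `slope_k`,
#'   `intercept_a`, `r_squared`, `transform`, `n`, `group`.
#' @examples
#' fit_coupling(c(1, 2, 3), c(1, 3, 4))  # k = 1.5, a = -1/3
#' @export
fit_coupling <- function(x, y, transform = c("identity", "log10"),
                         group = NA_character_, leaf_id = NULL) {
  transform <- match.arg(transform)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length.", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("At least 3 leaves are required for a coupling fit.",
         call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("Coupling inputs must be finite.", call. = FALSE)
  }
  if (transform == "log10") {
    bad <- x <= 0 | y <= 0
    if (any(bad)) {
      who <- if (!is.null(leaf_id)) paste(leaf_id[bad], collapse = ", ")
             else paste(which(bad), collapse = ", ")
      stop(sprintf(
        "log10 coupling requires positive values; offending leaves: %s.",
        who), call. = FALSE)
    }
    x <- log10(x)
    y <- log10(y)
  }
  if (stats::var(x) == 0) {
    stop("Degenerate abscissa: x has zero variance.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope_k = unname(stats::coef(fit)[2L]),
         intercept_a = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         transform = transform,
         n = length(x),
         group = group),
    class = "coupling_fit"
  )
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat(sprintf(
    "Side coupling (%s%s): k = %.4g, a = %.4g, r2 = %.4g, n = %d\n",
    x$transform,
    if (is.na(x$group)) "" else paste0(", ", x$group),
    x$slope_k, x$intercept_a, x$r_squared, x$n))
  invisible(x)
}

#' ASL along the stomatal side-coupling line
#'
#' For leaves obeying `SD_ad = k * SD_ab + a`, the amphistomy level can be
#' written as a function of the adaxial density alone:
#' `ASL = k / (k + 1 - a / SD_ad)`. As SD_ad grows it tends to the
#' asymptote `k / (k + 1)` (the potential ASL).
#'
#' @param fit A `"coupling_fit"` with `transform = "identity"`.
#' @param sd_ad Adaxial stomatal density, mm^-2; positive.
#' @return ASL fraction, vectorized over `sd_ad`. Errors if the
#'   denominator `k + 1 - a/SD_ad` is not positive (outside the curve's
#'   domain).
#' @export
asl_curve <- function(fit, sd_ad) {
  stopifnot(inherits(fit, "coupling_fit"))
  if (fit$transform != "identity") {
    stop("`asl_curve()` needs an identity-scale coupling fit.",
         call. = FALSE)
  }
  if (any(!is.finite(sd_ad)) || any(sd_ad <= 0)) {
    stop("`sd_ad` must be positive.", call. = FALSE)
  }
  denom <- fit$slope_k + 1 - fit$intercept_a / sd_ad
  if (any(denom <= 0)) {
    stop("ASL curve undefined: k + 1 - a/SD_ad must be positive.",
         call. = FALSE)
  }
  fit$slope_k / denom
}

#' Potential (asymptotic) amphistomy level
#'
#' The limit of the ASL curve at high adaxial stomatal density,
#' `ASL_pot = k / (k + 1)`, where `k` is the slope of the side-coupling
#' regression `SD_ad = k * SD_ab + a`.
#'
#' @param slope_k Coupling slope (dimensionless, >= 0), or a
#'   `"coupling_fit"` object.
#' @return ASL_pot in \[0, 1).
#' @examples
#' asl_pot(0.37)  # 0.27, a high-light magnitude
#' @export
asl_pot <- function(slope_k) {
  if (inherits(slope_k, "coupling_fit")) slope_k <- slope_k$slope_k
  if (any(!is.finite(slope_k)) || any(slope_k < 0)) {
    stop("Anti-coupled sides (negative slope) are outside the model.",
         call. = FALSE)
  }
  slope_k / (slope_k + 1)
}

#' AWL along the log-linear wax side-coupling line
#'
#' The wax coverages of the two leaf sides couple log-linearly:
#' `log10 W_ad = k * log10 W_ab + a`. Inverting for the abaxial coverage
#' implied by a given adaxial coverage,
#' `W_ab = 10^((log10 W_ad - a) / k)`, gives the amphiwaxy level as a
#' function of W_ad alone: `AWL = W_ad / (W_ad + W_ab)`.
#'
#' @param fit A `"coupling_fit"` with `transform = "log10"` and nonzero
#'   slope.
#' @param w_ad Adaxial wax coverage, ug cm^-2; positive.
#' @return AWL fraction, vectorized over `w_ad`. Constant in `w_ad` when
#'   `k = 1`; strictly increasing for `k > 1`, decreasing for `k < 1`.
#' @export
awl_curve <- function(fit, w_ad) {
  stopifnot(inherits(fit, "coupling_fit"))
  if (fit$transform != "log10") {
    stop("`awl_curve()` needs a log10-scale coupling fit.", call. = FALSE)
  }
  if (fit$slope_k == 0) {
    stop("AWL curve undefined for zero coupling slope.", call. = FALSE)
  }
  if (any(!is.finite(w_ad)) || any(w_ad <= 0)) {
    stop("`w_ad` must be positive.", call. = FALSE)
  }
  w_ab <- 10^((log10(w_ad) - fit$intercept_a) / fit$slope_k)
  w_ad / (w_ad + w_ab)
}

#' Potential (near-asymptotic) amphiwaxy level
#'
#' AWL evaluated at a high reference adaxial coverage (default
#' `w_ref = 10` ug cm^-2). Unlike the stomatal case, the mathematical
#' limit of the log-linear AWL curve as W_ad grows is degenerate — 0 for
#' `k < 1`, 1 for `k > 1`, and `1 / (1 + 10^-a)` only when `k = 1` — so
#' the operational near-asymptotic value at `w_ref` is reported, together
#' with the limit class.
#'
#' @inheritParams awl_curve
#' @param w_ref Reference adaxial coverage, ug cm^-2.
#' @return List with `awl_pot` (AWL at `w_ref`), `w_ref`, and `limit`
#'   (the true limit as W_ad grows without bound).
#' @export
awl_pot <- function(fit, w_ref = 10) {
  value <- awl_curve(fit, w_ref)
  k <- fit$slope_k
  limit <- if (abs(k - 1) < 1e-9) 1 / (1 + 10^(-fit$intercept_a))
           else if (k < 1) 0
           else 1
  list(awl_pot = value, w_ref = w_ref, limit = limit)
}

#' Per-group regression of ASL on wax isotopic polarity
#'
#' Fits, within each group, an ordinary least-squares line of the
#' amphistomy level on the wax isotopic polarity `delta_ab - delta_ad`.
#' The fitted intercept is the zero-polarity ASL — the amphistomy level
#' at which the two leaf sides experience the same CO2 concentration —
#' reported with its t-based 95 % confidence interval. Mean-response
#' confidence bands are available from the returned model objects via
#' `predict(fit, interval = "confidence")`.
#'
#' @param data Data frame with columns `asl`, `polarity`, plus the
#'   grouping columns.
#' @param group Character vector of grouping column names; `NULL` fits a
#'   single pooled regression.
#' @param level Confidence level for the intercept interval.
#' @param min_n Groups with fewer leaves than this are skipped with a
#'   warning.
#' @return Data frame with one row per fitted group: group keys, `slope`,
#'   `intercept` (the zero-polarity ASL), `ci_low`, `ci_high`,
#'   `r_squared`, `n`. The fitted `lm` objects are attached as attribute
#'   `"fits"` (named by group).
#' @export
regress_asl_on_polarity <- function(data, group = NULL, level = 0.95,
                                    min_n = 3L) {
  if (!all(c("asl", "polarity") %in% names(data))) {
    stop("`data` needs columns `asl` and `polarity`.", call. = FALSE)
  }
  if (is.null(group)) {
    data$.group <- "all"
    group <- ".group"
  }
  key <- interaction(data[group], drop = TRUE, sep = ":")
  fits <- list()
  rows <- list()
  for (g in levels(key)) {
    sub <- data[key == g, , drop = FALSE]
    sub <- sub[is.finite(sub$asl) & is.finite(sub$polarity), , drop = FALSE]
    if (nrow(sub) < min_n) {
      warning(sprintf("Group %s skipped: only %d usable leaves.",
                      g, nrow(sub)), call. = FALSE)
      next
    }
    fit <- stats::lm(asl ~ polarity, data = sub)
    # exact (noiseless) inputs are legitimate here; silence the
    # perfect-fit note from summary.lm
    ci <- suppressWarnings(
      stats::confint(fit, "(Intercept)", level = level))
    ss_tot <- sum((sub$asl - mean(sub$asl))^2)
    r2 <- if (ss_tot == 0) 0 else
      1 - sum(stats::residuals(fit)^2) / ss_tot
    fits[[g]] <- fit
    keyvals <- sub[1L, group, drop = FALSE]
    rownames(keyvals) <- NULL
    rows[[g]] <- cbind(
      keyvals,
      data.frame(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 ci_low = ci[1L], ci_high = ci[2L],
                 r_squared = r2, n = nrow(sub)))
  }
  if (!length(rows)) {
    stop("No group had enough leaves to fit.", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$.group <- NULL
  attr(out, "fits") <- fits
  out
}

#' Per-leaf patterning summary
#'
#' Adds amphistomy and amphiwaxy levels to a leaves table.
#'
#' @param leaves Data frame with columns `leaf_id`, `sd_ad`, `sd_ab`, and
#'   optionally `w_ad`, `w_ab`.
#' @return The input with `asl` (and `awl` when wax columns are present)
#'   appended.
#' @export
patterning_summary <- function(leaves) {
  if (!all(c("sd_ad", "sd_ab") %in% names(leaves))) {
    stop("`leaves` needs columns `sd_ad` and `sd_ab`.", call. = FALSE)
  }
  leaves$asl <- asl(leaves$sd_ad, leaves$sd_ab)
  if (all(c("w_ad", "w_ab") %in% names(leaves))) {
    leaves$awl <- awl(leaves$w_ad, leaves$w_ab)
  }
  leaves
}
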