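# Table contracts ----------------------------------------------------------

.leaves_cols <- c("leaf_id", "species", "light", "age", "plant_id",
                  "sd_ad_mm2", "sd_ab_mm2", "w_ad_ug_cm2", "w_ab_ug_cm2",
                  "delta_leaf_permil")
.compounds_cols <- c("leaf_id", "side", "compound", "abundance",
                     "delta_permil")

.collect_violations <- function(problems) {
  if (length(problems)) {
    stop(paste0("Table validation failed:\n  ",
                paste(problems, collapse = "\n  ")), call. = FALSE)
  }
}

#' Validate and canonicalize a leaves table
#'
#' Enforces the leaves-table contract (columns `leaf_id`, `species`,
#' `light`, `age`, `plant_id`, `sd_ad_mm2`, `sd_ab_mm2`, `w_ad_ug_cm2`,
#' `w_ab_ug_cm2`, `delta_leaf_permil`) and returns the table with
#' canonical short column names (`sd_ad`, `sd_ab`, `w_ad`, `w_ab`,
#' `delta_leaf`). Unknown columns are dropped with a warning; enum
#' violations and duplicate leaf ids are collected and reported together
#' with their row numbers.
#'
#' @param df Data frame in contract layout.
#' @return Validated data frame with canonical names, ordered by
#'   `leaf_id`.
#' @export
as_leaf_records <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("Leaves table is empty.", call. = FALSE)
  }
  extra <- setdiff(names(df), .leaves_cols)
  if (length(extra)) {
    warning(sprintf("Ignoring unknown leaves column(s): %s.",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  miss <- setdiff(.leaves_cols, names(df))
  if (length(miss)) {
    stop(sprintf("Leaves table lacks column(s): %s.",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[.leaves_cols]
  problems <- character(0)
  bad <- which(!df$light %in% c("HL", "LL"))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "row %d: light = \"%s\" (must be HL or LL)", bad, df$light[bad]))
  }
  bad <- which(!df$age %in% c("young", "mature", "old"))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "row %d: age = \"%s\" (must be young, mature or old)",
      bad, df$age[bad]))
  }
  for (col in c("sd_ad_mm2", "sd_ab_mm2")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad)) {
      problems <- c(problems, sprintf("row %d: %s < 0", bad, col))
    }
  }
  dup <- which(duplicated(df$leaf_id))
  if (length(dup)) {
    problems <- c(problems, sprintf(
      "row %d: duplicate leaf_id \"%s\"", dup, df$leaf_id[dup]))
  }
  .collect_violations(problems)
  names(df) <- c("leaf_id", "species", "light", "age", "plant_id",
                 "sd_ad", "sd_ab", "w_ad", "w_ab", "delta_leaf")
  df <- df[order(df$leaf_id), ]
  rownames(df) <- NULL
  df
}

#' Validate a compounds table
#'
#' Enforces the compounds-table contract (columns `leaf_id`, `side`,
#' `compound`, `abundance`, `delta_permil`): `side` must be `adaxial` or
#' `abaxial`, abundances non-negative, and the key
#' `(leaf_id, side, compound)` unique. Violations are collected and
#' reported together with row numbers.
#'
#' @param df Data frame in contract layout.
#' @return The validated data frame (unknown columns dropped with a
#'   warning).
#' @export
as_compound_records <- function(df) {
  if (!is.data.frame(df) || nrow(df) == 0L) {
    stop("Compounds table is empty.", call. = FALSE)
  }
  extra <- setdiff(names(df), .compounds_cols)
  if (length(extra)) {
    warning(sprintf("Ignoring unknown compounds column(s): %s.",
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  miss <- setdiff(.compounds_cols, names(df))
  if (length(miss)) {
    stop(sprintf("Compounds table lacks column(s): %s.",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- df[.compounds_cols]
  problems <- character(0)
  bad <- which(!df$side %in% c("adaxial", "abaxial"))
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "row %d: side = \"%s\" (must be adaxial or abaxial)",
      bad, df$side[bad]))
  }
  bad <- which(!is.na(df$abundance) & df$abundance < 0)
  if (length(bad)) {
    problems <- c(problems, sprintf("row %d: abundance < 0", bad))
  }
  bad <- which(!is.na(df$delta_permil) & df$delta_permil <= -1000)
  if (length(bad)) {
    problems <- c(problems, sprintf(
      "row %d: delta_permil <= -1000", bad))
  }
  key <- paste(df$leaf_id, df$side, df$compound, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    problems <- c(problems, sprintf(
      "row %d: duplicate key (%s, %s, %s)", dup, df$leaf_id[dup],
      df$side[dup], df$compound[dup]))
  }
  .collect_violations(problems)
  df
}

.read_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("File not found: %s", path), call. = FALSE)
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = TRUE,
                    na.strings = "")
}

#' Read and validate a leaves table from delimited text
#'
#' @param path Path to a CSV or TSV file (delimiter autodetected from the
#'   header line) in the leaves-table contract layout.
#' @return See [as_leaf_records()].
#' @export
read_leaves <- function(path) as_leaf_records(.read_table(path))

#' Read and validate a compounds table from delimited text
#'
#' @param path Path to a CSV or TSV file in the compounds-table contract
#'   layout.
#' @return See [as_compound_records()].
#' @export
read_compounds <- function(path) as_compound_records(.read_table(path))

# Fixed float formatting (6 significant digits) so re-running the
# pipeline on identical inputs yields byte-identical tables.
.format_table <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- sprintf("%.6g", df[[col]])
    }
  }
  df
}

.write_table <- function(df, path) {
  utils::write.csv(.format_table(df), path, row.names = FALSE,
                   quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a pair of validated tables (or on a freshly
#' simulated study): per-leaf polarity and CO2 drawdown, per-leaf
#' patterning (ASL/AWL), per-stratum side-coupling fits with their
#' asymptotes, ASL-on-polarity regressions with zero-polarity
#' intercepts, and the per-species path analysis. Writes one CSV per
#' stage plus a JSON report echoing every parameter used.
#'
#' @param leaves Leaves table (contract layout or the canonical output of
#'   [as_leaf_records()]); ignored when `simulate = TRUE`.
#' @param compounds Compounds table; ignored when `simulate = TRUE`.
#' @param out_dir Output directory, created if needed. `NULL` skips
#'   writing and just returns the stage results.
#' @param params A [disc_params()] object.
#' @param config A [synthetic_config()], used when `simulate = TRUE`.
#' @param simulate Generate the input tables with [generate_study()]
#'   instead of reading them.
#' @param shared_only Passed to [polarity_table()].
#' @param w_ref Reference adaxial coverage for [awl_pot()], ug cm^-2.
#' @param n_boot,seed Bootstrap settings for [fit_path_model()].
#' @return Invisibly, a list with elements `polarity`, `patterning`,
#'   `coupling`, `asl_regressions`, `path` (one entry per species) and
#'   `report` (the parameter echo; also written as `report.json`).
#' @export
run_pipeline <- function(leaves = NULL, compounds = NULL, out_dir = NULL,
                         params = disc_params(),
                         config = synthetic_config(),
                         simulate = FALSE, shared_only = FALSE,
                         w_ref = 10, n_boot = 1000L, seed = 1L) {
  truth <- NULL
  if (isTRUE(simulate)) {
    study <- generate_study(config)
    leaves <- study$leaves
    compounds <- study$compounds
    truth <- study$truth
  }
  if (is.null(leaves) || is.null(compounds)) {
    stop("Provide `leaves` and `compounds`, or set `simulate = TRUE`.",
         call. = FALSE)
  }
  if ("sd_ad_mm2" %in% names(leaves)) leaves <- as_leaf_records(leaves)
  compounds <- as_compound_records(compounds)

  pol <- polarity_table(compounds, leaves, params,
                        shared_only = shared_only)
  pat <- patterning_summary(leaves)
  merged <- merge(pat, pol[c("leaf_id", "polarity", "drawdown")],
                  by = "leaf_id")
  merged <- merged[order(merged$leaf_id), ]

  coupling_rows <- list()
  for (sp in unique(leaves$species)) {
    for (light in unique(leaves$light)) {
      sub <- leaves[leaves$species == sp & leaves$light == light, ]
      if (nrow(sub) < 3L) next
      fsd <- fit_coupling(sub$sd_ab, sub$sd_ad, "identity",
                          group = paste(sp, light))
      fw <- fit_coupling(sub$w_ab, sub$w_ad, "log10",
                         group = paste(sp, light),
                         leaf_id = sub$leaf_id)
      coupling_rows[[paste(sp, light)]] <- data.frame(
        species = sp, stratum = light,
        sd_slope_k = fsd$slope_k, sd_intercept_a = fsd$intercept_a,
        sd_r_squared = fsd$r_squared, asl_pot = asl_pot(fsd),
        wax_slope_k = fw$slope_k, wax_intercept_a = fw$intercept_a,
        wax_r_squared = fw$r_squared,
        awl_pot = awl_pot(fw, w_ref)$awl_pot,
        n = nrow(sub), stringsAsFactors = FALSE)
    }
  }
  coupling <- do.call(rbind, coupling_rows)
  rownames(coupling) <- NULL

  regr <- regress_asl_on_polarity(merged, group = "species")

  path <- list()
  for (sp in unique(merged$species)) {
    sub <- merged[merged$species == sp, ]
    path[[sp]] <- tryCatch(
      fit_path_model(sub, cluster = "plant_id", n_boot = n_boot,
                     seed = seed),
      error = function(e) {
        warning(sprintf("Path stage skipped for %s: %s", sp,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
  }

  report <- list(
    package_version = as.character(utils::packageVersion("amphistomy")),
    parameters = list(frac_a = params$frac_a,
                      delta_air = params$delta_air,
                      ci_over_ca_ref = params$ci_over_ca_ref,
                      delta_b = params$delta_b, frac_b = params$frac_b,
                      c_a = params$c_a, w_ref = w_ref,
                      shared_only = shared_only,
                      n_boot = n_boot, seed = seed,
                      simulate = simulate,
                      config_seed = if (simulate) config$seed else NULL),
    n_leaves = nrow(leaves),
    n_compound_rows = nrow(compounds),
    zero_polarity_asl = stats::setNames(
      as.list(regr$intercept), regr$species),
    direct_effects = lapply(path, function(p) {
      if (is.null(p)) NULL else p$direct_effect
    })
  )

  result <- list(polarity = pol, patterning = merged,
                 coupling = coupling, asl_regressions = regr,
                 path = path, report = report, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_table(pol, file.path(out_dir, "polarity.csv"))
    .write_table(merged, file.path(out_dir, "patterning.csv"))
    .write_table(coupling, file.path(out_dir, "coupling.csv"))
    regr_out <- regr
    attr(regr_out, "fits") <- NULL
    .write_table(regr_out, file.path(out_dir, "asl_regressions.csv"))
    path_tabs <- lapply(names(path), function(sp) {
      p <- path[[sp]]
      if (is.null(p)) return(NULL)
      cbind(species = sp, p$coefficients,
            n_clusters = p$n_clusters, n_boot = p$n_boot,
            seed = p$seed)
    })
    path_tab <- do.call(rbind, path_tabs)
    if (!is.null(path_tab)) {
      .write_table(path_tab, file.path(out_dir, "path.csv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    if (!is.null(truth)) {
      .write_table(truth$leaves, file.path(out_dir, "truth.csv"))
    }
  }
  invisible(result)
}
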