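#' Stratified descriptive statistics of positional errors
#'
#' Summary table of positional error magnitudes, and of the absolute
#' east-west (`|dx|`) and north-south (`|dy|`) displacement components by
#' street orientation, stratified by rurality.
#'
#' @param data Tibble with columns `rurality`, `orientation`, `dx_m`,
#'   `dy_m`, `magnitude_m`.
#'
#' @return Tibble with columns `group`, `measure`, `orientation`, `n`,
#'   `min`, `median`, `max`, `mean`, `sd`, `sd_defined`. For a
#'   single-record stratum the SD is reported as 0 with
#'   `sd_defined = FALSE`.
#' @export
descriptive_table <- function(data) {
  if (nrow(data) == 0) abort("data is empty")
  one <- function(x, group, measure, orientation) {
    tibble(group = group, measure = measure, orientation = orientation,
           n = length(x), min = min(x), median = median(x), max = max(x),
           mean = mean(x),
           sd = if (length(x) > 1) sd(x) else 0,
           sd_defined = length(x) > 1)
  }
  rows <- list(one(data$magnitude_m, "all", "magnitude", "all"))
  for (g in intersect(c("rural", "municipal"), unique(data$rurality))) {
    sub <- data[data$rurality == g, ]
    rows <- c(rows, list(one(sub$magnitude_m, g, "magnitude", "all")))
    for (o in intersect(c("NS", "EW"), unique(sub$orientation))) {
      so <- sub[sub$orientation == o, ]
      rows <- c(rows, list(one(abs(so$dx_m), g, "abs_dx", o),
                           one(abs(so$dy_m), g, "abs_dy", o)))
    }
  }
  bind_rows(rows)
}

#' Covariate-effect summary of a geocoding-error table
#'
#' Runs the standard covariate analyses on log error magnitude: the
#' rurality ANOVA, the per-group correlation and simple OLS fit on the
#' group's key covariate (street segment length for municipal, street
#' intersection density for rural), the percent-effect translation of the
#' slopes, the fitted values at reference covariate levels (100 m length;
#' density 5), and the full interaction model R-squared.
#'
#' @param data Tibble with `rurality`, `seg_length_m`,
#'   `density_per_sqmi`, `magnitude_m`.
#' @return Tidy tibble with columns `quantity`, `rurality`, `value`.
#' @export
covariate_effects <- function(data) {
  rows <- list()
  add <- function(quantity, rurality, value)
    rows[[length(rows) + 1]] <<- tibble(quantity = quantity,
                                        rurality = rurality, value = value)
  groups <- intersect(c("rural", "municipal"), unique(data$rurality))

  if (length(groups) == 2) {
    av <- anova_rurality(data)
    add("anova_fraction_explained", "all", av$fraction_explained)
    add("anova_p_value", "all", av$p_value)
    int <- fit_interaction_model(data)
    add("interaction_r_squared", "all", int$r_squared)
  }
  covar <- c(municipal = "seg_length_m", rural = "density_per_sqmi")
  ref <- c(municipal = 100, rural = 5)         # reference covariate values
  delta <- c(municipal = 100, rural = 5)       # percent-effect increments
  for (g in groups) {
    sub <- data[data$rurality == g, ]
    x <- sub[[covar[[g]]]]
    ct <- pearson_correlation(log(sub$magnitude_m), x)
    add(paste0("cor_", covar[[g]]), g, ct$r)
    add(paste0("cor_p_", covar[[g]]), g, ct$p_value)
    fit <- fit_simple_ols(log(sub$magnitude_m), x)
    add("slope", g, fit$beta_hat)
    add("percent_effect", g, percent_effect(fit$beta_hat, delta[[g]]))
    add("fitted_log_at_ref", g, predict(fit, ref[[g]]))
    add("fitted_m_at_ref", g, exp(predict(fit, ref[[g]])))
  }
  bind_rows(rows)
}

#' Configuration of a full analysis run
#'
#' @param generator A [generator_config()].
#' @param alpha Error level for all intervals and regions.
#' @param content Population content `1 - p` for tolerance statements.
#' @param probs Covariate percentiles for [tolerance_report()].
#' @param n_resamples Subsample count for [mve_tolerance_region()].
#' @param n_calib Calibration replicates for [john_radius2()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; per-stage seeds are derived as
#'   `seed + 1` (generator) and `seed + 2` (region resampling) so stages
#'   are independently reproducible.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(), alpha = 0.05,
                       content = 0.95, probs = c(0.10, 0.50, 0.90),
                       n_resamples = 3000, n_calib = 4000,
                       out_dir = tempfile("geotol_run_"), seed = 1L) {
  if (alpha <= 0 || alpha >= 1 || content <= 0 || content >= 1)
    abort("alpha and content must be in (0, 1)")
  structure(list(generator = generator, alpha = alpha, content = content,
                 probs = probs, n_resamples = n_resamples, n_calib = n_calib,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full positional-error analysis pipeline
#'
#' Generates a seeded synthetic dataset, then computes the descriptive
#' table, the covariate-effect summary, the confidence/tolerance table at
#' covariate percentiles, and the stratified bivariate tolerance regions,
#' writing each artifact to `config$out_dir`:
#' `data.csv`, `table1.csv`, `covariate_effects.csv`, `table2.csv`,
#' `regions.json` and `run_log.txt`. Any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the output paths and the in-memory
#'   tibbles (`data`, `table1`, `effects`, `table2`, `regions`).
#' @export
run_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("data.csv", "table1.csv", "covariate_effects.csv",
                       "table2.csv", "regions.json", "run_log.txt"))
  names(paths) <- c("data", "table1", "effects", "table2", "regions", "log")
  log_lines <- character()
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(paths)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  p <- 1 - config$content

  gen <- config$generator
  gen$seed <- config$seed + 1L
  note("stage generate: %d addresses, seed %d",
       gen$n_rural + gen$n_municipal, gen$seed)
  dat <- stage("generate", generate_dataset(gen))
  readr::write_csv(dat, paths["data"])

  note("stage describe")
  tab1 <- stage("describe", descriptive_table(dat))
  readr::write_csv(tab1, paths["table1"])

  groups <- intersect(c("rural", "municipal"), unique(dat$rurality))
  if (length(groups) < 2)
    note("only group '%s' present; cross-group sections omitted", groups)

  note("stage covariate effects")
  eff <- stage("covariate_effects", covariate_effects(dat))
  readr::write_csv(eff, paths["effects"])

  note("stage tolerance table (alpha %.2f, content %.2f)",
       config$alpha, config$content)
  tab2 <- stage("tolerance_table",
                tolerance_report(dat, alpha = config$alpha, p = p,
                                 probs = config$probs))
  readr::write_csv(tab2, paths["table2"])

  note("stage tolerance regions (%d resamples, seed %d)",
       config$n_resamples, config$seed + 2L)
  regions <- stage("regions", {
    suppressWarnings(
      stratified_regions(dat, alpha = config$alpha, p = p,
                         n_resamples = config$n_resamples,
                         n_calib = config$n_calib,
                         seed = config$seed + 2L))
  })
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions)))
      note("  stratum %s/%s: n = %d", regions$rurality[i],
           regions$orientation[i], regions$n[i])
  }
  ser <- purrr::pmap(regions, function(rurality, orientation, n, john, mve) {
    lapply(list(john = john, mve = mve), function(e)
      list(stratum = paste(rurality, orientation, sep = "_"),
           method = e$method, center = e$center,
           shape = as.numeric(t(e$shape)),   # row-major
           radius2 = e$radius2, alpha = e$alpha, p = e$p, n = e$n))
  })
  jsonlite::write_json(ser, paths["regions"], auto_unbox = TRUE, digits = NA)

  note("run complete")
  writeLines(log_lines, paths["log"])
  invisible(list(paths = as.list(paths), data = dat, table1 = tab1,
                 effects = eff, table2 = tab2, regions = regions))
}
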