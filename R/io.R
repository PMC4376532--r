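#' Write a batch of run summaries to disk
#'
#' Serialises the per-replicate summaries of [run_replicates()] as a
#' tidy long-format CSV (`results.csv`: one row per grid point,
#' replicate and metric) plus a JSON manifest (`manifest.json`) echoing
#' the configuration, every replicate seed, the package version and the
#' quantile convention. Reading the pair back with [read_results()]
#' recovers the summaries exactly for integers and to better than 1e-12
#' for reals.
#'
#' @param summaries A tibble of per-replicate records from
#'   [run_replicates()] (or one of the `run_*` experiment functions).
#' @param out_dir Output directory (created if needed).
#' @param config Optional `nutlat_config` echoed in the manifest.
#' @return Invisibly, the paths written (named character vector).
#' @export
write_results <- function(summaries, out_dir, config = NULL) {
  stopifnot(is.data.frame(summaries), nrow(summaries) > 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("Cannot create output directory: %s", out_dir),
         call. = FALSE)
  }
  id_cols <- intersect(
    c("experiment", "c", "prop_high", "k", "group", "replicate", "seed",
      "extinct", "extinct_generation"),
    names(summaries)
  )
  long <- summaries |>
    dplyr::mutate(dplyr::across(dplyr::any_of("extinct_generation"),
                                as.integer)) |>
    tidyr::pivot_longer(cols = -dplyr::all_of(id_cols),
                        names_to = "metric", values_to = "value")
  csv_path <- file.path(out_dir, "results.csv")
  readr::write_csv(long, csv_path)

  manifest <- list(
    package = "nutlat",
    version = as.character(utils::packageVersion("nutlat")),
    quantile_convention = "linear interpolation (R type 7)",
    n_records = nrow(summaries),
    seeds = if ("seed" %in% names(summaries)) unique(summaries$seed)
            else integer(0),
    extinctions = if ("extinct" %in% names(summaries))
      sum(summaries$extinct, na.rm = TRUE) else 0L,
    config = if (!is.null(config)) config_as_list(config) else NULL
  )
  json_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(results = csv_path, manifest = json_path))
}

config_as_list <- function(config) {
  list(
    experiment = config$experiment,
    foods = config$environment$foods$value_v,
    intake_target = config$environment$intake_target,
    c = config$c, eta = config$eta, n_ind = config$n_ind,
    phi = config$phi, mu = config$mu,
    n_iterations = config$n_iterations,
    n_generations = config$n_generations,
    selection = unclass(config$selection),
    composition = config$composition,
    n_replicates = config$n_replicates, seed = config$seed
  )
}

#' @rdname write_results
#' @param dir Directory previously written by [write_results()].
#' @return `read_results()`: a list with `summaries` (wide tibble,
#'   metrics as columns) and `manifest` (the parsed JSON manifest).
#' @export
read_results <- function(dir) {
  csv_path <- file.path(dir, "results.csv")
  json_path <- file.path(dir, "manifest.json")
  if (!file.exists(csv_path)) {
    stop(sprintf("No results.csv found in %s", dir), call. = FALSE)
  }
  long <- readr::read_csv(csv_path, show_col_types = FALSE)
  wide <- tidyr::pivot_wider(long, names_from = "metric",
                             values_from = "value")
  manifest <- if (file.exists(json_path)) {
    jsonlite::read_json(json_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  list(summaries = wide, manifest = manifest)
}
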