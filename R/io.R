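# Feature-table I/O, run configuration, and reporting.

#' Read a feature table into an experiment
#'
#' Expects a CSV with header `feature_id, mz, rt_min` followed by
#' intensity channels whose roles are inferred from the column-name
#' prefixes `sample_` and `control_`.
#'
#' @param path CSV file.
#' @param protein_um Input protein concentration the injection was
#'   normalized to (default 1 uM).
#' @param metadata Optional named list (marker protein, MCC/MCP label,
#'   ...).
#' @return `experiment` list: `features` (feature table), `sample_cols`,
#'   `control_cols`, `protein_um`, `metadata`.
#' @export
read_feature_table <- function(path, protein_um = 1, metadata = list()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("feature_id", "mz", "rt_min")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing)) {
    stop("feature table misses mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- tab$feature_id[duplicated(tab$feature_id)]
  if (length(dup)) {
    stop("duplicated feature_id: ", paste(unique(dup), collapse = ", "))
  }
  scol <- grep("^sample_", names(tab), value = TRUE)
  ccol <- grep("^control_", names(tab), value = TRUE)
  if (length(scol) == 0L || length(ccol) == 0L) {
    stop("need at least one sample_* and one control_* column")
  }
  num <- c("mz", "rt_min", scol, ccol)
  bad <- num[!vapply(tab[num], is.numeric, logical(1))]
  if (length(bad)) stop("non-numeric cells in column(s): ",
                        paste(bad, collapse = ", "))
  class(tab) <- c("feature_table", "data.frame")
  structure(list(features = tab, sample_cols = scol, control_cols = ccol,
                 protein_um = protein_um, metadata = metadata),
            class = "experiment")
}

.KNOWN_CONFIG_KEYS <- c(
  "seed", "out_dir", "n_species", "n_replicates", "control_channels",
  "noise_cv", "gradient_span_min", "enrichment_fold", "pseudo_count",
  "mz_tol_ppm", "rt_tol_min", "isotope_ratio_max", "defect_slope",
  "min_ladder_len", "rt_window", "area_per_lipid", "circle_radius",
  "slab_half_width", "n_wedges", "smalp_diameter_nm", "sma_rim_nm",
  "protein_area_nm2", "protein_um")

#' Default run configuration
#'
#' Flat key/value configuration tying the stage configs together.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(seed = 1, out_dir = ".", n_species = 50, n_replicates = 3,
       control_channels = 3, noise_cv = 0.10, gradient_span_min = 20,
       enrichment_fold = 10, pseudo_count = 1, mz_tol_ppm = 5,
       rt_tol_min = 0.1, isotope_ratio_max = 0.6, defect_slope = 0.00045,
       min_ladder_len = 3, rt_window = 0.1, area_per_lipid = 47.1,
       circle_radius = 35, slab_half_width = 2, n_wedges = 80,
       smalp_diameter_nm = 9, sma_rim_nm = 1, protein_area_nm2 = 20,
       protein_um = 1)
}

#' Write / read a flat `key: value` run configuration
#'
#' Unknown keys are rejected on read; serialize -> parse -> serialize is
#' idempotent.
#'
#' @param config Named list (subset of [default_run_config()] keys).
#' @param path Text file path.
#' @return `read_run_config` returns the full configuration with file
#'   values overriding defaults.
#' @export
write_run_config <- function(config, path) {
  unknown <- setdiff(names(config), .KNOWN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  keys <- names(config)[order(match(names(config), .KNOWN_CONFIG_KEYS))]
  writeLines(sprintf("%s: %s", keys,
                     vapply(config[keys], format, character(1))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- lines[vapply(kv, length, integer(1)) != 3L]
  if (length(bad)) stop("malformed config line: ", bad[1])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  unknown <- setdiff(keys, .KNOWN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- default_run_config()
  for (i in seq_along(keys)) {
    v <- suppressWarnings(as.numeric(vals[i]))
    cfg[[keys[i]]] <- if (is.na(v)) vals[i] else v
  }
  cfg
}

#' Write the standard report file set
#'
#' Deterministic file set regardless of which results are present:
#' `events.csv`, `annotations.csv`, `audit.json`, `quant.csv`,
#' `ratios.json`, `geometry.json`. Absent components produce
#' header-only / empty files so downstream tooling can rely on the
#' manifest.
#'
#' @param results Named list with any of `events`, `annotations`,
#'   `audit`, `quant`, `ratios`, `geometry`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of written file paths (the manifest).
#' @export
write_report <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  p <- function(f) file.path(outdir, f)
  ev <- results$events
  if (is.null(ev)) ev <- .empty_events()
  utils::write.csv(ev, p("events.csv"), row.names = FALSE)
  ann <- results$annotations
  if (is.null(ann)) {
    ann <- data.frame(event_id = character(0), mz = numeric(0),
                      class = character(0), carbons = integer(0),
                      double_bonds = integer(0), adduct = character(0),
                      ppm = numeric(0), status = character(0),
                      candidates = character(0))
  }
  utils::write.csv(ann, p("annotations.csv"), row.names = FALSE)
  audit <- results$audit
  if (is.null(audit)) audit <- c(input = 0L, enriched = 0L,
                                 after_censor = 0L, after_dedup = 0L)
  jsonlite::write_json(as.list(audit), p("audit.json"), auto_unbox = TRUE)
  quant <- results$quant
  if (is.null(quant)) quant <- data.frame(class = character(0),
                                          mol_percent = numeric(0))
  utils::write.csv(quant, p("quant.csv"), row.names = FALSE)
  ratios <- results$ratios
  jsonlite::write_json(if (is.null(ratios)) list() else unclass(ratios),
                       p("ratios.json"), auto_unbox = TRUE, digits = NA)
  geometry <- results$geometry
  jsonlite::write_json(if (is.null(geometry)) list() else geometry,
                       p("geometry.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  manifest <- c(p("events.csv"), p("annotations.csv"), p("audit.json"),
                p("quant.csv"), p("ratios.json"), p("geometry.json"))
  manifest
}
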