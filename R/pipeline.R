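#' Configuration for an end-to-end calibration study
#'
#' A run is fully reproducible from its config and seed: either a
#' simulation config or input CSV paths, the analytes to calibrate, the
#' recipe grid, the split/CV/outlier settings and the output directory.
#'
#' @param simulation `NULL`, or a list with `cfg` (a
#'   [synthetic_config()]) and `diet` (a [diet_spec()]); mutually
#'   exclusive with the CSV paths.
#' @param spectra_csv,reference_csv Input paths for user data (wide
#'   spectra CSV and reference CSV with a `sample_id` column).
#' @param analytes Character vector of reference columns to calibrate.
#' @param dmd_markers Named numeric vector of diet marker concentrations
#'   (% of DM, same basis/units as the matching reference columns) used
#'   to derive per-sample DMD; names must be reference columns. `NULL`
#'   skips the DMD stage.
#' @param scatters,treatments The recipe grid (see [grid_search()]).
#' @param variant PLS variant.
#' @param split_fraction,split_strategy,k,max_factors Protocol settings.
#' @param outlier_passes,t_crit,h_crit,cap Outlier settings.
#' @param seed Integer seed driving every random element.
#' @param out_dir Output directory for the report bundle.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, spectra_csv = NULL,
                       reference_csv = NULL, analytes,
                       dmd_markers = NULL,
                       scatters = c("SNV", "D", "SNV+D", "MSC"),
                       treatments = c("1.4.4.1", "2.4.4.1",
                                      "1.5.5.1", "2.5.5.1"),
                       variant = "modified",
                       split_fraction = 0.75, split_strategy = "rank",
                       k = 6, max_factors = 16,
                       outlier_passes = 2, t_crit = 2.5, h_crit = 10,
                       cap = 0.10, seed = 1, out_dir = tempfile("run")) {
  if (is.null(simulation) && (is.null(spectra_csv) || is.null(reference_csv)))
    stop("provide either a simulation block or both input CSV paths",
         call. = FALSE)
  structure(as.list(environment()), class = "run_config")
}

descriptive_row <- function(v, set, constituent) {
  data.frame(constituent = constituent, set = set, n = length(v),
             mean = mean(v), sd = stats::sd(v),
             cv = 100 * stats::sd(v) / mean(v),
             min = min(v), max = max(v))
}

fmt_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a full calibration study
#'
#' Executes the whole workflow: simulate (or load) spectra and
#' reference values, average any replicates, run the preprocessing grid
#' search with outlier elimination and 6-fold cross-validation per
#' analyte, validate externally, and — when diet marker concentrations
#' are supplied — derive per-sample DMD and cross-marker agreement.
#' Five artifacts are written under `cfg$out_dir`:
#' `descriptive_stats.csv` (per-analyte calibration/validation
#' summaries), `model_table.csv` (the ranked recipe table per analyte),
#' `predictions_<analyte>.csv` (reference vs predicted scatter data for
#' the winning model), `dmd_agreement.csv` (pairwise r-squared of
#' marker-based DMD), and `run_log.json`. Outputs are byte-identical
#' across repeated runs with the same config and seed.
#'
#' @param cfg A [run_config()].
#' @return A `report_bundle` list: `config`, `tables` (the in-memory
#'   data.frames), `best` (winning fit per analyte), `files`, `log`.
#' @export
run_calibration_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = cfg$seed, variant = cfg$variant, stages = character(),
              errors = list())
  files <- character()
  tables <- list()
  best <- list()

  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      log$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (is.null(log$errors[[name]]))
      log$stages <<- c(log$stages, name)
    res
  }

  dat <- stage("load", {
    if (!is.null(cfg$simulation)) {
      sim <- simulate_excreta_dataset(cfg$simulation$cfg,
                                      cfg$simulation$diet)
      list(spectra = sim$spectra, reference = sim$reference)
    } else {
      sp <- read_spectra_table(cfg$spectra_csv)
      rf <- utils::read.csv(cfg$reference_csv)
      if (anyDuplicated(sp$sample_ids)) sp <- average_duplicates(sp)
      list(spectra = sp, reference = align_reference(rf, sp))
    }
  })
  if (is.null(dat)) return(finish_bundle(cfg, tables, best, files, log))

  missing_an <- setdiff(cfg$analytes, names(dat$reference))
  if (length(missing_an)) {
    log$errors$analytes <- paste("not in reference table:",
                                 paste(missing_an, collapse = ", "))
    cfg$analytes <- setdiff(cfg$analytes, missing_an)
  }

  desc_rows <- list(); model_rows <- list()
  for (an in cfg$analytes) {
    y <- dat$reference[[an]]
    gs <- stage(paste0("gridsearch_", an), {
      grid_search(dat$spectra, y, scatters = cfg$scatters,
                  treatments = cfg$treatments, variant = cfg$variant,
                  split_fraction = cfg$split_fraction,
                  split_strategy = cfg$split_strategy, k = cfg$k,
                  max_factors = cfg$max_factors, seed = cfg$seed,
                  outlier_passes = cfg$outlier_passes,
                  t_crit = cfg$t_crit, h_crit = cfg$h_crit,
                  cap = cfg$cap)
    })
    if (is.null(gs)) next
    sp <- gs$split
    desc_rows[[paste0(an, "_cal")]] <-
      descriptive_row(y[sp$calibration], "calibration", an)
    desc_rows[[paste0(an, "_val")]] <-
      descriptive_row(y[sp$validation], "validation", an)
    tab <- gs$table
    tab$constituent <- an
    model_rows[[an]] <- tab
    win <- gs$models[[1]]
    best[[an]] <- win
    if (!is.null(win)) {
      prep <- apply_recipe(dat$spectra, win$recipe)
      pred <- predict(win$model, prep$absorbance)
      set <- rep("calibration", length(y))
      set[sp$validation] <- "validation"
      out_idx <- sp$calibration[setdiff(seq_along(sp$calibration),
                                        win$kept)]
      set[out_idx] <- "calibration-outlier"
      pdf_ <- data.frame(sample_id = dat$spectra$sample_ids, set = set,
                         reference = y, predicted = pred)
      f <- file.path(cfg$out_dir, paste0("predictions_", an, ".csv"))
      fmt_csv(pdf_, f)
      files <- c(files, f)
      tables[[paste0("predictions_", an)]] <- pdf_
    }
  }
  if (length(desc_rows)) {
    tables$descriptive_stats <- do.call(rbind, c(desc_rows,
                                                 make.row.names = FALSE))
    f <- file.path(cfg$out_dir, "descriptive_stats.csv")
    fmt_csv(tables$descriptive_stats, f); files <- c(files, f)
  }
  if (length(model_rows)) {
    tables$model_table <- do.call(rbind, c(model_rows,
                                           make.row.names = FALSE))
    f <- file.path(cfg$out_dir, "model_table.csv")
    fmt_csv(tables$model_table, f); files <- c(files, f)
  }

  if (!is.null(cfg$dmd_markers)) {
    dmd_tab <- stage("dmd", {
      cols <- intersect(names(cfg$dmd_markers), names(dat$reference))
      if (length(cols) < 1) stop("no dmd_markers found in reference")
      out <- data.frame(sample_id = dat$reference$sample_id)
      for (mk in cols)
        out[[paste0("DMD_", mk)]] <-
          dmd_from_marker(cfg$dmd_markers[[mk]], dat$reference[[mk]])
      out
    })
    if (!is.null(dmd_tab)) {
      tables$dmd <- dmd_tab
      f <- file.path(cfg$out_dir, "dmd_per_sample.csv")
      fmt_csv(dmd_tab, f); files <- c(files, f)
      if (ncol(dmd_tab) >= 3) {
        ag <- marker_agreement(dmd_tab[, -1, drop = FALSE])
        agd <- data.frame(marker = rownames(ag), as.data.frame(ag),
                          check.names = FALSE)
        tables$dmd_agreement <- agd
        f <- file.path(cfg$out_dir, "dmd_agreement.csv")
        fmt_csv(agd, f); files <- c(files, f)
      } else {
        log$notes <- c(log$notes,
                       "single marker: agreement matrix omitted")
      }
    }
  }
  finish_bundle(cfg, tables, best, files, log)
}

finish_bundle <- function(cfg, tables, best, files, log) {
  log_path <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(
    list(seed = log$seed, variant = log$variant,
         analytes = cfg$analytes, stages = log$stages,
         errors = log$errors, notes = log$notes),
    log_path, auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(config = cfg, tables = tables, best = best,
                 files = c(files, log_path), log = log),
            class = "report_bundle")
}

#' Render a report bundle as markdown text
#'
#' Formats the bundle's already-computed tables — nothing is recomputed
#' at render time. Models classified `"unreliable"` are flagged in the
#' text.
#'
#' @param bundle A `report_bundle` from [run_calibration_study()].
#' @param path Optional file to write the markdown to.
#' @return The markdown lines, invisibly if `path` is given.
#' @export
render_report <- function(bundle, path = NULL) {
  stopifnot(inherits(bundle, "report_bundle"))
  miss <- setdiff(c("model_table", "descriptive_stats"),
                  names(bundle$tables))
  if (length(miss))
    stop("bundle is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- c("# Calibration study report", "",
           paste0("Seed: ", bundle$log$seed, "; PLS variant: ",
                  bundle$log$variant), "")
  ds <- bundle$tables$descriptive_stats
  out <- c(out, "## Reference data", "",
           md_table(ds, c("constituent", "set", "n", "mean", "sd",
                          "cv", "min", "max")), "")
  mt <- bundle$tables$model_table
  out <- c(out, "## Ranked calibration models", "",
           md_table(mt, c("constituent", "recipe", "n_factors",
                          "r2_cal", "sec", "r2_cv", "secv", "r2_val",
                          "sep", "bias", "slope", "rpd", "rer",
                          "quality")), "")
  unrel <- mt[!is.na(mt$quality) & mt$quality == "unreliable", ]
  if (nrow(unrel))
    out <- c(out, paste0("**Flagged as unreliable:** ",
                         paste(unique(paste(unrel$constituent,
                                            unrel$recipe)),
                               collapse = "; ")), "")
  if (!is.null(bundle$tables$dmd_agreement)) {
    out <- c(out, "## Marker-based DMD agreement (r-squared)", "",
             md_table(bundle$tables$dmd_agreement,
                      names(bundle$tables$dmd_agreement)), "")
  }
  if (length(bundle$log$errors))
    out <- c(out, "## Stage errors", "",
             paste0("- ", names(bundle$log$errors), ": ",
                    unlist(bundle$log$errors)), "")
  out <- unname(out)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

md_table <- function(df, cols) {
  cols <- intersect(cols, names(df))
  d <- df[, cols, drop = FALSE]
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) formatC(x, digits = 4,
                                               format = "g"))
  d[] <- lapply(d, as.character)
  hdr <- paste0("| ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols)), collapse = "|"), "|")
  rows <- apply(d, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}
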