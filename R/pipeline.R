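# End-to-end pipeline: simulate -> extract -> analyze -> report, with a
# JSON-serialisable configuration and provenance stamping.

#' Analysis-stage settings
#'
#' @param rbc_range Half-open RBC filter (M/uL) for the correlation and
#'   stratification analyses.
#' @param plt_range Closed PLT filter (K/uL).
#' @param plt_bins PLT stratification bins (K/uL), low to high.
#' @param band Fit band (THz) for delta spectra.
#' @param test_freqs Frequencies (THz) at which group comparisons are
#'   reported.
#' @param corr_freq Frequency (THz) for the covariate correlations.
#' @param min_slope Minimum |slope| for a defined transparency frequency.
#' @return An object of class `analysis_settings`.
#' @export
analysis_settings <- function(rbc_range = c(4, 5),
                              plt_range = c(100, 300),
                              plt_bins = list(low = c(100, 200),
                                              high = c(200, 300)),
                              band = c(0.13, 1.02),
                              test_freqs = c(0.2, 0.27, 0.34, 0.75, 0.82, 0.885),
                              corr_freq = 0.27,
                              min_slope = 0.005) {
  structure(
    list(rbc_range = as.numeric(rbc_range), plt_range = as.numeric(plt_range),
         plt_bins = lapply(plt_bins, as.numeric), band = as.numeric(band),
         test_freqs = as.numeric(test_freqs), corr_freq = as.numeric(corr_freq),
         min_slope = as.numeric(min_slope)),
    class = "analysis_settings"
  )
}

#' Full pipeline configuration
#'
#' Bundles the generator, extraction and analysis settings with the master
#' seed. Every tunable of the pipeline appears here explicitly with its
#' default, and the object round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort A [cohort_config()].
#' @param extraction An [extraction_settings()].
#' @param analysis An [analysis_settings()].
#' @param seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            extraction = extraction_settings(),
                            analysis = analysis_settings(),
                            seed = 1L) {
  cfg <- structure(
    list(cohort = cohort, extraction = extraction, analysis = analysis,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Structural and invariant checks of a [pipeline_config()]: component
#' classes, positive tolerances, ordered bands and filter ranges, group
#' names and sizes. Errors with a descriptive message on the first violation.
#'
#' @param config A `pipeline_config` (or a plain list with its structure).
#' @return The validated config, invisibly.
#' @export
validate_pipeline_config <- function(config) {
  need <- c("cohort", "extraction", "analysis", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(paste("Config is missing:", paste(missing, collapse = ", ")),
          class = "thzcoag_config_error")
  }
  stopifnot(inherits(config$cohort, "cohort_config"),
            inherits(config$extraction, "extraction_settings"),
            inherits(config$analysis, "analysis_settings"))
  a <- config$analysis
  if (a$rbc_range[1] >= a$rbc_range[2] || a$plt_range[1] >= a$plt_range[2]) {
    abort("Analysis filter ranges must be increasing.",
          class = "thzcoag_config_error")
  }
  if (!is.finite(config$seed)) {
    abort("`seed` must be a finite integer.", class = "thzcoag_config_error")
  }
  invisible(config)
}

# strip S3 classes recursively so jsonlite sees plain lists; named atomic
# vectors become lists so their names survive the JSON object notation
.unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    x <- as.list(x)
  }
  x
}

#' Serialize / deserialize a pipeline configuration
#'
#' The JSON document contains every tunable explicitly. Reading reconstructs
#' the typed components through their constructors, so
#' `read_pipeline_config(write_pipeline_config(cfg, path))` is identical to
#' `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path File path of the JSON document.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  jsonlite::write_json(.unclass_deep(unclass(config)), path,
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_pipeline_config(raw)
}

#' @rdname write_pipeline_config
#' @param x A plain (e.g. JSON-parsed) list with the pipeline-config
#'   structure.
#' @export
as_pipeline_config <- function(x) {
  co <- x$cohort
  cohort <- cohort_config(
    groups = setNames(as.integer(co$groups), names(co$groups)),
    covariates = lapply(co$covariates, function(s) lapply(s, as.numeric)),
    water = do.call(debye_water, lapply(co$water, as.numeric)),
    effect = do.call(coagulation_effect, lapply(co$effect, as.numeric)),
    geometry = do.call(chamber_geometry, lapply(co$geometry, as.numeric)),
    instrument = do.call(instrument_model, co$instrument),
    rbc_coeff = as.numeric(co$rbc_coeff), rbc_ref = as.numeric(co$rbc_ref),
    subject_sdlog = as.numeric(co$subject_sdlog),
    clotting_time_range = as.numeric(co$clotting_time_range)
  )
  pipeline_config(
    cohort = cohort,
    extraction = do.call(extraction_settings, x$extraction),
    analysis = do.call(analysis_settings, x$analysis),
    seed = x$seed
  )
}

# run one stage with a stage-tagged error
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = "thzcoag_stage_error", parent = e)
  })
}

#' Run the full simulate -> extract -> analyze pipeline
#'
#' Simulates the configured cohort, extracts per-subject optical constants,
#' runs the cohort statistics (group comparisons at the configured test
#' frequencies, covariate correlations, normalized absorption-change spectra
#' with transparency frequencies, platelet-stratified shift), and writes CSV
#' and JSON outputs with a provenance stamp (config hash, seed, package
#' version). Identical config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param seed Override of `config$seed`.
#' @return An object of class `thz_report`: list with `summary` (the JSON
#'   summary as an R list), `comparisons`, `correlations`, `group_alpha`,
#'   `alphas`, `cohort`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL) {
  validate_pipeline_config(config)
  seed <- seed %||% config$seed
  config_hash <- rlang::hash(.unclass_deep(unclass(config)))
  an <- config$analysis

  cohort <- run_stage("simulate", simulate_cohort(config$cohort, seed = seed))
  alphas <- run_stage("extract", extract_cohort(cohort, config$extraction))

  res <- run_stage("analyze", {
    subjects <- cohort$subjects
    present <- names(config$cohort$groups)
    group_alpha <- alphas |>
      left_join(select(subjects, "subject_id", "group"), by = "subject_id") |>
      group_by(.data$group, .data$freq_THz) |>
      summarise(alpha_cm1 = mean(.data$alpha_cm1), .groups = "drop")

    pairs <- list(c("thrombus", "uncoagulated"),
                  c("early_coagulated", "uncoagulated"))
    comparisons <- list_rbind(map(pairs, function(p) {
      if (!all(p %in% present)) return(NULL)
      compare_groups(alphas, subjects, p[1], p[2], freqs = an$test_freqs) |>
        mutate(group_a = p[1], group_b = p[2], .before = 1)
    }))

    correlations <- list_rbind(map(intersect(present, .thz_groups), function(g) {
      recs <- filter(subjects, .data$group == g)
      out <- correlate_covariate(alphas, recs, "rbc", an$corr_freq) |>
        mutate(group = g, filtered = FALSE, .before = 1)
      recs_f <- filter_subjects(recs, an$rbc_range, an$plt_range)
      if (nrow(recs_f) >= 3) {
        out <- bind_rows(out,
          correlate_covariate(
            alphas |> filter(.data$subject_id %in% recs_f$subject_id),
            recs_f, "plt", an$corr_freq) |>
            mutate(group = g, filtered = TRUE, .before = 1))
      }
      out
    }))

    mean_spec <- function(g) {
      ids <- subjects$subject_id[subjects$group == g]
      minute_average_alpha(filter(alphas, .data$subject_id %in% ids))
    }
    deltas <- list(); shift <- NULL
    if ("uncoagulated" %in% present) {
      blood <- mean_spec("uncoagulated")
      for (g in intersect(c("early_coagulated", "thrombus"), present)) {
        deltas[[g]] <- delta_spectrum(mean_spec(g), blood, band = an$band,
                                      min_slope = an$min_slope)
      }
      if ("early_coagulated" %in% present) {
        early <- filter(subjects, .data$group == "early_coagulated")
        shift <- plt_stratified_shift(
          early, filter(alphas, .data$subject_id %in% early$subject_id),
          blood, bins = an$plt_bins, rbc_range = an$rbc_range,
          band = an$band, min_slope = an$min_slope)
      }
    }
    list(group_alpha = group_alpha, comparisons = comparisons,
         correlations = correlations, deltas = deltas, shift = shift)
  })

  summary <- list(
    provenance = list(config_hash = config_hash, seed = seed,
                      package = "thzcoag",
                      version = as.character(utils::packageVersion("thzcoag"))),
    n_subjects = nrow(cohort$subjects),
    groups = as.list(table(cohort$subjects$group)),
    comparisons = if (!is.null(res$comparisons)) res$comparisons,
    correlations = if (!is.null(res$correlations)) res$correlations,
    transparency = c(
      lapply(res$deltas, function(d) glance(d)),
      if (!is.null(res$shift)) list(
        plt_bins = res$shift$bins,
        plt_shift_THz = res$shift$shift)
    )
  )

  if (!is.null(out_dir)) {
    run_stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, out_dir)
      sdir <- file.path(out_dir, "spectra")
      dir.create(sdir, showWarnings = FALSE)
      for (id in unique(alphas$subject_id)) {
        write_csv_prov(filter(alphas, .data$subject_id == id) |>
                         select(-"subject_id"),
                       file.path(sdir, paste0(id, ".csv")), config_hash)
      }
      if (!is.null(res$comparisons)) {
        write_csv_prov(res$comparisons, file.path(out_dir, "comparisons.csv"),
                       config_hash)
      }
      if (!is.null(res$correlations)) {
        write_csv_prov(res$correlations, file.path(out_dir, "correlations.csv"),
                       config_hash)
      }
      if (length(res$deltas) > 0) {
        delta_tbl <- list_rbind(imap(res$deltas, function(d, g) {
          mutate(tidy(d), group = g, .before = 1)
        }))
        write_csv_prov(delta_tbl, file.path(out_dir, "delta_spectra.csv"),
                       config_hash)
      }
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           dataframe = "rows")
      write_pipeline_config(config, file.path(out_dir, "config.json"))
    })
  }

  structure(list(summary = summary, comparisons = res$comparisons,
                 correlations = res$correlations, deltas = res$deltas,
                 shift = res$shift, group_alpha = res$group_alpha,
                 alphas = alphas, cohort = cohort),
            class = "thz_report")
}

#' @export
print.thz_report <- function(x, ...) {
  cat("<thz_report> n =", x$summary$n_subjects, "subjects (",
      paste(names(x$summary$groups), unlist(x$summary$groups),
            sep = "=", collapse = ", "), ")\n")
  tr <- x$summary$transparency
  for (g in intersect(c("early_coagulated", "thrombus"), names(tr))) {
    cat(sprintf("  transparency (%s): %.3f THz\n", g,
                tr[[g]]$transparency_freq))
  }
  if (!is.null(tr$plt_shift_THz)) {
    cat(sprintf("  PLT-bin transparency shift: %.3f THz\n", tr$plt_shift_THz))
  }
  invisible(x)
}
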