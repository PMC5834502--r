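# File dialects: cohort metadata CSV, two-column trace files with a sidecar
# JSON of the instrument model and seed.

# canonical columns of the metadata table, in order
.metadata_cols <- c(subject_id = "subject_id", group = "group",
                    rbc = "rbc_M_per_uL", wbc = "wbc_K_per_uL",
                    mch = "mch_pg", mchc = "mchc_g_per_dL",
                    plt = "plt_K_per_uL", clotting_time = "clotting_time_min")

#' Write a simulated cohort to disk
#'
#' Writes the cohort metadata CSV (`metadata.csv`, unit-suffixed column
#' names, empty clotting time for uncoagulated subjects), a sidecar
#' `instrument.json` with the instrument model and master seed, and
#' optionally the raw per-acquisition trace files
#' (`traces/<subject>_<arm>_<acq>.csv`, two columns `time_ps`, `field_au`).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param traces Write the individual trace files (one per subject, arm and
#'   acquisition). Off by default: a full cohort holds thousands of traces.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, traces = FALSE) {
  stopifnot(inherits(cohort, "thz_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- cohort$subjects |>
    select(dplyr::all_of(names(.metadata_cols))) |>
    rlang::set_names(unname(.metadata_cols))
  readr::write_csv(meta, file.path(dir, "metadata.csv"), na = "")
  jsonlite::write_json(
    list(instrument = unclass(cohort$config$instrument), seed = cohort$seed),
    file.path(dir, "instrument.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (traces) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort$traces))) {
      id <- cohort$traces$subject_id[i]
      arm <- cohort$traces$arm[i]
      m <- cohort$traces$field[[i]]
      for (k in seq_len(ncol(m))) {
        readr::write_csv(
          tibble(time_ps = cohort$time_ps, field_au = m[, k]),
          file.path(tdir, sprintf("%s_%s_%03d.csv", id, arm, k)))
      }
    }
  }
  invisible(dir)
}

#' Read a two-column trace file
#'
#' @param path Path to a delimited file with columns `time_ps`, `field_au`
#'   (as written by [write_cohort()], or any matching TDS export).
#' @return A tibble with columns `time_ps`, `field`.
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("time_ps", "field_au") %in% names(tr))) {
    abort("Trace file needs columns time_ps and field_au.",
          class = "thzcoag_input_error")
  }
  tibble(time_ps = tr$time_ps, field = tr$field_au)
}

#' Read a cohort metadata table
#'
#' @param path Path to a `metadata.csv` written by [write_cohort()].
#' @return A tibble with the package-internal short column names
#'   (`rbc`, `wbc`, `mch`, `mchc`, `plt`, `clotting_time`).
#' @export
read_cohort_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(unname(.metadata_cols), names(meta))
  if (length(missing) > 0) {
    abort(paste("Metadata is missing columns:", paste(missing, collapse = ", ")),
          class = "thzcoag_input_error")
  }
  meta |> rlang::set_names(
    names(.metadata_cols)[match(names(meta), unname(.metadata_cols))])
}

# CSV writer stamping the provenance (config hash) as a comment line
write_csv_prov <- function(df, path, config_hash) {
  writeLines(paste0("# config_hash: ", config_hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, na = "")
  invisible(path)
}
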