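#' Default configuration of the synthetic coagulation cohort
#'
#' Bundles every tunable of the generator: group sizes, hematology covariate
#' distributions (truncated normals), the water dielectric baseline, the
#' platelet-dependent coagulation effect, chamber geometry, instrument model,
#' the RBC absorption coefficient of uncoagulated blood, the between-subject
#' log-normal absorption scatter, and the clotting-time range.
#'
#' The defaults emulate the study conditions: 28 uncoagulated controls plus
#' 29 subjects each for the early-coagulated and thrombus measurement states;
#' PLT ~ Normal(196.6, 31) truncated to [100, 400] K/uL, so that the
#' conditional means of the 100-200 and 200-300 K/uL platelet bins are about
#' 175 and 224 K/uL and the transparency frequency at the cohort-mean PLT is
#' about 0.68 THz.
#'
#' @param groups Named integer vector of group sizes; names from
#'   `uncoagulated`, `early_coagulated`, `thrombus`. Omit a name to omit the
#'   group; a size of zero is an error.
#' @param covariates Named list of truncated-normal specs
#'   `list(mean, sd, min, max)` for `rbc` (M/uL), `wbc` (K/uL), `mch` (pg),
#'   `mchc` (g/dL), `plt` (K/uL).
#' @param water A [debye_water()] model.
#' @param effect A [coagulation_effect()].
#' @param geometry A [chamber_geometry()].
#' @param instrument An [instrument_model()].
#' @param rbc_coeff,rbc_ref RBC absorption coefficient (per M/uL) and
#'   reference count for the uncoagulated state.
#' @param subject_sdlog Log-normal sd of the per-subject absorption scale.
#' @param clotting_time_range Clotting-time range in minutes, drawn uniformly
#'   for coagulating subjects.
#' @return An object of class `cohort_config` (a named list).
#' @export
cohort_config <- function(groups = c(uncoagulated = 28L,
                                     early_coagulated = 29L,
                                     thrombus = 29L),
                          covariates = list(
                            rbc  = list(mean = 4.5,   sd = 0.45, min = 3,   max = 6),
                            wbc  = list(mean = 7.0,   sd = 1.8,  min = 2,   max = 15),
                            mch  = list(mean = 29.5,  sd = 2.0,  min = 20,  max = 38),
                            mchc = list(mean = 33.5,  sd = 1.0,  min = 28,  max = 38),
                            plt  = list(mean = 196.6, sd = 31,   min = 100, max = 400)
                          ),
                          water = debye_water(),
                          effect = coagulation_effect(),
                          geometry = chamber_geometry(),
                          instrument = instrument_model(),
                          rbc_coeff = 0.02,
                          rbc_ref = 4.5,
                          subject_sdlog = 0.02,
                          clotting_time_range = c(8, 21)) {
  groups <- setNames(as.integer(groups), names(groups))
  covariates <- lapply(covariates, function(s) lapply(s, as.numeric))
  rbc_coeff <- as.numeric(rbc_coeff); rbc_ref <- as.numeric(rbc_ref)
  subject_sdlog <- as.numeric(subject_sdlog)
  clotting_time_range <- as.numeric(clotting_time_range)
  if (is.null(names(groups)) || !all(names(groups) %in% .thz_groups)) {
    abort("`groups` must be named with measurement states.",
          class = "thzcoag_config_error")
  }
  if (any(groups < 1)) {
    bad <- names(groups)[groups < 1]
    abort(paste0("Group '", bad[1], "' has size ", groups[bad[1]],
                 "; every listed group needs at least one subject."),
          class = "thzcoag_config_error")
  }
  structure(
    list(groups = groups, covariates = covariates, water = water,
         effect = effect, geometry = geometry, instrument = instrument,
         rbc_coeff = rbc_coeff, rbc_ref = rbc_ref,
         subject_sdlog = subject_sdlog,
         clotting_time_range = clotting_time_range),
    class = "cohort_config"
  )
}

# truncated-normal draw by rejection (truncation is mild for all defaults)
rtruncnorm <- function(n, spec) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n, spec$mean, spec$sd)
    out <- c(out, x[x >= spec$min & x <= spec$max])
  }
  out[seq_len(n)]
}

#' Simulate a synthetic coagulation cohort
#'
#' Draws hematology covariates and a per-subject absorption scale, builds each
#' subject's ground-truth optical constants via [blood_index()], propagates
#' the single-cycle source pulse through the empty and blood-filled chamber,
#' and emits `traces_per_minute` noisy time traces per subject and arm. Fully
#' reproducible: one master seed drives covariates, and deterministic
#' per-subject substream seeds drive the trace noise, so any subject subset is
#' reproducible independently.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @return An object of class `thz_cohort`: a list with
#'   \describe{
#'     \item{subjects}{tibble of subject records (id, group, covariates,
#'       clotting time, latent `kappa_scale`, substream seed).}
#'     \item{traces}{tibble with one row per subject and arm; column `field`
#'       holds a `trace_length x traces_per_minute` matrix.}
#'     \item{time_ps}{shared delay grid.}
#'     \item{truth}{tibble of ground-truth `n`, `kappa`, `alpha_cm1` per
#'       subject on the native frequency grid.}
#'     \item{config, seed}{provenance.}
#'   }
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n_total <- sum(config$groups)
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_total)),
    group = rep(names(config$groups), config$groups),
    rbc  = rtruncnorm(n_total, config$covariates$rbc),
    wbc  = rtruncnorm(n_total, config$covariates$wbc),
    mch  = rtruncnorm(n_total, config$covariates$mch),
    mchc = rtruncnorm(n_total, config$covariates$mchc),
    plt  = rtruncnorm(n_total, config$covariates$plt),
    kappa_scale = rlnorm(n_total, 0, config$subject_sdlog),
    clotting_time = ifelse(
      rep(names(config$groups), config$groups) == "uncoagulated", NA_real_,
      runif(n_total, config$clotting_time_range[1], config$clotting_time_range[2])),
    trace_seed = sample.int(.Machine$integer.max - 1L, n_total)
  )

  # flag subjects whose transparency frequency leaves the source band; the
  # calibrated PLT slope extrapolates out of band at high platelet counts
  coag <- subjects$group != "uncoagulated"
  if (any(coag)) {
    f_t <- transparency_frequency(subjects$plt[coag], config$effect)
    out_of_band <- f_t < config$instrument$source_band[1] |
      f_t > config$instrument$source_band[2]
    if (any(out_of_band)) {
      inform(sprintf(
        "%d coagulating subject(s) have a transparency frequency outside the source band.",
        sum(out_of_band)))
    }
  }

  fk <- instrument_freqs(config$instrument)
  dr <- config$instrument$peak_dynamic_range
  noise_sd <- if (is.finite(dr)) 10^(-dr / 20) else 0 # reference peak is 1

  per_subject <- map(seq_len(n_total), function(i) {
    s <- subjects[i, ]
    index_fun <- function(f) {
      blood_index(s, f, water = config$water, effect = config$effect,
                  rbc_coeff = config$rbc_coeff, rbc_ref = config$rbc_ref)
    }
    optics <- index_fun(fk)
    clean <- clean_trace_pair(index_fun, config$geometry, config$instrument)
    set.seed(s$trace_seed)
    nt <- config$instrument$traces_per_minute
    list(
      truth = mutate(optics, subject_id = s$subject_id, .before = 1),
      reference = noisy_acquisitions(clean$reference, nt, noise_sd),
      sample = noisy_acquisitions(clean$sample, nt, noise_sd),
      time_ps = clean$time_ps
    )
  })

  traces <- tibble(
    subject_id = rep(subjects$subject_id, each = 2),
    arm = rep(c("reference", "sample"), n_total),
    field = unlist(map(per_subject, function(p) list(p$reference, p$sample)),
                   recursive = FALSE)
  )

  structure(
    list(subjects = subjects,
         traces = traces,
         time_ps = per_subject[[1]]$time_ps,
         truth = list_rbind(map(per_subject, "truth")),
         config = config,
         seed = seed),
    class = "thz_cohort"
  )
}

#' @export
print.thz_cohort <- function(x, ...) {
  sizes <- table(x$subjects$group)
  cat("<thz_cohort> ", nrow(x$subjects), " subjects (",
      paste(names(sizes), sizes, sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  traces: ", ncol(x$traces$field[[1]]), " x ",
      length(x$time_ps), " samples per arm; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# long tidy view of one subject/arm trace matrix, used by IO and tests
trace_tibble <- function(cohort, subject_id, arm) {
  m <- cohort$traces$field[[
    which(cohort$traces$subject_id == subject_id & cohort$traces$arm == arm)]]
  tibble(
    time_ps = rep(cohort$time_ps, ncol(m)),
    field = as.vector(m),
    acquisition = rep(seq_len(ncol(m)), each = nrow(m)),
    arm = arm
  )
}
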