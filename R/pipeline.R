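# End-to-end analysis pipeline, delimited-log I/O and YAML configuration.

#' Write a gait log to delimited text
#'
#' One row per sample, header
#' `t,hip_L,hip_R,knee_L,knee_R,ankle_L,ankle_R,slider_x,fourbar,I_hip_L,I_hip_R,I_knee_L,I_knee_R`,
#' SI units, with `#`-prefixed provenance comment lines.
#'
#' @param log a `gait_log`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gait_log <- function(log, path) {
  stopifnot(inherits(log, "gait_log"))
  cols <- c("hip_L", "hip_R", "knee_L", "knee_R", "ankle_L", "ankle_R",
            "slider_x", "fourbar", "I_hip_L", "I_hip_R", "I_knee_L",
            "I_knee_R")
  df <- data.frame(t = log$timestamps)
  for (nm in cols) df[[nm]] <- log$channels[[nm]]
  hdr <- c("# gait sensor log; SI units (s, rad, m, A)",
           "# convention: ankle dorsiflexion+, knee flexion+, hip flexion+ (swing ankle plateau -22 deg)")
  if (!is.null(log$metadata$condition)) {
    hdr <- c(hdr, sprintf("# condition: %s", log$metadata$condition))
  }
  if (!is.null(log$metadata$seed)) {
    hdr <- c(hdr, sprintf("# generator seed: %s", log$metadata$seed))
  }
  writeLines(c(hdr, capture_csv(df)), path)
  invisible(path)
}

#' Read a delimited gait log
#'
#' @param path file written by [write_gait_log()] (or compatible: same
#'   header, `#` comments allowed).
#' @param condition optional condition label stored in the metadata.
#' @return a `gait_log`.
#' @export
read_gait_log <- function(path, condition = NULL) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("t", "hip_L", "hip_R", "knee_L", "knee_R", "ankle_L", "ankle_R",
            "slider_x", "fourbar", "I_hip_L", "I_hip_R", "I_knee_L",
            "I_knee_R")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("log file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(condition)) {
    cm <- grep("^# condition:", readLines(path, n = 10), value = TRUE)
    if (length(cm)) condition <- trimws(sub("^# condition:", "", cm[1]))
  }
  gait_log(df$t, df[setdiff(need, "t")],
           metadata = list(condition = condition, source = path))
}

#' Default analysis configuration
#'
#' All tunables of the pipeline in one nested list, overridable via YAML
#' (see [read_gait_config()]): `morphology`, `control`, `filtering`,
#' `synthesis` and `analysis` sections.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    morphology = default_morphology(),
    control = list(mode = "AKFI"),
    filtering = list(rate = 1000, order = 2, cutoff_angles = 50,
                     cutoff_currents = 10),
    synthesis = list(n_cycles = 120, mean_forward_speed = 0.44,
                     event_jitter_sd = 0.3, sampling_rate_nominal = 600,
                     sampling_jitter = 0.15, cpg_phase_offset = 0.20),
    analysis = list(n_keep = 120, n_grid = 1000, trailing_side = "L",
                    gradient_threshold = 1, stance_window = c(10, 90),
                    touchdown_quiescence = 0.2, touchdown_dwell = 0.1,
                    transition_search = c(30, 80), prominence_frac = 0.1,
                    idle_power = 0, cot_nr = 1.36)
  )
}

#' Read a YAML analysis configuration
#'
#' Reads a YAML file with any subset of the sections of
#' [default_config()]; unspecified entries keep their defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_gait_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' Analyse one walking record end to end
#'
#' Runs the full single-condition pipeline: uniform resampling, zero-phase
#' filtering, touch-down segmentation, ensemble averaging, gait-event
#' detection, momentum/impulse analysis over the step-to-step transition
#' and the energy summary.
#'
#' @param log a raw `gait_log`.
#' @param config configuration list (see [default_config()]).
#' @param n_keep number of cycles to analyse; defaults to
#'   `config$analysis$n_keep`, reduced to the available count if
#'   `n_keep = NULL`.
#' @return object of class `gait_analysis`: list with `ensemble`, `events`,
#'   `momentum`, `impulses`, `energy`, `boundaries`, `config`.
#' @export
analyze_gait <- function(log, config = default_config(), n_keep = NULL) {
  stopifnot(inherits(log, "gait_log"))
  an <- config$analysis
  filt <- default_filtering(rate = config$filtering$rate,
                            order = config$filtering$order,
                            cutoff_angles = config$filtering$cutoff_angles,
                            cutoff_currents = config$filtering$cutoff_currents)
  ulog <- resample_uniform(log, filt$rate)
  flog <- filter_log(ulog, filt)
  td_channel <- paste0("ankle_", an$trailing_side)
  boundaries <- detect_touchdowns(flog$channels[[td_channel]], filt$rate,
                                  activity_threshold = an$gradient_threshold,
                                  quiescence_threshold = an$touchdown_quiescence,
                                  dwell = an$touchdown_dwell)
  if (is.null(n_keep)) {
    n_keep <- min(an$n_keep, length(boundaries) - 1)
  }
  ens <- segment_cycles(flog, boundaries, n_keep = n_keep,
                        n_grid = an$n_grid)
  events <- extract_events(ens, trailing_side = an$trailing_side,
                           threshold = an$gradient_threshold,
                           stance_window = an$stance_window)
  morph <- validate_morphology(config$morphology)
  ms <- momentum_series(flog, morph, trailing_side = an$trailing_side)
  imp <- transition_impulses(ms, boundaries, n_keep = n_keep,
                             events = events, n_grid = an$n_grid,
                             search = an$transition_search,
                             prominence_frac = an$prominence_frac)
  span <- c(boundaries[1], boundaries[n_keep + 1])
  en <- energy_summary(flog, morph, idle_power = an$idle_power,
                       COT_nr = an$cot_nr, span = span)
  structure(list(ensemble = ens, events = events, momentum = ms,
                 impulses = imp, energy = en, boundaries = boundaries,
                 n_keep = n_keep, config = config,
                 condition = log$metadata$condition),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> condition %s, %d cycles\n",
              x$condition %||% "?", x$n_keep))
  print(x$events)
  print(x$energy)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two analysed conditions
#'
#' Thin wrapper around [compare_experiments()] for two [analyze_gait()]
#' results.
#'
#' @param a,b `gait_analysis` objects (a is the reference condition).
#' @param ... passed to [compare_experiments()].
#' @return a `comparison_report`.
#' @export
compare_gait_analyses <- function(a, b, ...) {
  stopifnot(inherits(a, "gait_analysis"), inherits(b, "gait_analysis"))
  compare_experiments(a$events, b$events, a$impulses, b$impulses, ...)
}

#' Event-recovery errors against a ground-truth schedule
#'
#' Matches each analysed cycle to the nearest scheduled touch-down and
#' tabulates detected minus scheduled event times (percent GC) for the five
#' events. Used to validate the generator-detector loop closure.
#'
#' @param analysis a [analyze_gait()] result.
#' @param truth schedule with absolute starts (`simulate_gait()$truth`).
#' @return data.frame with one row per analysed cycle: `cycle`, matched
#'   `truth_cycle`, and `err_SKF`, `err_SHF`, `err_SAPF`, `err_LLTD`,
#'   `err_TO` in percent GC.
#' @export
event_recovery_errors <- function(analysis, truth) {
  stopifnot(inherits(analysis, "gait_analysis"))
  det_starts <- analysis$ensemble$starts
  match_idx <- vapply(det_starts, function(s) {
    which.min(abs(truth$t_start - s))
  }, 1L)
  ev <- c("t_SKF", "t_SHF", "t_SAPF", "t_LLTD", "t_TO")
  out <- data.frame(cycle = analysis$events$per_cycle$cycle,
                    truth_cycle = match_idx)
  for (e in ev) {
    out[[sub("t_", "err_", e)]] <-
      analysis$events$per_cycle[[e]] - truth[[e]][match_idx]
  }
  out
}
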