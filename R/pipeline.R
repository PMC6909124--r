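## ---- per-case arm comparison ---------------------------------------------

#' Register one phantom case with all four arms and evaluate it
#'
#' Runs, on one fixed/moving pair: rigid registration; plain deformable
#' registration (intensity only); structure-guided deformable registration
#' with liver-surface guidance; and structure-guided registration with
#' liver surfaces plus anatomical landmarks. The rigid result is the shared
#' baseline of the three deformable arms. Each arm is evaluated with the
#' full TG-132 QA bundle ([qa_report]).
#'
#' @param case a `phantom_case` from [make_case] (or any list with the same
#'   `fixed` / `moving` fields).
#' @param config a [registration_config]; its `roi`, if `NULL`, is set to
#'   the fixed liver bounding box padded by 20 mm.
#' @param arms subset of `c("rigid", "dir", "sgdir_liver",
#'   "sgdir_liver_lm")`.
#' @param held_out_tre also compute TRE restricted to the case's held-out
#'   landmark subset (reported under `tre_held_out`); relevant because the
#'   landmark-guided arm is otherwise evaluated on the same landmarks that
#'   guided it.
#' @return list with `transforms`, `reports` (named lists per arm), and
#'   `config`.
#' @export
run_case_arms <- function(case, config = registration_config(),
                          arms = c("rigid", "dir", "sgdir_liver",
                                   "sgdir_liver_lm"),
                          held_out_tre = FALSE) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (is.null(config$roi))
    config$roi <- roi_from_mask(case$fixed$mask, 20)
  fixed <- case$fixed$volume
  moving <- case$moving$volume
  rigid <- register_rigid(fixed, moving, config)
  transforms <- list()
  if ("rigid" %in% arms) transforms$rigid <- rigid
  if ("dir" %in% arms)
    transforms$dir <- register_deformable(fixed, moving, rigid, config,
                                          guidance = NULL)$transform
  if ("sgdir_liver" %in% arms)
    transforms$sgdir_liver <- register_deformable(
      fixed, moving, rigid, config,
      guidance = structure_guidance(case$fixed$mask, case$moving$mask))$transform
  if ("sgdir_liver_lm" %in% arms)
    transforms$sgdir_liver_lm <- register_deformable(
      fixed, moving, rigid, config,
      guidance = structure_guidance(case$fixed$mask, case$moving$mask,
                                    case$fixed$landmarks,
                                    case$moving$landmarks))$transform
  reports <- lapply(transforms, function(tr) {
    rep <- qa_report(tr, case$fixed$mask, case$moving$mask,
                     case$fixed$landmarks, case$moving$landmarks)
    if (held_out_tre && length(case$held_out) > 0) {
      keep <- case$fixed$landmarks$points$name %in% case$held_out
      fl <- case$fixed$landmarks; fl$points <- fl$points[keep, ]
      ml <- case$moving$landmarks
      ml$points <- ml$points[ml$points$name %in% case$held_out, ]
      rep$tre_held_out <- target_registration_error(
        apply_to_points(tr, fl), ml)
    }
    rep
  })
  list(transforms = transforms, reports = reports, config = config)
}

## ---- cohort experiment ---------------------------------------------------

#' Cohort-scale comparison of the four registration arms
#'
#' Generates a seeded phantom cohort, registers every case with every arm,
#' and summarizes the TG-132 metrics per arm with pairwise Wilcoxon
#' signed-rank tests ([compare_arms]). Also reports whether the cohort
#' medians follow the expected ordering
#' rigid >= DIR >= SG-DIR(liver) >= SG-DIR(liver+landmarks) for TRE and
#' MDA (registration error decreasing as guidance is added).
#'
#' @param n_cases cohort size.
#' @param spec a [phantom_spec] (per-case seeds are derived from `seed`).
#' @param seed cohort master seed (also seeds the registrations).
#' @param config a [registration_config].
#' @return list with `cases`, `arm_reports` (arm -> list of [qa_report]),
#'   `comparison` ([compare_arms] output), `ordering` (list of logicals
#'   `tre`, `mda`).
#' @export
run_cohort_experiment <- function(n_cases = 10, spec = phantom_spec(),
                                  seed = 1L,
                                  config = registration_config()) {
  cases <- make_cohort(n_cases, spec, seed)
  config$rng_seed <- seed
  per_case <- lapply(cases, run_case_arms, config = config)
  arm_names <- names(per_case[[1]]$reports)
  arm_reports <- lapply(arm_names, function(a)
    lapply(per_case, function(x) x$reports[[a]]))
  names(arm_reports) <- arm_names
  comparison <- compare_arms(arm_reports)
  ord <- c("rigid", "dir", "sgdir_liver", "sgdir_liver_lm")
  ordering <- list()
  for (m in c("tre", "mda")) {
    med <- comparison$table[[paste0("median_", m)]]
    names(med) <- comparison$table$arm
    ordering[[m]] <- all(diff(med[ord]) <= 1e-9)
  }
  list(cases = cases, arm_reports = arm_reports, comparison = comparison,
       ordering = ordering)
}

#' Export an arm-comparison summary as a flat table
#'
#' One row per case and arm with the headline metrics, in the shape used
#' for whole-structure reporting (case, arm, DSC, MDA, TRE median and
#' range, percentage of negative Jacobian voxels).
#'
#' @param arm_reports named list: arm -> list of [qa_report]s.
#' @return data.frame.
#' @export
summary_table <- function(arm_reports) {
  rows <- list()
  for (arm in names(arm_reports)) {
    reps <- arm_reports[[arm]]
    for (i in seq_along(reps)) {
      r <- reps[[i]]
      rows[[length(rows) + 1]] <- data.frame(
        case = i, arm = arm, dsc = r$dsc, mda_mm = r$mda_mm,
        tre_median_mm = if (!is.null(r$tre)) r$tre$median else NA_real_,
        tre_min_mm = if (!is.null(r$tre)) r$tre$range[1] else NA_real_,
        tre_max_mm = if (!is.null(r$tre)) r$tre$range[2] else NA_real_,
        pct_negative_jacobian = r$jacobian$pct_negative,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Serialize a QA report to JSON
#'
#' @param report a [qa_report].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qa_report <- function(report, path) {
  obj <- list(
    dsc = report$dsc, mda_mm = report$mda_mm,
    tre = if (!is.null(report$tre))
      list(pairs = report$tre$pairs, median = report$tre$median,
           range = report$tre$range, mean = report$tre$mean,
           sem = report$tre$sem),
    jacobian = report$jacobian,
    cumulative_histogram = list(curve = report$cum_hist$curve,
                                mean_mm = report$cum_hist$mean,
                                sem_mm = report$cum_hist$sem))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
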