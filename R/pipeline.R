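# Seeded end-to-end run: targets -> launch solutions -> session plans ->
# synthetic cohort -> per-trial metrics -> cohort table -> statistical
# battery. The same seed reproduces the whole bundle bit-for-bit on one
# platform.

#' Run the full suite end to end
#'
#' Synthesises a cohort under `config`, pushes every recording through the
#' kinematic pipeline, aggregates to the participant x game x height table
#' and fits the repeated-measures battery (two-way ANOVA per outcome,
#' per-height simple effects and LSD post hoc for the two lumbar outcomes).
#'
#' @param n_participants Cohort size (default 31).
#' @param seed Master integer seed.
#' @param config Suite configuration from [default_config()] or
#'   [read_config()].
#' @param out_dir Optional directory; when given, the cohort table, the
#'   per-trial metrics, the ANOVA tables (JSON) and an md5 manifest are
#'   written there.
#'
#' @return A list of class `reachvr_run`: `metrics`, `table` (cohort table),
#'   `anova` (named list of `reachvr_rm_anova` fits), `simple` (named list
#'   of simple-effects tables), `normality`, `config`, `seed`.
#' @export
run_end_to_end <- function(n_participants = 31, seed = 1L,
                           config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  cohort <- synthesize_cohort(n_participants, seed, config)
  spec <- filter_spec(config$filter_window, config$filter_order, config$rate)
  metrics <- trial_metrics(cohort, spec, config$min_excursion)
  table <- aggregate_trials(metrics)
  if (nrow(attr(table, "incomplete"))) {
    warning(sprintf("%d participant x game x height cells are empty; ANOVA may fail",
                    nrow(attr(table, "incomplete"))))
  }

  outcomes <- c(lumbar_excursion = "lumbar_excursion_deg",
                peak_lumbar_velocity = "peak_lumbar_velocity_dps",
                impact_ap = "impact_ap_m",
                impact_vertical = "impact_vertical_m")
  anova <- lapply(outcomes, function(oc) {
    tryCatch(rm_anova(table, !!rlang::sym(oc), participant, c(game, theta_deg)),
             reachvr_design_error = function(e) {
               warning(sprintf("ANOVA on %s skipped: %s", oc, conditionMessage(e)))
               NULL
             })
  })
  simple <- lapply(outcomes[1:2], function(oc) {
    simple_effects(table, !!rlang::sym(oc), participant, game, theta_deg)
  })
  normality <- lapply(outcomes, function(oc) {
    normality_screen(table, !!rlang::sym(oc), c(game, theta_deg))
  })

  res <- structure(list(metrics = metrics, table = table, anova = anova,
                        simple = simple, normality = normality,
                        config = config, seed = seed),
                   class = "reachvr_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.reachvr_run <- function(x, ...) {
  cat(sprintf("<reachvr_run> %d participants, seed %d, %d trials (%d included)\n",
              length(unique(x$metrics$participant)), x$seed,
              nrow(x$metrics), sum(x$metrics$included)))
  for (nm in names(x$anova)) {
    cat("\n==", nm, "==\n")
    print(x$anova[[nm]])
  }
  invisible(x)
}

#' Write a run bundle to disk
#'
#' Writes `cohort_table.csv`, `trial_metrics.csv`, `anova.json` (per-effect
#' tables for each outcome, mirroring the layout effect / F(df1, df2) / p /
#' partial eta-squared) and `manifest.csv` with md5 checksums of every file.
#'
#' @param run A `reachvr_run` object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(run$table, file.path(out_dir, "cohort_table.csv"))
  write_metrics_csv(run$metrics, file.path(out_dir, "trial_metrics.csv"))
  jsonlite::write_json(lapply(run$anova, function(f) f$table),
                       file.path(out_dir, "anova.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c("cohort_table.csv", "trial_metrics.csv", "anova.json")
  manifest <- tibble::tibble(
    file = files, md5 = unname(tools::md5sum(file.path(out_dir, files))))
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}
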