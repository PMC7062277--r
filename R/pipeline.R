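# Analysis pipeline chaining all stages, with delimited-text stage
# outputs and a JSON run manifest.

#' Run the full drive-hunt analysis chain
#'
#' Chains event detection, flee/stay classification and movement
#' metrics, per-individual annual utilization distributions and the
#' familiarity index, censored return-time construction with
#' Kaplan-Meier estimation, the two mixed-effects response models and
#' the flee/stay distance comparison. Stages that cannot run on the
#' data at hand (e.g. the familiarity stage on trajectories shorter
#' than a season, or model fits with too few events) are skipped with
#' a message and recorded in the manifest.
#'
#' @param trajectories named list of `hm_traj` (from
#'   [read_relocations()] or a generator).
#' @param hunts hunt data frame.
#' @param areas named list of `hm_area`.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory; when given, writes
#'   `events.csv`, `returns.csv`, `survival_post.csv`,
#'   `survival_control.csv`, `fits.csv` and `manifest.json`.
#' @param with_familiarity estimate annual UDs and the familiarity
#'   covariate (needs year-scale trajectories)?
#' @return list with `events`, `returns`, `km` (per condition),
#'   `fit_immediate`, `fit_delayed`, `fit_return`,
#'   `group_comparison` and `manifest`.
#' @export
run_pipeline <- function(trajectories, hunts, areas,
                         config = analysis_config(), out_dir = NULL,
                         with_familiarity = TRUE) {
  manifest <- list(package = "huntmove",
                   version = as.character(utils::packageVersion("huntmove")),
                   n_individuals = length(trajectories),
                   n_hunts = nrow(hunts),
                   config = unclass(config), stages = list())
  isopleths <- NULL
  if (with_familiarity) {
    isopleths <- list()
    for (id in names(trajectories)) {
      iso <- tryCatch({
        sub <- suppressWarnings(
          annual_relocation_subsample(trajectories[[id]]))
        ud <- estimate_ud(sub, cell_m = config$ud_cell_m,
                          bandwidth = config$ud_bandwidth,
                          bandwidth_value = config$ud_bandwidth_value)
        isopleth_regions(ud)
      }, error = function(e) {
        message("familiarity stage skipped for ", id, ": ",
                conditionMessage(e))
        NULL
      })
      isopleths[[id]] <- iso
    }
    manifest$stages$familiarity <- list(
      band_weights = iso_band_weights(),
      individuals_with_ud = sum(!vapply(isopleths, is.null, logical(1L))))
  }
  events <- detect_events(trajectories, hunts, areas, config)
  events <- build_event_table(events, trajectories, areas, config,
                              isopleths = isopleths)
  manifest$stages$events <- list(
    n_detected = nrow(events),
    n_classified = sum(!is.na(events$classification)),
    n_fleeing = sum(events$classification == "fleeing", na.rm = TRUE))
  returns <- build_return_table(events, trajectories, areas, config)
  km <- list()
  for (cond in c("post_hunt", "control")) {
    if (nrow(returns) && any(returns$condition == cond))
      km[[cond]] <- km_estimate(returns, cond)
  }
  manifest$stages$returns <- list(
    n_records = nrow(returns),
    km_median_post = if (!is.null(km$post_hunt))
      km_median(km$post_hunt) else NA,
    km_median_control = if (!is.null(km$control))
      km_median(km$control) else NA)
  try_fit <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      message(label, " skipped: ", conditionMessage(e))
      NULL
    })
  }
  fit_imm <- try_fit(fit_distance_model(events, "immediate"),
                     "immediate-distance model")
  fit_del <- try_fit(fit_distance_model(events, "delayed"),
                     "delayed-distance model")
  fit_ret <- try_fit(fit_return_model(returns), "short-return model")
  cmp <- try_fit(compare_group_distances(events, "immediate"),
                 "group comparison")
  manifest$stages$models <- list(
    backend = if (!is.null(fit_imm)) fit_imm$backend else NA,
    fitted = c(immediate = !is.null(fit_imm), delayed = !is.null(fit_del),
               short_return = !is.null(fit_ret)))
  out <- list(events = events, returns = returns, km = km,
              fit_immediate = fit_imm, fit_delayed = fit_del,
              fit_return = fit_ret, group_comparison = cmp,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ev <- events
    ev$t_start <- format(ev$t_start, TS_FMT, tz = "UTC")
    ev$t_end <- format(ev$t_end, TS_FMT, tz = "UTC")
    utils::write.csv(ev, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    if (nrow(returns))
      utils::write.csv(returns, file.path(out_dir, "returns.csv"),
                       row.names = FALSE)
    for (cond in names(km))
      utils::write.csv(as.data.frame(km[[cond]]),
                       file.path(out_dir, paste0("survival_",
                                                 sub("_hunt", "", cond),
                                                 ".csv")),
                       row.names = FALSE)
    fits <- list()
    for (nm in c("fit_immediate", "fit_delayed", "fit_return")) {
      f <- out[[nm]]
      if (!is.null(f)) {
        cf <- f$coefficients
        cf$model <- sub("fit_", "", nm)
        fits[[nm]] <- cf
      }
    }
    if (length(fits))
      utils::write.csv(do.call(rbind, fits),
                       file.path(out_dir, "fits.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}
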