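# End-to-end orchestration: chill -> hardiness -> budbreak -> damage ->
# risk per site, plus the evaluation report. A thin command-line front-end
# over these functions ships in inst/scripts/budfreeze.R.

#' Build a run configuration
#'
#' @param cultivars Cultivars to simulate (subset of the parameterized set).
#' @param convention Observation convention used for thresholds.
#' @param damage_correction Apply freeze-damage correction (default TRUE).
#' @param shift_c Chill phase shift, degC (default 0).
#' @param floor Spring floor configuration.
#' @param params_path Path to the parameter CSV (default: packaged table).
#' @param mdst_method MDST convention, `"midpoint"` or `"hourly"`.
#' @param seed Integer seed (used only by synthetic stages downstream).
#' @return A `run_config` list (parameter table loaded and validated).
#' @export
run_config <- function(cultivars = .cultivars, convention = "BBCH07_50",
                       damage_correction = TRUE, shift_c = 0,
                       floor = spring_floor(), params_path = NULL,
                       mdst_method = "midpoint", seed = 1) {
  unknown <- setdiff(cultivars, .cultivars)
  if (length(unknown) > 0) {
    stop("unknown cultivar(s) in config: ", paste(unknown, collapse = ", "))
  }
  if (!convention %in% .conventions) stop("unknown convention: ", convention)
  params_tbl <- if (is.null(params_path)) load_cultivar_params()
                else load_cultivar_params(params_path)
  structure(list(cultivars = cultivars, convention = convention,
                 damage_correction = damage_correction, shift_c = shift_c,
                 floor = floor, params_tbl = params_tbl,
                 mdst_method = mdst_method, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline for one site
#'
#' For each complete dormant season: accumulate chill portions, simulate the
#' three hardiness percentiles with freeze-damage detection/correction,
#' extract initial and FDC budbreak, and summarize risk.
#'
#' @param config A `run_config`.
#' @param series The site's `site_series`.
#' @param out_dir Optional directory; when given, per-site CSV outputs are
#'   written (`chill.csv`, `hardiness_<cultivar>.csv`,
#'   `events_<cultivar>.csv`, `predictions.csv`, `risk.csv`).
#' @return List of season results; each has `season`, `chill`, and per
#'   cultivar `trajectory`, `events`, `budbreak_initial`, `budbreak_fdc`,
#'   `risk`.
#' @export
run_site <- function(config, series, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"), inherits(series, "site_series"))
  seasons <- split_seasons(series, mdst_method = config$mdst_method)
  if (length(seasons) == 0) stop("no complete dormant season in series")
  results <- lapply(seasons, function(season) {
    chill <- chill_for_season(season, shift_c = config$shift_c)
    per_cv <- lapply(config$cultivars, function(cv) {
      res <- simulate_with_damage(cv, season, chill,
                                  convention = config$convention,
                                  floor = config$floor,
                                  params_tbl = config$params_tbl,
                                  damage_correction = config$damage_correction)
      res$risk <- risk_summary(season, res)
      res
    })
    names(per_cv) <- config$cultivars
    list(season = season, chill = chill, cultivars = per_cv)
  })
  names(results) <- vapply(results, function(r) as.character(r$season$season_year),
                           character(1))
  if (!is.null(out_dir)) {
    write_site_outputs(results, series$site_id, out_dir, config$convention)
  }
  results
}

# Stable-column-order CSV outputs per site (golden-file friendly).
write_site_outputs <- function(results, site_id, out_dir,
                               convention = "BBCH07_50") {
  dir.create(file.path(out_dir, site_id), recursive = TRUE, showWarnings = FALSE)
  base <- file.path(out_dir, site_id)
  chill <- do.call(rbind, lapply(results, function(r) {
    data.frame(season_year = r$season$season_year, r$chill)
  }))
  utils::write.csv(chill, file.path(base, "chill.csv"), row.names = FALSE)
  preds <- list(); risks <- list()
  for (r in results) {
    for (cv in names(r$cultivars)) {
      res <- r$cultivars[[cv]]
      slug <- gsub("[^A-Za-z0-9]+", "_", cv)
      traj <- data.frame(season_year = r$season$season_year, res$trajectory)
      f <- file.path(base, sprintf("hardiness_%s.csv", slug))
      utils::write.table(traj, f, sep = ",", row.names = FALSE,
                         col.names = !file.exists(f), append = file.exists(f))
      if (nrow(res$events) > 0) {
        ev <- data.frame(season_year = r$season$season_year, res$events)
        f <- file.path(base, sprintf("events_%s.csv", slug))
        utils::write.table(ev, f, sep = ",", row.names = FALSE,
                           col.names = !file.exists(f), append = file.exists(f))
      }
      preds[[length(preds) + 1]] <- data.frame(
        site_id = site_id, cultivar = cv,
        season_year = r$season$season_year,
        convention = convention,
        threshold_c = res$budbreak_initial$threshold_c,
        doy_initial = res$budbreak_initial$doy,
        doy_fdc = res$budbreak_fdc$doy,
        status = res$budbreak_fdc$status)
      risks[[length(risks) + 1]] <- res$risk
    }
  }
  utils::write.csv(do.call(rbind, preds), file.path(base, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, risks), file.path(base, "risk.csv"),
                   row.names = FALSE)
  invisible(base)
}

#' Flatten run results into a predictions table
#'
#' @param results Output of [run_site()].
#' @param site_id Site identifier (taken from the seasons if omitted).
#' @return data.frame with one row per season x cultivar: identity columns,
#'   `threshold_c`, `doy_initial`, `doy_fdc`, `status`, `n_events`.
#' @export
predictions_table <- function(results, site_id = NULL) {
  rows <- list()
  for (r in results) {
    sid <- site_id %||% r$season$site_id
    for (cv in names(r$cultivars)) {
      res <- r$cultivars[[cv]]
      rows[[length(rows) + 1]] <- data.frame(
        site_id = sid, cultivar = cv, season_year = r$season$season_year,
        mdst_c = r$season$mdst_c,
        threshold_c = res$budbreak_initial$threshold_c,
        doy_initial = res$budbreak_initial$doy,
        doy_fdc = res$budbreak_fdc$doy,
        status = res$budbreak_fdc$status,
        n_events = nrow(res$events))
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a run against observations
#'
#' Joins predictions to observations by site, cultivar and season and
#' reports fit statistics overall and in the damage groupings: `initial`
#' (uncorrected predictions, all seasons), `no_damage` (seasons without
#' predicted events), `damaged_uncorrected`, `damaged_corrected` (seasons
#' with events, initial vs FDC predictions), and `full_corrected` (FDC
#' predictions, all seasons).
#'
#' @param results Output of [run_site()] (or a list of such outputs for
#'   several sites).
#' @param observations data.frame with `site_id`, `cultivar`,
#'   `season_year`, `observed_doy`.
#' @return List of class `evaluation_report` with `groups` (named list of
#'   `fit_stats`), `n_matched`, `n_unmatched`.
#' @export
evaluate_run <- function(results, observations) {
  preds <- if (!is.null(results[[1]]$season)) {
    predictions_table(results)
  } else {
    do.call(rbind, lapply(results, predictions_table))
  }
  m <- merge(preds, observations, by = c("site_id", "cultivar", "season_year"))
  if (nrow(m) == 0) stop("no prediction/observation pairs matched")
  damaged <- m$n_events > 0
  groups <- list(
    initial = fit_stats(m$doy_initial, m$observed_doy),
    full_corrected = fit_stats(m$doy_fdc, m$observed_doy))
  if (any(!damaged)) {
    groups$no_damage <- fit_stats(m$doy_initial[!damaged],
                                  m$observed_doy[!damaged])
  }
  if (any(damaged)) {
    groups$damaged_uncorrected <- fit_stats(m$doy_initial[damaged],
                                            m$observed_doy[damaged])
    groups$damaged_corrected <- fit_stats(m$doy_fdc[damaged],
                                          m$observed_doy[damaged])
  }
  structure(list(groups = groups, n_matched = nrow(m),
                 n_unmatched = nrow(observations) - nrow(m)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d matched, %d unmatched\n",
              x$n_matched, x$n_unmatched))
  for (g in names(x$groups)) {
    cat(sprintf("  %-20s", g)); print(x$groups[[g]])
  }
  invisible(x)
}
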