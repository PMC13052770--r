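# Condition-level aggregation and pipeline orchestration.

#' Walk-type fractions and motility distributions per condition
#'
#' @param classifications List of `track_classification` objects (one
#'   condition; see [classify_tracks]).
#' @param condition Condition label; defaults to the label carried by the
#'   classifications.
#' @param step_stats Optional per-track statistics data.frame
#'   ([summarize_tracks]) whose `median_speed` is summarized alongside.
#' @return An object of class `population_summary`: `condition`, `n_tracks`,
#'   `model_fractions` (constrained/brownian/prw/unclassified, summing to 1),
#'   and `stat_distributions` (median and IQR of speed, rmc, persistence
#'   speed/time over classified tracks).
#' @export
model_fractions <- function(classifications, condition = NULL,
                            step_stats = NULL) {
  if (!length(classifications))
    stop("model_fractions: empty classification list", call. = FALSE)
  stopifnot(all(vapply(classifications, inherits, logical(1),
                       "track_classification")))
  if (is.null(condition))
    condition <- classifications[[1L]]$condition %||% "default"
  best <- vapply(classifications, `[[`, character(1), "best_model")
  levels <- c("constrained", "brownian", "prw", "unclassified")
  counts <- table(factor(best, levels = levels))
  n <- length(best)
  fractions <- as.numeric(counts) / n
  names(fractions) <- levels
  if (fractions[["unclassified"]] == 1)
    warning("model_fractions: all tracks unclassified")

  mot <- do.call(rbind, lapply(classifications, derive_motility))
  summarize_num <- function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(list(median = NA_real_, iqr = NA_real_,
                                n = 0L))
    list(median = median(v), iqr = unname(diff(quantile(v, c(0.25, 0.75)))),
         n = length(v))
  }
  dists <- list(
    rmc = summarize_num(mot$rmc),
    effective_coefficient = summarize_num(mot$effective_coefficient),
    persistence_speed = summarize_num(mot$persistence_speed),
    persistence_time = summarize_num(mot$persistence_time))
  if (!is.null(step_stats))
    dists$median_speed <- summarize_num(step_stats$median_speed)

  structure(list(condition = condition, n_tracks = n,
                 model_fractions = fractions, stat_distributions = dists),
            class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary> %s: %d tracks\n", x$condition, x$n_tracks))
  f <- x$model_fractions
  cat(sprintf("  fractions: constrained %.3f | brownian %.3f | prw %.3f | unclassified %.3f\n",
              f[["constrained"]], f[["brownian"]], f[["prw"]],
              f[["unclassified"]]))
  invisible(x)
}

#' Origin-aligned trajectories for windrose plots
#'
#' Translates every track so its first position is the origin (no rotation),
#' the conventional windrose overlay of dispersal.
#'
#' @param tracks A [track_collection].
#' @return A data.frame with columns `condition`, `track_id`, `t_min`,
#'   `x_um`, `y_um`; every track starts at (0, 0).
#' @export
windrose <- function(tracks) {
  stopifnot(inherits(tracks, "track_collection"))
  if (!length(tracks$tracks))
    return(data.frame(condition = character(), track_id = character(),
                      t_min = numeric(), x_um = numeric(), y_um = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(tracks$tracks, function(tr) {
    data.frame(condition = tr$condition, track_id = tr$track_id,
               t_min = tr$t, x_um = tr$x - tr$x[1L], y_um = tr$y - tr$y[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# classification list -> tidy per-track table (AICc deltas + parameters)
.classification_table <- function(classifications) {
  do.call(rbind, lapply(classifications, function(cls) {
    mot <- derive_motility(cls)
    d <- cls$delta_aicc
    ai <- vapply(cls$fits, `[[`, numeric(1), "aicc")
    data.frame(mot,
               delta_aicc_brownian = unname(d[["brownian"]]),
               delta_aicc_constrained = unname(d[["constrained"]]),
               delta_aicc_prw = unname(d[["prw"]]),
               aicc_brownian = unname(ai[["brownian"]]),
               aicc_constrained = unname(ai[["constrained"]]),
               aicc_prw = unname(ai[["prw"]]),
               stringsAsFactors = FALSE)
  }))
}

#' Run the full motility pipeline
#'
#' Read -> filter -> step statistics -> MSD -> classification -> summaries.
#' Writes, under `config$outdir`: `tracks_filtered.csv`, `track_stats.csv`,
#' `msd_curves.csv` (long format), `classifications.csv`, `windrose.csv`,
#' `summary.json`, and `run_log.txt` (versions, configuration echo, filter
#' report; timestamps live only in the log so `summary.json` is
#' byte-reproducible). Any stage error aborts with a stage-tagged message and
#' removes partial outputs.
#'
#' @param config A list (or path to a JSON file encoding one) with elements:
#'   `input` (path), `input_format` (`"csv"` or `"trackmate"`), optional
#'   `filter` (arguments for [track_filter_config]), optional
#'   `max_lag_fraction`, `fit_fraction`, `powerlaw` (logical), and `outdir`.
#' @return Invisibly, a list with the filtered tracks, statistics,
#'   classifications, per-condition summaries, and output paths.
#' @export
run_motility_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("[config] pipeline config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  if (is.null(config$input) || is.null(config$outdir))
    stop("[config] pipeline config needs 'input' and 'outdir'", call. = FALSE)
  fmt <- config$input_format %||% "csv"
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fail <- function(stage, e) {
    unlink(written)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  }
  emit <- function(file) {
    path <- file.path(config$outdir, file)
    written <<- c(written, path)
    path
  }

  tracks <- tryCatch({
    if (!file.exists(config$input)) stop("input file not found: ", config$input)
    switch(fmt,
           csv = read_tracks_csv(config$input),
           trackmate = read_trackmate_xml(config$input),
           stop("unknown input_format: ", fmt))
  }, error = function(e) fail("read", e))

  filtered <- tryCatch({
    fc <- do.call(track_filter_config, as.list(config$filter %||% list()))
    apply_track_filters(tracks, fc)
  }, error = function(e) fail("filter", e))

  stats_df <- tryCatch(summarize_tracks(filtered),
                       error = function(e) fail("stats", e))

  res <- tryCatch({
    mlf <- config$max_lag_fraction %||% 1.0
    ff <- config$fit_fraction %||% 0.4
    curves <- lapply(filtered$tracks, function(tr)
      truncate_for_fit(compute_msd(tr, mlf), ff))
    cls <- lapply(curves, classify_track)
    pl <- if (isTRUE(config$powerlaw))
      lapply(curves, fit_power_law) else NULL
    list(curves = curves, cls = cls, pl = pl)
  }, error = function(e) fail("msd", e))

  out <- tryCatch({
    write_tracks_csv(filtered, emit("tracks_filtered.csv"))
    data.table::fwrite(stats_df, emit("track_stats.csv"))

    msd_long <- data.table::rbindlist(lapply(res$curves, function(cu)
      data.table::data.table(track_id = cu$track_id, lag_min = cu$lags,
                             msd_um2 = cu$msd, n_pairs = cu$n_pairs,
                             fitted = seq_along(cu$lags) <= cu$fitted_window)))
    data.table::fwrite(msd_long, emit("msd_curves.csv"))

    cls_df <- .classification_table(res$cls)
    if (!is.null(res$pl)) {
      cls_df$powerlaw_alpha <- vapply(res$pl, function(f)
        f$params[["alpha"]], numeric(1))
      cls_df$powerlaw_A <- vapply(res$pl, function(f)
        f$params[["A"]], numeric(1))
    }
    data.table::fwrite(cls_df, emit("classifications.csv"))

    data.table::fwrite(windrose(filtered), emit("windrose.csv"))

    by_cond <- split(res$cls,
                     vapply(res$cls, `[[`, character(1), "condition"))
    stats_by_cond <- split(stats_df, stats_df$condition)
    summaries <- lapply(names(by_cond), function(cd)
      model_fractions(by_cond[[cd]], condition = cd,
                      step_stats = stats_by_cond[[cd]]))
    names(summaries) <- names(by_cond)
    json <- lapply(summaries, function(s)
      list(n_tracks = s$n_tracks,
           model_fractions = as.list(s$model_fractions),
           stat_distributions = s$stat_distributions))
    jsonlite::write_json(json, emit("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    cfg_canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    log_lines <- c(
      sprintf("synaptrack %s | R %s",
              as.character(utils::packageVersion("synaptrack")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      sprintf("config: %s", cfg_canon),
      sprintf("config md5: %s", .md5_string(cfg_canon)),
      sprintf("filter report: %s",
              jsonlite::toJSON(filtered$metadata$filter_report,
                               auto_unbox = TRUE)))
    writeLines(log_lines, emit("run_log.txt"))
    list(summaries = summaries, paths = written)
  }, error = function(e) fail("write", e))

  invisible(list(tracks = filtered, stats = stats_df,
                 classifications = res$cls, summaries = out$summaries,
                 paths = out$paths))
}

.md5_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}
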