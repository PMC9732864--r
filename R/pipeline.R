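#' Pipeline configuration
#'
#' @param input_dir directory holding a cohort (as written by
#'   [make_cohort()]): `patients/<id>/{lesion.nii.gz,surface.ply,
#'   electrodes.tsv}` plus `events.csv`, `artifacts.csv`, `patients.csv`.
#'   May be `NULL` when `sim_spec` is given, in which case the cohort is
#'   simulated into `out_dir/cohort` first.
#' @param out_dir output directory for the report bundle.
#' @param sim_spec optional [cohort_spec()] for the simulate stage.
#' @param distance_families subset of `c("edge", "com", "geo")`.
#' @param montage_direction `"row"` or `"column"`.
#' @param n_boot bootstrap resamples for regression CIs.
#' @param alpha significance level.
#' @param seed integer seed (simulation and bootstraps).
#' @param use_cache reuse a previously simulated cohort and computed
#'   channel table when the configuration hash matches (geodesics dominate
#'   runtime).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, out_dir, sim_spec = NULL,
                            distance_families = c("edge", "com", "geo"),
                            montage_direction = "row",
                            n_boot = 1000L, alpha = 0.05, seed = 1L,
                            use_cache = TRUE) {
  if (is.null(input_dir) && is.null(sim_spec))
    stop("either input_dir or sim_spec is required")
  if (!all(distance_families %in% c("edge", "com", "geo")))
    stop("distance_families must be a subset of edge/com/geo")
  if (n_boot < 1L) stop("bootstrap count must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(input_dir = input_dir, out_dir = out_dir, sim_spec = sim_spec,
                 distance_families = distance_families,
                 montage_direction = montage_direction,
                 n_boot = as.integer(n_boot), alpha = alpha,
                 seed = as.integer(seed), use_cache = isTRUE(use_cache)),
            class = "pipeline_config")
}

# small stable polynomial hash of a config (for stage caching / the manifest)
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                        auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

dist_col <- c(edge = "d_edge_mm", com = "d_com_mm", geo = "d_geo_mm")

#' Run the full lesion-distance analysis pipeline
#'
#' Orchestrates simulate (optional), localize (read electrode tables and
#' extrapolate hidden electrodes on the surface), distances (bipolar
#' midpoints and the selected lesion-distance families), rates (event
#' logs to per-channel rates with artifact exclusion), fit
#' (pathology-stratified HC3 regressions for each distance family and the
#' family comparison), moderation (pathology type and lesion volume),
#' D-max and Welch's ANOVA, fast ripple logistic occurrence, and report
#' writing. Every excluded channel is logged with its reason.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the channel table and all result
#'   objects; the report bundle is written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- character()
  logmsg <- function(stage, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  ## -- simulate ------------------------------------------------------------
  input_dir <- config$input_dir
  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "cohort")
    marker <- file.path(input_dir, ".hash")
    if (config$use_cache && file.exists(marker) &&
        identical(readLines(marker, warn = FALSE), hash)) {
      logmsg("simulate", "reusing cached cohort in %s", input_dir)
    } else {
      logmsg("simulate", "generating synthetic cohort (seed %d)", config$seed)
      make_cohort(config$sim_spec, out_dir = input_dir, seed = config$seed)
      writeLines(hash, marker)
    }
  }
  if (!dir.exists(input_dir))
    stop("pipeline stage 'simulate/input': missing input directory: ", input_dir)

  ## -- localize + distances (cached jointly on the config hash) ------------
  chan_path <- file.path(out_dir, "channel_table.csv")
  marker2 <- file.path(out_dir, ".channels_hash")
  if (config$use_cache && file.exists(chan_path) && file.exists(marker2) &&
      identical(readLines(marker2, warn = FALSE), hash)) {
    logmsg("distances", "reusing cached channel table")
    channels <- utils::read.csv(chan_path, stringsAsFactors = FALSE)
  } else {
    channels <- compute_channel_table(input_dir, config, logmsg)
    utils::write.csv(format_channel_table(channels), chan_path,
                     row.names = FALSE, quote = FALSE)
    writeLines(hash, marker2)
    channels <- utils::read.csv(chan_path, stringsAsFactors = FALSE)
  }

  ## -- rates ---------------------------------------------------------------
  needed <- c("events.csv", "artifacts.csv", "patients.csv")
  missing <- needed[!file.exists(file.path(input_dir, needed))]
  if (length(missing))
    stop("pipeline stage 'rates': missing inputs: ",
         paste(file.path(input_dir, missing), collapse = ", "))
  events <- utils::read.csv(file.path(input_dir, "events.csv"),
                            stringsAsFactors = FALSE)
  artifacts <- utils::read.csv(file.path(input_dir, "artifacts.csv"),
                               stringsAsFactors = FALSE)
  patients <- utils::read.csv(file.path(input_dir, "patients.csv"),
                              stringsAsFactors = FALSE)
  rates <- compute_rates(events, channels, artifacts = artifacts)
  if (nrow(artifacts))
    for (i in seq_len(nrow(artifacts)))
      log_lines <- c(log_lines, sprintf("[rates] excluded %s/%s/%s: artifact",
                                        artifacts$patient_id[i],
                                        artifacts$recording_id[i],
                                        artifacts$channel_id[i]))
  logmsg("rates", "%d channels included, %d excluded as artifactual",
         nrow(rates), nrow(artifacts))
  key <- function(d) paste(d$patient_id, d$recording_id, d$channel_id, sep = "\r")
  channels <- channels[match(key(rates), key(channels)), ]
  channels <- cbind(channels,
                    rates[, c("epoch_min", unname(RATE_COLS)), drop = FALSE])
  channels$pathology <- patients$pathology[match(channels$patient_id,
                                                 patients$patient_id)]
  channels$lesion_volume_cm3 <-
    patients$lesion_volume_cm3[match(channels$patient_id, patients$patient_id)]
  rownames(channels) <- NULL

  ## -- fit -----------------------------------------------------------------
  logmsg("fit", "pathology-stratified HC3 regressions (%d bootstrap resamples)",
         config$n_boot)
  fits <- fit_regressions(channels, config)
  fam_comp <- compare_families(fits, config$alpha)

  ## -- moderation ----------------------------------------------------------
  moder <- fit_moderations(channels, config$alpha)

  ## -- dmax + Welch --------------------------------------------------------
  dm <- dmax(channels)
  dm$pathology <- patients$pathology[match(dm$patient_id, patients$patient_id)]
  welch <- NULL
  groups <- split(dm$distance_mm, dm$event_type)
  groups <- groups[vapply(groups, function(g)
    length(g) >= 2L && stats::var(g) > 0, logical(1L))]
  if (length(groups) >= 2L) welch <- welch_anova(groups)
  vst <- visual_slope_table(dm)

  ## -- logistic fast ripple occurrence -------------------------------------
  logistic <- list()
  occ <- channels$fr_rate > 0
  if ("d_edge_mm" %in% names(channels) && length(unique(occ)) == 2L)
    logistic$overall <- logistic_occurrence(occ, channels$d_edge_mm)
  for (g in unique(channels$pathology)) {
    sel <- channels$pathology == g
    if (length(unique(occ[sel])) == 2L)
      logistic[[g]] <- tryCatch(
        logistic_occurrence(occ[sel], channels$d_edge_mm[sel]),
        error = function(e) NULL)
  }

  ## -- report --------------------------------------------------------------
  utils::write.csv(format_channel_table(channels),
                   file.path(out_dir, "channel_table_rates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_channel_table(fits),
                   file.path(out_dir, "regression_results.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_channel_table(fam_comp),
                   file.path(out_dir, "distance_family_comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_channel_table(dm), file.path(out_dir, "dmax.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_channel_table(summarize_rates(channels)),
                   file.path(out_dir, "rate_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  results <- list(moderation = moder, welch = welch, logistic = logistic,
                  visual_slopes = vst)
  jsonlite::write_json(strip_for_json(results),
                       file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  manifest <- list(package_version = as.character(utils::packageVersion("ecoglesion")),
                   config_hash = hash, seed = config$seed,
                   n_boot = config$n_boot, alpha = config$alpha,
                   distance_families = config$distance_families,
                   montage_direction = config$montage_direction,
                   n_channels = nrow(channels))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(channels = channels, fits = fits,
                 family_comparison = fam_comp, moderation = moder,
                 dmax = dm, welch = welch, logistic = logistic,
                 visual_slopes = vst, out_dir = out_dir))
}

# drop matrices/vcov so the JSON report stays compact
strip_for_json <- function(x) {
  if (inherits(x, "ecog_moderation"))
    return(list(moderator_kind = x$moderator_kind,
                interaction_F = x$interaction_F, df_num = x$df_num,
                df_den = x$df_den, p_value = x$p_value,
                simple_slopes = x$simple_slopes, n = x$n))
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(x, strip_for_json))
  x
}

# localize + distances: read per-patient files, extrapolate hidden
# electrodes, build the montage, compute the selected distance families
compute_channel_table <- function(input_dir, config, logmsg) {
  pdirs <- sort(list.dirs(file.path(input_dir, "patients"), recursive = FALSE))
  if (!length(pdirs))
    stop("pipeline stage 'localize': no patient directories under ",
         file.path(input_dir, "patients"))
  fams <- config$distance_families
  out <- list()
  for (pdir in pdirs) {
    patient_id <- basename(pdir)
    need <- file.path(pdir, c("lesion.nii.gz", "surface.ply", "electrodes.tsv"))
    if (!all(file.exists(need)))
      stop("pipeline stage 'localize': missing inputs: ",
           paste(need[!file.exists(need)], collapse = ", "))
    lesion <- read_lesion_nifti(need[1L])
    surface <- read_ply(need[2L])
    tab <- utils::read.delim(need[3L], stringsAsFactors = FALSE)
    graph <- if ("geo" %in% fams) surface_graph(surface) else NULL
    for (aid in unique(tab$array_id)) {
      at <- tab[tab$array_id == aid, , drop = FALSE]
      at <- at[order(at$row, at$col), , drop = FALSE]
      nr <- max(at$row); nc <- max(at$col)
      co <- matrix(NA_real_, nr * nc, 3L)
      i <- (at$row - 1L) * nc + at$col
      co[i, ] <- as.matrix(at[, c("x_mm", "y_mm", "z_mm")])
      arr <- electrode_array(aid, nr, nc, co, visible = at$visible[order(i)] == 1L,
                             nominal_spacing = config$sim_spec$nominal_spacing %||% 10)
      n_missing <- sum(!stats::complete.cases(co))
      arr <- tryCatch(extrapolate_grid(arr, surface), error = function(e) {
        logmsg("localize", "excluded array %s: unlocalizable (%s)", aid,
               conditionMessage(e))
        NULL
      })
      if (is.null(arr)) next
      if (n_missing > 0L)
        logmsg("localize", "array %s: extrapolated %d hidden electrodes",
               aid, n_missing)
      mont <- build_montage(arr, direction = config$montage_direction)
      mids <- as.matrix(mont[, c("mid_x", "mid_y", "mid_z")])
      ch <- data.frame(patient_id = patient_id,
                       recording_id = at$recording_id[1L],
                       channel_id = mont$channel_id,
                       mid_x = mids[, 1L], mid_y = mids[, 2L],
                       mid_z = mids[, 3L], stringsAsFactors = FALSE)
      if ("edge" %in% fams) ch$d_edge_mm <- euclidean_edge_distance(mids, lesion)
      if ("com" %in% fams) ch$d_com_mm <- euclidean_com_distance(mids, lesion)
      if ("geo" %in% fams)
        ch$d_geo_mm <- geodesic_distance(mids, lesion, surface, graph = graph,
                                         labels = mont$channel_id)
      out[[length(out) + 1L]] <- ch
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one HC3 regression per pathology x event type x distance family,
# plus whole-cohort rows; cells without events get NA (the em-dash cells)
fit_regressions <- function(channels, config) {
  fams <- config$distance_families
  groups <- c("all", sort(unique(channels$pathology)))
  rows <- list()
  bseed <- config$seed
  for (g in groups) {
    sel <- if (g == "all") rep(TRUE, nrow(channels)) else channels$pathology == g
    for (ty in EVENT_TYPES) for (fam in fams) {
      x <- channels[[RATE_COLS[[ty]]]][sel]
      y <- channels[[dist_col[[fam]]]][sel]
      bseed <- (bseed + 7919L) %% .Machine$integer.max
      row <- data.frame(pathology = g, event_type = ty, family = fam,
                        n = sum(sel), slope = NA_real_, hc3_se = NA_real_,
                        F = NA_real_, df_num = NA_integer_, df_den = NA_integer_,
                        p_value = NA_real_, eta_squared = NA_real_,
                        effect_class = NA_character_, ci_low = NA_real_,
                        ci_high = NA_real_, stringsAsFactors = FALSE)
      if (sum(sel) >= 3L && sum(x > 0) > 0L && stats::var(x) > 0) {
        f <- ols_hc3(y, x, n_boot = config$n_boot, seed = bseed)
        row[, c("slope", "hc3_se", "F", "p_value", "eta_squared")] <-
          list(f$slope, f$hc3_se, f$F, f$p_value, f$eta_squared)
        row$df_num <- f$df_num; row$df_den <- f$df_den
        row$effect_class <- f$effect_class
        row$ci_low <- f$boot_ci[1L]; row$ci_high <- f$boot_ci[2L]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# which family shows the largest effect per pathology x event type
compare_families <- function(fits, alpha) {
  fits <- fits[!is.na(fits$eta_squared), , drop = FALSE]
  if (!nrow(fits)) return(data.frame())
  combos <- unique(fits[, c("pathology", "event_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- fits$pathology == combos$pathology[i] &
      fits$event_type == combos$event_type[i]
    d <- fits[sel, , drop = FALSE]
    j <- which.max(d$eta_squared)
    data.frame(pathology = combos$pathology[i],
               event_type = combos$event_type[i],
               best_family = d$family[j], eta_squared = d$eta_squared[j],
               significant = d$p_value[j] <= alpha, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# pathology (categorical) and lesion volume (continuous) moderation of the
# rate-distance relationship, per event type, on the edge distance
fit_moderations <- function(channels, alpha) {
  out <- list()
  for (ty in EVENT_TYPES) {
    x <- channels[[RATE_COLS[[ty]]]]
    y <- channels$d_edge_mm
    usable <- vapply(split(x, channels$pathology), function(v)
      length(v) >= 3L && stats::var(v) > 0, logical(1L))
    keep <- channels$pathology %in% names(usable)[usable]
    res <- list()
    if (sum(usable) >= 2L) {
      res$pathology <- tryCatch(
        moderation(y[keep], x[keep], channels$pathology[keep]),
        error = function(e) NULL)
    }
    if (any(keep) && stats::var(x[keep]) > 0) {
      res$volume <- tryCatch(
        moderation(y[keep], x[keep], channels$lesion_volume_cm3[keep]),
        error = function(e) NULL)
    }
    out[[ty]] <- res
  }
  out
}
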