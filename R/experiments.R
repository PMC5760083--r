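#' Velocity-transient experiment
#'
#' Runs a [transient_protocol()] through the pathway and quantifies, per
#' transient, the response contrast against the decaying background response
#' ([transient_contrasts()]).
#'
#' @param background_tf,transient_tf,contrast,i_mean,n_transients protocol
#'   parameters (see [transient_protocol()]).
#' @param params a [pathway_params()].
#' @param adaptation logical, run with or without motion adaptation.
#' @return list with the `run`, the `contrasts` series, the `enhancement`
#'   score and `bg_decay`, the fractional decay of the background response
#'   from the first to the last inter-transient interval.
#' @export
sim_transients <- function(background_tf = 2, transient_tf = 4,
                           contrast = 0.88, i_mean = 1000, n_transients = 8,
                           params = pathway_params(), adaptation = TRUE) {
  pro <- transient_protocol(background_tf, transient_tf, contrast, i_mean,
                            n_transients)
  run <- run_protocol(pro, params, adaptation = adaptation)
  ct <- transient_contrasts(run)
  list(run = run, contrasts = ct, enhancement = enhancement(ct),
       bg_decay = 1 - ct$r_bg[nrow(ct)] / ct$r_bg[1])
}

#' Temporal-frequency x contrast screening of the enhancement score
#'
#' Runs the full 9 x 5 grid of [parameter_grid()] and tabulates the
#' enhancement score per condition.
#'
#' @inheritParams parameter_grid
#' @param scale duration multiplier in (0, 1]: the transient count is
#'   `round(8 * scale)` (>= 2), shortening every run proportionally.
#' @param params a [pathway_params()].
#' @return data frame with `tf`, `contrast`, `enhancement`, `bg_first`,
#'   `bg_last` per condition.
#' @export
sim_transient_grid <- function(kind = c("increment", "decrement"),
                               i_mean = 1000, scale = 1,
                               params = pathway_params()) {
  kind <- match.arg(kind)
  n_tr <- max(2L, as.integer(round(8 * scale)))
  grid <- parameter_grid(kind, i_mean, n_transients = n_tr)
  rows <- lapply(grid, function(pro) {
    cond <- attr(pro, "condition")
    run <- run_protocol(pro, params)
    # near-zero signed responses (deep low-frequency/low-contrast corner)
    # leave the response contrast undefined; such cells are recorded as NA
    ct <- tryCatch(transient_contrasts(run), error = function(e) NULL)
    data.frame(tf = cond$tf, contrast = cond$contrast,
               enhancement = if (is.null(ct)) NA_real_ else enhancement(ct),
               bg_first = if (is.null(ct)) NA_real_ else ct$r_bg[1],
               bg_last = if (is.null(ct)) NA_real_ else ct$r_bg[nrow(ct)])
  })
  do.call(rbind, rows)
}

segment_window <- function(protocol, role, dt, first = NULL) {
  tab <- segment_table(protocol)
  i <- which(!is.na(tab$role) & tab$role == role)[1]
  t0 <- tab$t0[i]
  t1 <- t0 + protocol$segments$duration[i]
  if (!is.null(first)) t1 <- min(t1, t0 + first)
  c(t0, t1)
}

mean_in_window <- function(run, w) {
  mean(run$lptc[run$time >= w[1] & run$time < w[2]])
}

#' Direction dependence of motion adaptation
#'
#' Runs the [adaptation_protocol()] with PD, ND and orthogonal adaptation
#' and compares the test response (after 4 s of adaptation) with the
#' parameter-identical reference response (before adaptation).
#'
#' @param params a [pathway_params()].
#' @param directions adaptation directions to run.
#' @return list with `summary` (per direction: mean reference, test and
#'   adaptation-period LPTC responses and the `test_ref_ratio`) and the
#'   LPTC `traces`.
#' @export
sim_adaptation_direction <- function(params = pathway_params(),
                                     directions = c("pd", "nd", "orthogonal")) {
  traces <- list()
  rows <- lapply(directions, function(dir) {
    pro <- adaptation_protocol(dir)
    run <- run_protocol(pro, params)
    traces[[dir]] <<- run$lptc
    dt <- params$dt
    data.frame(
      direction = dir,
      ref = mean_in_window(run, segment_window(pro, "reference", dt)),
      test = mean_in_window(run, segment_window(pro, "test", dt)),
      adapt = mean_in_window(run, segment_window(pro, "adaptation", dt))
    )
  })
  s <- do.call(rbind, rows)
  s$test_ref_ratio <- s$test / s$ref
  list(summary = s, traces = traces, dt = params$dt)
}

#' Contrast-gain modulation by motion adaptation
#'
#' Sweeps the contrast of the reference/test grating over logarithmically
#' spaced levels and measures the mean LPTC response over the first 300 ms
#' of the reference period (before adaptation) and of the test period (after
#' 4 s of PD or ND adaptation).  Curves are normalised to the maximum of the
#' before curve; the semi-saturation contrast summarises each curve's
#' horizontal position.
#'
#' The reference/test gratings drift horizontally, so every pixel row is
#' identical; `rows` trims the redundant rows (the LPTC sum scales linearly,
#' and both the normalised curves and semi-saturation points are
#' scale-invariant).
#'
#' @param n_levels number of contrast levels between 0.005 and 1.
#' @param params a [pathway_params()].
#' @param rows grid rows used for the runs.
#' @return list with `levels`, normalised `before`, `after_pd`, `after_nd`
#'   curves (data frames) and the three semi-saturation contrasts in `c50`.
#' @export
sim_contrast_gain <- function(n_levels = 20, params = pathway_params(),
                              rows = 6) {
  levels <- exp(seq(log(0.005), log(1), length.out = n_levels))
  resp <- list(before = numeric(n_levels), pd = numeric(n_levels),
               nd = numeric(n_levels))
  for (dir in c("pd", "nd")) {
    for (i in seq_len(n_levels)) {
      pro <- adaptation_protocol(dir, ref_contrast = levels[i])
      pro$rows <- as.integer(rows)
      run <- run_protocol(pro, params)
      if (dir == "pd") {
        resp$before[i] <-
          mean_in_window(run, segment_window(pro, "reference", params$dt,
                                             first = 0.3))
      }
      resp[[dir]][i] <-
        mean_in_window(run, segment_window(pro, "test", params$dt,
                                           first = 0.3))
    }
  }
  m <- max(resp$before)
  before <- contrast_gain_curve(levels, resp$before, m)
  after_pd <- contrast_gain_curve(levels, resp$pd, m)
  after_nd <- contrast_gain_curve(levels, resp$nd, m)
  list(levels = levels, before = before, after_pd = after_pd,
       after_nd = after_nd,
       c50 = c(before = semisaturation_contrast(before),
               after_pd = semisaturation_contrast(after_pd),
               after_nd = semisaturation_contrast(after_nd)))
}

#' Corridor / decagon flight experiment
#'
#' Builds the 3D scene, renders the flight onto the spherical eye, runs the
#' pathway and computes the lateral (90 deg azimuth) motion-energy series
#' and the per-bar response contrasts.
#'
#' @param wall_distance trajectory-to-wall distance, m (0.55, 2 or 4).
#' @param seed texture seed.
#' @param dynamics `"translation"` (straight, 1 m/s) or `"decagon"`
#'   (saccadic flight of [decagon_trajectory()]).
#' @param params a [pathway_params()].
#' @param i_mean,texture_contrast texture parameters.
#' @param prelude stationary prelude before motion, seconds.
#' @param n_bars bars passed (8; smaller values shorten the flight).
#' @param eye the [eye_model()].
#' @param snapshot_bars bar indices at which full detector maps are stored
#'   (default: first and last passage, the before/after-adaptation pair).
#' @return object of class `corridor_result`: list with `series` (lateral
#'   motion energy, attribute `"time"`), `crossings`, `contrasts`
#'   (a `contrast_series`), `gain` (`C_last - C_first`), `snapshots`,
#'   `lptc`, `a_mean`, `time` and `meta`.
#' @export
sim_corridor <- function(wall_distance = 0.55, seed = 1,
                         dynamics = c("translation", "decagon"),
                         params = pathway_params(), i_mean = 1000,
                         texture_contrast = 0.3, prelude = 0.5, n_bars = 8,
                         eye = eye_model(), snapshot_bars = NULL) {
  dynamics <- match.arg(dynamics)
  if (dynamics == "translation") {
    scene <- corridor_scene(wall_distance, seed, i_mean, texture_contrast,
                            n_bars = n_bars)
    traj <- translation_trajectory(duration = n_bars, speed = 1, dt = 0.01)
  } else {
    scene <- decagon_scene(wall_distance, seed, i_mean, texture_contrast)
    traj <- decagon_trajectory(cycles = n_bars, dt = 0.01)
  }
  crossings <- bar_crossings(scene, traj) + prelude
  stim <- render_eye_sequence(scene, traj, eye, prelude = prelude)
  snapshot_bars <- snapshot_bars %||% c(1L, length(crossings))
  run <- run_pathway(stim, params, adaptation = TRUE,
                     snapshot_times = crossings[snapshot_bars])
  series <- azimuth_energy_series(run, eye, 90)
  contrasts <- bar_contrast_series(series, params$dt, crossings)
  structure(
    list(series = series, crossings = crossings, contrasts = contrasts,
         gain = enhancement(contrasts), snapshots = run$snapshots,
         lptc = run$lptc, a_mean = run$a_mean, time = run$time,
         meta = c(scene$meta, list(dynamics = dynamics, prelude = prelude))),
    class = "corridor_result")
}

#' @export
print.corridor_result <- function(x, ...) {
  cat(sprintf(
    "<corridor_result> %s, wall at %g m, seed %d: %d bar passages\n",
    x$meta$dynamics, x$meta$wall_distance, x$meta$seed, length(x$crossings)))
  cat(sprintf("  bar/background contrast: first %.3f, last %.3f (gain %+.3f)\n",
              x$contrasts$c_resp[1], x$contrasts$c_resp[nrow(x$contrasts)],
              x$gain))
  invisible(x)
}

#' Steady-state temporal-frequency tuning
#'
#' Mean LPTC response over the first second of motion of a constant-velocity
#' grating, across temporal frequencies, with and without motion adaptation.
#' Correlation-type detectors give a bell-shaped curve; the adaptive stage
#' should not shift its peak materially.
#'
#' @param freqs temporal frequencies, Hz.
#' @param contrast,i_mean grating parameters.
#' @param params a [pathway_params()].
#' @param window response window after motion onset, seconds.
#' @return data frame `freq`, `adapted`, `unadapted`, with attribute
#'   `"peaks"`: interpolated peak frequencies (Hz) for both curves.
#' @export
sim_tuning <- function(freqs = c(0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 12.8, 25.6),
                       contrast = 0.88, i_mean = 1000,
                       params = pathway_params(), window = 1) {
  resp <- sapply(c(TRUE, FALSE), function(ad) {
    vapply(freqs, function(f) {
      segs <- rbind(grating_segment(0.5, 0, "stationary", role = "prelude"),
                    grating_segment(window + 0.2, f, "pd", role = "motion"))
      pro <- grating_protocol(3, 360, 19, i_mean, contrast, segs)
      run <- run_protocol(pro, params, adaptation = ad)
      mean_in_window(run, c(0.5, 0.5 + window))
    }, numeric(1))
  })
  df <- data.frame(freq = freqs, adapted = resp[, 1], unadapted = resp[, 2])
  attr(df, "peaks") <- c(adapted = peak_frequency(freqs, df$adapted),
                         unadapted = peak_frequency(freqs, df$unadapted))
  df
}

# Interpolated peak location on a log2-spaced frequency axis (parabolic fit
# around the argmax).  NA if the maximum sits on the boundary (no bell).
peak_frequency <- function(freqs, resp) {
  i <- which.max(resp)
  if (i == 1 || i == length(resp)) return(NA_real_)
  l2 <- log2(freqs)
  num <- resp[i - 1] - resp[i + 1]
  den <- resp[i - 1] - 2 * resp[i] + resp[i + 1]
  delta <- if (den != 0) 0.5 * num / den else 0
  2^(l2[i] + delta * (l2[i + 1] - l2[i]))
}

# --- experiment runner ------------------------------------------------------

#' Available figure-level experiments
#' @export
list_experiments <- function() {
  c("transients", "transient_grid", "adaptation_direction", "contrast_gain",
    "corridor", "corridor_distances", "decagon", "natural_sequence",
    "tuning_curve")
}

#' Run a figure-level experiment and write its results
#'
#' Config-driven wrapper over the `sim_*` functions: builds the stimuli,
#' runs the pathway, runs the analyses and writes tidy CSV results plus a
#' JSON manifest (experiment, config, seed, package version, file
#' checksums).  Identical config and seed give byte-identical results.
#'
#' @param name one of [list_experiments()].
#' @param out_dir output directory (created if needed).
#' @param seed global seed for all texture randomness.
#' @param scale duration/repetition multiplier in (0, 1] for reduced-scale
#'   runs.
#' @param config named list of overrides passed to the underlying `sim_*`
#'   function (e.g. `wall_distance`, `i_mean`, `path` for
#'   `natural_sequence`).
#' @return the result object, invisibly.
#' @export
run_experiment <- function(name, out_dir, seed = 1, scale = 1,
                           config = list()) {
  if (!name %in% list_experiments()) {
    stop("unknown experiment '", name, "'; valid names: ",
         paste(list_experiments(), collapse = ", "))
  }
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop("scale must be in (0, 1]")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  params <- do.call(pathway_params, config$params %||% list())
  n_seeds <- config$n_seeds %||% max(1L, as.integer(round(3 * scale)))
  files <- character(0)
  put <- function(df, fn) {
    path <- file.path(out_dir, fn)
    data.table::fwrite(df, path)
    files <<- c(files, path)
  }

  res <- switch(
    name,
    transients = {
      r <- sim_transients(
        background_tf = config$background_tf %||% 2,
        transient_tf = config$transient_tf %||% 4,
        contrast = config$contrast %||% 0.88,
        i_mean = config$i_mean %||% 1000,
        n_transients = max(2L, as.integer(round(8 * scale))),
        params = params)
      put(data.frame(time = r$run$time, lptc = r$run$lptc), "trace.csv")
      put(as.data.frame(r$contrasts), "contrasts.csv")
      r
    },
    transient_grid = {
      df <- sim_transient_grid(config$kind %||% "decrement",
                               i_mean = config$i_mean %||% 1000,
                               scale = scale, params = params)
      put(df, "grid.csv")
      df
    },
    adaptation_direction = {
      r <- sim_adaptation_direction(params)
      put(r$summary, "summary.csv")
      r
    },
    contrast_gain = {
      r <- sim_contrast_gain(n_levels = config$n_levels %||% 20,
                             params = params)
      put(cbind(condition = "before", r$before), "curve_before.csv")
      put(cbind(condition = "after_pd", r$after_pd), "curve_after_pd.csv")
      put(cbind(condition = "after_nd", r$after_nd), "curve_after_nd.csv")
      r
    },
    corridor = ,
    decagon = {
      r <- sim_corridor(
        wall_distance = config$wall_distance %||% 0.55, seed = seed,
        dynamics = if (name == "decagon") "decagon" else "translation",
        params = params, i_mean = config$i_mean %||% 1000,
        n_bars = max(2L, as.integer(round(8 * scale))))
      put(data.frame(time = attr(r$series, "time"), energy = r$series),
          "series.csv")
      put(as.data.frame(r$contrasts), "contrasts.csv")
      r
    },
    corridor_distances = {
      dists <- config$wall_distances %||% c(0.55, 2, 4)
      rows <- list()
      for (d in dists) {
        for (s in seq_len(n_seeds)) {
          r <- sim_corridor(d, seed = seed + s - 1, params = params,
                            n_bars = max(2L, as.integer(round(8 * scale))))
          rows[[length(rows) + 1L]] <-
            cbind(wall_distance = d, seed = seed + s - 1,
                  as.data.frame(r$contrasts))
        }
      }
      df <- do.call(rbind, rows)
      put(df, "contrasts.csv")
      df
    },
    natural_sequence = {
      if (is.null(config$path)) {
        stop("natural_sequence needs config$path pointing at a stimulus ",
             "directory (see write_stimulus)")
      }
      stim <- read_stimulus(config$path)
      reps <- config$repeats %||% 8
      d <- dim(stim$frames)
      frames <- array(0, c(d[1] * reps, d[2], d[3]))
      for (k in seq_len(reps)) {
        frames[(k - 1) * d[1] + seq_len(d[1]), , ] <- stim$frames
      }
      big <- luminance_seq(frames, stim$dt, stim$azimuth_wrap)
      rep_dur <- d[1] * stim$dt
      snaps <- c(0.5, reps - 0.5) * rep_dur
      run <- run_pathway(big, params, snapshot_times = snaps)
      chg <- local_contrast_change(run$snapshots[[1]]$energy,
                                   run$snapshots[[2]]$energy,
                                   window = config$window %||% 5)
      put(as.data.frame(chg), "change_map.csv")
      put(data.frame(time = run$time, lptc = run$lptc), "trace.csv")
      list(run = run, change_map = chg)
    },
    tuning_curve = {
      df <- sim_tuning(params = params)
      put(df, "tuning.csv")
      df
    })

  manifest <- list(
    experiment = name, seed = seed, scale = scale, config = config,
    package_version = as.character(utils::packageVersion("emdadapt")),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Write a miniature deterministic stimulus fixture
#'
#' Small inputs for tests and demos: a tiny grating clip, a 64 x 64 cloud
#' texture, or a short corridor rendering, all written through the
#' plain-text stimulus interface.
#'
#' @param kind `"grating"`, `"texture"` or `"corridor_clip"`.
#' @param seed texture seed.
#' @param out_dir target directory.
#' @return the output path, invisibly.
#' @export
make_fixture <- function(kind = c("grating", "texture", "corridor_clip"),
                         seed = 1, out_dir) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(
    kind,
    grating = {
      segs <- rbind(grating_segment(0.2, 0, "stationary"),
                    grating_segment(0.8, 2, "pd"))
      pro <- grating_protocol(3, 36, 9, 1000, 0.5, segs)
      write_stimulus(render_grating(pro, dt = 0.01), out_dir)
    },
    texture = {
      tx <- cloud_texture(c(64, 64), 1, seed = seed)
      data.table::fwrite(data.table::as.data.table(tx$luminance),
                         file.path(out_dir, "texture.csv"), col.names = FALSE)
      jsonlite::write_json(
        list(world_size = tx$world_size, i_mean = tx$i_mean,
             contrast = tx$contrast, seed = tx$seed),
        file.path(out_dir, "meta.json"), auto_unbox = TRUE, digits = NA)
    },
    corridor_clip = {
      scene <- corridor_scene(0.55, seed, n_bars = 2)
      traj <- translation_trajectory(duration = 1, dt = 0.01)
      eye <- eye_model(azimuth = c(60, 120), elevation = c(-40, 40))
      write_stimulus(render_eye_sequence(scene, traj, eye), out_dir)
    })
  invisible(out_dir)
}
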