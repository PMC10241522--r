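#' Default run configuration
#'
#' All knobs of the end-to-end synthetic study in one list: master seed,
#' temperatures, protocol geometry, drug panel, preset pair, morphology and
#' imaging recipes, and output options. Any entry can be overridden through
#' `...` or by a YAML file via [load_config()].
#'
#' @param seed master integer seed
#' @param ... overrides of the defaults
#' @return a `run_config` list
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    presets = c("RAPN-like", "AId-like"),
    temperatures = c(24, 40),
    spont_duration = 2000,      # ms
    discard_ms = 300,           # settle transient before feature extraction
    fi_steps = seq(0, 500, by = 100),  # pA
    fi_duration = 1000,         # ms
    drugs = c("TEA", "4AP", "AUT5"),
    vclamp_tests = c(-30, 0),   # mV
    vclamp_duration = 200,      # ms
    vclamp_holding = -80,       # mV
    passive_noise_sd = 0.2,     # acquisition noise on the recorded V (mV)
    passive_n_seeds = 5,
    morph = list(
      `RAPN-like` = list(spine_density = 0.4, spine_radius = 0.40,
                         n_bifurcations = 2),
      `AId-like` = list(spine_density = 0.9, spine_radius = 0.28,
                        n_bifurcations = 3)),
    ish = list(ra_cells = 60, aid_cells = 25, ra_intensity = 160,
               aid_intensity = 120, background = 40, noise_sd = 2),
    stats_n_per_group = 12,
    outdir = NULL,
    overwrite = FALSE)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("invalid config key: ", nm)
    cfg[[nm]] <- ov[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and overlays it on [default_config()]; unknown keys
#' fail fast with the offending name.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(default_config, c(list(seed = raw$seed %||% 1L),
                            raw[setdiff(names(raw), "seed")]))
}

spont_features_row <- function(params, temperature, cfg) {
  tr <- simulate_spontaneous(params, cfg$spont_duration, temperature)
  ft <- trace_ap_features(tr, discard_ms = cfg$discard_ms)
  data.frame(preset = params$label, temperature = temperature,
             spont_rate_hz = attr(ft, "spont_rate_hz"),
             threshold = mean(ft$threshold), peak = mean(ft$peak),
             amplitude = mean(ft$amplitude),
             half_width = mean(ft$half_width), ahp = mean(ft$ahp),
             max_depol_rate = mean(ft$max_depol_rate),
             max_repol_rate = mean(ft$max_repol_rate),
             n_spikes = nrow(ft))
}

stage_ephys <- function(cfg) {
  rows <- list()
  for (nm in cfg$presets) for (temp in cfg$temperatures)
    rows[[length(rows) + 1]] <- spont_features_row(make_preset(nm), temp, cfg)
  do.call(rbind, rows)
}

stage_fi <- function(cfg, temperature = 24) {
  pr <- step_protocol("current-clamp", steps = cfg$fi_steps,
                      step_duration = cfg$fi_duration, pre_duration = 100,
                      post_duration = 50, seed = cfg$seed)
  rows <- lapply(cfg$presets, function(nm) {
    fi <- fi_analysis(simulate_current_clamp(make_preset(nm), pr,
                                             temperature))
    fi$preset <- nm; fi$temperature <- temperature
    fi
  })
  do.call(rbind, rows)
}

stage_pharm <- function(cfg, temperature = 24) {
  pr <- step_protocol("current-clamp", steps = max(cfg$fi_steps),
                      step_duration = cfg$fi_duration, pre_duration = 100,
                      post_duration = 50, seed = cfg$seed)
  rows <- list()
  for (drug in cfg$drugs) for (nm in cfg$presets) {
    p0 <- make_preset(nm)
    p1 <- apply_drug(p0, drug_preset(drug))
    f0 <- trace_ap_features(simulate_spontaneous(p0, cfg$spont_duration,
                                                 temperature),
                            discard_ms = cfg$discard_ms)
    f1 <- trace_ap_features(simulate_spontaneous(p1, cfg$spont_duration,
                                                 temperature),
                            discard_ms = cfg$discard_ms)
    e0 <- fi_analysis(simulate_current_clamp(p0, pr, temperature))
    e1 <- fi_analysis(simulate_current_clamp(p1, pr, temperature))
    rows[[length(rows) + 1]] <- data.frame(
      drug = drug, preset = nm, temperature = temperature,
      half_width_pre = mean(f0$half_width),
      half_width_post = mean(f1$half_width),
      half_width_fold = fold_change(mean(f0$half_width),
                                    mean(f1$half_width)),
      repol_pre = mean(f0$max_repol_rate),
      repol_post = mean(f1$max_repol_rate),
      repol_fold = fold_change(mean(f0$max_repol_rate),
                               mean(f1$max_repol_rate)),
      evoked_rate_pre = e0$rate_hz[1], evoked_rate_post = e1$rate_hz[1],
      evoked_rate_change_pct = percent_change(e0$rate_hz[1], e1$rate_hz[1]),
      steady_state_pre = e0$steady_state_hz[1],
      steady_state_post = e1$steady_state_hz[1],
      steady_state_change_pct = percent_change(e0$steady_state_hz[1],
                                               e1$steady_state_hz[1]))
  }
  do.call(rbind, rows)
}

stage_passive <- function(cfg) {
  rows <- list()
  for (nm in cfg$presets) {
    p <- make_preset(nm)
    cell <- passive_cell(p$capacitance, p$leak$g, p$leak$e)
    pr <- step_protocol("current-clamp", steps = c(-100, -60, -30),
                        step_duration = 300, pre_duration = 100,
                        post_duration = 100)
    clean <- simulate_current_clamp(cell, pr)
    for (k in seq_len(cfg$passive_n_seeds)) {
      set.seed(cfg$seed + 1000L * k)
      traces <- lapply(clean, function(tr) {
        # white acquisition noise on the recorded potential
        tr$samples <- tr$samples +
          stats::rnorm(length(tr$samples), 0, cfg$passive_noise_sd)
        tr
      })
      est <- passive_properties(traces)
      est$preset <- nm; est$replicate <- k
      est$true_c <- p$capacitance; est$true_r <- 1000 / p$leak$g
      rows[[length(rows) + 1]] <- est
    }
  }
  do.call(rbind, rows)
}

stage_vclamp <- function(cfg) {
  pr <- step_protocol("voltage-clamp", baseline = cfg$vclamp_holding,
                      steps = cfg$vclamp_tests,
                      step_duration = cfg$vclamp_duration,
                      pre_duration = 50, post_duration = 50,
                      seed = cfg$seed)
  rows <- list()
  for (nm in cfg$presets) {
    p <- make_preset(nm)
    pre <- simulate_voltage_clamp(p, pr, na_disabled = TRUE,
                                  leak_subtract = TRUE)
    post <- simulate_voltage_clamp(apply_drug(p, drug_preset("TEA")), pr,
                                   na_disabled = TRUE, leak_subtract = TRUE)
    for (v in names(pre)) {
      m0 <- vclamp_metrics(pre[[v]])
      m1 <- vclamp_metrics(post[[v]])
      ms <- vclamp_metrics(subtract_currents(pre[[v]], post[[v]]))
      rows[[length(rows) + 1]] <- data.frame(
        preset = nm, test_mv = as.numeric(v),
        i200_pre = m0$i_sustained, i200_post = m1$i_sustained,
        i200_tea_sensitive = ms$i_sustained,
        a_peak_tea_sensitive = ms$a_type_peak,
        time_to_peak_tea_sensitive = ms$time_to_peak,
        inactivation_ratio_tea_sensitive = ms$inactivation_ratio)
    }
  }
  do.call(rbind, rows)
}

stage_morpho <- function(cfg) {
  rows <- list()
  for (nm in cfg$presets) {
    mcfg <- cfg$morph[[nm]]
    spec <- morph_spec(spine_density = mcfg$spine_density,
                       spine_radius = mcfg$spine_radius,
                       n_bifurcations = mcfg$n_bifurcations,
                       seed = cfg$seed)
    gen <- generate_swc(spec)
    dg <- dendrite_geometry(gen$morphology, voxel_size = 0.2)
    sp <- spine_geometry(gen$morphology)
    st <- generate_soma_stack(spec$soma_radius, slice_thickness = 0.25)
    first_rad <- rep(spec$radius, spec$n_primary)
    sg <- soma_geometry(st, first_dendrite_radius = first_rad)
    rep_ <- summarize_morphometry(soma = sg, dendrite = dg, spines = sp)
    rep_$preset <- nm
    rep_$sholl_peak <- max(sholl(gen$morphology)$crossings)
    rep_$spine_density_segment <-
      spine_density(gen$morphology, "segment")$density
    rep_$spine_density_rolling <-
      spine_density(gen$morphology, "rolling")$density
    rows[[length(rows) + 1]] <- rep_
  }
  do.call(rbind, rows)
}

stage_ish <- function(cfg) {
  icfg <- cfg$ish
  place_cells <- function(n, intensity, seed) {
    set.seed(seed)
    grid <- expand.grid(x = seq(20, 380, by = 25), y = seq(20, 380, by = 25))
    # keep the background control corner free of label, as in real material
    # where the control area is chosen over unexpressing tissue
    grid <- grid[!(grid$x < 80 & grid$y < 80), ]
    pick <- grid[sample(nrow(grid), n), ]
    data.frame(x = pick$x, y = pick$y, radius = 5, intensity = intensity)
  }
  ra <- generate_ish_image(400, 400, icfg$background,
                           place_cells(icfg$ra_cells, icfg$ra_intensity,
                                       cfg$seed),
                           noise_sd = icfg$noise_sd, seed = cfg$seed)
  aid <- generate_ish_image(400, 400, icfg$background,
                            place_cells(icfg$aid_cells, icfg$aid_intensity,
                                        cfg$seed + 1L),
                            noise_sd = icfg$noise_sd, seed = cfg$seed + 1L)
  win <- list(x = 100, y = 100, width = 200, height = 200)
  bgw <- list(x = 0, y = 0, width = 60, height = 60)
  od_ra <- window_od(ra, win, bgw)
  od_aid <- window_od(aid, win, bgw)
  data.frame(
    ra_net_od = od_ra$net_od, aid_net_od = od_aid$net_od,
    od_ratio = expression_ratio(od_ra$net_od, od_aid$net_od),
    ra_cells = as.integer(count_labeled_cells(ra, od_ra$background_od)),
    aid_cells = as.integer(count_labeled_cells(aid, od_aid$background_od)),
    cell_ratio = as.integer(count_labeled_cells(ra, od_ra$background_od)) /
      as.integer(count_labeled_cells(aid, od_aid$background_od)))
}

stage_stats <- function(cfg, ephys_tbl = NULL) {
  # group comparison on per-cell half-widths: cells emulated by jittered
  # conductance densities plus current noise
  set.seed(cfg$seed)
  sample_cells <- function(nm, n) {
    vapply(seq_len(n), function(i) {
      p <- make_preset(nm)
      for (ch in c("nav", "kv_low", "kv3", "kv_a"))
        p[[ch]]$g <- p[[ch]]$g * exp(stats::rnorm(1, 0, 0.08))
      tr <- simulate_spontaneous(p, 1200, 24)
      ft <- trace_ap_features(tr, discard_ms = cfg$discard_ms)
      if (nrow(ft) == 0) NA_real_ else mean(ft$half_width)
    }, numeric(1))
  }
  a <- stats::na.omit(sample_cells("RAPN-like", cfg$stats_n_per_group))
  b <- stats::na.omit(sample_cells("AId-like", cfg$stats_n_per_group))
  cmp <- compare_groups(a, b)
  cmp$comparison <- "half_width RAPN-like vs AId-like (24C)"
  cmp$mean_a <- mean(a); cmp$mean_b <- mean(b)
  cmp
}

#' Run the full synthetic study end to end
#'
#' Simulates both presets, extracts spontaneous and evoked firing metrics,
#' estimates passive properties, decomposes voltage-clamp currents,
#' measures synthetic morphologies and ISH images, and compares the two
#' neuron classes; writes per-stage CSVs and a JSON summary when an output
#' directory is configured. Deterministic for a fixed config.
#'
#' @param config a `run_config` from [default_config()] or [load_config()]
#' @param stages subset of
#'   `c("ephys", "fi", "pharm", "passive", "vclamp", "morpho", "ish",
#'   "stats")`
#' @return named list of per-stage tables (skipped stages are `NULL`),
#'   plus `config`
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("ephys", "fi", "pharm", "passive",
                                    "vclamp", "morpho", "ish", "stats")) {
  stopifnot(inherits(config, "run_config"))
  all_stages <- c("ephys", "fi", "pharm", "passive", "vclamp", "morpho",
                  "ish", "stats")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  res <- stats::setNames(vector("list", length(all_stages)), all_stages)
  t0 <- Sys.time()
  log_line <- function(...) message(sprintf("[%s] %s",
                                            format(Sys.time(), "%H:%M:%S"),
                                            sprintf(...)))
  for (st in all_stages) {
    if (!st %in% stages) next
    log_line("stage %-7s (seed %d) ...", st, config$seed)
    res[[st]] <- switch(st,
      ephys = stage_ephys(config), fi = stage_fi(config),
      pharm = stage_pharm(config), passive = stage_passive(config),
      vclamp = stage_vclamp(config), morpho = stage_morpho(config),
      ish = stage_ish(config), stats = stage_stats(config))
  }
  log_line("done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  res$config <- config
  if (!is.null(config$outdir)) write_report(res, config)
  res
}

write_report <- function(res, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  for (st in setdiff(names(res), "config")) {
    if (is.null(res[[st]])) next
    path <- file.path(config$outdir, paste0(st, ".csv"))
    if (file.exists(path) && !config$overwrite)
      stop("refusing to overwrite ", path, " (set overwrite = TRUE)")
    utils::write.csv(res[[st]], path, row.names = FALSE)
  }
  summary <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("arcoephys")),
    stages = lapply(res[setdiff(names(res), "config")], function(x)
      if (is.null(x)) NULL else as.list(x)))
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  invisible(config$outdir)
}
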