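# End-to-end pipeline driver.

#' Pipeline configuration
#'
#' Builds a validated nested configuration with defaults matching the
#' analysis conventions of the package (500 ms baseline, 26-175 ms /
#' 25-160 Hz analysis domain, 5 ms ROC bins, 4 SD / 80th percentile /
#' r >= 0.5 screening thresholds, distance bins at 0.75-degree steps).
#' The configuration round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param simulation,preprocessing,screening,erf,roc,sensitivity,classification
#'   named lists overriding block defaults (see the package vignette).
#' @param output_dir directory for stage outputs and caches.
#' @return list of class `efp_config`.
#' @export
efp_config <- function(seed = 1L, simulation = list(), preprocessing = list(),
                       screening = list(), erf = list(), roc = list(),
                       sensitivity = list(), classification = list(),
                       output_dir = tempfile("efp_run_")) {
  defaults <- list(
    simulation = list(n_electrodes = 202, n_trials = c(21, 39),
                      sweeps_per_direction = 3, condition_ids = NULL,
                      artifact = list(clip = 0, power_outlier = 0, correlated_burst = 0),
                      design = list()),
    preprocessing = list(freqs = seq(10, 160, by = 2), n_cycles = 7, bin_ms = 5,
                         t_keep = c(0, 250), baseline_ms = c(-500, 0)),
    screening = list(sd_limit = 4, power_percentile = 0.8, r_limit = 0.5,
                     majority_frac = 0.5, broadband = c(30, 160),
                     window = c(26, 175), manual_exclude = integer()),
    erf = list(band = c(60, 150), resolution = 0.1, half_extent = 6.7,
               z_threshold = 1, min_area = 1, n_null = 19, n_permutations = 0),
    roc = list(z_sel = 2, domain_t = c(0, 175), domain_f = c(25, 160),
               manual_windows = NULL),
    sensitivity = list(bin_edges = c(0, 0.75, 1.5, 2.25, 3),
                       early = c(40, 90), late = c(120, 175)),
    classification = list(enabled = TRUE, n_runs = 10, alpha = 0.01,
                          max_electrodes = Inf)
  )
  user <- list(simulation = simulation, preprocessing = preprocessing,
               screening = screening, erf = erf, roc = roc,
               sensitivity = sensitivity, classification = classification)
  bad <- character()
  for (blk in names(user)) {
    unknown <- setdiff(names(user[[blk]]), names(defaults[[blk]]))
    if (length(unknown)) bad <- c(bad, paste0(blk, "$", unknown))
    for (nm in names(user[[blk]])) {
      defaults[[blk]][nm] <- list(user[[blk]][[nm]])  # NULL-preserving merge
    }
  }
  if (length(bad)) stop("invalid config field(s): ", paste(bad, collapse = ", "))
  # YAML-safe coercions (empty sequences deserialize as lists)
  defaults$screening$manual_exclude <-
    as.integer(unlist(defaults$screening$manual_exclude))
  cfg <- c(list(seed = as.integer(seed), output_dir = output_dir), defaults)
  class(cfg) <- "efp_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg an `efp_config` (or plain list with the same shape).
#' @return the configuration, invisibly; a schema error lists every
#'   offending field.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  req_block <- c("seed", "simulation", "preprocessing", "screening", "erf",
                 "roc", "sensitivity", "classification")
  missing_blocks <- setdiff(req_block, names(cfg))
  if (length(missing_blocks)) {
    problems <- c(problems, paste0("missing block: ", missing_blocks))
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  if (!"simulation" %in% missing_blocks) {
    chk(is.numeric(cfg$simulation$n_electrodes) && cfg$simulation$n_electrodes >= 1,
        "simulation$n_electrodes must be >= 1")
    chk(all(cfg$simulation$n_trials >= 1), "simulation$n_trials must be >= 1")
  }
  if (!"preprocessing" %in% missing_blocks) {
    chk(!is.unsorted(cfg$preprocessing$freqs, strictly = TRUE),
        "preprocessing$freqs must be strictly increasing")
    chk(cfg$preprocessing$bin_ms > 0, "preprocessing$bin_ms must be positive")
  }
  if (!"sensitivity" %in% missing_blocks) {
    chk(!is.unsorted(cfg$sensitivity$bin_edges, strictly = TRUE),
        "sensitivity$bin_edges must be strictly increasing")
  }
  if (length(problems)) {
    stop("config schema error:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a configuration as YAML
#'
#' @param cfg an `efp_config`.
#' @param path YAML file path.
#' @return `read_config` returns the `efp_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(efp_config, c(list(seed = raw$seed, output_dir = raw$output_dir),
                        raw[setdiff(names(raw), c("seed", "output_dir"))]))
}

stage_cache <- function(outdir, name, hash, builder) {
  dir.create(file.path(outdir, "cache"), showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, "cache", paste0(name, ".rds"))
  if (file.exists(path)) {
    cached <- readRDS(path)
    if (identical(cached$hash, hash)) return(cached$value)
  }
  value <- builder()
  saveRDS(list(hash = hash, value = value), path)
  value
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, screen, map-erf, roc-select, sensitivity
#' and classify in order, writing per-stage tables, a machine-readable
#' summary (JSON) and a log to the output directory. Stage outputs are
#' cached and re-used when the relevant part of the configuration has not
#' changed, so later stages can be re-run from cached upstream results.
#'
#' @param cfg an [efp_config()].
#' @param stages character vector of stages to run (default: all).
#' @return list with all stage outputs plus `summary`.
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "preprocess", "screen",
                                         "map_erf", "roc_select", "sensitivity",
                                         "classify")) {
  validate_config(cfg)
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                               sep = "", file = log_path, append = TRUE)
  ver <- tryCatch(as.character(utils::packageVersion("efptools")),
                  error = function(e) "dev")
  logline("efptools ", ver, " | seed ", cfg$seed,
          " | config hash ", hash(unclass(cfg)))

  h_sim <- hash(cfg[c("seed", "simulation")])
  sim <- stage_cache(outdir, "simulate", h_sim, function() {
    logline("simulate")
    des <- do.call(efp_design, c(list(n_electrodes = cfg$simulation$n_electrodes),
                                 cfg$simulation$design))
    truth <- generate_ground_truth(des, seed = derive_seed(cfg$seed, "sim"))
    trials <- generate_object_trials(truth, cfg$simulation$n_trials,
                                     seed = derive_seed(cfg$seed, "obj"),
                                     condition_ids = cfg$simulation$condition_ids)
    art <- cfg$simulation$artifact
    if (sum(unlist(art[c("clip", "power_outlier", "correlated_burst")])) > 0) {
      trials <- inject_artifacts(trials, do.call(artifact_spec, art),
                                 seed = derive_seed(cfg$seed, "art"))
    }
    mapping <- generate_mapping_trials(truth, cfg$simulation$sweeps_per_direction,
                                       seed = derive_seed(cfg$seed, "map"))
    export_truth_csv(truth, trials, outdir)
    list(truth = truth, trials = trials, mapping = mapping)
  })
  if (!any(stages %in% c("preprocess", "screen", "map_erf", "roc_select",
                         "sensitivity", "classify"))) {
    return(invisible(list(sim = sim)))
  }

  h_pre <- hash(list(h_sim, cfg$preprocessing))
  tfp <- stage_cache(outdir, "preprocess", h_pre, function() {
    logline("preprocess")
    do.call(compute_wp, c(list(trials = sim$trials), cfg$preprocessing))
  })

  h_scr <- hash(list(h_pre, cfg$screening))
  screening <- stage_cache(outdir, "screen", h_scr, function() {
    logline("screen")
    rep <- screen_trials(sim$trials, tfp, do.call(screen_params, cfg$screening))
    utils::write.csv(rep, file.path(outdir, "screening.csv"), row.names = FALSE)
    rep
  })
  keep <- screening$decision == "keep"
  tfp_kept <- tfp
  tfp_kept$power <- tfp$power[keep, , , , drop = FALSE]
  tfp_kept$labels <- tfp$labels[keep, , drop = FALSE]

  h_erf <- hash(list(h_sim, cfg$erf))
  erfmap <- stage_cache(outdir, "map_erf", h_erf, function() {
    logline("map_erf")
    res <- do.call(map_erfs, c(list(mapping = sim$mapping),
                               cfg$erf, list(seed = derive_seed(cfg$seed, "erf"))))
    utils::write.csv(res$summary, file.path(outdir, "erf_summary.csv"),
                     row.names = FALSE)
    res
  })

  h_roc <- hash(list(h_scr, cfg$roc))
  windows <- stage_cache(outdir, "roc_select", h_roc, function() {
    logline("roc_select")
    manual <- cfg$roc$manual_windows
    ws <- lapply(names(CATEGORY_COLUMNS), function(cat) {
      if (!is.null(manual[[cat]])) {
        return(structure(c(list(category = cat), manual[[cat]],
                           list(provenance = "manual")), class = "efp_window"))
      }
      am <- auc_map(tfp_kept, cat, domain_t = cfg$roc$domain_t,
                    domain_f = cfg$roc$domain_f)
      tryCatch(select_window(grand_variance_map(am), z_sel = cfg$roc$z_sel),
               error = function(e) {
                 logline("roc_select: ", cat, ": ", conditionMessage(e),
                         " -- falling back to the full analysis domain")
                 structure(list(category = cat, t0 = 26, t1 = 175,
                                f0 = cfg$roc$domain_f[1], f1 = cfg$roc$domain_f[2],
                                provenance = "fallback"), class = "efp_window")
               })
    })
    names(ws) <- names(CATEGORY_COLUMNS)
    write_windows_json(ws, file.path(outdir, "windows.json"))
    ws
  })

  h_sen <- hash(list(h_roc, h_erf, cfg$sensitivity))
  sens <- stage_cache(outdir, "sensitivity", h_sen, function() {
    logline("sensitivity")
    centers <- erfmap$summary
    assignment <- assign_electrodes(centers)
    esel <- match(assignment$electrode, sim$trials$electrodes)
    sub_tfp <- tfp_kept
    sub_tfp$power <- tfp_kept$power[, esel, , , drop = FALSE]
    cmps <- lapply(names(CATEGORY_COLUMNS), function(cat) {
      category_mean_power(sub_tfp, cat, windows[[cat]])
    })
    names(cmps) <- names(CATEGORY_COLUMNS)
    tab <- sensitivity_table(cmps, assignment)
    utils::write.csv(tab, file.path(outdir, "sensitivity.csv"), row.names = FALSE)
    stats <- lapply(names(CATEGORY_COLUMNS)[1:3], function(cat) {
      v <- tab$index[tab$category == cat]
      tryCatch(distance_binned_stats(v, assignment$dist_rnk1,
                                     edges = cfg$sensitivity$bin_edges),
               error = function(e) NULL)
    })
    names(stats) <- names(CATEGORY_COLUMNS)[1:3]
    profile <- rank_distance_profile(cmps$location, assignment)
    resp_assigned <- vapply(seq_len(nrow(assignment)), function(i) {
      cmps$location[i, as.character(assignment$assigned_location[i])]
    }, numeric(1))
    hg <- tryCatch(fit_half_gaussian(assignment$dist_rnk1, resp_assigned),
                   error = function(e) NULL)
    el <- early_late_color_comparison(sub_tfp,
                                      c(windows$color$f0, windows$color$f1),
                                      early = cfg$sensitivity$early,
                                      late = cfg$sensitivity$late)
    list(assignment = assignment, cmps = cmps, table = tab, stats = stats,
         rank_profile = profile, half_gauss = hg, early_late = el)
  })

  classification <- NULL
  if (isTRUE(cfg$classification$enabled) && "classify" %in% stages) {
    h_cls <- hash(list(h_sen, cfg$classification))
    classification <- stage_cache(outdir, "classify", h_cls, function() {
      logline("classify")
      pairs <- gamma_contrast_pairs()
      pair <- pairs[pairs$contrast == "high_vs_low", ][1, ]
      rows <- list()
      ass <- sens$assignment
      n_el <- min(nrow(ass), cfg$classification$max_electrodes)
      for (i in seq_len(n_el)) {
        el <- ass$electrode[i]
        esel <- match(el, sim$trials$electrodes)
        loc <- ass$assigned_location[i]
        lab <- tfp_kept$labels
        sel_a <- lab$location_id == loc & lab$size_class == pair$size_a &
          lab$shape == pair$shape_a & lab$color == pair$color_a
        sel_b <- lab$location_id == loc & lab$size_class == pair$size_b &
          lab$shape == pair$shape_b & lab$color == pair$color_b
        if (sum(sel_a) < 6 || sum(sel_b) < 6) next
        sub <- tfp_kept
        sub$power <- tfp_kept$power[sel_a | sel_b, esel, , , drop = FALSE]
        X <- extract_feature_triplet(sub, 1, windows[c("size", "shape", "color")])
        y <- ifelse(sel_a[sel_a | sel_b], "a", "b")
        sd_cls <- derive_seed(cfg$seed, paste0("cls", el))
        tr <- loocv_svm(X, y, n_runs = cfg$classification$n_runs, seed = sd_cls)
        sh <- loocv_svm(X, y, n_runs = cfg$classification$n_runs, seed = sd_cls,
                        shuffle = TRUE)
        cs <- chance_and_significance(tr, sh, alpha = cfg$classification$alpha)
        rows[[length(rows) + 1]] <- tibble(
          electrode = el, contrast = pair$contrast, distance = ass$dist_rnk1[i],
          mean_acc = cs$mean_acc, chance_acc = cs$chance_acc,
          p = cs$p.value, significant = cs$significant)
      }
      out <- if (length(rows)) do.call(rbind, rows) else NULL
      if (!is.null(out)) {
        utils::write.csv(out, file.path(outdir, "classification.csv"),
                         row.names = FALSE)
      }
      out
    })
  }

  summary <- pipeline_summary(screening, erfmap, sens, classification, cfg)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  logline("done")
  invisible(list(sim = sim, tfp = tfp, screening = screening, erfmap = erfmap,
                 windows = windows, sensitivity = sens,
                 classification = classification, summary = summary))
}

pipeline_summary <- function(screening, erfmap, sens, classification, cfg) {
  med_by_bin <- function(cat) {
    s <- sens$stats[[cat]]
    if (is.null(s)) return(NULL)
    as.list(setNames(as.numeric(s$bin_medians), names(s$bin_medians)))
  }
  checks <- list(
    rank_profile_decreasing = !is.unsorted(rev(sens$rank_profile)),
    late_csi_greater = sens$early_late$test$p.value < 0.01 &&
      median(sens$early_late$csi_late) > median(sens$early_late$csi_early),
    chance_near_half = if (!is.null(classification)) {
      abs(mean(classification$chance_acc) - 0.5) < 0.05
    } else NA
  )
  for (cat in names(sens$stats)) {
    m <- sens$stats[[cat]]
    checks[[paste0(cat, "_medians_nonincreasing")]] <-
      if (is.null(m)) NA else !is.unsorted(rev(as.numeric(m$bin_medians)))
  }
  list(
    seed = cfg$seed,
    n_trials_total = nrow(screening),
    n_trials_kept = sum(screening$decision == "keep"),
    n_valid_erfs = sum(erfmap$summary$valid),
    n_sensitivity_records = nrow(sens$table),
    rank_profile = as.numeric(sens$rank_profile),
    index_medians_by_bin = lapply(setNames(nm = names(sens$stats)), med_by_bin),
    half_gaussian = if (!is.null(sens$half_gauss)) {
      sens$half_gauss[c("a", "sigma", "r_squared")]
    } else NULL,
    early_late_p = sens$early_late$test$p.value,
    mean_accuracy = if (!is.null(classification)) mean(classification$mean_acc) else NA,
    mean_chance = if (!is.null(classification)) mean(classification$chance_acc) else NA,
    pattern_checks = checks
  )
}
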