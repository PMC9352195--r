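#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()]: the
#' generator settings (see [sim_config()]), per-stage toggles, alpha
#' levels, epoch definitions and change-point settings. Any YAML file
#' with the same structure can override parts of it.
#'
#' @param seed Master seed; every stochastic stage receives a derived,
#'   logged sub-seed.
#' @return A nested list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    generator = list(),
    alpha = 0.05,
    epochs = list(
      early = c(200, 400), middle = c(400, 700), late = c(800, 1100)
    ),
    changepoint = list(
      n_shuffles = 50, percentile = 99, n_samples = 2000, n_chains = 4
    ),
    coupling = list(n_sims = 10000, window = c(0, 20)),
    decoding = list(bin_ms = 250),
    stages = list(
      lfp = TRUE, changepoint = TRUE, behavior = TRUE, coupling = TRUE,
      response = TRUE, decoding = TRUE, palatability = TRUE, held = TRUE
    )
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config(seed = config$seed %||% 1L)
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_lists(a[[nm]], b[[nm]])
      } else {
        b[[nm]]
      }
    }
    a
  }
  cfg <- merge_lists(base, config)
  stopifnot(
    is.numeric(cfg$seed), cfg$alpha > 0, cfg$alpha < 1,
    all(vapply(cfg$stages, is.logical, logical(1)))
  )
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on synthetic data
#'
#' Synthesizes every input (LFP power, ensemble pair, behavior,
#' waveforms) from one seed, runs the enabled stages in dependency order
#' and writes per-stage CSV/JSON plus a top-level `summary.json` to
#' `output_dir`. Identical config and seed give byte-identical summaries.
#' Stages depending on a disabled stage fail with a clear message
#' (coupling needs changepoint and behavior; held needs palatability).
#'
#' @param config A config list as from [pipeline_config()], a partial
#'   list overriding it, or the path to a YAML file.
#' @param output_dir Directory for outputs (created if needed).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = tempfile()) {
  cfg <- read_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  st <- cfg$stages
  if (isTRUE(st$coupling) && (!isTRUE(st$changepoint) || !isTRUE(st$behavior))) {
    stop("stage 'coupling' requires stages 'changepoint' and 'behavior'")
  }
  if (isTRUE(st$held) && !isTRUE(st$palatability)) {
    stop("stage 'held' requires stage 'palatability'")
  }
  epochs <- do.call(epoch_def, cfg$epochs)
  gen <- do.call(sim_config, c(cfg$generator, list(seed = cfg$seed)))
  stage_offset <- c(
    changepoint = 1L, coupling = 30L, decoding = 40L, held = 60L
  )
  sub_seed <- function(stage, i) {
    (cfg$seed * 97L + (stage_offset[[stage]] + i) * 1009L) %%
      .Machine$integer.max
  }
  logmsg <- function(...) message("[pipeline] ", ...)
  summary <- list(seed = cfg$seed)

  logmsg("synthesizing inputs (seed ", cfg$seed, ")")
  lfp <- sim_lfp_power(gen)
  ens <- sim_ensemble_pair(gen)
  beh <- sim_behavior(gen)

  if (isTRUE(st$lfp)) {
    logmsg("stage lfp: quartile ANOVA")
    qa <- quartile_power_anova(lfp$power)
    write.csv(qa$differences, file.path(output_dir, "lfp_quartiles.csv"),
      row.names = FALSE
    )
    summary$lfp <- list(
      interaction = as.list(qa$interaction),
      per_quartile_p = qa$per_quartile$p.value
    )
  }

  if (isTRUE(st$changepoint)) {
    exp_ids <- unique(lfp$truth$animal_id[lfp$truth$group == "experimental"])
    cps <- purrr::imap(setNames(exp_ids, exp_ids), function(id, nm) {
      s <- sub_seed("changepoint", match(id, exp_ids))
      logmsg("stage changepoint: ", id, " (sub-seed ", s, ")")
      series <- lfp$power[lfp$power$animal_id == id &
        lfp$power$condition == "licl", ]
      glance(detect_changepoint(series,
        n_shuffles = cfg$changepoint$n_shuffles,
        percentile = cfg$changepoint$percentile,
        n_samples = cfg$changepoint$n_samples,
        n_chains = cfg$changepoint$n_chains, seed = s
      ))
    })
    cp_tbl <- dplyr::bind_rows(cps, .id = "animal_id")
    write.csv(cp_tbl, file.path(output_dir, "changepoints.csv"),
      row.names = FALSE
    )
    summary$changepoint <- list(
      estimates = setNames(cp_tbl$estimate, cp_tbl$animal_id),
      mean_estimate = mean(cp_tbl$estimate, na.rm = TRUE)
    )
  }

  if (isTRUE(st$behavior)) {
    logmsg("stage behavior")
    diff_tr <- condition_difference(beh$events, gen$session_minutes)
    sig <- fit_sigmoid(diff_tr)
    qw <- quartile_wilcoxon(beh$events, gen$session_minutes)
    write.csv(diff_tr, file.path(output_dir, "behavior_difference.csv"),
      row.names = FALSE
    )
    summary$behavior <- list(
      sigmoid = as.list(glance(sig)),
      quartile_p = setNames(qw$p.value, paste0("q", qw$quartile))
    )
  }

  if (isTRUE(st$coupling)) {
    logmsg("stage coupling")
    lfp_cps <- summary$changepoint$estimates
    lfp_cps <- lfp_cps[!is.na(lfp_cps)]
    if (!length(lfp_cps)) {
      logmsg("no LFP change points detected; skipping coupling test")
    } else {
      ct <- coupling_test(
        summary$behavior$sigmoid$midpoint, lfp_cps,
        n_sims = cfg$coupling$n_sims, window = cfg$coupling$window,
        seed = sub_seed("coupling", 1)
      )
      summary$coupling <- list(
        observed = ct$observed, p = ct$p, mode = ct$mode
      )
    }
  }

  if (isTRUE(st$response)) {
    logmsg("stage response")
    ma <- magnitude_condition_anova(ens$saline, ens$licl, alpha = cfg$alpha)
    write.csv(ma$data, file.path(output_dir, "response_magnitudes.csv"),
      row.names = FALSE
    )
    summary$response <- list(
      interaction = as.list(ma$interaction),
      tukey_p = setNames(ma$tukey$p.adj, ma$tukey$contrast)
    )
  }

  if (isTRUE(st$decoding)) {
    logmsg("stage decoding")
    dec_s <- lda_loo_accuracy(ens$saline,
      bin_ms = cfg$decoding$bin_ms,
      epochs = epochs, seed = sub_seed("decoding", 1)
    )
    dec_l <- lda_loo_accuracy(ens$licl,
      bin_ms = cfg$decoding$bin_ms,
      epochs = epochs, seed = sub_seed("decoding", 2)
    )
    et <- epoch_condition_test(dec_s, dec_l)
    write.csv(
      dplyr::bind_rows(
        dplyr::mutate(dec_s$accuracy, condition = "saline"),
        dplyr::mutate(dec_l$accuracy, condition = "licl")
      ),
      file.path(output_dir, "decoding_accuracy.csv"),
      row.names = FALSE
    )
    summary$decoding <- list(
      epoch_saline = setNames(dec_s$epoch_means$accuracy,
        dec_s$epoch_means$epoch
      ),
      epoch_licl = setNames(dec_l$epoch_means$accuracy,
        dec_l$epoch_means$epoch
      ),
      epoch_p_adj = setNames(et$p.adj, et$epoch)
    )
  }

  tr_s <- tr_l <- NULL
  if (isTRUE(st$palatability)) {
    logmsg("stage palatability")
    tr_s <- moving_spearman(ens$saline)
    tr_l <- moving_spearman(ens$licl)
    pct <- palatability_condition_test(tr_s, tr_l, epochs)
    ppi_s <- compute_ppi(ens$saline, epochs)
    ppi_l <- compute_ppi(ens$licl, epochs)
    pt <- ppi_tests(ppi_s, ppi_l)
    write.csv(
      dplyr::bind_rows(
        dplyr::mutate(ppi_s, condition = "saline"),
        dplyr::mutate(ppi_l, condition = "licl")
      ),
      file.path(output_dir, "ppi.csv"),
      row.names = FALSE
    )
    summary$palatability <- list(
      kruskal_p = setNames(pct$p.value, pct$epoch),
      ppi_between_p = setNames(pt$between$p.value, pt$between$epoch)
    )
  }

  if (isTRUE(st$held)) {
    logmsg("stage held units")
    wf <- sim_waveforms(gen)
    screen <- held_unit_screen(wf$waveforms, seed = sub_seed("held", 1))
    held_ids <- screen$unit_id[screen$held]
    neuron_map <- ens$truth$neurons$neuron_id[seq_len(nrow(screen))]
    held_neurons <- neuron_map[screen$held]
    rds <- response_difference_vectors(ens$saline, ens$licl,
      held_ids = held_neurons
    )
    cl <- gmm_cluster(rds)
    write.csv(cl$assignments, file.path(output_dir, "rd_clusters.csv"),
      row.names = FALSE
    )
    ca <- tryCatch(
      cluster_palatability_anova(cl, tr_s, tr_l, epochs),
      error = function(e) NULL
    )
    be <- baseline_equivalence(ens$saline, ens$licl, held_ids = held_neurons)
    summary$held <- list(
      n_held = length(held_ids), k = cl$k,
      n_angle_peaks = cl$n_angle_peaks,
      cluster_interaction_p = if (!is.null(ca)) ca$anova$p.value else NA,
      baseline_t_p = be$t_test$p.value, baseline_ks_p = be$ks_test$p.value
    )
  }

  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  logmsg("done: ", file.path(output_dir, "summary.json"))
  invisible(summary)
}
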