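#' Pipeline configuration
#'
#' Configuration for the end-to-end synthetic-cohort pipeline. Unknown
#' fields are rejected so typos cannot silently disable a stage; the full
#' configuration (plus the seed) is serialized into every report for
#' provenance.
#'
#' @param n_subjects cohort size
#' @param session named list of [session_config()] overrides applied to
#'   every subject (per-subject seeds are derived from `seed`)
#' @param stages character vector of stages to run, a subset of
#'   `c("behavior", "erp", "cluster", "egg", "periphys", "stats")`
#' @param n_perm permutations for the cluster stage
#' @param grace hit-attribution grace window (s), see [score_block()]
#' @param seed master seed
#' @return object of class `gw_pipeline_config`
#' @export
pipeline_config <- function(n_subjects = 5, session = list(),
                            stages = c("behavior", "erp", "cluster",
                                       "egg", "periphys", "stats"),
                            n_perm = 500, grace = 1.0, seed = 1L) {
  known <- c("behavior", "erp", "cluster", "egg", "periphys", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  allowed_session <- names(formals(session_config))
  bad <- setdiff(names(session), allowed_session)
  if (length(bad)) stop("unknown session fields: ",
                        paste(bad, collapse = ", "))
  structure(list(n_subjects = n_subjects, session = session,
                 stages = stages, n_perm = n_perm, grace = grace,
                 seed = as.integer(seed)),
            class = "gw_pipeline_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Simulates `n_subjects` sessions and pushes each through vibration
#' detection, behavioural scoring, ERP extraction, EGG and peripheral
#' physiology, then runs the group stage: a spatiotemporal cluster
#' permutation test on the normal vs. enhanced subject ERPs and paired
#' contrasts / condition-controlled correlations on the measure table.
#' With a fixed seed the report bundle is byte-identical across runs.
#'
#' @param config a [pipeline_config()]
#' @param out optional directory; when given, writes `measures.csv`,
#'   `scores.csv`, `cluster.json` and `config.json`
#' @return report list: `measures` (tidy table), `scores`, `erps`
#'   (subject x channel x time arrays per condition), `cluster`, `stats`
#' @export
run_pipeline <- function(config, out = NULL) {
  stopifnot(inherits(config, "gw_pipeline_config"))
  st <- config$stages
  measures <- NULL; scores <- NULL
  erps <- list(); labels <- NULL; times <- NULL

  for (s in seq_len(config$n_subjects)) {
    args <- config$session
    args$seed <- derive_seed(config$seed, 100 + s)
    scfg <- do.call(session_config, args)
    sim <- simulate_session(scfg)
    rec <- sim$recording
    subj <- sprintf("S%02d", s)

    ## vibration detection
    det <- detect_vibrations(get_channel(rec, "stetho"),
                             expected_count = sum(scfg$n_stims),
                             expected_duration = scfg$stim_duration)
    # label detected events by the block schedule
    det$block <- as.character(cut(det$onset,
                                  breaks = c(rec$blocks$start,
                                             Inf),
                                  labels = rec$blocks$label))
    det$condition <- det$block

    add <- function(block, measure, value)
      rbind(measures, data.frame(subject = subj, block = block,
                                 measure = measure, value = value))

    sc <- list()
    if ("behavior" %in% st) {
      for (b in names(scfg$n_stims)) {
        ev <- det[det$block == b, , drop = FALSE]
        if (nrow(ev) == 0) next
        r <- score_block(ev, sim$presses, block_span(rec, b),
                         grace = config$grace)
        sc[[b]] <- r
        scores <- rbind(scores, data.frame(
          subject = subj, block = b, TP = r$TP, FP = r$FP,
          a_prime = r$a_prime, a_prime_norm = r$a_prime_norm,
          latency_mean = r$latency_mean, latency_sd = r$latency_sd,
          above_chance = r$above_chance))
        measures <- add(b, "a_prime_norm", r$a_prime_norm)
        measures <- add(b, "latency_mean", r$latency_mean)
        measures <- add(b, "latency_sd", r$latency_sd)
      }
    }

    if ("erp" %in% st) {
      eeg <- preprocess_eeg(get_channel(rec, "eeg"))
      eeg <- rereference_mastoids(eeg)
      for (b in names(scfg$n_stims)) {
        ev <- det[det$block == b, , drop = FALSE]
        if (nrow(ev) == 0 || is.null(sc[[b]])) next
        ev <- classify_events(ev, sc[[b]])
        ep <- epoch_eeg(eeg, ev, class_filter = "true_positive")
        if (dim(ep$data)[1] == 0) next
        ep <- reject_artifacts(ep)
        if (all(ep$reject)) next
        erp <- average_erp(ep)
        lpp <- lpp_metrics(erp)
        measures <- add(b, "lpp_amplitude", lpp$amplitude)
        measures <- add(b, "lpp_latency", lpp$latency)
        if (is.null(labels)) { labels <- erp$labels; times <- erp$times }
        if (is.null(erps[[b]])) erps[[b]] <- list()
        erps[[b]][[subj]] <- erp$mean
      }
    }

    if ("egg" %in% st) {
      egg <- get_channel(rec, "egg")
      for (b in rec$blocks$label) {
        sp <- tryCatch(egg_spectrum(egg, block_span(rec, b)),
                       error = function(e) NULL)
        if (is.null(sp)) next
        measures <- add(b, "egg_total_power", sp$band_power$total)
        measures <- add(b, "egg_normo_power", sp$band_power$normogastria)
        measures <- add(b, "egg_peak_freq", sp$peak_freq)
      }
    }

    if ("periphys" %in% st) {
      peaks <- detect_r_peaks(get_channel(rec, "ecg"))
      ser <- clean_ibis(peaks)
      scr_ch <- get_channel(rec, "scr")
      base <- block_span(rec, "baseline")
      pseudo <- make_pseudo_events(
        base,
        n = min(60, floor((diff(base) - 120) / 3) - 1))
      for (b in rec$blocks$label) {
        span <- block_span(rec, b)
        ev <- if (b == "baseline") pseudo
        else det[det$block == b, , drop = FALSE]
        measures <- add(b, "tonic_hr", tonic_hr(ser, span))
        measures <- add(b, "sdnn", sdnn(ser, span))
        measures <- add(b, "br", suppressMessages(estimate_br(ser, span)))
        ph <- phasic_hr(ser, ev, span = span)
        measures <- add(b, "phasic_hr",
                        if (is.null(ph)) NA_real_
                        else mean(ph$delta, na.rm = TRUE))
        psc <- phasic_scr(scr_ch, ev)
        measures <- add(b, "phasic_scr",
                        if (is.null(psc$per_event)) NA_real_
                        else mean(psc$per_event$max_phasic))
      }
    }
  }

  cluster <- NULL
  if ("cluster" %in% st && length(erps) >= 2 &&
      !is.null(erps$normal) && !is.null(erps$enhanced)) {
    common <- intersect(names(erps$normal), names(erps$enhanced))
    if (length(common) >= 2) {
      mk <- function(lst) {
        a <- array(0, c(length(common), length(labels), length(times)))
        for (i in seq_along(common)) a[i, , ] <- lst[[common[i]]]
        a
      }
      adj <- build_adjacency()
      cluster <- cluster_test(mk(erps$enhanced), mk(erps$normal), adj,
                              labels = labels, n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 7000))
    }
  }

  statres <- NULL
  if ("stats" %in% st && !is.null(measures)) {
    measures <- flag_outliers(measures)
    statres <- list()
    for (m in c("a_prime_norm", "latency_mean", "latency_sd",
                "lpp_amplitude")) {
      if (!m %in% measures$measure) next
      statres[[paste0(m, "_enh_vs_norm")]] <- tryCatch(
        paired_contrast(measures, m, "enhanced", "normal", family = 3),
        error = function(e) NULL)
    }
    if (all(c("lpp_amplitude", "a_prime_norm") %in% measures$measure) &&
        !is.null(scores)) {
      lp <- measures[measures$measure == "lpp_amplitude", ]
      ap <- measures[measures$measure == "a_prime_norm", ]
      mm <- merge(lp[, c("subject", "block", "value")],
                  ap[, c("subject", "block", "value")],
                  by = c("subject", "block"),
                  suffixes = c("_lpp", "_ap"))
      if (nrow(mm) >= 4)
        statres$lpp_vs_accuracy <- partial_spearman(
          mm$value_lpp, mm$value_ap, mm$block)
    }
  }

  report <- list(measures = measures, scores = scores, erps = erps,
                 erp_labels = labels, erp_times = times,
                 cluster = cluster, stats = statres, config = config)
  if (!is.null(out)) write_report(report, out)
  report
}

write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$measures))
    write.csv(report$measures, file.path(out, "measures.csv"),
              row.names = FALSE)
  if (!is.null(report$scores))
    write.csv(report$scores, file.path(out, "scores.csv"),
              row.names = FALSE)
  if (!is.null(report$cluster)) {
    cl <- report$cluster
    jsonlite::write_json(
      list(n_perm = cl$n_perm, t_crit = cl$t_crit, seed = cl$seed,
           clusters = lapply(cl$clusters, function(c0)
             list(polarity = c0$polarity, mass = c0$mass, p = c0$p,
                  n_points = nrow(c0$members)))),
      file.path(out, "cluster.json"), auto_unbox = TRUE, digits = NA)
  }
  cfg <- report$config
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
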