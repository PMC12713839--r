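## End-to-end orchestration: simulate a synthetic cohort, run the
## architecture and circadian analyses, compare genotypes, and emit tidy
## CSVs plus a provenance manifest.

canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canonical_json(config)), tf)
  unname(tools::md5sum(tf))
}

#' Derive a per-subject seed from the master seed
#'
#' Stable hash of the subject id folded into the master seed, so cohorts
#' can grow without reshuffling existing subjects.  Kept below 2^31.
#'
#' @param master_seed Integer master seed.
#' @param subject_id Character id.
#' @return Integer seed.
#' @export
subject_seed <- function(master_seed, subject_id) {
  h <- 0
  for (ch in utf8ToInt(subject_id)) h <- (h * 31 + ch) %% 1000003
  as.integer((master_seed + h * 1009) %% .Machine$integer.max)
}

default_config <- function() {
  list(n_wt = 4, n_mut = 4, days = 2, sex = "M",
       signals = FALSE, activity = TRUE, resume = FALSE)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> (optionally synthesize + stage) -> architecture ->
#' circadian -> compare, from one configuration.  All outputs are tidy
#' CSVs under `outdir`; a JSON manifest records the config hash, seeds,
#' output files and row counts.  Deterministic for a fixed config and
#' seed.
#'
#' @param config A named list or a path to a YAML file.  Recognised
#'   keys: `seed` (required), `outdir` (required), `n_wt`, `n_mut`,
#'   `days` (simulated days per subject), `sex`, `signals` (synthesize
#'   EEG/EMG and stage them; slow), `activity`, `resume` (skip stages
#'   whose outputs already exist under a matching config hash).
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed)) stop("config must provide a seed")
  if (is.null(cfg$outdir)) stop("config must provide an outdir")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg[setdiff(names(cfg), c("outdir", "resume"))])
  presets <- genotype_presets()
  study <- study_config(seed = cfg$seed)

  manifest <- list(config_hash = hash, seed = cfg$seed, outputs = list(),
                   subjects = list())
  out_file <- function(name) file.path(cfg$outdir, name)
  note <- function(name, rows) {
    manifest$outputs[[name]] <<- list(file = name, rows = rows)
  }
  prev <- if (file.exists(out_file("manifest.json")))
    tryCatch(jsonlite::read_json(out_file("manifest.json")),
             error = function(e) NULL)
  resumable <- isTRUE(cfg$resume) && !is.null(prev) &&
    identical(prev$config_hash, unname(hash))

  subjects <- rbind(
    data.frame(subject_id = sprintf("WT_%02d", seq_len(cfg$n_wt)),
               genotype = "WT"),
    data.frame(subject_id = sprintf("MUT_%02d", seq_len(cfg$n_mut)),
               genotype = "MUT"))
  subjects$sex <- cfg$sex
  subjects$seed <- mapply(subject_seed, cfg$seed, subjects$subject_id)
  utils::write.csv(subjects, out_file("cohort.csv"), row.names = FALSE)
  note("cohort.csv", nrow(subjects))

  ## -- simulate stage -------------------------------------------------
  hyps <- list(); acts <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    gt <- subjects$genotype[i]
    hpath <- out_file(paste0(sid, "_hypnogram.csv"))
    if (resumable && file.exists(hpath)) {
      hyp <- read_hypnogram(hpath)
    } else {
      hyp <- simulate_hypnogram(presets[[gt]]$kinetics, days = cfg$days,
                                seed = subjects$seed[i], subject_id = sid,
                                genotype = gt, sex = cfg$sex)
      write_hypnogram(hyp, hpath)
    }
    note(basename(hpath), length(hyp$labels))
    hyps[[sid]] <- hyp
    if (isTRUE(cfg$activity)) {
      apath <- out_file(paste0(sid, "_activity.csv"))
      act <- simulate_activity(presets[[gt]]$activity,
                               seed = subjects$seed[i] + 1L)
      dd_from <- act$dd_from_bin
      if (!(resumable && file.exists(apath))) write_activity(act, apath)
      act <- read_activity(apath)
      act$dd_from_bin <- dd_from
      note(basename(apath), length(act$counts))
      acts[[sid]] <- act
    }
    if (isTRUE(cfg$signals)) {
      epath <- out_file(paste0(sid, ".edf"))
      spath <- out_file(paste0(sid, "_staged.csv"))
      if (!(resumable && file.exists(spath))) {
        rec <- synthesize_signals(hyp, preset_recipe(), fs = study$sampling_rate,
                                  seed = subjects$seed[i] + 2L,
                                  n_eeg = 1, n_emg = 1)
        write_signal_record(rec, epath)
        staged <- stage_record(rec, cfg = study, subject_id = sid,
                               genotype = gt, sex = cfg$sex)
        write_hypnogram(staged, spath)
      }
      note(basename(spath), length(read_hypnogram(spath)$labels))
    }
  }

  ## -- architecture stage ---------------------------------------------
  join_meta <- function(df, sid, gt) cbind(subject_id = sid, genotype = gt, df)
  profiles <- list(); summaries6 <- list(); transitions <- list()
  latencies <- list(); episodes6 <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]; gt <- subjects$genotype[i]
    hyp <- hyps[[sid]]
    profiles[[sid]] <- join_meta(state_time_profile(hyp, 1), sid, gt)
    summaries6[[sid]] <- join_meta(state_time_profile(hyp, 6), sid, gt)
    tt <- transition_table(hyp, 6)
    transitions[[sid]] <- join_meta(tt$table, sid, gt)
    lt <- rem_latency_histogram(hyp)
    latencies[[sid]] <- join_meta(lt, sid, gt)
    episodes6[[sid]] <- join_meta(episode_summary(find_episodes(hyp), 6),
                                  sid, gt)
  }
  tabs <- list(profile_1h = do.call(rbind, profiles),
               state_time_6h = do.call(rbind, summaries6),
               transitions_6h = do.call(rbind, transitions),
               rem_latency = do.call(rbind, latencies),
               episodes_6h = do.call(rbind, episodes6))
  for (nm in names(tabs)) {
    f <- paste0(nm, ".csv")
    utils::write.csv(tabs[[nm]], out_file(f), row.names = FALSE)
    note(f, nrow(tabs[[nm]]))
  }

  ## -- circadian stage ------------------------------------------------
  if (isTRUE(cfg$activity)) {
    circ <- list()
    pgs <- list()
    for (i in seq_len(nrow(subjects))) {
      sid <- subjects$subject_id[i]; gt <- subjects$genotype[i]
      seg <- split_activity(acts[[sid]])
      pr <- activity_profile(seg$ld, 1)
      tot <- phase_totals(seg$ld)
      circ[[sid]] <- cbind(subject_id = sid, genotype = gt, pr,
                           total = tot$total, light = tot$light,
                           dark = tot$dark)
      pg <- chi_square_periodogram(seg$dd)
      pgs[[sid]] <- data.frame(subject_id = sid, genotype = gt,
                               best_period_h = pg$best_period,
                               best_qp = pg$best_qp,
                               best_excess = pg$best_excess)
    }
    circ <- do.call(rbind, circ)
    pgs <- do.call(rbind, pgs)
    utils::write.csv(circ, out_file("activity_profile_1h.csv"),
                     row.names = FALSE)
    note("activity_profile_1h.csv", nrow(circ))
    utils::write.csv(pgs, out_file("periodogram.csv"), row.names = FALSE)
    note("periodogram.csv", nrow(pgs))
  }

  ## -- compare stage ---------------------------------------------------
  comp <- compare_genotypes(tabs,
                            if (isTRUE(cfg$activity)) out_file("activity_profile_1h.csv"))
  utils::write.csv(comp, out_file("comparisons.csv"), row.names = FALSE)
  note("comparisons.csv", nrow(comp))

  manifest$subjects <- subjects$subject_id
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE)
  writeLines(as.character(json), out_file("manifest.json"))
  invisible(manifest)
}

# genotype comparisons on the tidy stage outputs; returns one tidy frame
compare_genotypes <- function(tabs, activity_csv = NULL) {
  rows <- list()
  add <- function(measure, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      measure = measure, t = res$t, df = res$df, p = res$p,
      cohens_d = res$cohens_d,
      mean_wt = res$summary$mean[res$summary$group == "a"],
      mean_mut = res$summary$mean[res$summary$group == "b"])
  }
  st6 <- tabs$state_time_6h
  for (s in state_levels()) {
    sel <- st6$state == s & st6$bin_start_zt == 12
    wt <- st6$minutes[sel & st6$genotype == "WT"]
    mut <- st6$minutes[sel & st6$genotype == "MUT"]
    add(paste0(s, "_minutes_ZT12_18"), unpaired_t(wt, mut))
  }
  tr <- tabs$transitions_6h
  dark_nr <- stats::aggregate(
    prob ~ subject_id + genotype,
    tr[tr$type == "N>R" & tr$bin_start_zt >= 12, ], mean)
  add("P_NtoR_dark",
      unpaired_t(dark_nr$prob[dark_nr$genotype == "WT"],
                 dark_nr$prob[dark_nr$genotype == "MUT"]))
  lat <- tabs$rem_latency
  short <- stats::aggregate(
    count ~ subject_id + genotype,
    lat[lat$phase == "light" & lat$bin_hi_s <= 150, ], sum)
  add("rem_latency_lt150s_light",
      unpaired_t(short$count[short$genotype == "WT"],
                 short$count[short$genotype == "MUT"]))
  if (!is.null(activity_csv) && file.exists(activity_csv)) {
    act <- utils::read.csv(activity_csv)
    dk <- unique(act[, c("subject_id", "genotype", "dark")])
    add("activity_dark_total",
        unpaired_t(dk$dark[dk$genotype == "WT"],
                   dk$dark[dk$genotype == "MUT"]))
  }
  do.call(rbind, rows)
}

#' Summary report for a completed run
#'
#' Group-level figure-analog tables (and, when ggplot2 is installed and
#' `plots = TRUE`, simple plots) from a pipeline output directory:
#' genotype-mean daily profiles, transition matrices, REM-latency
#' histograms and activity profiles.  Plot data are always written as
#' CSV.
#'
#' @param outdir Pipeline output directory containing `manifest.json`.
#' @param plots Logical; also write PDF plots.
#' @return Invisible list of the report tables.
#' @export
pipeline_report <- function(outdir, plots = FALSE) {
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  rp <- function(f) utils::read.csv(file.path(outdir, f))
  out <- list()
  prof <- rp("profile_1h.csv")
  out$profile_group <- stats::aggregate(minutes ~ genotype + state + bin_start_zt,
                                        prof, mean)
  lat <- rp("rem_latency.csv")
  out$rem_latency_group <- stats::aggregate(count ~ genotype + phase + bin_lo_s,
                                            lat, mean)
  tr <- rp("transitions_6h.csv")
  out$transition_group <- stats::aggregate(prob ~ genotype + type + bin_start_zt,
                                           tr, mean)
  if (file.exists(file.path(outdir, "activity_profile_1h.csv"))) {
    act <- rp("activity_profile_1h.csv")
    out$activity_group <- stats::aggregate(mean_counts ~ genotype + bin_start_zt,
                                           act, mean)
  }
  for (nm in names(out))
    utils::write.csv(out[[nm]], file.path(outdir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    g <- ggplot2::ggplot(out$profile_group,
                         ggplot2::aes(bin_start_zt, minutes,
                                      colour = genotype)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~state, scales = "free_y") +
      ggplot2::labs(x = "ZT (h)", y = "minutes per hour")
    ggplot2::ggsave(file.path(outdir, "report_profiles.pdf"), g,
                    width = 8, height = 3)
  }
  invisible(out)
}
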