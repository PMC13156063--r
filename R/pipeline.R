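#' Build a validated pipeline configuration
#'
#' One config drives simulate -> preprocess -> features (lzc, gedbounds,
#' gsngc, graph) -> stats -> classify.  Unknown keys are rejected before any
#' compute.  `scale = "test"` uses the desk-scale defaults (60 s at 250 Hz,
#' capped connectivity segments); `scale = "full"` the full-scale analogues
#' (180 s at 1000 Hz, all segments).
#'
#' @param ... overrides of the defaults (nested lists merged by name).
#' @return An `nf_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    out_dir = "neurofuse-out",
    scale = "test",
    band_mode = "canonical",          # or "individualized" (for LZC bands)
    simulate = list(n_per_group = 20, preset = "paper_like",
                    duration = 60, fs = 250),
    preprocess = list(notch = 50, band = c(0.5, 45)),
    lzc = list(epoch_len = 4),
    gedbounds = list(f_lo = 2, f_hi = 45, step = 0.5, method = "dbscan"),
    gsngc = list(m = 4, tau = 2, sigma = 4, n_surr = 20, alpha = 0.001,
                 seg_len = 2000, seg_overlap = 0.8, max_segments = 1,
                 max_train = 150, stride = NULL),
    graph = list(mode = "weighted"),
    stats = list(q = 0.05, global_fdr = FALSE),
    classify = list(reps = 5, folds = 10, C = 1),
    force = FALSE
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  cfg <- merge_config(defaults, over)
  if (identical(cfg$scale, "full")) {
    cfg$simulate$duration <- 180
    cfg$simulate$fs <- 1000
    cfg$gsngc$max_segments <- Inf
    cfg$gsngc$max_train <- 400
  }
  structure(cfg, class = "nf_config")
}

merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 paste0(path, nm, "."))
    else base[[nm]] <- over[[nm]]
  }
  base
}

config_hash <- function(cfg) digest::digest(unclass(cfg), algo = "xxhash64")

stage_done <- function(dir, files) all(file.exists(file.path(dir, files)))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Run the full pipeline
#'
#' Executes all stages in order against one output directory, writing
#' per-stage TSV/JSON outputs and a provenance manifest (config, hash,
#' seeds, timings).  A re-run with the same config skips stages whose
#' outputs exist, unless `force`.
#'
#' @param config an [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a result bundle: paths, the feature table, stats
#'   table, CV/ablation results.
#' @export
run_all <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "nf_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage, expr) {
    s <- Sys.time()
    on.exit(timings[[stage]] <<- as.numeric(difftime(Sys.time(), s,
                                                     units = "secs")))
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  od <- config$out_dir

  # --- simulate
  sim_dir <- file.path(od, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  cohort <- tick("simulate", {
    say("[simulate] %d per group (%s)", config$simulate$n_per_group,
        config$simulate$preset)
    ch <- generate_cohort(config$simulate$n_per_group,
                          preset = config$simulate$preset,
                          base_seed = config$seed,
                          duration = config$simulate$duration,
                          fs = config$simulate$fs)
    if (config$force || !stage_done(sim_dir, "manifest.yaml"))
      write_cohort(ch, sim_dir)
    ch
  })
  subjects <- cohort$truth$subjects

  # --- preprocess
  recs <- tick("preprocess", {
    say("[preprocess] notch %s, band [%s]", config$preprocess$notch,
        paste(config$preprocess$band, collapse = ", "))
    lapply(cohort$recordings, preprocess, notch = config$preprocess$notch,
           band = config$preprocess$band)
  })
  names(recs) <- subjects$subject

  # --- features: lzc
  lzc_tab <- tick("lzc", {
    say("[lzc] %d subjects", length(recs))
    do.call(rbind, lapply(recs, lzc_features,
                          epoch_len = config$lzc$epoch_len))
  })
  write_tsv(lzc_tab, file.path(od, "lzc.tsv"))

  # --- features: gedbounds
  gb <- tick("gedbounds", {
    say("[gedbounds] %g-%g Hz step %g (%s)", config$gedbounds$f_lo,
        config$gedbounds$f_hi, config$gedbounds$step,
        config$gedbounds$method)
    lapply(recs, function(r)
      gedbounds(r, f_lo = config$gedbounds$f_lo,
                f_hi = config$gedbounds$f_hi, step = config$gedbounds$step,
                method = config$gedbounds$method))
  })
  bounds_tab <- do.call(rbind, lapply(names(gb), function(s)
    cbind(subject = s, gb[[s]]$canonical)))
  write_tsv(bounds_tab, file.path(od, "bounds.tsv"))
  power_tab <- do.call(rbind, lapply(names(gb), function(s)
    individualized_band_power(recs[[s]], gb[[s]])))
  write_tsv(power_tab, file.path(od, "powers.tsv"))

  # --- features: gsngc + graph
  conn <- tick("gsngc", {
    say("[gsngc] %d subjects x 4 bands x %d surrogates",
        length(recs), config$gsngc$n_surr)
    gpar <- config$gsngc
    if (is.null(gpar$stride)) {
      # autoregression spacing of about 12 ms, in samples (see vignette)
      gpar$stride <- max(1, round(recs[[1]]$fs * 0.012))
    }
    cl <- lapply(names(recs), function(s) {
      bank <- bandpass_bank(recs[[s]])
      do.call(connectivity,
              c(list(rec_by_band = bank,
                     seed = child_seed(config$seed, match(s, names(recs)))),
                gpar))
    })
    names(cl) <- names(recs)
    cl
  })
  conn_dir <- file.path(od, "conn")
  dir.create(conn_dir, showWarnings = FALSE)
  for (s in names(conn))
    for (bn in names(conn[[s]]$matrices))
      write_tsv(as.data.frame(conn[[s]]$matrices[[bn]]),
                file.path(conn_dir, paste0(s, "_", bn, ".tsv")))
  gtab <- tick("graph", metric_table(conn, mode = config$graph$mode))
  write_tsv(gtab$global, file.path(od, "graph.tsv"))
  write_tsv(gtab$nodal, file.path(od, "graph_nodal.tsv"))

  # --- stats
  fused <- assemble_features(lzc_tab, fill_missing_power(power_tab, recs),
                             conn, gtab$nodal, subjects)
  stats_tab <- tick("stats", {
    long <- features_long(fused)
    group_compare_table(long, group_a = "ASD-like", group_b = "TD-like",
                        q = config$stats$q,
                        global_fdr = config$stats$global_fdr)
  })
  write_tsv(stats_tab, file.path(od, "stats.tsv"))

  # --- classify
  cls <- tick("classify", {
    say("[classify] %dx%d-fold CV", config$classify$reps,
        config$classify$folds)
    ab <- ablation(fused, reps = config$classify$reps,
                   folds = config$classify$folds, C = config$classify$C,
                   seed = config$seed)
    base <- baseline_demographics(subjects$age, subjects$sex,
                                  subjects$group, subjects$subject,
                                  reps = config$classify$reps,
                                  folds = config$classify$folds,
                                  C = config$classify$C, seed = config$seed)
    list(ablation = ab, baseline = base)
  })
  write_tsv(cls$ablation$table, file.path(od, "report.tsv"))
  jsonlite::write_json(
    list(ablation = cls$ablation$table,
         baseline = cls$baseline$summary,
         config = unclass(config)),
    file.path(od, "cv.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "neurofuse",
    version = as.character(utils::packageVersion("neurofuse")),
    config_hash = config_hash(config),
    seed = config$seed,
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    timings_s = lapply(timings, function(x) round(x, 2)),
    outputs = list.files(od, recursive = TRUE))
  yaml::write_yaml(manifest, file.path(od, "provenance.yaml"))
  say("[done] %s (%.1f s)", od,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(dir = od, features = fused, stats = stats_tab,
                 classify = cls, bounds = gb, connectivity = conn,
                 lzc = lzc_tab, powers = power_tab, graph = gtab,
                 cohort = cohort, manifest = manifest))
}

# unassigned individualized bands yield NA power; the classifier contract
# requires a complete block, so fall back to canonical-interval Welch power
fill_missing_power <- function(power_tab, recs) {
  bad <- which(!is.finite(power_tab$power))
  if (!length(bad)) return(power_tab)
  cb <- canonical_bands()
  for (i in bad) {
    rec <- recs[[power_tab$subject[i]]]
    w <- welch_psd(rec)
    b <- cb[[power_tab$band[i]]]
    sel <- w$freq >= b[1] & w$freq <= b[2]
    ch <- match(power_tab$channel[i], rec$labels)
    power_tab$power[i] <- mean(w$psd[ch, sel])
    power_tab$lo[i] <- b[1]; power_tab$hi[i] <- b[2]
  }
  power_tab
}

features_long <- function(fused) {
  blk <- attr(fused, "block")
  cols <- names(blk)
  fam <- ifelse(blk == "T", "lzc",
                ifelse(blk == "F", "band_power",
                       ifelse(grepl("^S_conn", cols), "connectivity",
                              "graph")))
  do.call(rbind, lapply(seq_along(cols), function(j)
    data.frame(subject = fused$subject, group = fused$group,
               family = fam[j], feature = cols[j],
               value = unname(fused[[cols[j]]]), row.names = NULL)))
}

#' Write a generated cohort to disk
#'
#' One TSV matrix per subject, a ground-truth band table, a coupling table,
#' a subject table and a YAML manifest.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  subs <- cohort$truth$subjects
  files <- character(nrow(subs))
  for (i in seq_len(nrow(subs))) {
    files[i] <- paste0(subs$subject[i], ".tsv")
    write_recording(cohort$recordings[[i]], file.path(dir, files[i]))
  }
  write_tsv(cohort$truth$bands, file.path(dir, "truth_bands.tsv"))
  if (!is.null(cohort$truth$couplings) && nrow(cohort$truth$couplings))
    write_tsv(cohort$truth$couplings, file.path(dir, "truth_couplings.tsv"))
  write_tsv(cohort$truth$directions, file.path(dir, "truth_directions.tsv"))
  write_tsv(subs, file.path(dir, "subjects.tsv"))
  manifest <- list(n_subjects = nrow(subs),
                   groups = as.list(table(subs$group)),
                   fs = cohort$recordings[[1]]$fs,
                   duration_s = ncol(cohort$recordings[[1]]$data) /
                     cohort$recordings[[1]]$fs,
                   effects = cohort$truth$effects,
                   files = files)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return `list(recordings, subjects)`.
#' @export
read_cohort <- function(dir) {
  subs <- read_tsv(file.path(dir, "subjects.tsv"))
  recs <- lapply(seq_len(nrow(subs)), function(i)
    read_recording(file.path(dir, paste0(subs$subject[i], ".tsv")),
                   meta = list(subject = subs$subject[i],
                               group = subs$group[i], age = subs$age[i],
                               sex = subs$sex[i])))
  names(recs) <- subs$subject
  list(recordings = recs, subjects = subs)
}
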