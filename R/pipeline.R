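#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults: the full 6x4 (PBSL, RTTL) design grid over a few
#' hundred synthetic sites, a consecutive-RTTL companion grid at PBSL 13 for
#' the stepwise model, all 24 elastic-net cells, and a reduced neural-net
#' training budget so a complete run stays within minutes on one CPU.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_sites Number of synthetic target sites.
#' @param dnn_epochs Epoch cap for the neural-net stage.
#' @param dnn_max_designs Designs subsampled for neural-net training.
#' @param run_dnn Run the neural-net + interpretation stages (the slowest
#'   part of the pipeline).
#' @param sa_steps,maxent_samples Interpretation-stage chain budgets.
#' @param ... Overrides for [synthetic_config()] fields.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_sites = 210L, dnn_epochs = 80L,
                            dnn_max_designs = 5100L, run_dnn = TRUE,
                            sa_steps = 3000L, maxent_samples = 500L, ...) {
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 dnn_epochs = as.integer(dnn_epochs),
                 dnn_max_designs = as.integer(dnn_max_designs),
                 run_dnn = isTRUE(run_dnn),
                 sa_steps = as.integer(sa_steps),
                 maxent_samples = as.integer(maxent_samples),
                 synthetic = list(...)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()]
#'   arguments (synthetic-world overrides under a `synthetic:` block).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- y$synthetic %||% list()
  y$synthetic <- NULL
  do.call(pipeline_config, c(y, syn))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_bedgraph <- function(track, path) {
  n <- length(track$values)
  df <- data.frame(chrom = track$chrom,
                   start = (seq_len(n) - 1L) * track$bin_size,
                   end = seq_len(n) * track$bin_size,
                   value = track$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  path
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order - simulate, quantify, chromatin,
#' thermodynamics, stepwise regression, elastic nets, neural net,
#' interpretation - writing each stage's outputs under `out_dir` and
#' returning a manifest with file checksums and a metric summary.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param out_dir Output directory (created if missing).
#' @return List of class `run_manifest`: `config`, `files` (named md5
#'   checksums), `metrics`, `timings` (seconds per stage).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("pegforge_run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  metrics <- list()
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  ## -- simulate ------------------------------------------------------------
  dataset <- stage("simulate", {
    syn_args <- c(list(seed = config$seed, n_sites = config$n_sites), config$synthetic)
    cfg <- do.call(synthetic_config, syn_args)
    sites <- generate_sites(cfg)
    designs <- design_grid(sites)
    ds <- generate_edit_percentages(sites, designs, cfg)
    files["sites"] <- write_tsv(sites, file.path(out_dir, "sites.tsv"))
    files["designs"] <- write_tsv(
      cbind(ds$designs, ds$observed_ep), file.path(out_dir, "designs.tsv"))
    genome <- Biostrings::DNAStringSet(attr(sites, "genome"))
    Biostrings::writeXStringSet(genome, file.path(out_dir, "genome.fa"))
    files["genome"] <- file.path(out_dir, "genome.fa")
    ds
  })

  ## gate-off companion dataset for the sequence-only models (the assay they
  ## emulate uses integrated constructs without genomic chromatin context)
  nogate_cfg <- local({
    syn_args <- c(list(seed = config$seed, n_sites = config$n_sites), config$synthetic)
    syn_args$chromatin_slope <- 0
    do.call(synthetic_config, syn_args)
  })
  dataset_nogate <- generate_edit_percentages(
    dataset$sites, dataset$designs[c("design_id", "site_id", "pbsl", "rttl")],
    nogate_cfg)

  ## -- quantify: read-level round trip on a handful of loci ---------------
  metrics$quantify <- stage("quantify", {
    ord <- order(-dataset$designs$true_ep)
    # one design per site so read tables of different designs never mix
    take <- ord[!duplicated(dataset$designs$site_id[ord])][1:5]
    reads <- do.call(rbind, lapply(seq_along(take), function(j) {
      i <- take[j]
      generate_reads(dataset$designs$site_id[i], dataset$designs$true_ep[i],
                     n_pairs = 4000L, seed = config$seed + j)
    }))
    files["reads"] <- write_tsv(reads, file.path(out_dir, "reads.tsv"))
    est <- vapply(seq_along(take), function(j) {
      i <- take[j]
      edit_percentage(reads[startsWith(reads$read_id, dataset$designs$site_id[i]), ])
    }, numeric(1))
    list(max_abs_error = max(abs(est - dataset$designs$true_ep[take])))
  })

  ## -- chromatin: consensus peaks + editability classifier -----------------
  metrics$chromatin <- stage("chromatin", {
    chip <- generate_chip_tracks(seed = config$seed + 10L)
    peaks <- consensus_enrichment(chip$tracks)
    for (t in chip$tracks) {
      files[paste0("track_", t$sample)] <- write_bedgraph(
        t, file.path(out_dir, paste0("track_", t$sample, ".bedGraph")))
    }
    files["peaks"] <- write_bed(peaks, file.path(out_dir, "consensus_peaks.bed"))
    files["peaks_truth"] <- write_bed(chip$truth, file.path(out_dir, "peaks_truth.bed"))
    site_ep <- tapply(dataset$designs$mean_observed_ep, dataset$designs$site_id, mean)
    sites <- dataset$sites[match(names(site_ep), dataset$sites$site_id), ]
    editable <- site_ep > 1
    model_metrics <- if (length(unique(editable)) == 2L) {
      model <- fit_editability(log10(pmax(sites$dist_kb, 0.1)), editable)
      eval <- evaluate_classifier(
        predict(model, log10(pmax(sites$dist_kb, 0.1))), editable,
        threshold = model$prob_threshold)
      writeLines(jsonlite::toJSON(list(
        coefficients = as.list(model$coefficients),
        prob_threshold = model$prob_threshold,
        distance_threshold_kb = model$distance_threshold_kb
      ), auto_unbox = TRUE, digits = NA), file.path(out_dir, "editability_model.json"))
      files["editability_model"] <- file.path(out_dir, "editability_model.json")
      list(auroc = eval$auroc, accuracy = eval$accuracy,
           distance_threshold_kb = model$distance_threshold_kb)
    } else {
      list(auroc = NA_real_, accuracy = NA_real_, distance_threshold_kb = NA_real_)
    }
    c(list(peak_jaccard = interval_jaccard(peaks, chip$truth)), model_metrics)
  })

  ## -- thermodynamics ------------------------------------------------------
  metrics$thermo <- stage("thermo", {
    params <- nn_params()
    d <- dataset_nogate$designs
    win <- dataset$sites$window[match(d$site_id, dataset$sites$site_id)]
    per_nt <- vapply(seq_len(nrow(d)), function(i)
      pbs_energy_for_design(win[i], d$pbsl[i], params)$per_nt_dG, numeric(1))
    energy_tab <- data.frame(design_id = d$design_id, pbsl = d$pbsl,
                             rttl = d$rttl, per_nt_dG = per_nt,
                             mean_observed_ep = d$mean_observed_ep)
    files["pbs_energy"] <- write_tsv(energy_tab, file.path(out_dir, "pbs_energy.tsv"))
    cor_at <- function(p) stats::cor(per_nt[d$pbsl == p], d$mean_observed_ep[d$pbsl == p])
    list(cor_pbsl7 = cor_at(7L), cor_pbsl17 = cor_at(17L))
  })

  ## -- stepwise regression on a consecutive-RTTL companion grid ------------
  metrics$stepwise <- stage("stepwise", {
    step_designs <- design_grid(dataset$sites, pbsl = 13L, rttl = 10:20)
    step_ds <- generate_edit_percentages(dataset$sites, step_designs, nogate_cfg)
    ep_table <- data.frame(locus = step_ds$designs$site_id,
                           rttl = step_ds$designs$rttl,
                           ep = step_ds$designs$mean_observed_ep)
    windows <- stats::setNames(dataset$sites$window, dataset$sites$site_id)
    obs <- build_step_observations(ep_table, windows)
    fit <- fit_stepwise(obs)
    cv <- crossvalidate_stepwise(obs, k = 8L, seed = config$seed)
    loc1 <- obs$locus[1]
    traj <- predict_trajectory(fit, windows[[loc1]], 10:20,
                               mean(ep_table$ep[ep_table$locus == loc1]))
    files["trajectory"] <- write_tsv(traj, file.path(out_dir, "trajectory.tsv"))
    files["step_fit"] <- {
      p <- file.path(out_dir, "stepwise_fit.json")
      writeLines(jsonlite::toJSON(list(a0 = as.list(fit$a0), a1 = as.list(fit$a1),
                                       intercept = fit$intercept),
                                  auto_unbox = TRUE, digits = NA), p)
      p
    }
    list(cv_rmse = cv$mean_rmse, cv_r = cv$mean_r)
  })

  ## -- elastic nets, one per (PBSL, RTTL) cell -----------------------------
  metrics$elastic <- stage("elastic", {
    d <- dataset_nogate$designs
    win <- dataset$sites$window[match(d$site_id, dataset$sites$site_id)]
    X <- one_hot_encode(dataset$sites$window)
    rows <- match(d$site_id, dataset$sites$site_id)
    cells <- unique(d[c("pbsl", "rttl")])
    res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- d$pbsl == cells$pbsl[i] & d$rttl == cells$rttl[i]
      fit <- fit_elastic(X[rows[sel], , drop = FALSE], d$mean_observed_ep[sel],
                         seed = config$seed, pbsl = cells$pbsl[i],
                         rttl = cells$rttl[i])
      pred <- predict(fit, X[rows[sel], , drop = FALSE])
      train_r <- if (stats::sd(pred) > 0) {
        stats::cor(pred, d$mean_observed_ep[sel])
      } else NA_real_  # fully shrunk fit: constant predictions
      data.frame(pbsl = cells$pbsl[i], rttl = cells$rttl[i],
                 lambda = fit$lambda, nonzero = sum(fit$beta != 0),
                 train_r = train_r)
    }))
    files["elastic_cells"] <- write_tsv(res, file.path(out_dir, "elastic_cells.tsv"))
    # coefficient letter-height table for the reference cell (PBSL 13, RTTL 15)
    ref_sel <- d$pbsl == 13L & d$rttl == 15L
    ref <- fit_elastic(X[rows[ref_sel], , drop = FALSE],
                       d$mean_observed_ep[ref_sel], seed = config$seed,
                       pbsl = 13L, rttl = 15L)
    coef_tab <- data.frame(feature = names(ref$beta), beta = unname(ref$beta),
                           height = abs(unname(ref$beta)))
    files["elastic_coefficients"] <- write_tsv(
      coef_tab, file.path(out_dir, "elastic_coefficients.tsv"))
    list(n_cells = nrow(res), mean_train_r = mean(res$train_r, na.rm = TRUE))
  })

  ## -- neural net + interpretation -----------------------------------------
  if (config$run_dnn) {
    dnn_res <- stage("dnn", {
      d <- dataset_nogate$designs
      if (nrow(d) > config$dnn_max_designs) {
        set.seed(config$seed + 20L)
        d <- d[sort(sample.int(nrow(d), config$dnn_max_designs)), ]
      }
      win <- dataset$sites$window[match(d$site_id, dataset$sites$site_id)]
      X <- build_input_matrix(win, d$pbsl, d$rttl)
      sp <- split_grouped(d$site_id, seed = config$seed)
      ep <- d$mean_observed_ep
      trained <- dnn_train(dnn_new(seed = config$seed),
                           X[sp$train, ], ep[sp$train], X[sp$val, ], ep[sp$val],
                           max_epochs = config$dnn_epochs, seed = config$seed)
      pred <- dnn_predict(trained$model, X[sp$test, ])
      list(model = trained$model,
           test_r = stats::cor(pred, ep[sp$test]),
           best_epoch = trained$best_epoch)
    })
    metrics$dnn <- dnn_res[c("test_r", "best_epoch")]

    metrics$interpret <- stage("interpret", {
      scorer <- function(w) dnn_predict(dnn_res$model,
                                        matrix(flatten_input(build_input(w, 13L, 15L)), 1L))
      sa <- sa_optimize(scorer, dataset$sites$window[1],
                        sa_config(n_steps = config$sa_steps, seed = config$seed))
      files["sa_trace"] <- write_tsv(sa$trace, file.path(out_dir, "sa_trace.tsv"))
      # widen the band and retry if the chain cannot move at the default delta
      delta <- max(0.05 * abs(sa$best_score), 0.5)
      me <- NULL
      for (attempt in 1:4) {
        me <- tryCatch(
          maxent_sample(scorer, sa$best_window, delta = delta,
                        n_samples = config$maxent_samples, seed = config$seed),
          error = function(e) NULL)
        if (!is.null(me)) break
        delta <- delta * 4
      }
      if (is.null(me)) stop("MaxEnt chain stuck even after widening delta")
      prof <- kl_profile(me$samples)
      files["kl_profile"] <- write_tsv(prof, file.path(out_dir, "kl_profile.tsv"))
      d <- dataset$designs
      win <- dataset$sites$window[match(d$site_id, dataset$sites$site_id)]
      cond <- conditional_effect(win, d$mean_observed_ep, focal_pos = 9L,
                                 condition = list(`8` = "T", `10` = "G"))
      files["conditional"] <- write_tsv(cond, file.path(out_dir, "conditional_effect.tsv"))
      list(sa_best_score = sa$best_score,
           maxent_acceptance = me$acceptance,
           max_kl_position = prof$position[which.max(prof$kl)])
    })
  }

  manifest <- structure(list(
    config = config,
    seed = config$seed,
    files = vapply(files, function(f) unname(tools::md5sum(f)), character(1)),
    metrics = metrics,
    timings = timings,
    out_dir = out_dir
  ), class = "run_manifest")
  writeLines(jsonlite::toJSON(list(seed = manifest$seed,
                                   files = as.list(manifest$files),
                                   metrics = manifest$metrics,
                                   timings = as.list(manifest$timings)),
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  manifest
}

#' Human-readable summary of a pipeline run
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param file Optional path to also write the report text to.
#' @return The report lines, invisibly.
#' @export
report <- function(manifest, file = NULL) {
  if (!inherits(manifest, "run_manifest") || length(manifest$metrics) == 0L) {
    stop("a completed run_manifest is required")
  }
  m <- manifest$metrics
  lines <- c(
    "pegforge pipeline report",
    sprintf("  seed %d; outputs in %s", manifest$seed, manifest$out_dir),
    sprintf("  quantify: max |EP error| on read-level round trip = %.3f pp",
            m$quantify$max_abs_error),
    sprintf("  chromatin: peak Jaccard vs truth = %.3f; AUROC = %s; distance threshold = %s kb",
            m$chromatin$peak_jaccard,
            format(round(m$chromatin$auroc, 3)),
            format(signif(m$chromatin$distance_threshold_kb, 3))),
    sprintf("  thermo: cor(per-nt dG, EP) = %.3f at PBSL 7 vs %.3f at PBSL 17",
            m$thermo$cor_pbsl7, m$thermo$cor_pbsl17),
    sprintf("  stepwise: locus-grouped CV RMSE = %.3f pp, mean Pearson r = %.3f",
            m$stepwise$cv_rmse, m$stepwise$cv_r),
    sprintf("  elastic: %d (PBSL, RTTL) cells fitted, mean training r = %.3f",
            m$elastic$n_cells, m$elastic$mean_train_r)
  )
  if (!is.null(m$dnn)) {
    lines <- c(lines,
      sprintf("  dnn: held-out Pearson r = %.3f (best epoch %d)",
              m$dnn$test_r, m$dnn$best_epoch),
      sprintf("  interpret: SA best score = %.2f; max-KL position = %+d",
              m$interpret$sa_best_score, m$interpret$max_kl_position))
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", length(x$files), "files,",
      length(x$metrics), "stage metric sets; total",
      round(sum(unlist(x$timings)), 1), "s\n")
  invisible(x)
}
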