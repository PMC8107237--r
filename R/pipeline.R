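# ---- pipeline stages -------------------------------------------------

# decompose both power modes
stage_decompose <- function(study, config) {
  lapply(list(abs = study$E_abs, rel = study$E_rel), function(Es) {
    red <- stack_and_reduce(Es, config$n_pcs_unit, config$n_pcs_group)
    infomax_ica(red, m = config$n_pcs_group, n_runs = config$n_runs,
                seed = child_seed(config$seed, 301L,
                                  if (Es[[1]]$power_mode == "absolute")
                                    1L else 2L))
  })
}

# per-subject fluctuation matrix U (rows = epochs over sessions,
# columns = stable patterns) for one model
subject_fluctuation_matrix <- function(study, decomps, stable, model,
                                       subject) {
  sessions <- length(study$schedules[[subject]])
  units <- vapply(seq_len(sessions), function(j) unit_id(subject, j), "")
  cols <- lapply(seq_len(nrow(stable)), function(i) {
    if (model %in% c("ASM", "RSM")) {
      dec <- if (model == "ASM") decomps$abs else decomps$rel
      idx <- if (model == "ASM") stable$abs_index[i] else
        stable$rel_index[i]
      g <- average_over_leads(pattern_matrix(dec, idx))
      Es <- (if (model == "ASM") study$E_abs else study$E_rel)[units]
      pattern_fluctuation(model, E_list = Es, g = g,
                          subject_id = subject,
                          label = stable$label[i])$values
    } else {
      dec <- if (model == "ASSM") decomps$abs else decomps$rel
      idx <- if (model == "ASSM") stable$abs_index[i] else
        stable$rel_index[i]
      pattern_fluctuation(model, decomposition = dec,
                          pattern_index = idx, unit_ids = units,
                          subject_id = subject,
                          label = stable$label[i])$values
    }
  })
  U <- do.call(cbind, cols)
  colnames(U) <- stable$label
  U
}

# match patterns across modes, regress fluctuations on the task design,
# and select task-related patterns
stage_select <- function(study, decomps, config, models) {
  if (config$subjects < 2) {
    stopf("group pattern statistics need at least 2 subjects")
  }
  pattern_set <- match_across_power_modes(decomps$abs, decomps$rel,
                                          r_min = config$r_min,
                                          stability_min =
                                            config$stability_min,
                                          var_share_min =
                                            config$var_share_min)
  stable <- pattern_set[pattern_set$stable, , drop = FALSE]
  if (!nrow(stable)) {
    stopf("no stable patterns found across power modes")
  }
  designs <- lapply(study$schedules, build_task_design, TR = config$TR,
                    n_epochs = config$n_scans)
  types <- designs[[1]]$types
  t_tables <- list()
  fluct <- list()
  for (model in models) {
    betas <- vector("list", config$subjects)
    Us <- vector("list", config$subjects)
    for (s in seq_len(config$subjects)) {
      U <- subject_fluctuation_matrix(study, decomps, stable, model, s)
      Us[[s]] <- U
      betas[[s]] <- fit_pattern_glm(U, designs[[s]])
    }
    tt <- vapply(types, function(ty) {
      group_ttest(betas, contrast_for_type(designs[[1]], ty))$t
    }, numeric(nrow(stable)))
    tt <- matrix(tt, nrow = nrow(stable),
                 dimnames = list(stable$label, types))
    t_tables[[model]] <- tt
    fluct[[model]] <- Us
  }
  selection <- select_task_related(t_tables, t_crit = config$t_crit,
                                   mean_crit = config$mean_crit,
                                   std_crit = config$std_crit)
  list(pattern_set = pattern_set, stable = stable, t_tables = t_tables,
       selection = selection, fluctuations = fluct, types = types)
}

# fuse every selected pattern with the BOLD data under each model
stage_fuse <- function(study, sel, config, models, patterns = NULL) {
  if (config$subjects < 2) {
    stopf("group F statistics need at least 2 subjects")
  }
  basis <- canonical_basis(dt = config$hrf_dt,
                           duration = config$hrf_duration)
  chosen <- unique(sel$selection$pattern[sel$selection$selected])
  if (!is.null(patterns)) chosen <- intersect(chosen, patterns)
  grid_shape <- dim(study$volumes[[1]][[1]]$data)[1:3]
  ref <- study$volumes[[1]][[1]]
  betas <- list() # [pattern.model][[subject]]
  for (s in seq_len(config$subjects)) {
    # scans x voxels matrix built once per subject, shared by all maps
    Y <- do.call(rbind, lapply(study$volumes[[s]], function(v) {
      t(matrix(v$data, ncol = dim(v$data)[4]))
    }))
    for (lab in chosen) {
      for (model in models) {
        U <- sel$fluctuations[[model]][[s]]
        fl <- list(values = U[, lab],
                   session = rep(seq_len(config$sessions),
                                 each = config$n_scans))
        reg <- build_regressors(fl, basis, config$TR, config$n_scans)
        fit <- voxel_glm_fit(Y, reg, config$estimator)
        key <- paste(lab, model, sep = ".")
        betas[[key]][[s]] <- structure(
          list(b1 = array(fit$beta[1, ], grid_shape),
               b2 = array(fit$beta[2, ], grid_shape),
               b3 = array(fit$beta[3, ], grid_shape),
               sigma2 = array(fit$sig2, grid_shape),
               mask = NULL, grid_shape = grid_shape,
               voxel_size = ref$voxel_size, affine = ref$affine,
               rho = fit$rho, method = config$estimator,
               subject_id = s), class = "voxel_betas")
      }
    }
  }
  fmaps <- list()
  for (lab in chosen) {
    for (model in models) {
      key <- paste(lab, model, sep = ".")
      fmap <- sign_f_map(group_f_test(betas[[key]]), basis)
      fmaps[[key]] <- list(pattern = lab, model = model, fmap = fmap)
    }
  }
  list(fmaps = fmaps, basis = basis)
}

# threshold, cluster and summarize every fused map
stage_stats <- function(fused, config) {
  rows <- lapply(fused$fmaps, function(fm) {
    cl <- threshold_and_cluster(fm$fmap, config$f_crit,
                                config$min_extent, config$connectivity)
    st <- summarize_clusters(fm$fmap, cl)
    list(pattern = fm$pattern, model = fm$model, clusters = cl,
         stats = st)
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    data.frame(pattern = r$pattern, model = r$model,
               volume_mm3 = r$stats$volume_mm3,
               mean_F = r$stats$mean_F, median_F = r$stats$median_F,
               max_F = r$stats$max_F, n_clusters = r$stats$n_clusters,
               stringsAsFactors = FALSE)
  }))
  list(per_map = rows, table = tab)
}

# cluster-mean response shapes for one fused map
cluster_hrf_table <- function(fm, clusters, basis) {
  if (clusters$n_clusters == 0) return(NULL)
  out <- data.frame(time = basis$t)
  for (k in seq_len(clusters$n_clusters)) {
    vox <- which(clusters$labels == k)
    b <- c(mean(fm$mean_b1[vox]), mean(fm$mean_b2[vox]),
           mean(fm$mean_b3[vox]))
    out[[sprintf("cluster%02d", k)]] <- reconstruct_hrf(b, basis)$h
  }
  out
}

#' Run the blind task-network visualization pipeline
#'
#' Executes simulate (or load) -> epoch spectra (both power modes) ->
#' group decomposition (both modes) -> cross-mode matching and
#' task-related pattern selection -> per-model EEG-fMRI fusion with the
#' variable response basis -> signed group F-maps -> cluster statistics.
#' With an `out_dir`, stage outputs (selection and spatial statistic
#' TSVs, signed F-map NIfTIs, cluster response-shape TSVs, a run log and
#' per-stage checkpoints) are written as they complete, so a failing
#' stage leaves prior results on disk.
#'
#' @param config a [study_config()] object.
#' @param out_dir optional output directory.
#' @param input_dir optional dataset directory ([generate_dataset()]);
#'   when absent the study is simulated in memory.
#' @param seed master seed (defaults to `config$seed`).
#' @param models subset of `c("ASM", "RSM", "ASSM", "RSSM")`.
#' @param stages stages to run, a prefix-closed subset of
#'   `c("simulate", "decompose", "select", "fuse", "stats")`; later
#'   stages resume from checkpoints in `out_dir`.
#' @param fuse_patterns optional pattern labels restricting the fusion
#'   stage (default: all selected patterns).
#' @param verbose print stage progress.
#' @return a `pipeline_result` list with the study, decompositions,
#'   pattern set, t-value tables, selection data frame, fused maps and
#'   the spatial statistics table.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         input_dir = NULL, seed = config$seed,
                         models = config$models,
                         stages = c("simulate", "decompose", "select",
                                    "fuse", "stats"),
                         fuse_patterns = NULL,
                         verbose = FALSE) {
  config$seed <- seed
  t0 <- proc.time()[3]
  log_lines <- c(sprintf("specfuse %s | R %s | seed %d | models %s",
                         as.character(utils::packageVersion("specfuse")),
                         getRversion(), seed,
                         paste(models, collapse = ",")))
  checkpoint <- !is.null(out_dir)
  if (checkpoint) dir.create(out_dir, recursive = TRUE,
                             showWarnings = FALSE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%8.1fs] %s",
                                       proc.time()[3] - t0, msg))
    if (verbose) message(msg)
  }
  load_ck <- function(name) {
    path <- file.path(out_dir, paste0(name, ".rds"))
    if (checkpoint && file.exists(path)) readRDS(path) else
      stopf("stage '%s' needs the '%s' checkpoint in out_dir",
            name, name)
  }
  save_ck <- function(obj, name) {
    if (checkpoint) saveRDS(obj, file.path(out_dir,
                                           paste0(name, ".rds")))
  }
  res <- list(config = config)

  run_stage <- function(name, fun) {
    say("stage %s: start", name)
    out <- fun()
    say("stage %s: done", name)
    out
  }
  study <- if ("simulate" %in% stages) {
    run_stage("simulate", function() {
      st <- if (!is.null(input_dir)) load_study(input_dir, config)
      else simulate_study(config, seed)
      save_ck(st, "study")
      st
    })
  } else load_ck("study")
  res$study <- study

  decomps <- if ("decompose" %in% stages) {
    run_stage("decompose", function() {
      d <- stage_decompose(study, config)
      save_ck(d, "decompose")
      d
    })
  } else if (any(c("select", "fuse", "stats") %in% stages)) {
    load_ck("decompose")
  }
  res$decompositions <- decomps

  sel <- if ("select" %in% stages) {
    run_stage("select", function() {
      s <- stage_select(study, decomps, config, models)
      if (checkpoint) {
        utils::write.table(s$selection,
                           file.path(out_dir, "t_values.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      save_ck(s, "select")
      s
    })
  } else if (any(c("fuse", "stats") %in% stages)) load_ck("select")
  res$pattern_set <- sel$pattern_set
  res$t_tables <- sel$t_tables
  res$selection <- sel$selection

  fused <- if ("fuse" %in% stages) {
    run_stage("fuse", function() {
      f <- stage_fuse(study, sel, config, models, fuse_patterns)
      if (checkpoint) {
        for (nm in names(f$fmaps)) {
          fm <- f$fmaps[[nm]]$fmap
          write_fmri_nifti(fm$signed_F,
                           file.path(out_dir,
                                     sprintf("%s_signedF.nii.gz", nm)),
                           voxel_size = fm$voxel_size,
                           affine = fm$affine)
        }
      }
      save_ck(f, "fuse")
      f
    })
  } else if ("stats" %in% stages) load_ck("fuse")
  res$fused = fused

  if ("stats" %in% stages) {
    stats_out <- run_stage("stats", function() {
      st <- stage_stats(fused, config)
      if (checkpoint) {
        utils::write.table(st$table,
                           file.path(out_dir, "spatial_stats.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (r in st$per_map) {
          ht <- cluster_hrf_table(
            fused$fmaps[[paste(r$pattern, r$model,
                               sep = ".")]]$fmap,
            r$clusters, fused$basis)
          if (!is.null(ht)) {
            utils::write.table(
              ht, file.path(out_dir, sprintf("hrf_%s_%s.tsv", r$pattern,
                                             r$model)),
              sep = "\t", quote = FALSE, row.names = FALSE)
          }
        }
      }
      st
    })
    res$stats <- stats_out$table
    res$per_map <- stats_out$per_map
  }
  if (checkpoint) {
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  structure(res, class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$selection)) {
    sel <- x$selection[x$selection$selected, c("pattern", "type",
                                               "mean_t")]
    cat(sprintf("  selected pattern-type pairs: %d\n", nrow(sel)))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  fused maps: %d\n", nrow(x$stats)))
  }
  invisible(x)
}

#' Read a pipeline/study configuration from a YAML or JSON file
#'
#' Scalar fields override [study_config()] defaults; unknown fields are
#' rejected. Pattern specifications may be given as a list of records
#' with the [pattern_spec()] fields.
#'
#' @param path YAML or JSON file.
#' @return a [study_config()] object.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$patterns)) {
    raw$patterns <- lapply(raw$patterns, function(p) {
      do.call(pattern_spec, p)
    })
  }
  if (!is.null(raw$proportions)) raw$proportions <- unlist(raw$proportions)
  do.call(study_config, raw)
}
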