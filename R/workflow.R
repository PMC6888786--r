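#' Pipeline configuration
#'
#' Collects and validates every tunable parameter of the simulated-study
#' pipeline. The configuration is fully serializable; a short hash of its
#' JSON form is stamped into run metadata so outputs can be traced to the
#' exact settings that produced them.
#'
#' @param seed Master seed; all stage and subject randomness derives from it.
#' @param q Number of regions.
#' @param n_middlemen Planted middleman count.
#' @param density Background edge density of the ground truth.
#' @param coeff_scale Lag-1 coefficient magnitude.
#' @param T Timepoints per subject.
#' @param TR Repetition time, seconds.
#' @param dt_hr Simulation grid step, seconds.
#' @param group_sizes Four subject counts (NC, EMCI, LMCI, AD).
#' @param pruning_fractions Four non-decreasing pruning fractions.
#' @param behav_coupling Behavioral coupling multiplier.
#' @param noise_sd Neural innovation SD.
#' @param obs_noise_sd Observation noise SD.
#' @param threshold_sd Pseudo-event threshold (SD units).
#' @param nsr Wiener noise-to-signal regularizer (or "auto").
#' @param window_s HRF window, seconds.
#' @param order MVAR model order.
#' @param n_surr Surrogate replicates per subject.
#' @param alpha_edge FDR level for edge selection.
#' @param alpha_group FDR level per group comparison.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, q = 16, n_middlemen = 3, density = 0.15,
                            coeff_scale = 0.65, T = 140, TR = 3, dt_hr = 0.5,
                            group_sizes = c(10, 10, 10, 10),
                            pruning_fractions = c(0, 0.3, 0.6, 0.9),
                            behav_coupling = 1, noise_sd = 1,
                            obs_noise_sd = 1, threshold_sd = 1, nsr = 0.1,
                            window_s = 30, order = 1, n_surr = 1000,
                            alpha_edge = 0.05, alpha_group = 0.05) {
  cfg <- list(seed = seed, q = q, n_middlemen = n_middlemen, density = density,
              coeff_scale = coeff_scale, T = T, TR = TR, dt_hr = dt_hr,
              group_sizes = group_sizes, pruning_fractions = pruning_fractions,
              behav_coupling = behav_coupling, noise_sd = noise_sd,
              obs_noise_sd = obs_noise_sd, threshold_sd = threshold_sd,
              nsr = nsr, window_s = window_s, order = order, n_surr = n_surr,
              alpha_edge = alpha_edge, alpha_group = alpha_group)
  stopifnot(q >= 6, T >= 2 * order + 1, TR > 0, dt_hr > 0,
            length(group_sizes) == 4, all(group_sizes >= 1),
            length(pruning_fractions) == 4,
            all(diff(pruning_fractions) >= 0),
            pruning_fractions[1] >= 0, pruning_fractions[4] <= 1,
            order >= 1, n_surr >= 19,
            alpha_edge > 0, alpha_edge < 1, alpha_group > 0, alpha_group < 1)
  if (abs(TR / dt_hr - round(TR / dt_hr)) > 1e-9)
    stopf("TR must be an integer multiple of dt_hr")
  if (q >= 100 || sum(group_sizes) >= 100)
    message("large configuration (q, n_surr or cohort size at acquisition scale); expect a long run")
  cfg$hash <- fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("Pipeline config %s: q = %d, T = %d, TR = %gs, groups %s, n_surr = %d, seed = %d\n",
              x$hash, x$q, x$T, x$TR, paste(x$group_sizes, collapse = "/"),
              x$n_surr, x$seed))
  invisible(x)
}

stage_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  sprintf(msg, ...)))
}

#' Run the full simulated study
#'
#' End-to-end orchestration: synthetic cohort generation, blind
#' deconvolution, surrogate-thresholded causal networks, nodal graph
#' measures, the six-comparison progressive analysis for middleman power and
#' betweenness centrality, behavioral correlations, and the undirected-FC
#' control arm. All artifacts are persisted under `out_dir`; rerunning with
#' the same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @param deconvolve Apply blind deconvolution before network estimation
#'   (disable to run the causal analysis on the raw observed series).
#' @return A list with `cohort`, `measures_mp`, `measures_bc` (subject x
#'   node matrices), `report_mp`, `report_bc`, `report_fc`,
#'   `behavioral` (per-score correlations for MP at the planted middlemen),
#'   `networks` (per-subject `cpgc_result`), `ground_truth`, `config`.
#' @export
run_simulated_study <- function(config = pipeline_config(), out_dir = NULL,
                                deconvolve = TRUE) {
  stage_seeds <- derive_seeds(config$seed, 3L, salt = 1L)
  stage_log("simulate", "generating ground truth (q = %d) and cohort", config$q)
  gt <- make_ground_truth_network(config$q, config$n_middlemen,
                                  config$density, config$coeff_scale,
                                  seed = stage_seeds[1])
  cohort_data <- generate_cohort(gt, group_sizes = config$group_sizes,
                                 pruning_fractions = config$pruning_fractions,
                                 behav_coupling = config$behav_coupling,
                                 seed = stage_seeds[2], T = config$T,
                                 TR = config$TR, dt_hr = config$dt_hr,
                                 noise_sd = config$noise_sd,
                                 obs_noise_sd = config$obs_noise_sd)
  res <- analyze_cohort(cohort_data$timeseries, cohort_data$cohort, config,
                        seed = stage_seeds[3], deconvolve = deconvolve)
  res$ground_truth <- gt
  res$subject_networks <- cohort_data$subject_networks
  res$config <- config
  # behavioral correlations of MP at the planted middlemen, pooled sample
  mm_labels <- gt$node_labels[gt$middleman_nodes]
  res$behavioral <- lapply(mm_labels, function(lb) {
    vals <- res$measures_mp[, lb]
    out <- lapply(c("npiq", "mmse", "faq", "cdr"), function(sc) {
      tryCatch(behavioral_correlation(vals, cohort_data$cohort[[sc]]),
               error = function(e) list(r = NA_real_, p = NA_real_))
    })
    names(out) <- c("npiq", "mmse", "faq", "cdr")
    out
  })
  names(res$behavioral) <- mm_labels
  if (!is.null(out_dir)) persist_study(res, cohort_data, out_dir)
  res
}

# Shared analysis chain: deconvolution -> causal networks -> measures ->
# progressive reports -> FC arm.
analyze_cohort <- function(ts_list, cohort, config, seed, deconvolve = TRUE) {
  n <- length(ts_list)
  subj_seeds <- derive_seeds(seed, n, salt = 2L)
  networks <- vector("list", n)
  q <- ncol(ts_list[[1]]$data)
  labels <- ts_list[[1]]$roi_labels
  mp <- matrix(NA_real_, n, q, dimnames = list(cohort$subject_id, labels))
  bc <- matrix(NA_real_, n, q, dimnames = list(cohort$subject_id, labels))
  brk <- matrix(NA_integer_, n, q, dimnames = list(cohort$subject_id, labels))
  for (s in seq_len(n)) {
    obs <- ts_list[[s]]
    neural <- if (deconvolve) {
      deconvolve_subject(obs, threshold_sd = config$threshold_sd,
                         nsr = config$nsr, window_s = config$window_s)
    } else obs
    cp <- surrogate_null_and_threshold(neural, order = config$order,
                                       n_surr = config$n_surr,
                                       alpha = config$alpha_edge,
                                       seed = subj_seeds[s])
    networks[[s]] <- cp
    net <- as_directed_network(cp)
    nm <- nodal_measures(net, subject_id = obs$subject_id)
    mp[s, ] <- nm$mp
    bc[s, ] <- nm$bc
    brk[s, ] <- nm$brokerage
    if (s %% 10 == 0) stage_log("connectivity", "subject %d/%d done", s, n)
  }
  report_mp <- progressive_nodes(mp, cohort, "MP", alpha = config$alpha_group)
  report_bc <- progressive_nodes(bc, cohort, "BC", alpha = config$alpha_group)
  stage_log("fc-arm", "undirected functional-connectivity control")
  report_fc <- fc_bc_comparison_arm(ts_list, cohort,
                                    alpha_edge = config$alpha_edge,
                                    alpha_group = config$alpha_group)
  list(cohort = cohort, networks = networks, measures_mp = mp,
       measures_bc = bc, measures_brokerage = brk,
       report_mp = report_mp, report_bc = report_bc,
       report_fc = report_fc)
}

persist_study <- function(res, cohort_data, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ts_dir <- file.path(out_dir, "timeseries")
  write_cohort(cohort_data$timeseries, res$cohort, ts_dir)
  gt <- res$ground_truth
  if (!is.null(gt)) {
    write_edgelist_tsv(as_directed_network(gt),
                       file.path(out_dir, "ground_truth_edges.tsv"),
                       weights = t(gt$coeff))
    jsonlite::write_json(
      list(middleman_nodes = gt$node_labels[gt$middleman_nodes],
           feeder_nodes = gt$node_labels[gt$feeder_nodes],
           seed = gt$seed, config_hash = res$config$hash),
      file.path(out_dir, "ground_truth_meta.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  net_dir <- file.path(out_dir, "networks")
  for (s in seq_along(res$networks)) {
    write_cpgc_result(res$networks[[s]], net_dir, res$cohort$subject_id[s])
  }
  meas <- data.frame(subject_id = rep(res$cohort$subject_id, each = ncol(res$measures_mp)),
                     node_label = rep(colnames(res$measures_mp), nrow(res$measures_mp)),
                     bc = as.vector(t(res$measures_bc)),
                     brokerage = as.vector(t(res$measures_brokerage)),
                     mp = as.vector(t(res$measures_mp)))
  utils::write.csv(meas, file.path(out_dir, "nodal_measures.csv"), row.names = FALSE)
  rep_dir <- file.path(out_dir, "reports")
  write_progressive_report(res$report_mp, rep_dir)
  write_progressive_report(res$report_bc, rep_dir)
  write_progressive_report(res$report_fc, rep_dir)
  if (!is.null(res$behavioral)) {
    jsonlite::write_json(res$behavioral,
                         file.path(rep_dir, "behavioral_correlations.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  cfg <- unclass(res$config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Run the analysis chain on user-supplied data
#'
#' Reads per-subject time-series TSVs and a cohort manifest CSV, validates
#' them, and runs deconvolution, causal-network estimation, graph measures
#' and the progressive analysis.
#'
#' @param timeseries_dir Directory of per-subject TSV files named
#'   `<subject_id>.tsv` (first row ROI labels, rows = timepoints).
#' @param manifest_path CSV with header
#'   `subject_id,group,age,sex,npiq,mmse,faq,cdr`.
#' @param config A [pipeline_config()]; simulation fields are ignored.
#' @param out_dir Output directory, or NULL.
#' @param deconvolve Apply blind deconvolution first.
#' @return As [run_simulated_study()], without ground-truth fields.
#' @export
run_user_study <- function(timeseries_dir, manifest_path,
                           config = pipeline_config(), out_dir = NULL,
                           deconvolve = TRUE) {
  cohort <- read_manifest(manifest_path)
  ts_list <- lapply(cohort$subject_id, function(sid) {
    path <- file.path(timeseries_dir, paste0(sid, ".tsv"))
    if (!file.exists(path))
      stopf("time-series file missing for subject '%s': %s", sid, path)
    read_timeseries_tsv(path, dt = config$TR, subject_id = sid)
  })
  shapes <- vapply(ts_list, function(x) paste(dim(x$data), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1)
    stopf("inconsistent time-series shapes across subjects: %s",
          paste(unique(shapes), collapse = ", "))
  stage_seeds <- derive_seeds(config$seed, 3L, salt = 1L)
  res <- analyze_cohort(ts_list, cohort, config, seed = stage_seeds[3],
                        deconvolve = deconvolve)
  res$config <- config
  if (!is.null(out_dir)) persist_study(res, list(timeseries = ts_list), out_dir)
  res
}

#' Time-series and manifest file formats
#'
#' Per-subject series are tab-separated text: first row ROI labels,
#' subsequent rows timepoints. The manifest is a CSV with columns
#' `subject_id,group,age,sex,npiq,mmse,faq,cdr`; extra columns are ignored
#' with a warning.
#'
#' @param ts A [roi_timeseries()].
#' @param path File path.
#' @param dt Sampling interval assigned on read, seconds.
#' @param subject_id Subject id assigned on read.
#' @return Writers return `path` invisibly; readers return the parsed object.
#' @name timeseries_io
NULL

#' @rdname timeseries_io
#' @export
write_timeseries_tsv <- function(ts, path) {
  utils::write.table(ts$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname timeseries_io
#' @export
read_timeseries_tsv <- function(path, dt, subject_id = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!nrow(df)) stopf("empty time-series file: %s", path)
  m <- as.matrix(df)
  if (!is.numeric(m)) stopf("non-numeric values in %s", path)
  if (anyNA(m)) stopf("missing values in %s", path)
  roi_timeseries(m, dt = dt, roi_labels = colnames(df), subject_id = subject_id)
}

#' @rdname timeseries_io
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "npiq", "mmse", "faq", "cdr")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("manifest %s lacks required columns: %s", path,
          paste(missing, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("ignoring undeclared manifest columns: %s",
                    paste(extra, collapse = ", ")))
    df <- df[, required]
  }
  bad <- !df$group %in% c("NC", "EMCI", "LMCI", "AD")
  if (any(bad))
    stopf("unknown group label(s) in manifest: %s (rows %s)",
          paste(unique(df$group[bad]), collapse = ", "),
          paste(which(bad), collapse = ", "))
  num_cols <- c("age", "sex", "npiq", "mmse", "faq", "cdr")
  for (cn in num_cols) {
    if (anyNA(df[[cn]]))
      stopf("missing covariate '%s' in manifest rows %s", cn,
            paste(which(is.na(df[[cn]])), collapse = ", "))
  }
  df$group <- factor(df$group, levels = c("NC", "EMCI", "LMCI", "AD"),
                     ordered = TRUE)
  df
}

# Export a generated cohort to disk in the documented formats.
write_cohort <- function(ts_list, cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in ts_list) {
    write_timeseries_tsv(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  }
  man <- cohort
  man$group <- as.character(man$group)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
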