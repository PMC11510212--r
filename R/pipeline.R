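# Whole-pipeline runs on a test-vs-reference ensemble pair, with config
# validation and provenance logging.

#' Validate a pipeline run configuration
#'
#' Checks the full configuration at once and returns every violation (not
#' fail-fast).  A valid config is a list (or YAML file) with:
#' `ensembles` (named list label -> PDB path; first = test, second =
#' reference), `segment_table` (path), `window` (list `t_start`/`t_end`,
#' ns), `time_step_ns`, cutoffs (`lock_threshold`, `salt_cutoff`,
#' `hbond_d_cut`, `hbond_angle_cut`, `hydrophobic_cutoff`), thresholds
#' (`delta_threshold`, `transition_threshold`, `corr_window`,
#' `corr_threshold`), `seed`, `output_dir`.
#'
#' @param config list or YAML path.
#' @return list with `config` (defaults filled) and `violations`
#'   (character vector; empty when valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      return(list(config = NULL,
                  violations = sprintf("config file not found: %s", config)))
    config <- yaml::read_yaml(config)
  }
  defaults <- list(time_step_ns = 0.1, lock_threshold = 5.0,
                   salt_cutoff = 4.0, hbond_d_cut = 3.5,
                   hbond_angle_cut = 120, hydrophobic_cutoff = 4.5,
                   delta_threshold = 0.2, transition_threshold = 30,
                   corr_window = 100, corr_threshold = 0.5, seed = 1,
                   output_dir = "gactdyn_out")
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  v <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  ens <- config$ensembles
  need(length(ens) >= 2, "ensembles: need at least two (test, reference)")
  need(!is.null(names(ens)) && all(nzchar(names(ens))),
       "ensembles: every ensemble needs a label")
  need(!anyDuplicated(names(ens)), "ensembles: duplicate labels")
  for (nm in names(ens))
    need(is.character(ens[[nm]]) && file.exists(ens[[nm]]),
         sprintf("ensembles.%s: path does not exist", nm))
  need(!is.null(config$segment_table), "segment_table: missing")
  if (!is.null(config$segment_table))
    need(file.exists(config$segment_table),
         sprintf("segment_table: file not found: %s", config$segment_table))
  if (!is.null(config$window)) {
    need(is.numeric(config$window$t_start) && is.numeric(config$window$t_end) &&
           config$window$t_start < config$window$t_end,
         "window: needs numeric t_start < t_end")
  }
  for (k in c("time_step_ns", "lock_threshold", "salt_cutoff", "hbond_d_cut",
              "hbond_angle_cut", "hydrophobic_cutoff", "delta_threshold",
              "transition_threshold", "corr_window", "corr_threshold"))
    need(is.numeric(config[[k]]) && config[[k]] > 0,
         sprintf("%s: must be a positive number", k))
  list(config = config, violations = v)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  # small stable polynomial hash over the canonical JSON, hex-encoded
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full two-ensemble comparison pipeline
#'
#' Loads the test and reference ensembles, restricts to the analysis window,
#' and produces per ensemble the C-alpha RMSD series, RMSF profile and
#' ionic-lock series, and per pair the combined PCA, the salt-bridge /
#' hydrogen-bond / hydrophobic differential occupancy matrices and the
#' windowed correlation-fraction differences.  All tables are written as
#' TSV/CSV with a JSON summary and a provenance record (package version,
#' config hash, per-stage parameter echo); identical config + inputs + seed
#' reproduce identical numbers.
#'
#' @param config list or YAML path accepted by [validate_config].
#' @return invisibly, a list with the in-memory results and `output_dir`.
#' @export
run_pipeline <- function(config) {
  chk <- validate_config(config)
  if (length(chk$violations))
    stop_gact("invalid configuration:\n  %s",
              paste(chk$violations, collapse = "\n  "),
              class = "gact_config_error")
  cfg <- chk$config
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "gactdyn",
               version = as.character(utils::packageVersion("gactdyn")),
               config_hash = config_hash(cfg), stages = list())
  stage <- function(name, params) prov$stages[[name]] <<- params

  seg <- read_segment_table(cfg$segment_table)
  ens <- list()
  for (nm in names(cfg$ensembles)) {
    top <- load_topology(cfg$ensembles[[nm]])
    map <- assign_generic_numbers(top, seg)
    top <- annotate_topology(top, map)
    fr <- load_frames(cfg$ensembles[[nm]], top, cfg$time_step_ns, label = nm)
    if (!is.null(cfg$window))
      fr <- slice_window(fr, cfg$window$t_start, cfg$window$t_end)
    else if (n_frames(fr) > 5) {
      # default convention: drop the first 20% as equilibration
      t0 <- stats::quantile(fr$times, 0.2, names = FALSE)
      fr <- slice_window(fr, t0, fr$times[n_frames(fr)])
    }
    ens[[nm]] <- list(frames = fr, map = map)
  }
  stage("load", list(ensembles = names(ens), time_step_ns = cfg$time_step_ns))

  results <- list()
  for (nm in names(ens)) {
    fr <- ens[[nm]]$frames
    ca <- select_atoms(fr$topology, "name CA and protein")
    r <- list()
    r$rmsd <- rmsd_series(fr, frame_coords(fr, 1), ca)
    write_tsv(r$rmsd, file.path(cfg$output_dir, sprintf("rmsd_%s.tsv", nm)))
    r$rmsf <- rmsf(fr, ca)
    write_tsv(r$rmsf, file.path(cfg$output_dir, sprintf("rmsf_%s.tsv", nm)))
    r$lock <- ionic_lock_series(fr, ens[[nm]]$map,
                                formed_threshold = cfg$lock_threshold)
    write_tsv(r$lock$series, file.path(cfg$output_dir,
                                       sprintf("lock_%s.tsv", nm)))
    r$contacts <- list(
      salt_bridge = salt_bridge_contacts(fr, cutoff = cfg$salt_cutoff),
      hbond = hydrogen_bond_contacts(fr, d_cut = cfg$hbond_d_cut,
                                     angle_cut = cfg$hbond_angle_cut),
      hydrophobic = hydrophobic_contacts(fr, cutoff = cfg$hydrophobic_cutoff))
    results[[nm]] <- r
  }
  stage("per_ensemble", list(lock_threshold = cfg$lock_threshold,
                             salt_cutoff = cfg$salt_cutoff,
                             hbond_d_cut = cfg$hbond_d_cut,
                             hydrophobic_cutoff = cfg$hydrophobic_cutoff))

  test_nm <- names(ens)[1]; ref_nm <- names(ens)[2]
  deltas <- list()
  for (kind in c("salt_bridge", "hbond", "hydrophobic")) {
    d <- delta_fractions(results[[test_nm]]$contacts[[kind]],
                         results[[ref_nm]]$contacts[[kind]])
    deltas[[kind]] <- d
    write_tsv(d$pairs, file.path(cfg$output_dir,
                                 sprintf("delta_%s.tsv", kind)))
    write_tsv(top_differential_pairs(d, cfg$delta_threshold),
              file.path(cfg$output_dir, sprintf("top_delta_%s.tsv", kind)))
  }
  stage("delta", list(delta_threshold = cfg$delta_threshold))

  ca_t <- select_atoms(ens[[test_nm]]$frames$topology, "name CA and protein")
  pca <- combined_pca(list(ens[[test_nm]]$frames, ens[[ref_nm]]$frames), ca_t)
  write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                       eigenvalue_A2 = pca$eigenvalues,
                       contribution_pct = pca$contribution),
            file.path(cfg$output_dir, "pca_contributions.tsv"))
  utils::write.csv(pca$projections,
                   file.path(cfg$output_dir, "pca_projections.csv"),
                   row.names = FALSE)
  write_frames(ev_trace_frames(pca, 1),
               file.path(cfg$output_dir, "ev1_trace.pdb"))
  stage("pca", list(selection = "name CA and protein", mean_refits = 2))

  corr <- lapply(ens, function(e)
    tryCatch(windowed_correlation_fractions(e$frames,
                                            select_atoms(e$frames$topology,
                                                         "name CA and protein"),
                                            window = cfg$corr_window,
                                            threshold = cfg$corr_threshold),
             gact_window_error = function(e) NULL))
  dcorr <- NULL
  if (!is.null(corr[[test_nm]]) && !is.null(corr[[ref_nm]])) {
    dcorr <- delta_correlation_fractions(corr[[test_nm]], corr[[ref_nm]])
    utils::write.table(dcorr$correlated,
                       file.path(cfg$output_dir, "delta_corr_fraction.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(dcorr$anticorrelated,
                       file.path(cfg$output_dir, "delta_anticorr_fraction.tsv"),
                       sep = "\t", quote = FALSE)
  }
  stage("correlation", list(window = cfg$corr_window,
                            threshold = cfg$corr_threshold))

  summary <- list(
    ensembles = names(ens),
    n_frames = lapply(ens, function(e) n_frames(e$frames)),
    lock_broken_fraction = lapply(results, function(r) r$lock$broken_fraction),
    lock_mean_distance_A = lapply(results, function(r)
      mean(r$lock$series$distance)),
    pca_contribution_pct = pca$contribution[1:min(5,
                                                  length(pca$contribution))],
    top_delta_counts = lapply(deltas, function(d)
      nrow(top_differential_pairs(d, cfg$delta_threshold))))
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, deltas = deltas, pca = pca,
                 correlation = dcorr, summary = summary,
                 output_dir = cfg$output_dir))
}
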