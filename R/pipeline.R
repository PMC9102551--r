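# Pipeline entry point: a single run_stage() dispatches the named stage on
# a config (an R list or a YAML file), writes its outputs plus a provenance
# record (parameters, input digests, seed, package version), and returns the
# output paths. Deterministic stages produce byte-identical outputs on
# repeated runs; stochastic stages are deterministic under a fixed seed.

#' Read a run configuration
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Must contain `stage`; remaining entries are stage parameters.
#' @return the config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$stage))
    stop("config must be a list with a `stage` entry", call. = FALSE)
  config
}

pipeline_stages <- c("simulate", "rin_build", "rca", "hotspots", "burden",
                     "label", "de", "translocate", "migrate", "peak",
                     "dff0", "ratio")

cfg_get <- function(config, name, default = NULL, required = FALSE) {
  val <- config[[name]]
  if (is.null(val)) {
    if (required) stop("config entry `", name, "` is required", call. = FALSE)
    return(default)
  }
  val
}

check_inputs_exist <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(paths)
}

write_provenance <- function(out_dir, stage, config, inputs, outputs) {
  prov <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("hotspotr")),
    parameters = config[setdiff(names(config), c("stage", "out_dir"))],
    input_digests = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list(),
    outputs = basename(outputs))
  path <- file.path(out_dir, sprintf("provenance_%s.json", stage))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write synthetic poses, mutation, metadata, trace and
#' track files), `rin_build` (PDB -> RIN edge TSV), `rca` (RIN TSV ->
#' centrality TSV), `hotspots` (pose PDBs -> consensus hotspot TSV),
#' `burden` (MAF -> per-gene burden TSV), `label` (metadata -> label TSV),
#' `de` (expression + groups -> test report TSV), `translocate`, `migrate`,
#' `peak`, `dff0`, `ratio` (CSV summaries). Unknown stages and out-of-range
#' parameters are errors; no partial outputs are left on failure (outputs
#' are written into the output directory only after the computation
#' succeeds).
#'
#' @param config list or YAML path, see [read_run_config()]. Common entries:
#'   `stage`, `out_dir` (default `"."`), `seed`, plus stage parameters
#'   (`pdb`, `rin`, `poses`, `receptor_chains`, `ligand_chains`, `d_min`,
#'   `d_max`, `z_threshold`, `maf`, `patients`, `lengths`, `meta`, `expr`,
#'   `traces`, `tracks`, `stimulus_time`, `window`, `baseline`, ...).
#' @return invisible list with `stage`, `outputs` (paths) and `provenance`
#'   (path of the provenance JSON).
#' @export
run_stage <- function(config) {
  config <- read_run_config(config)
  stage <- config$stage
  if (!stage %in% pipeline_stages)
    stop("unknown stage: ", stage, call. = FALSE)
  out_dir <- cfg_get(config, "out_dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d_min <- cfg_get(config, "d_min", 2.5)
  d_max <- cfg_get(config, "d_max", 5.0)
  z_thr <- cfg_get(config, "z_threshold", 3)
  if (d_min < 0 || d_min >= d_max)
    stop("parameter out of range: need 0 <= d_min < d_max", call. = FALSE)
  inputs <- character(0)
  outputs <- character(0)
  out_path <- function(name) file.path(out_dir, name)

  if (stage == "simulate") {
    seed <- cfg_get(config, "seed", 1)
    spec <- toy_complex_spec(
      n_res_receptor = cfg_get(config, "n_res_receptor", 40),
      n_res_ligand = cfg_get(config, "n_res_ligand", 40),
      contact_radius = cfg_get(config, "contact_radius", 4.2),
      jitter_sd = cfg_get(config, "jitter_sd", 0.3),
      n_poses = cfg_get(config, "n_poses", 5), seed = seed)
    poses <- gen_toy_poses(spec)
    for (i in seq_along(poses)) {
      f <- out_path(sprintf("pose_%d.pdb", i))
      write_structure(poses[[i]], f)
      outputs <- c(outputs, f)
    }
    genes <- data.frame(name = c("RAP1A", "TRPM8"), length_aa = c(184, 1104))
    mut <- gen_mutation_table(cohort_spec(
      genes, n_patients = cfg_get(config, "n_patients", 500),
      rates = c(RAP1A = 0.005, TRPM8 = 0.02),
      watch_codons = list(TRPM8 = data.frame(position = c(207, 240),
                                             ref = c("E", "Y"),
                                             alt = c("D", "C"))),
      seed = seed))
    f <- out_path("mutations.tsv"); write_maf(mut$mutations, f)
    outputs <- c(outputs, f)
    meta <- gen_clinical_metadata(cfg_get(config, "n_per_rule", 3), seed = seed)
    f <- out_path("metadata.tsv")
    utils::write.table(meta, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, f)
    traces <- gen_roi_traces(n_cells = cfg_get(config, "n_cells", 10),
                             seed = seed)
    f <- out_path("roi_traces.csv")
    utils::write.csv(traces, f, row.names = FALSE)
    outputs <- c(outputs, f)
    tracks <- gen_tracks(n_cells = cfg_get(config, "n_cells", 10),
                         true_speed = cfg_get(config, "true_speed", 1.2),
                         seed = seed)
    f <- out_path("tracks.csv")
    utils::write.csv(tracks, f, row.names = FALSE)
    outputs <- c(outputs, f)
  } else if (stage == "rin_build") {
    pdb <- cfg_get(config, "pdb", required = TRUE)
    inputs <- check_inputs_exist(pdb)
    model <- read_structure(pdb)
    if (!inherits(model, "StructureModel")) model <- model[[1]]
    rin <- build_rin(model, d_min, d_max)
    f <- out_path("rin_edges.tsv"); write_rin_tsv(rin, f)
    outputs <- f
  } else if (stage == "rca") {
    rin_file <- cfg_get(config, "rin", required = TRUE)
    inputs <- check_inputs_exist(rin_file)
    rin <- read_rin_tsv(rin_file)
    cen <- residue_centrality(rin, z_threshold = z_thr)
    f <- out_path("centrality.tsv"); write_centrality_tsv(cen, f)
    outputs <- f
  } else if (stage == "hotspots") {
    pose_files <- cfg_get(config, "poses", required = TRUE)
    inputs <- check_inputs_exist(pose_files)
    partners <- partner_map(
      cfg_get(config, "receptor_chains", "A"),
      cfg_get(config, "ligand_chains", "B"))
    results <- lapply(pose_files, function(f) {
      model <- read_structure(f)
      if (!inherits(model, "StructureModel")) model <- model[[1]]
      analyze_pose(model, partners, d_min, d_max, z_thr)
    })
    tab <- consensus_hotspots(results,
                              candidates = cfg_get(config, "candidates"))
    f <- out_path("hotspots.tsv"); write_hotspot_tsv(tab, f)
    outputs <- f
  } else if (stage == "burden") {
    maf <- cfg_get(config, "maf", required = TRUE)
    inputs <- check_inputs_exist(maf)
    lengths <- unlist(cfg_get(config, "lengths", required = TRUE))
    n_patients <- cfg_get(config, "patients", required = TRUE)
    tab <- cohort_burden(read_maf(maf), n_patients, lengths)
    f <- out_path("burden.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- f
  } else if (stage == "label") {
    meta_file <- cfg_get(config, "meta", required = TRUE)
    inputs <- check_inputs_exist(meta_file)
    meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
    labels <- label_sample(meta)
    f <- out_path("labels.tsv")
    utils::write.table(labels, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- f
  } else if (stage == "de") {
    expr_file <- cfg_get(config, "expr", required = TRUE)
    inputs <- check_inputs_exist(expr_file)
    expr <- utils::read.delim(expr_file, stringsAsFactors = FALSE)
    de <- run_de(expr$value, expr$group,
                 alpha = cfg_get(config, "alpha", 0.05),
                 gene = cfg_get(config, "gene"))
    f <- out_path("de_report.tsv")
    utils::write.table(cbind(de$pairwise, np = de$np, omnibus_p = de$omnibus$p),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- f
  } else if (stage == "translocate") {
    traces_file <- cfg_get(config, "traces", required = TRUE)
    inputs <- check_inputs_exist(traces_file)
    traces <- utils::read.csv(traces_file, stringsAsFactors = FALSE)
    out <- cell_translocation_series(traces,
                                     aggregate = cfg_get(config, "aggregate", "mean"))
    f <- out_path("translocation.csv")
    utils::write.csv(out, f, row.names = FALSE)
    outputs <- f
  } else if (stage == "migrate") {
    tracks_file <- cfg_get(config, "tracks", required = TRUE)
    inputs <- check_inputs_exist(tracks_file)
    tracks <- utils::read.csv(tracks_file, stringsAsFactors = FALSE)
    out <- migration_rate(tracks, exclude = cfg_get(config, "exclude"))
    f <- out_path("migration.csv")
    utils::write.csv(out, f, row.names = FALSE)
    outputs <- f
  } else if (stage %in% c("peak", "dff0")) {
    trace_file <- cfg_get(config, "trace", required = TRUE)
    inputs <- check_inputs_exist(trace_file)
    tr <- utils::read.csv(trace_file, stringsAsFactors = FALSE)
    stim <- cfg_get(config, "stimulus_time", required = TRUE)
    if (stage == "peak") {
      amp <- peak_amplitude(tr$time, tr$value, stim,
                            window = cfg_get(config, "window", 300))
      f <- out_path("peak.csv")
      utils::write.csv(data.frame(stimulus_time = stim, amplitude = amp),
                       f, row.names = FALSE)
    } else {
      d <- delta_f_over_f0(tr$time, tr$value, stim,
                           baseline = cfg_get(config, "baseline", 100),
                           slope_window = cfg_get(config, "slope_window", 60))
      f <- out_path("dff0.csv")
      utils::write.csv(cbind(d$trace, f0 = d$f0, slope = d$slope),
                       f, row.names = FALSE)
    }
    outputs <- f
  } else if (stage == "ratio") {
    vals <- vapply(c("sample_num", "sample_den", "control_num", "control_den"),
                   function(k) as.numeric(cfg_get(config, k, required = TRUE)),
                   0)
    r <- normalized_ratio(vals[1], vals[2], vals[3], vals[4],
                          log2_output = isTRUE(config$log2))
    f <- out_path("ratio.csv")
    utils::write.csv(data.frame(ratio = r, log2 = isTRUE(config$log2)),
                     f, row.names = FALSE)
    outputs <- f
  }
  prov <- write_provenance(out_dir, stage, config, inputs, outputs)
  invisible(list(stage = stage, outputs = outputs, provenance = prov))
}
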