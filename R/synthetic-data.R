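# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on these outputs with known ground truth: toy docked complexes
# with planted high-connectivity interface residues, somatic mutation tables
# with configurable per-gene rates and watch-list codons, clinical metadata
# exercising every labeling rule, grouped expression values, ROI intensity
# traces with a stimulus step, and 2-D cell tracks with known speed.
#
# Toy residues are pseudo-atom clusters of 1-6 points: the contact criterion
# only needs interatomic distances, so no real side-chain chemistry is
# modelled. Scaffold residues sit on a ring (chord spacing 4.0 A, so each
# contacts its two neighbours); a planted hotspot residue additionally
# carries four "anchor" atoms bridging pairs of scaffold residues spread
# around its own ring, plus an interface atom meeting its partner hotspot at
# `contact_radius`. This gives planted residues 10+ contacts against 2-4 for
# scaffold residues, which is what makes closeness Z >= 3 reachable.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Specification of a synthetic two-partner docked complex
#'
#' @param n_res_receptor,n_res_ligand residues per partner (>= 16).
#' @param planted_receptor,planted_ligand residue indices planted as
#'   hotspots on each partner; defaults place two per partner at the ring
#'   quarter points.
#' @param contact_radius cross-partner distance (Angstrom) of the planted
#'   hotspot contact; must lie inside the RIN window.
#' @param jitter_sd per-pose Gaussian positional noise (Angstrom) applied to
#'   non-planted residues.
#' @param n_poses number of poses to generate (>= 1).
#' @param seed RNG seed.
#' @return a validated `ToyComplexSpec`.
#' @export
toy_complex_spec <- function(n_res_receptor = 40, n_res_ligand = 40,
                             planted_receptor = NULL, planted_ligand = NULL,
                             contact_radius = 4.2, jitter_sd = 0.3,
                             n_poses = 5, seed = 1) {
  default_planted <- function(n) unique(pmax(2L, c(round(n * 0.25), round(n * 0.75))))
  if (is.null(planted_receptor)) planted_receptor <- default_planted(n_res_receptor)
  if (is.null(planted_ligand)) planted_ligand <- default_planted(n_res_ligand)
  spec <- structure(
    list(n_res_receptor = as.integer(n_res_receptor),
         n_res_ligand = as.integer(n_res_ligand),
         planted_receptor = as.integer(planted_receptor),
         planted_ligand = as.integer(planted_ligand),
         contact_radius = contact_radius, jitter_sd = jitter_sd,
         n_poses = as.integer(n_poses), seed = seed),
    class = "ToyComplexSpec")
  validate_toy_complex_spec(spec)
}

validate_toy_complex_spec <- function(spec) {
  for (side in c("receptor", "ligand")) {
    n <- spec[[paste0("n_res_", side)]]
    planted <- spec[[paste0("planted_", side)]]
    if (n < 16) stop("each partner needs at least 16 residues", call. = FALSE)
    if (length(planted) < 1 || anyDuplicated(planted))
      stop("planted hotspot indices must be a non-empty set", call. = FALSE)
    if (any(planted < 1 | planted > n))
      stop("planted hotspot index outside the residue range", call. = FALSE)
    if (length(planted) > floor(n / 8))
      stop(sprintf("impossible geometry: %d planted hotspots do not fit on %d residues",
                   length(planted), n), call. = FALSE)
  }
  if (spec$n_poses < 1) stop("n_poses must be >= 1", call. = FALSE)
  if (spec$jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (spec$contact_radius < 2.5 + 0.5 || spec$contact_radius > 5 - 0.2)
    stop("contact_radius must lie well inside the [2.5, 5] A contact window",
         call. = FALSE)
  spec
}

# ring position of residue i (1-based, wraps) on a partner's scaffold
ring_xy <- function(i, n, spacing = 4.0) {
  R <- spacing / (2 * sin(pi / n))
  th <- 2 * pi * ((i - 1) %% n) / n
  c(R * cos(th), R * sin(th))
}

# anchor pairs for one hub: four pairs of adjacent scaffold residues at the
# ring fifth-points from the hub, shifted off planted/patch residues
anchor_pairs <- function(h, n, banned) {
  starts <- ((h - 1 + round(n * (1:4) / 5)) %% n) + 1
  lapply(starts, function(a) {
    repeat {
      pair <- c(a, (a %% n) + 1)
      if (!any(pair %in% banned)) return(pair)
      a <- (a %% n) + 1
    }
  })
}

build_partner_atoms <- function(n, planted, chain, z0, dir, contact_pts,
                                jitter_sd, spacing = 4.0) {
  patch <- setdiff(((c(planted - 1, planted + 1) - 1) %% n) + 1, planted)
  banned <- c(planted, patch)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    xy <- ring_xy(i, n, spacing)
    if (i %in% planted) {
      xyz <- rbind(c(xy, z0), c(xy, z0 + dir * 2.15))
      for (pr in anchor_pairs(i, n, banned)) {
        m <- (ring_xy(pr[1], n, spacing) + ring_xy(pr[2], n, spacing)) / 2
        xyz <- rbind(xyz, c(m, z0 + dir * 3.0))
      }
      pts <- contact_pts[[as.character(i)]]
      if (!is.null(pts)) xyz <- rbind(xyz, pts)
      resname <- "TRP"
    } else {
      dz <- if (i %in% patch) dir * 1.85 else 0
      xyz <- matrix(c(xy, z0 + dz), nrow = 1)
      xyz <- xyz + rep(stats::rnorm(3, 0, jitter_sd), each = nrow(xyz))
      resname <- "ALA"
    }
    rows[[i]] <- data.frame(
      chain = chain, resno = i, icode = "", resname = resname,
      atom = paste0("C", seq_len(nrow(xyz))), element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], is_h = FALSE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate synthetic docking poses with planted interface hotspots
#'
#' Each pose holds two chains (`A` = receptor, `B` = ligand) whose scaffold
#' residues form rings; planted hotspot residues carry extra pseudo-atoms so
#' that (a) their cross-partner minimum distance equals `contact_radius`
#' (inside the contact window) and (b) their contact count far exceeds that
#' of scaffold residues, making closeness Z >= 3 reachable. Non-planted
#' residues are jittered independently per pose; planted geometry is held
#' fixed so the ground truth survives the noise. Deterministic under the
#' spec seed.
#'
#' @param spec a [toy_complex_spec()].
#' @return list of `StructureModel` poses, with attributes `partners` (a
#'   [partner_map()]) and `planted` (the planted residue keys).
#' @examples
#' poses <- gen_toy_poses(toy_complex_spec(n_poses = 2, seed = 7))
#' attr(poses, "planted")
#' @export
gen_toy_poses <- function(spec) {
  spec <- validate_toy_complex_spec(spec)
  sep <- spec$contact_radius + 4.3  # ring plane separation
  # pair planted residues cyclically; contact point sits at the receptor
  # hub's ring position, the ligand hub hangs an atom down to meet it
  n_pairs <- max(length(spec$planted_receptor), length(spec$planted_ligand))
  cp_rec <- list(); cp_lig <- list()
  for (k in seq_len(n_pairs)) {
    r <- spec$planted_receptor[((k - 1) %% length(spec$planted_receptor)) + 1]
    l <- spec$planted_ligand[((k - 1) %% length(spec$planted_ligand)) + 1]
    xy <- ring_xy(r, spec$n_res_receptor)
    cp_rec[[as.character(r)]] <- unique(rbind(cp_rec[[as.character(r)]],
                                              c(xy, 2.15)))
    cp_lig[[as.character(l)]] <- unique(rbind(cp_lig[[as.character(l)]],
                                              c(xy, 2.15 + spec$contact_radius)))
  }
  with_seed(spec$seed, {
    poses <- lapply(seq_len(spec$n_poses), function(p) {
      atoms <- rbind(
        build_partner_atoms(spec$n_res_receptor, spec$planted_receptor, "A",
                            0, +1, cp_rec, spec$jitter_sd),
        build_partner_atoms(spec$n_res_ligand, spec$planted_ligand, "B",
                            sep, -1, cp_lig, spec$jitter_sd))
      new_structure_model(sprintf("toy_pose_%d", p), atoms)
    })
    attr(poses, "partners") <- partner_map("A", "B")
    attr(poses, "planted") <- c(residue_key("A", spec$planted_receptor),
                                residue_key("B", spec$planted_ligand))
    poses
  })
}

#' Specification of a synthetic somatic-mutation cohort
#'
#' @param genes data frame with columns `name` and `length_aa` (protein
#'   length in amino acids, >= 1).
#' @param n_patients cohort size.
#' @param rates named numeric vector, expected missense mutations per
#'   patient for each gene (>= 0).
#' @param watch_codons named list, gene -> either an integer vector of codon
#'   positions or a data frame `position`, `ref`, `alt`; one forced missense
#'   record is generated per watch codon.
#' @param seed RNG seed.
#' @return a validated `CohortSpec`.
#' @export
cohort_spec <- function(genes, n_patients, rates, watch_codons = list(),
                        seed = 1) {
  stopifnot(is.data.frame(genes), all(c("name", "length_aa") %in% names(genes)))
  if (any(genes$length_aa < 1)) stop("protein lengths must be >= 1", call. = FALSE)
  if (!all(genes$name %in% c(names(rates), NA)) && length(rates) > 0 &&
      is.null(names(rates)))
    stop("`rates` must be named by gene", call. = FALSE)
  rates <- rates[genes$name]
  rates[is.na(rates)] <- 0
  names(rates) <- genes$name
  if (any(rates < 0)) stop("rates must be >= 0", call. = FALSE)
  if (length(watch_codons) > 0 &&
      !all(names(watch_codons) %in% genes$name))
    stop("watch_codons gene not in `genes`", call. = FALSE)
  structure(list(genes = genes, n_patients = as.integer(n_patients),
                 rates = rates, watch_codons = watch_codons, seed = seed),
            class = "CohortSpec")
}

#' Generate a MAF-like somatic mutation table
#'
#' Per-gene missense counts are Poisson with mean `n_patients * rate`;
#' positions are uniform on the protein length; reference and alternate
#' amino acids are distinct 1-letter codes, giving well-formed
#' `p.<ref><pos><alt>` protein-change strings. One forced entry per
#' watch-list codon is appended. Deterministic under the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `mutations` (data frame `patient_id`, `gene`,
#'   `variant_class`, `protein_change`) and `n_patients`.
#' @export
gen_mutation_table <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  with_seed(spec$seed, {
    recs <- list()
    for (gi in seq_len(nrow(spec$genes))) {
      g <- spec$genes$name[gi]
      len <- spec$genes$length_aa[gi]
      n <- stats::rpois(1, spec$n_patients * spec$rates[[g]])
      if (n > 0) {
        pos <- sample.int(len, n, replace = TRUE)
        ref <- sample(AA1, n, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1), "")
        recs[[length(recs) + 1]] <- data.frame(
          patient_id = sprintf("PAT-%04d", sample.int(spec$n_patients, n, TRUE)),
          gene = g, variant_class = "Missense_Mutation",
          protein_change = paste0("p.", ref, pos, alt),
          stringsAsFactors = FALSE)
      }
      wc <- spec$watch_codons[[g]]
      if (!is.null(wc)) {
        if (!is.data.frame(wc)) {
          ref <- sample(AA1, length(wc), replace = TRUE)
          alt <- vapply(ref, function(r) sample(setdiff(AA1, r), 1), "")
          wc <- data.frame(position = wc, ref = ref, alt = alt)
        }
        recs[[length(recs) + 1]] <- data.frame(
          patient_id = sprintf("PAT-%04d", sample.int(spec$n_patients,
                                                      nrow(wc), TRUE)),
          gene = g, variant_class = "Missense_Mutation",
          protein_change = paste0("p.", wc$ref, wc$position, wc$alt),
          stringsAsFactors = FALSE)
      }
    }
    mutations <- if (length(recs) > 0) do.call(rbind, recs) else
      data.frame(patient_id = character(0), gene = character(0),
                 variant_class = character(0), protein_change = character(0),
                 stringsAsFactors = FALSE)
    rownames(mutations) <- NULL
    list(mutations = mutations, n_patients = spec$n_patients)
  })
}

#' Generate clinical metadata exercising every labeling rule
#'
#' Emits `n_per_rule` samples for each of the five labeling rules: GTEx
#' source (healthy), AJCC m-category M1 (metastatic), AJCC stage IV
#' (metastatic), FIGO stage III/IV (metastatic), and the no-staging fallback
#' (not metastatic). Tissue labels and TCGA project codes cycle over the
#' Breast/Prostate/Uterus cohorts.
#'
#' @param n_per_rule samples per rule (0 gives an empty, well-formed table).
#' @param seed RNG seed (kept for interface symmetry; the layout is
#'   deterministic).
#' @return data frame `sample_id`, `source_cohort`, `project`,
#'   `tissue_label`, `ajcc_m`, `ajcc_stage`, `figo_stage`.
#' @export
gen_clinical_metadata <- function(n_per_rule = 1, seed = 1) {
  cols <- c("sample_id", "source_cohort", "project", "tissue_label",
            "ajcc_m", "ajcc_stage", "figo_stage")
  empty <- function() {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  if (n_per_rule < 1) return(empty())
  gtex_tissues <- c("Breast", "Prostate", "Uterus", "Cervix Uteri")
  tcga_projects <- c("TCGA-BRCA", "TCGA-PRAD", "TCGA-UCEC")
  cyc <- function(v, i) v[((i - 1) %% length(v)) + 1]
  rows <- list()
  add <- function(rule, i, ...) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sprintf("S-%s-%03d", rule, i), stringsAsFactors = FALSE, ...)
  }
  for (i in seq_len(n_per_rule)) {
    add("gtex", i, source_cohort = "GTEx", project = NA_character_,
        tissue_label = cyc(gtex_tissues, i),
        ajcc_m = NA_character_, ajcc_stage = NA_character_,
        figo_stage = NA_character_)
    add("ajccm", i, source_cohort = "TCGA", project = cyc(tcga_projects, i),
        tissue_label = NA_character_, ajcc_m = "M1",
        ajcc_stage = NA_character_, figo_stage = NA_character_)
    add("stage4", i, source_cohort = "TCGA", project = cyc(tcga_projects, i),
        tissue_label = NA_character_, ajcc_m = "M0",
        ajcc_stage = "Stage IV", figo_stage = NA_character_)
    add("figo", i, source_cohort = "TCGA", project = "TCGA-UCEC",
        tissue_label = NA_character_, ajcc_m = NA_character_,
        ajcc_stage = NA_character_, figo_stage = cyc(c("III", "IV"), i))
    add("fallback", i, source_cohort = "TCGA", project = cyc(tcga_projects, i),
        tissue_label = NA_character_, ajcc_m = "M0",
        ajcc_stage = "Stage II", figo_stage = NA_character_)
  }
  meta <- do.call(rbind, rows)[, cols]
  rownames(meta) <- NULL
  validate_metadata(meta)
}

#' Validate a clinical metadata table
#'
#' Checks unique sample identifiers and known source cohorts.
#' @param meta metadata data frame (see [gen_clinical_metadata()]).
#' @return the table, invisibly unchanged; errors on violation.
#' @export
validate_metadata <- function(meta) {
  if (anyDuplicated(meta$sample_id))
    stop("duplicated sample ids in metadata", call. = FALSE)
  known <- c("TCGA", "GTEx", "TARGET")
  bad <- setdiff(unique(meta$source_cohort), known)
  if (length(bad) > 0)
    stop("unknown source_cohort: ", paste(bad, collapse = ", "), call. = FALSE)
  meta
}

#' Generate grouped expression values with planted group effects
#'
#' Gaussian values per group with the given means, for exercising the
#' normality-gated differential-expression procedure.
#'
#' @param n_per_group named integer vector (names are group labels).
#' @param group_means numeric vector, recycled over groups.
#' @param sd common standard deviation.
#' @param seed RNG seed.
#' @return data frame `sample_id`, `group`, `value`.
#' @export
gen_expression_groups <- function(n_per_group, group_means = 0, sd = 1,
                                  seed = 1) {
  stopifnot(!is.null(names(n_per_group)))
  mu <- rep(group_means, length.out = length(n_per_group))
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_along(n_per_group), function(i) {
      n <- n_per_group[[i]]
      if (n == 0) return(NULL)
      data.frame(
        sample_id = sprintf("%s-%03d", names(n_per_group)[i], seq_len(n)),
        group = names(n_per_group)[i],
        value = stats::rnorm(n, mu[i], sd), stringsAsFactors = FALSE)
    }))
    if (is.null(out))
      out <- data.frame(sample_id = character(0), group = character(0),
                        value = numeric(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Generate paired membrane/cytosol ROI intensity traces
#'
#' Each cell carries `n_roi_pairs` membrane/cytosol ROI pairs sampled at
#' unit-spaced time points. The translocation ratio R = (Ics - Im)/Im sits
#' at `baseline_r` before the stimulus frame and steps to
#' `baseline_r + response_amplitude` from it onwards; intensities carry
#' multiplicative Gaussian noise of relative standard deviation `noise_sd`.
#'
#' @param n_cells number of cells (0 gives an empty table).
#' @param n_roi_pairs ROI pairs per cell; values below 4 warn (fewer than
#'   the recommended minimum) but are generated.
#' @param response_amplitude step in R at the stimulus.
#' @param stim_index first post-stimulus frame (1-based).
#' @param n_timepoints frames per trace.
#' @param baseline_r pre-stimulus R.
#' @param membrane_intensity mean membrane fluorescence (arbitrary units).
#' @param noise_sd relative intensity noise.
#' @param seed RNG seed.
#' @return data frame `cell_id`, `roi_pair_id`, `compartment`, `time`,
#'   `intensity`; ground truth stored in attribute `truth`.
#' @export
gen_roi_traces <- function(n_cells = 10, n_roi_pairs = 4,
                           response_amplitude = 1, stim_index = 10,
                           n_timepoints = 25, baseline_r = 0.2,
                           membrane_intensity = 100, noise_sd = 0.02,
                           seed = 1) {
  if (n_roi_pairs < 4)
    warning("fewer than 4 ROI pairs per cell", call. = FALSE)
  truth <- list(baseline_r = baseline_r,
                response_amplitude = response_amplitude,
                stim_index = stim_index)
  if (n_cells == 0) {
    out <- data.frame(cell_id = character(0), roi_pair_id = integer(0),
                      compartment = character(0), time = numeric(0),
                      intensity = numeric(0), stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    return(out)
  }
  with_seed(seed, {
    r_t <- baseline_r + response_amplitude * (seq_len(n_timepoints) >= stim_index)
    grid <- expand.grid(time = seq_len(n_timepoints),
                        roi_pair_id = seq_len(n_roi_pairs),
                        cell = seq_len(n_cells))
    noise <- function(n) 1 + stats::rnorm(n, 0, noise_sd)
    im <- membrane_intensity * noise(nrow(grid))
    ics <- membrane_intensity * (1 + r_t[grid$time]) * noise(nrow(grid))
    out <- rbind(
      data.frame(cell_id = sprintf("cell-%03d", grid$cell),
                 roi_pair_id = grid$roi_pair_id, compartment = "membrane",
                 time = grid$time, intensity = im, stringsAsFactors = FALSE),
      data.frame(cell_id = sprintf("cell-%03d", grid$cell),
                 roi_pair_id = grid$roi_pair_id, compartment = "cytosol",
                 time = grid$time, intensity = ics, stringsAsFactors = FALSE))
    out <- out[order(out$cell_id, out$roi_pair_id, out$time, out$compartment), ]
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}

#' Generate 2-D cell tracks with known speed
#'
#' Random-walk tracks with a fixed per-step displacement of
#' `true_speed * dt` micrometres in a uniformly random direction, so the
#' mean frame-to-frame speed equals `true_speed` exactly.
#'
#' @param n_cells number of cells (0 gives an empty table).
#' @param true_speed ground-truth speed in micrometres per minute.
#' @param dt frame interval in minutes.
#' @param n_steps steps per track.
#' @param seed RNG seed.
#' @return data frame `cell_id`, `time` (minutes), `x`, `y` (micrometres);
#'   ground truth in attribute `truth`.
#' @export
gen_tracks <- function(n_cells = 10, true_speed = 1.2, dt = 10, n_steps = 36,
                       seed = 1) {
  stop_if_not_scalar_number(true_speed, "true_speed", 0)
  truth <- list(true_speed = true_speed, dt = dt)
  if (n_cells == 0) {
    out <- data.frame(cell_id = character(0), time = numeric(0),
                      x = numeric(0), y = numeric(0), stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    return(out)
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_cells), function(ci) {
      th <- stats::runif(n_steps, 0, 2 * pi)
      x <- cumsum(c(stats::runif(1, 0, 100), true_speed * dt * cos(th)))
      y <- cumsum(c(stats::runif(1, 0, 100), true_speed * dt * sin(th)))
      data.frame(cell_id = sprintf("cell-%03d", ci),
                 time = dt * (0:n_steps), x = x, y = y,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- truth
    out
  })
}
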