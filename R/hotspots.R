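# Interface residues and consensus hotspot calling across docking poses.
# A residue is an interface residue of a pose when it has at least one
# cross-partner contact inside the RIN distance window. A residue is a
# hotspot when it is at the interface in at least one pose AND central
# (closeness Z >= 3 on the full-complex RIN) in at least one pose; the
# maximum Z over poses is retained.

#' Partner map for a two-partner complex
#'
#' Assigns every chain of a docked complex to one binding partner.
#' @param receptor,ligand character vectors of chain identifiers.
#' @return a `PartnerMap` (named character vector chain -> label).
#' @export
partner_map <- function(receptor, ligand) {
  if (length(receptor) == 0 || length(ligand) == 0)
    stop("both partners need at least one chain", call. = FALSE)
  if (length(intersect(receptor, ligand)) > 0)
    stop("a chain cannot belong to both partners", call. = FALSE)
  structure(c(setNames(rep("receptor", length(receptor)), receptor),
              setNames(rep("ligand", length(ligand)), ligand)),
            class = "PartnerMap")
}

partner_of <- function(model, partners) {
  chains <- unique(model$atoms$chain)
  missing <- setdiff(chains, names(partners))
  if (length(missing) > 0)
    stop("chain(s) not assigned to a partner: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lab <- unname(partners[model$residues$chain])
  if (!all(c("receptor", "ligand") %in% lab))
    stop("model must contain chains of both partners", call. = FALSE)
  lab
}

#' Interface residues of a docked pose
#'
#' A residue is at the interface when its minimum heavy-atom distance to any
#' residue of the other partner lies in `[d_min, d_max]` (the RIN contact
#' window, so a single distance convention is used throughout).
#'
#' @param model a `StructureModel` containing both partners.
#' @param partners a [partner_map()].
#' @param d_min,d_max contact window in Angstrom.
#' @return list with character vectors `receptor` and `ligand` of residue keys.
#' @export
interface_residues <- function(model, partners, d_min = 2.5, d_max = 5.0) {
  lab <- partner_of(model, partners)
  D <- residue_distance_matrix(model)
  cross <- outer(lab, lab, "!=")
  hit <- (D >= d_min & D <= d_max) & cross
  is_iface <- rowSums(hit) > 0
  list(receptor = model$residues$key[is_iface & lab == "receptor"],
       ligand = model$residues$key[is_iface & lab == "ligand"])
}

#' Analyse one docking pose
#'
#' Builds the RIN on the full complex (both partners together, so
#' cross-partner contacts are edges), runs the residue centrality analysis
#' on it, and extracts the interface residues of each partner.
#'
#' @inheritParams interface_residues
#' @param z_threshold inclusive Z cut-off for central residues.
#' @return a `PoseResult`: `pose_id`, `interface` (receptor/ligand key sets),
#'   `centrality` (a `CentralityResult`), `partner` (per-residue label),
#'   and the parameters used.
#' @export
analyze_pose <- function(model, partners, d_min = 2.5, d_max = 5.0,
                         z_threshold = 3) {
  lab <- partner_of(model, partners)
  rin <- build_rin(model, d_min = d_min, d_max = d_max)
  cen <- residue_centrality(rin, z_threshold = z_threshold)
  iface <- interface_residues(model, partners, d_min = d_min, d_max = d_max)
  structure(list(pose_id = model$pose_id, interface = iface, centrality = cen,
                 partner = setNames(lab, model$residues$key),
                 params = list(d_min = d_min, d_max = d_max,
                               z_threshold = z_threshold)),
            class = "PoseResult")
}

#' @export
print.PoseResult <- function(x, ...) {
  cat(sprintf("<PoseResult '%s': %d receptor + %d ligand interface residues, %d central>\n",
              x$pose_id, length(x$interface$receptor), length(x$interface$ligand),
              sum(x$centrality$is_central)))
  invisible(x)
}

#' Consensus hotspots over an ensemble of docking poses
#'
#' Residues are matched across poses by their key (chain, number, insertion
#' code); a residue is flagged as a hotspot when it was at the interface in
#' at least `min_interface_poses` poses and central in at least
#' `min_central_poses` poses (defaults: one model suffices). The maximum
#' centrality Z-score over the poses where the residue exists is retained.
#'
#' @param pose_results list of `PoseResult` objects (same complex, shared
#'   residue numbering; inconsistent partner assignments are an error).
#' @param min_central_poses,min_interface_poses consensus thresholds.
#' @param candidates optional character vector of residue keys; when given,
#'   the table is restricted to these residues (replicates analyses run on a
#'   pre-selected candidate list).
#' @return a `HotspotTable` data frame: `residue`, `partner`,
#'   `n_poses_interface`, `n_poses_central`, `max_z`, `hotspot`, sorted by
#'   (`hotspot` desc, `max_z` desc).
#' @examples
#' poses <- gen_toy_poses(toy_complex_spec(n_poses = 2))
#' pm <- partner_map("A", "B")
#' results <- lapply(poses, analyze_pose, partners = pm)
#' consensus_hotspots(results)
#' @export
consensus_hotspots <- function(pose_results, min_central_poses = 1,
                               min_interface_poses = 1, candidates = NULL) {
  if (length(pose_results) < 1) stop("need at least one pose", call. = FALSE)
  stopifnot(all(vapply(pose_results, inherits, TRUE, "PoseResult")))
  all_partner <- list()
  for (pr in pose_results) {
    for (k in names(pr$partner)) {
      prev <- all_partner[[k]]
      if (!is.null(prev) && prev != pr$partner[[k]])
        stop("inconsistent partner maps across poses at residue ", k,
             call. = FALSE)
      all_partner[[k]] <- pr$partner[[k]]
    }
  }
  keys <- names(all_partner)
  n_iface <- setNames(integer(length(keys)), keys)
  n_central <- n_iface
  max_z <- setNames(rep(-Inf, length(keys)), keys)
  for (pr in pose_results) {
    iface <- c(pr$interface$receptor, pr$interface$ligand)
    n_iface[iface] <- n_iface[iface] + 1L
    cen <- pr$centrality
    n_central[cen$residue[cen$is_central]] <-
      n_central[cen$residue[cen$is_central]] + 1L
    max_z[cen$residue] <- pmax(max_z[cen$residue], cen$z)
  }
  tab <- data.frame(
    residue = keys, partner = unlist(all_partner, use.names = FALSE),
    n_poses_interface = unname(n_iface), n_poses_central = unname(n_central),
    max_z = unname(max_z),
    stringsAsFactors = FALSE
  )
  tab$hotspot <- tab$n_poses_interface >= min_interface_poses &
    tab$n_poses_central >= min_central_poses
  if (!is.null(candidates)) tab <- tab[tab$residue %in% candidates, , drop = FALSE]
  tab <- tab[order(-tab$hotspot, -tab$max_z), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("HotspotTable", "data.frame"),
            n_poses = length(pose_results))
}

#' @export
print.HotspotTable <- function(x, ...) {
  cat(sprintf("Consensus hotspots over %d pose(s): %d hotspot residue(s)\n",
              attr(x, "n_poses"), sum(x$hotspot)))
  NextMethod()
}

#' Write a hotspot table as TSV
#' @param table a `HotspotTable`.
#' @param file output path.
#' @export
write_hotspot_tsv <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}
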