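# Minimal structural data model: a pose is a set of residues, each residue a
# small group of atoms. Residue identity ("key") is chain:seqnum[icode],
# matching how residues are matched across docking poses.

residue_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  chain <- ifelse(is.na(chain), "", chain)
  paste0(chain, ":", resno, icode)
}

new_structure_model <- function(pose_id, atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  key <- residue_key(atoms$chain, atoms$resno, atoms$icode)
  first <- !duplicated(key)
  residues <- data.frame(
    key = key[first], chain = atoms$chain[first], resno = atoms$resno[first],
    icode = atoms$icode[first], resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )
  model <- structure(
    list(pose_id = pose_id, atoms = atoms, residues = residues,
         atom_res = match(key, residues$key)),
    class = "StructureModel"
  )
  model
}

#' Number of residues in a structure model
#' @param model a `StructureModel`
#' @return integer count
#' @export
n_residues <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  nrow(model$residues)
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("<StructureModel '%s': %d residues, %d atoms, chains %s>\n",
              x$pose_id, nrow(x$residues), nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

# Validate fixed-column ATOM/HETATM records so parse failures carry a line
# number; the actual parsing is then delegated to bio3d.
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  coord <- grep("^(ATOM  |HETATM)", lines)
  for (i in coord) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("line %d: truncated coordinate record", i), call. = FALSE)
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop(sprintf("line %d: unparseable coordinates", i), call. = FALSE)
    if (is.na(suppressWarnings(as.integer(substr(ln, 23, 26)))))
      stop(sprintf("line %d: unparseable residue number", i), call. = FALSE)
  }
  invisible(length(coord))
}

resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt) | alt == " "] <- ""
  if (all(alt == "")) return(at)
  grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(grp, unique(grp))),
                        function(idx) idx[which.max(occ[idx])]),
                 use.names = FALSE)
  at[sort(keep), , drop = FALSE]
}

#' Read a structure model from PDB text or a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records (via [bio3d::read.pdb()]),
#' grouping atoms into residues by chain, sequence number and insertion code.
#' Alternate locations are resolved to the highest-occupancy conformer (ties:
#' first in file). Waters and other `HETATM` records are excluded by default.
#' A file with several `MODEL` blocks yields one pose per model.
#'
#' @param pdb PDB text (single string or character vector of lines) or the
#'   path of an existing PDB file.
#' @param pose_id identifier attached to the returned pose; multi-model files
#'   get `"<pose_id>_<model#>"`. Defaults to the file name or `"pose"`.
#' @param keep_hetatm keep non-water `HETATM` records as residues.
#' @return a `StructureModel`, or a list of them for a multi-model file.
#' @examples
#' txt <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
#' m <- read_structure(txt, "demo")
#' n_residues(m)
#' @export
read_structure <- function(pdb, pose_id = NULL, keep_hetatm = FALSE) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
    if (is.null(pose_id)) pose_id <- sub("\\.pdb$", "", basename(path))
    lines <- readLines(path, warn = FALSE)
  } else {
    if (is.null(pose_id)) pose_id <- "pose"
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(lines, path)
  }
  validate_pdb_lines(lines)
  n_models <- max(1L, length(grep("^MODEL ", lines)))
  pdbobj <- withCallingHandlers(
    tryCatch(
      bio3d::read.pdb(path, multi = n_models > 1L, rm.alt = FALSE,
                      verbose = FALSE, hex = FALSE),
      error = function(e) stop("failed to parse PDB input: ",
                               conditionMessage(e), call. = FALSE)
    ),
    # duplicated serial numbers carry no meaning for the residue model
    warning = function(w) {
      if (grepl("eleno", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  at <- pdbobj$atom
  keep <- at$type == "ATOM"
  if (keep_hetatm) keep <- keep | (at$type == "HETATM" & at$resid != "HOH")
  if (!any(keep))
    stop("empty model: no ATOM records after exclusions", call. = FALSE)
  sel <- which(keep)
  at_one <- resolve_altloc(at[sel, , drop = FALSE])
  elem <- at_one$elesy
  elem[is.na(elem) | elem == ""] <- toupper(substr(trimws(at_one$elety), 1, 1))
  base <- data.frame(
    chain = ifelse(is.na(at_one$chain), "", at_one$chain),
    resno = at_one$resno,
    icode = ifelse(is.na(at_one$insert), "", at_one$insert),
    resname = at_one$resid, atom = trimws(at_one$elety), element = elem,
    x = at_one$x, y = at_one$y, z = at_one$z,
    is_h = toupper(elem) == "H",
    stringsAsFactors = FALSE
  )
  if (n_models <= 1L) return(new_structure_model(pose_id, base))
  xyz <- pdbobj$xyz
  rowidx <- as.integer(rownames(at_one))
  if (is.null(rowidx) || anyNA(rowidx)) rowidx <- sel
  lapply(seq_len(nrow(xyz)), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[rowidx, , drop = FALSE]
    b <- base
    b$x <- co[, 1]; b$y <- co[, 2]; b$z <- co[, 3]
    new_structure_model(sprintf("%s_%d", pose_id, m), b)
  })
}

#' Write a structure model (or list of poses) as PDB text
#'
#' Emits fixed-column `ATOM` records; a list of models becomes a multi-model
#' file with `MODEL`/`ENDMDL` blocks. Coordinates are written at PDB precision
#' (3 decimals) and must fit the 8-column field.
#'
#' @param model a `StructureModel` or list of them.
#' @param file optional path; when given the text is also written there.
#' @return the PDB text, invisibly when `file` is given.
#' @export
write_structure <- function(model, file = NULL) {
  models <- if (inherits(model, "StructureModel")) list(model) else model
  if (length(models) == 0) stop("empty model", call. = FALSE)
  stopifnot(all(vapply(models, inherits, TRUE, "StructureModel")))
  fmt_one <- function(m) {
    a <- m$atoms
    if (nrow(a) == 0) stop("empty model", call. = FALSE)
    bad <- a$x >= 1e4 | a$x <= -1e3 | a$y >= 1e4 | a$y <= -1e3 |
      a$z >= 1e4 | a$z <= -1e3
    if (any(bad))
      stop("coordinates outside the PDB fixed-width field range", call. = FALSE)
    name <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(a)) %% 100000L, name, a$resname,
      substr(paste0(a$chain, " "), 1, 1), a$resno,
      substr(paste0(a$icode, " "), 1, 1), a$x, a$y, a$z, 1, 0,
      toupper(a$element))
    ter <- cumsum(rle(a$chain)$lengths)
    out <- character(0)
    last <- 0
    for (t in ter) {
      out <- c(out, lines[(last + 1):t], "TER")
      last <- t
    }
    out
  }
  if (length(models) == 1L) {
    txt <- c(fmt_one(models[[1]]), "END")
  } else {
    txt <- unlist(lapply(seq_along(models), function(i)
      c(sprintf("MODEL     %4d", i), fmt_one(models[[i]]), "ENDMDL")))
    txt <- c(txt, "END")
  }
  txt <- paste(txt, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
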