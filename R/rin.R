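# Residue interaction network (RIN): nodes are residues, edges are contacts.
# A contact is a pair of residues whose minimum heavy-atom distance lies
# inside a window, by default [2.5, 5.0] Angstrom, inclusive at both ends.
# The lower bound excludes covalent/clash geometry; pairs closer than it are
# reported as a warning and produce no edge.

#' Minimum heavy-atom distance between two residues
#'
#' The distance between two residues is the minimum Euclidean distance over
#' all pairs of their non-hydrogen atoms. This is the standard contact
#' convention for residue interaction networks and the only reading
#' compatible with a 2.5-Angstrom lower contact bound.
#'
#' @param res_a,res_b data frames of atoms with columns `x`, `y`, `z` and
#'   optionally `is_h` (hydrogens are dropped before the computation).
#' @return the minimum distance in Angstrom.
#' @export
residue_min_distance <- function(res_a, res_b) {
  drop_h <- function(r) if ("is_h" %in% names(r)) r[!r$is_h, , drop = FALSE] else r
  a <- drop_h(res_a); b <- drop_h(res_b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("residue has no non-hydrogen atoms", call. = FALSE)
  am <- cbind(a$x, a$y, a$z); bm <- t(cbind(b$x, b$y, b$z))
  d2 <- Inf
  for (i in seq_len(nrow(am))) d2 <- min(d2, min(colSums((bm - am[i, ])^2)))
  sqrt(d2)
}

new_rin <- function(nodes, edges, d_min, d_max) {
  structure(list(nodes = nodes, edges = edges,
                 params = list(d_min = d_min, d_max = d_max,
                               atoms = "heavy")),
            class = "RIN")
}

#' @export
print.RIN <- function(x, ...) {
  cat(sprintf("<RIN: %d residues, %d contacts, window [%.2f, %.2f] A (heavy atoms)>\n",
              length(x$nodes), nrow(x$edges), x$params$d_min, x$params$d_max))
  invisible(x)
}

#' Build the residue interaction network of a structure model
#'
#' Every residue of the model (all chains, so inter-chain contacts become
#' edges) is a node; an undirected edge joins residues whose minimum
#' heavy-atom distance falls inside `[d_min, d_max]`, bounds inclusive.
#' Isolated residues remain as nodes. Sequence-adjacent residues are
#' eligible for edges unless `exclude_adjacent` is set.
#'
#' @param model a `StructureModel`.
#' @param d_min,d_max contact window in Angstrom; `0 <= d_min < d_max`.
#' @param exclude_adjacent drop edges between residues adjacent in sequence
#'   (same chain, consecutive numbers). Default `FALSE`: no exclusion.
#' @return a `RIN`: `nodes` (residue keys in model order), `edges`
#'   (data frame `a`, `b`, `distance`), and the window parameters.
#' @examples
#' spec <- toy_complex_spec(n_poses = 1)
#' pose <- gen_toy_poses(spec)[[1]]
#' build_rin(pose)
#' @export
build_rin <- function(model, d_min = 2.5, d_max = 5.0, exclude_adjacent = FALSE) {
  stopifnot(inherits(model, "StructureModel"))
  stop_if_not_scalar_number(d_min, "d_min", 0)
  stop_if_not_scalar_number(d_max, "d_max", 0)
  if (d_min >= d_max) stop("`d_min` must be smaller than `d_max`", call. = FALSE)
  D <- residue_distance_matrix(model)
  res <- model$residues
  n <- nrow(res)
  sel <- which(upper.tri(D) & D >= d_min & D <= d_max, arr.ind = TRUE)
  n_clash <- sum(upper.tri(D) & D < d_min)
  if (n_clash > 0)
    warning(sprintf("%d residue pair(s) below the %.2f A lower bound; no edge added",
                    n_clash, d_min), call. = FALSE)
  edges <- data.frame(a = res$key[sel[, 1]], b = res$key[sel[, 2]],
                      distance = D[sel], stringsAsFactors = FALSE)
  if (exclude_adjacent && nrow(edges) > 0) {
    ia <- sel[, 1]; ib <- sel[, 2]
    adj <- res$chain[ia] == res$chain[ib] &
      abs(res$resno[ia] - res$resno[ib]) == 1L &
      res$icode[ia] == "" & res$icode[ib] == ""
    edges <- edges[!adj, , drop = FALSE]
  }
  new_rin(res$key, edges, d_min, d_max)
}

# Pairwise minimum heavy-atom distance matrix over residues of a model.
residue_distance_matrix <- function(model) {
  a <- model$atoms
  heavy <- !a$is_h
  if (!any(heavy)) stop("model has no non-hydrogen atoms", call. = FALSE)
  co <- cbind(a$x, a$y, a$z)[heavy, , drop = FALSE]
  ridx <- model$atom_res[heavy]
  n <- nrow(model$residues)
  A <- as.matrix(stats::dist(co))
  D <- matrix(Inf, n, n)
  rf <- factor(ridx, levels = seq_len(n))
  for (i in seq_len(n)) {
    rows <- which(ridx == i)
    if (length(rows) == 0) next
    dmin <- if (length(rows) == 1) A[rows, ] else apply(A[rows, , drop = FALSE], 2, min)
    D[i, ] <- tapply(dmin, rf, min)
  }
  D[is.na(D)] <- Inf
  diag(D) <- Inf
  D
}

#' Write / read a RIN as an edge-list TSV
#'
#' Columns `a`, `b`, `distance` plus a `# params:` comment line recording the
#' window and the heavy-atom convention.
#' @param rin a `RIN`.
#' @param file path of the TSV.
#' @return `read_rin_tsv` returns a `RIN` (node set = endpoints of the edges).
#' @export
write_rin_tsv <- function(rin, file) {
  stopifnot(inherits(rin, "RIN"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# params: d_min=%g d_max=%g atoms=%s nodes=%s",
                     rin$params$d_min, rin$params$d_max, rin$params$atoms,
                     paste(rin$nodes, collapse = ",")), con)
  utils::write.table(rin$edges, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_rin_tsv
#' @export
read_rin_tsv <- function(file) {
  header <- readLines(file, n = 1)
  edges <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  get <- function(k, default) {
    m <- regmatches(header, regexec(paste0(k, "=([^ ]+)"), header))[[1]]
    if (length(m) == 2) m[2] else default
  }
  nodes <- strsplit(get("nodes", ""), ",", fixed = TRUE)[[1]]
  if (length(nodes) == 0) nodes <- unique(c(edges$a, edges$b))
  new_rin(nodes, edges,
          as.numeric(get("d_min", 2.5)), as.numeric(get("d_max", 5)))
}
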