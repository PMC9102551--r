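# Independent oracles and small fixture builders used across the suite.

# --- structure fixtures ----------------------------------------------------

pdb_line <- function(chain, resno, x, y, z, name = "CA", resname = "ALA",
                     serial = 1, element = "C", icode = " ", alt = " ",
                     occ = 1, record = "ATOM  ") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, paste0(" ", name), alt, resname, chain, resno,
          icode, x, y, z, occ, 0, element)
}

# a model straight from coordinates: `residues` is a list of lists with
# fields chain, resno, xyz (matrix), optional element vector
make_model <- function(residues, pose_id = "fixture") {
  atoms <- do.call(rbind, lapply(residues, function(r) {
    xyz <- r$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
    el <- if (is.null(r$element)) rep("C", nrow(xyz)) else r$element
    data.frame(chain = r$chain, resno = r$resno, icode = "",
               resname = "ALA", atom = paste0("X", seq_len(nrow(xyz))),
               element = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               is_h = toupper(el) == "H", stringsAsFactors = FALSE)
  }))
  hotspotr:::new_structure_model(pose_id, atoms)
}

# random heavy-atom structure in a box scaled to give a mix of contacts
random_structure <- function(n_res, seed, atoms_max = 3) {
  set.seed(seed)
  side <- max(8, round(4 * n_res^(1 / 3) * 1.6))
  residues <- lapply(seq_len(n_res), function(i) {
    na <- sample.int(atoms_max, 1)
    center <- runif(3, 0, side)
    xyz <- matrix(rep(center, each = na), ncol = 3) +
      matrix(runif(na * 3, -1, 1), ncol = 3)
    list(chain = if (i <= n_res / 2) "A" else "B", resno = i,
         xyz = round(xyz, 3))
  })
  make_model(residues, sprintf("rand_%d", seed))
}

# --- brute-force RIN oracle ------------------------------------------------

# direct double loop over residues and atoms; independent of build_rin
brute_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B))) {
      d <- sqrt(sum((A[i, ] - B[j, ])^2))
      if (d < best) best <- d
    }
  best
}

brute_rin_edges <- function(model, d_min = 2.5, d_max = 5.0) {
  res <- model$residues
  a <- model$atoms[!model$atoms$is_h, ]
  ridx <- model$atom_res[!model$atoms$is_h]
  coords <- lapply(seq_len(nrow(res)), function(i)
    cbind(a$x, a$y, a$z)[ridx == i, , drop = FALSE])
  out <- character(0)
  for (i in seq_len(nrow(res) - 1))
    for (j in (i + 1):nrow(res)) {
      d <- brute_min_dist(coords[[i]], coords[[j]])
      if (d >= d_min && d <= d_max) {
        k <- sort(c(res$key[i], res$key[j]))
        out <- c(out, paste(k[1], k[2], sep = "|"))
      }
    }
  sort(out)
}

edge_key_set <- function(rin) {
  if (nrow(rin$edges) == 0) return(character(0))
  sort(paste(pmin(rin$edges$a, rin$edges$b),
             pmax(rin$edges$a, rin$edges$b), sep = "|"))
}

# --- BFS closeness oracle --------------------------------------------------

# hand-rolled breadth-first search + Wasserman-Faust closeness,
# independent of igraph
bfs_closeness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- vector("list", n)
  if (nrow(edges) > 0) {
    ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
    for (k in seq_along(ia)) {
      adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
      adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
    }
  }
  vapply(seq_len(n), function(s) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(d[w])) {
        d[w] <- d[v] + 1L
        queue <- c(queue, w)
      }
    }
    reach <- d[-s][!is.na(d[-s])]
    r <- length(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
}

# random graph as a RIN-shaped object (no geometry)
random_graph_rin <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  new_rin_from_edges(nodes, data.frame(a = nodes[pairs[keep, 1]],
                                       b = nodes[pairs[keep, 2]],
                                       stringsAsFactors = FALSE))
}
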