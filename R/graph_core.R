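# Graph data model, XYZ / line-delimited container I/O, and radius-cutoff
# graph construction.

#' Construct an atomistic graph
#'
#' An \code{atom_graph} holds one molecular or atomistic graph: atomic numbers
#' \code{Z}, optional Cartesian coordinates (Angstrom), an undirected edge
#' list, optional raw node/edge features, and a named list of prediction
#' targets. Edges are stored internally as both ordered directions, since
#' message passing sends direction-explicit messages; file writers emit each
#' undirected edge once. Node indices are 1-based.
#'
#' @param atomic_numbers integer vector of atomic numbers (length N >= 1).
#' @param coords optional N x 3 numeric matrix of coordinates in Angstrom.
#' @param edge_index edge list, one row per undirected edge \code{(u, v)}
#'   (a 2-column matrix); both orientations may be supplied, duplicates are
#'   collapsed. Self loops are an error.
#' @param node_features optional N x p numeric matrix of raw node features.
#' @param edge_features optional numeric matrix with one row per supplied
#'   edge; rows follow the collapsed undirected edges and are mirrored onto
#'   both stored directions.
#' @param targets named list mapping task name to a graph-level scalar/vector
#'   or a node-level N-vector.
#' @param graph_id identifier string.
#' @return An object of class \code{atom_graph}.
#' @export
atom_graph <- function(atomic_numbers, coords = NULL, edge_index = NULL,
                       node_features = NULL, edge_features = NULL,
                       targets = list(), graph_id = "g") {
  z <- as.integer(atomic_numbers)
  n <- length(z)
  stopifnot(n >= 1)
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    stopifnot(nrow(coords) == n)
  }
  if (!is.null(node_features)) {
    node_features <- as.matrix(node_features)
    stopifnot(nrow(node_features) == n)
  }
  if (is.null(edge_index) || length(edge_index) == 0) {
    und <- matrix(integer(0), 0, 2)
  } else {
    ei <- matrix(as.integer(edge_index), ncol = 2)
    if (any(ei[, 1] == ei[, 2])) stop("self-loops are not allowed")
    if (any(ei < 1L) || any(ei > n)) stop("edge index out of range")
    lo <- pmin(ei[, 1], ei[, 2]); hi <- pmax(ei[, 1], ei[, 2])
    keep <- !duplicated(paste(lo, hi))
    und <- cbind(lo[keep], hi[keep])
    if (!is.null(edge_features)) {
      edge_features <- as.matrix(edge_features)
      stopifnot(nrow(edge_features) == nrow(ei))
      edge_features <- edge_features[keep, , drop = FALSE]
    }
  }
  ord <- order(und[, 1], und[, 2])
  und <- und[ord, , drop = FALSE]
  if (!is.null(edge_features)) edge_features <- edge_features[ord, , drop = FALSE]
  # both directions, undirected listing first then its mirror
  dir_edges <- rbind(und, und[, 2:1, drop = FALSE])
  dir_feats <- if (is.null(edge_features)) NULL else
    rbind(edge_features, edge_features)
  structure(list(
    atomic_numbers = z, coords = coords, node_features = node_features,
    edge_index = dir_edges, edge_features = dir_feats,
    n_undirected = nrow(und), targets = targets,
    graph_id = as.character(graph_id)
  ), class = "atom_graph")
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("<atom_graph %s: %d atoms, %d undirected edges, %s coords, %d targets>\n",
              x$graph_id, length(x$atomic_numbers), x$n_undirected,
              if (is.null(x$coords)) "no" else "3D", length(x$targets)))
  invisible(x)
}

n_atoms <- function(g) length(g$atomic_numbers)

#' Undirected edge list of a graph
#'
#' Each undirected edge once, as stored (u < v, sorted).
#' @param g an \code{atom_graph}.
#' @return integer matrix with 2 columns.
#' @export
undirected_edges <- function(g) {
  g$edge_index[seq_len(g$n_undirected), , drop = FALSE]
}

#' Build edges by radius cutoff
#'
#' Connects every pair of distinct atoms whose Euclidean distance is strictly
#' below the cutoff \code{r_c}: ties at exactly \code{r_c} are excluded. The
#' result is invariant under rigid motions of the coordinates.
#'
#' @param coords N x 3 numeric matrix (Angstrom).
#' @param r_c radius cutoff in Angstrom (default 5.0, the usual value for
#'   crystal/framework datasets).
#' @return integer matrix of undirected edges (u < v), one row per pair.
#' @export
build_radius_graph <- function(coords, r_c = 5.0) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) >= 1, r_c > 0)
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  d <- as.matrix(stats::dist(coords))
  hit <- which(d < r_c & upper.tri(d), arr.ind = TRUE)
  out <- cbind(hit[, 1], hit[, 2])[order(hit[, 1], hit[, 2]), , drop = FALSE]
  dimnames(out) <- NULL
  out
}

as_igraph <- function(g) {
  igraph::make_graph(as.vector(t(undirected_edges(g))), n = n_atoms(g),
                     directed = FALSE)
}

#' Shortest-path (hop) distance between two nodes
#'
#' BFS hop count on the undirected graph; \code{Inf} for disconnected pairs,
#' 0 on the diagonal.
#' @param g an \code{atom_graph}.
#' @param u,v 1-based node indices.
#' @return a non-negative number, possibly \code{Inf}.
#' @export
graph_distance <- function(g, u, v) {
  n <- n_atoms(g)
  stopifnot(u >= 1, u <= n, v >= 1, v <= n)
  ig <- as_igraph(g)
  as.numeric(igraph::distances(ig, v = u, to = v))
}

# ---- element symbols -------------------------------------------------------

element_symbols <- function() element_table()$symbol

symbol_to_z <- function(symbols) {
  z <- match(symbols, element_symbols())
  if (anyNA(z)) {
    bad <- symbols[is.na(z)][1]
    stop(sprintf("unknown element symbol '%s'", bad))
  }
  z
}

# ---- XYZ I/O ---------------------------------------------------------------

#' Read an XYZ file into an atom graph
#'
#' Standard XYZ: atom count line, comment line, then one
#' \code{symbol x y z} line per atom. Edges are not part of the format; build
#' them afterwards with \code{\link{build_radius_graph}}.
#'
#' @param path path to an XYZ file.
#' @param r_c optional radius cutoff; when given, edges are constructed
#'   immediately.
#' @return an \code{atom_graph}.
#' @export
read_xyz <- function(path, r_c = NULL) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2) stop("malformed XYZ: fewer atom lines than declared")
  rows <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  for (i in seq_along(rows)) {
    if (length(rows[[i]]) < 4)
      stop(sprintf("malformed XYZ record at line %d", i + 2))
  }
  sym <- vapply(rows, `[[`, "", 1)
  xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("malformed XYZ: non-numeric coordinates")
  z <- symbol_to_z(sym)
  ei <- if (is.null(r_c)) NULL else build_radius_graph(xyz, r_c)
  atom_graph(z, coords = xyz, edge_index = ei,
             graph_id = sub("\\.xyz$", "", basename(path)))
}

#' Write atom graphs to a line-delimited container
#'
#' One JSON record per line with fields \code{id}, \code{z}, optional
#' \code{coords} (flattened row-major), \code{edges} (each undirected edge
#' once, 1-based), optional \code{x}/\code{e} feature matrices, and
#' \code{targets}. Numbers are serialized at full precision so that
#' \code{read_container(write_container(g))} round-trips bit-exactly for
#' finite inputs.
#'
#' @param graphs list of \code{atom_graph}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_container <- function(graphs, path) {
  if (inherits(graphs, "atom_graph")) graphs <- list(graphs)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in graphs) {
    und <- undirected_edges(g)
    rec <- list(id = g$graph_id, z = g$atomic_numbers)
    if (!is.null(g$coords)) rec[["coords"]] <- as.numeric(t(g$coords))
    rec[["edges"]] <- as.integer(t(und))
    if (!is.null(g$node_features)) {
      rec$x <- as.numeric(t(g$node_features))
      rec[["x_ncol"]] <- ncol(g$node_features)
    }
    if (!is.null(g$edge_features)) {
      ef <- g$edge_features[seq_len(g$n_undirected), , drop = FALSE]
      rec$e <- as.numeric(t(ef))
      rec[["e_ncol"]] <- ncol(ef)
    }
    if (length(g$targets)) rec[["targets"]] <- g$targets
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' Read a line-delimited graph container
#'
#' @param path path written by \code{\link{write_container}}.
#' @return list of \code{atom_graph}.
#' @export
read_container <- function(path) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e)
                      stop(sprintf("malformed container record at line %d: %s",
                                   i, conditionMessage(e))))
    z <- as.integer(rec[["z"]])
    coords <- if (!is.null(rec[["coords"]]))
      matrix(rec[["coords"]], ncol = 3, byrow = TRUE) else NULL
    ei <- if (length(rec[["edges"]]))
      matrix(as.integer(rec[["edges"]]), ncol = 2, byrow = TRUE) else NULL
    x <- if (!is.null(rec[["x"]]))
      matrix(rec[["x"]], ncol = rec[["x_ncol"]], byrow = TRUE) else NULL
    e <- if (!is.null(rec[["e"]]))
      matrix(rec[["e"]], ncol = rec[["e_ncol"]], byrow = TRUE) else NULL
    targets <- if (is.null(rec[["targets"]])) list() else
      lapply(rec[["targets"]], function(t) as.numeric(t))
    atom_graph(z, coords = coords, edge_index = ei, node_features = x,
               edge_features = e, targets = targets, graph_id = rec[["id"]])
  })
}

#' Split a dataset of graphs into train/validation/test index sets
#'
#' Random disjoint 80/10/10 split by default; the union covers all graphs.
#'
#' @param n_graphs number of graphs.
#' @param fractions length-3 numeric summing to 1.
#' @param seed RNG seed.
#' @return list with integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
make_split <- function(n_graphs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  set.seed(seed)
  perm <- sample.int(n_graphs)
  n_tr <- floor(fractions[1] * n_graphs)
  n_va <- floor(fractions[2] * n_graphs)
  list(train = sort(perm[seq_len(n_tr)]),
       val   = sort(perm[n_tr + seq_len(n_va)]),
       test  = sort(perm[(n_tr + n_va + 1):n_graphs]))
}
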