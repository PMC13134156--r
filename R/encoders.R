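# Pre-computed per-graph feature channels: chemical element descriptors (CE,
# N x 15), node topological encodings (TE, N x 9), edge topological encodings
# (TE, |E| x 4), and Laplacian positional encodings (LPE, N x d_l), plus
# split-wise standardization and the invalid-sample discard rule.

.molgps_env <- new.env(parent = emptyenv())

#' Element property table
#'
#' The embedded table of 15 numeric properties per element, Z = 1..86:
#' atomic weight, group, period, block (ordinal s/p/d/f = 0..3), valence
#' electron count, covalent radius, van der Waals radius, Pauling and Allen
#' electronegativities, electron affinity, first ionization energy, melting
#' point, boiling point, density, and atomic volume. Properties without an
#' accepted value (e.g. noble-gas electron affinities) are \code{NA} and
#' propagate to the discard rule.
#'
#' @return data.frame with columns \code{z}, \code{symbol} and the 15
#'   property columns.
#' @export
element_table <- function() {
  if (is.null(.molgps_env$eltab)) {
    path <- system.file("extdata", "element_properties.csv",
                        package = "molgps", mustWork = TRUE)
    .molgps_env$eltab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .molgps_env$eltab
}

ce_property_names <- function() {
  c("atomic_weight", "group", "period", "block", "valence_electrons",
    "covalent_radius", "vdw_radius", "en_pauling", "en_allen",
    "electron_affinity", "ionization_energy", "melting_point",
    "boiling_point", "density", "atomic_volume")
}

#' Chemical element descriptors (CE)
#'
#' Looks up the 15-dimensional per-atom descriptor vector for each atomic
#' number; identical atoms yield identical rows. \code{NA} entries (missing
#' physical values) are returned as-is and later trigger the discard rule.
#'
#' @param atomic_numbers integer vector of atomic numbers.
#' @return N x 15 numeric matrix, columns in the fixed property order of
#'   \code{\link{element_table}}.
#' @export
chemical_descriptors <- function(atomic_numbers) {
  tab <- element_table()
  z <- as.integer(atomic_numbers)
  bad <- z[z < 1 | z > max(tab$z)]
  if (length(bad)) stop(sprintf("atomic number %d outside the element table", bad[1]))
  m <- as.matrix(tab[z, ce_property_names()])
  dimnames(m) <- list(NULL, ce_property_names())
  m
}

#' Node topological encodings (node TE)
#'
#' Nine classic centrality/structure measures per node, computed on the
#' undirected graph: degree, closeness, betweenness, eigenvector centrality,
#' PageRank, local clustering coefficient, k-core number, harmonic
#' centrality, and eccentricity. Disconnected graphs use within-component
#' conventions (closeness/eccentricity within the component, harmonic
#' centrality over reachable nodes); any remaining non-finite value marks the
#' graph invalid downstream.
#'
#' @param g an \code{atom_graph}.
#' @return N x 9 numeric matrix with named columns.
#' @export
node_topological_encodings <- function(g) {
  ig <- as_igraph(g)
  n <- n_atoms(g)
  deg <- igraph::degree(ig)
  clo <- suppressWarnings(igraph::closeness(ig))       # within component
  clo[deg == 0] <- 0                                   # isolated node
  btw <- igraph::betweenness(ig)
  eig <- if (igraph::ecount(ig) > 0)
    igraph::eigen_centrality(ig)$vector else rep(0, n)
  pr <- igraph::page_rank(ig)$vector
  clu <- igraph::transitivity(ig, type = "localundirected", isolates = "zero")
  kco <- igraph::coreness(ig)
  har <- igraph::harmonic_centrality(ig)
  ecc <- igraph::eccentricity(ig)
  m <- cbind(degree = deg, closeness = clo, betweenness = btw,
             eigenvector = eig, pagerank = pr, clustering = clu,
             kcore = kco, harmonic = har, eccentricity = ecc)
  rownames(m) <- NULL
  m
}

#' Edge topological encodings (edge TE)
#'
#' Four structural measures per edge: edge betweenness, Jaccard coefficient,
#' Adamic-Adar score, and preferential attachment, in that order. Rows align
#' with the graph's stored edge order (both directions carry the edge's
#' value, all four measures being symmetric).
#'
#' @param g an \code{atom_graph}.
#' @param directed_rows if \code{TRUE} (default) one row per stored directed
#'   edge; otherwise one row per undirected edge.
#' @return matrix with 4 named columns.
#' @export
edge_topological_encodings <- function(g, directed_rows = TRUE) {
  und <- undirected_edges(g)
  if (nrow(und) < 1) stop("graph has no edges")
  ig <- as_igraph(g)
  ebt <- igraph::edge_betweenness(ig, directed = FALSE)
  deg <- igraph::degree(ig)
  adj <- lapply(seq_len(n_atoms(g)), function(v)
    as.integer(igraph::neighbors(ig, v)))
  jac <- numeric(nrow(und)); aa <- numeric(nrow(und)); pa <- numeric(nrow(und))
  for (i in seq_len(nrow(und))) {
    u <- und[i, 1]; v <- und[i, 2]
    nu <- adj[[u]]; nv <- adj[[v]]
    common <- intersect(nu, nv)
    uni <- union(nu, nv)
    jac[i] <- if (length(uni)) length(common) / length(uni) else 0
    # a common neighbor of u and v always has degree >= 2, so log() > 0
    aa[i] <- if (length(common)) sum(1 / log(deg[common])) else 0
    pa[i] <- deg[u] * deg[v]
  }
  m <- cbind(edge_betweenness = ebt, jaccard = jac, adamic_adar = aa,
             pref_attachment = pa)
  if (directed_rows) m <- rbind(m, m)
  rownames(m) <- NULL
  m
}

#' Laplacian positional encodings (LPE)
#'
#' Unit-norm eigenvectors of the combinatorial Laplacian \code{L = D - A}
#' associated with the \code{k} smallest eigenvalues strictly above a
#' zero-tolerance (1e-8 relative to the largest eigenvalue), sorted ascending
#' by eigenvalue. Eigenvector sign is fixed deterministically by forcing the
#' largest-magnitude entry positive (ties broken by lowest index). Returns
#' the string \code{"insufficient"} when the graph has fewer than \code{k}
#' nonzero eigenpairs; such graphs are omitted by
#' \code{\link{filter_invalid}}.
#'
#' @param g an \code{atom_graph}.
#' @param k number of nonzero eigenvectors requested.
#' @param flip_signs if \code{TRUE}, apply a random sign flip per column
#'   (augmentation; default off).
#' @return N x k matrix with attribute \code{"eigenvalues"}, or
#'   \code{"insufficient"}.
#' @export
laplacian_pe <- function(g, k, flip_signs = FALSE) {
  stopifnot(k >= 1)
  n <- n_atoms(g)
  A <- matrix(0, n, n)
  und <- undirected_edges(g)
  if (nrow(und)) {
    A[und] <- 1
    A[und[, 2:1, drop = FALSE]] <- 1
  }
  L <- diag(rowSums(A), n) - A
  es <- eigen(L, symmetric = TRUE)
  lam <- rev(es$values)                 # ascending
  vec <- es$vectors[, rev(seq_len(n)), drop = FALSE]
  tol <- 1e-8 * max(abs(lam), 1)
  nz <- which(lam > tol)
  if (length(nz) < k) return("insufficient")
  sel <- nz[seq_len(k)]
  V <- vec[, sel, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))         # ties -> lowest index
    if (V[i, j] < 0) V[, j] <- -V[, j]
    if (flip_signs && stats::runif(1) < 0.5) V[, j] <- -V[, j]
  }
  attr(V, "eigenvalues") <- lam[sel]
  V
}

#' Compute the full encoding bundle of a graph
#'
#' @param g an \code{atom_graph}.
#' @param d_l LPE dimensionality (number of smallest nonzero Laplacian
#'   eigenvectors).
#' @return list with elements \code{C} (N x 15), \code{P} (N x 9), \code{G}
#'   (rows aligned with the stored directed edges, 4 columns), \code{L}
#'   (N x d_l or \code{"insufficient"}).
#' @export
encode_graph <- function(g, d_l = 2) {
  list(C = chemical_descriptors(g$atomic_numbers),
       P = node_topological_encodings(g),
       G = if (g$n_undirected > 0) edge_topological_encodings(g) else
         matrix(numeric(0), 0, 4),
       L = laplacian_pe(g, d_l))
}

# ---- standardization -------------------------------------------------------

#' Fit a per-column standardizer on a feature block
#'
#' Means and standard deviations are fitted on the designated (training)
#' split and applied unchanged elsewhere; constant columns are flagged and
#' map to zero.
#'
#' @param x numeric matrix (rows pooled over the fit split).
#' @return object of class \code{standardizer} with \code{mean}, \code{sd},
#'   \code{constant} (logical per column).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("cannot fit a standardizer on an empty split")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (nrow(x) == 1) sd <- rep(0, ncol(x))
  constant <- !is.finite(sd) | sd <= 0
  structure(list(mean = mu, sd = sd, constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param x numeric matrix.
#' @param stats a \code{standardizer} from \code{\link{fit_standardizer}}.
#' @return matrix of the same shape; constant columns are all zero.
#' @export
apply_standardizer <- function(x, stats) {
  x <- as.matrix(x)
  out <- sweep(x, 2, stats$mean, "-")
  sd <- ifelse(stats$constant, 1, stats$sd)
  out <- sweep(out, 2, sd, "/")
  out[, stats$constant] <- 0
  out
}

# ---- discard rule ----------------------------------------------------------

bundle_is_finite <- function(bundle) {
  ok_mat <- function(m) is.matrix(m) && all(is.finite(m))
  !identical(bundle$L, "insufficient") &&
    ok_mat(bundle$C) && ok_mat(bundle$P) && ok_mat(bundle$L) &&
    (nrow(bundle$G) == 0 || all(is.finite(bundle$G)))
}

#' Discard graphs with invalid encodings
#'
#' Retains exactly the graphs whose encoding bundles are fully finite and
#' whose LPE is not \code{"insufficient"} (fewer than \code{d_l} nontrivial
#' eigenvectors); each discard is logged with a reason code.
#'
#' @param graphs list of \code{atom_graph}.
#' @param d_l LPE dimensionality.
#' @param bundles optional precomputed list from \code{\link{encode_graph}}.
#' @return list with \code{graphs}, \code{bundles}, \code{kept} (indices into
#'   the input) and \code{discard_log} (data.frame id/reason).
#' @export
filter_invalid <- function(graphs, d_l = 2, bundles = NULL) {
  if (is.null(bundles)) bundles <- lapply(graphs, encode_graph, d_l = d_l)
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(graphs))
  for (i in seq_along(graphs)) {
    b <- bundles[[i]]
    if (identical(b$L, "insufficient")) {
      reasons <- c(reasons, "insufficient LPE"); ids <- c(ids, graphs[[i]]$graph_id)
    } else if (!all(is.finite(b$C))) {
      reasons <- c(reasons, "non-finite CE"); ids <- c(ids, graphs[[i]]$graph_id)
    } else if (!all(is.finite(b$P)) || (nrow(b$G) > 0 && !all(is.finite(b$G)))) {
      reasons <- c(reasons, "non-finite TE"); ids <- c(ids, graphs[[i]]$graph_id)
    } else if (!all(is.finite(b$L))) {
      reasons <- c(reasons, "non-finite LPE"); ids <- c(ids, graphs[[i]]$graph_id)
    } else keep[i] <- TRUE
  }
  list(graphs = graphs[keep], bundles = bundles[keep], kept = which(keep),
       discard_log = data.frame(id = ids, reason = reasons,
                                stringsAsFactors = FALSE))
}
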