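# Fusion embeddings: single bias-free linear maps from concatenated raw
# features + encodings to node/edge input subspaces, routed per scheme.

#' Channel routing for the four model schemes
#'
#' S1 = no attention / no encoders (raw X, raw E); S2 = encoders only;
#' S3 = attention only (nodes \code{[X || L]}, LPE-difference edges);
#' S4 = attention + encoders (G takes precedence on edges).
#'
#' @param scheme one of \code{"S1".."S4"}.
#' @return list with \code{node} and \code{edge} channel name vectors and the
#'   two switch flags.
#' @export
scheme_channels <- function(scheme) {
  scheme <- match.arg(scheme, c("S1", "S2", "S3", "S4"))
  switch(scheme,
    S1 = list(node = "X", edge = "E",
              global_attn_engine = FALSE, use_encodings = FALSE),
    S2 = list(node = c("X", "L", "P", "C"), edge = c("E", "G"),
              global_attn_engine = FALSE, use_encodings = TRUE),
    S3 = list(node = c("X", "L"), edge = c("E", "Ldiff"),
              global_attn_engine = TRUE, use_encodings = FALSE),
    S4 = list(node = c("X", "L", "P", "C"), edge = c("E", "G"),
              global_attn_engine = TRUE, use_encodings = TRUE))
}

concat_channels <- function(channels) {
  present <- Filter(Negate(is.null), channels)
  if (!length(present)) stop("no active channels to embed")
  do.call(cbind, present)
}

#' Node fusion embedding
#'
#' Concatenates the active node channels in the fixed order
#' \code{[X || L || P || C]} (absent channels omitted) and applies a single
#' bias-free linear projection \code{Z W}. Scheme S1 performs no learned
#' embedding and returns \code{X} unchanged.
#'
#' @param scheme \code{"S1".."S4"}.
#' @param W weight matrix \code{d_in x d_h}; ignored for S1.
#' @param X,L,P,C channel matrices (row-aligned; pass \code{NULL} for absent
#'   channels).
#' @return N x d_h matrix (or X for S1).
#' @export
node_embed <- function(scheme, W = NULL, X = NULL, L = NULL, P = NULL,
                       C = NULL) {
  if (scheme == "S1") return(X)
  active <- scheme_channels(scheme)$node
  chans <- list(X = X, L = L, P = P, C = C)[active]
  Z <- concat_channels(chans)
  stopifnot(nrow(W) == ncol(Z))
  Z %*% W
}

#' LPE-difference edge channel
#'
#' For each edge with endpoint indices \code{(i, j)}, the absolute row
#' difference \code{|L[i, ] - L[j, ]|}: a permutation-invariant spectral
#' displacement, symmetric in edge direction.
#'
#' @param L N x d_l LPE matrix.
#' @param edge_index matrix of edges (any orientation).
#' @return |edges| x d_l matrix.
#' @export
lpe_edge_diff <- function(L, edge_index) {
  abs(L[edge_index[, 1], , drop = FALSE] - L[edge_index[, 2], , drop = FALSE])
}

#' Edge fusion embedding
#'
#' Two modes: with encoders on (S2/S4) the edge input is \code{[E || G]};
#' with attention on but encoders off (S3) it is
#' \code{[E || |L_i - L_j|]}. Raw edge attributes \code{E} are omitted when
#' absent. A single bias-free projection maps to the edge embed width; the
#' result replaces the model's edge attributes. For S1 (or when the edge
#' embed width is 0 with encoders on), raw features pass through unchanged.
#'
#' @param scheme \code{"S1".."S4"}.
#' @param W weight matrix \code{d_in x d_e}; \code{NULL} passes raw features
#'   through (S1 / edge_embed_dim = 0).
#' @param E raw edge features or \code{NULL}.
#' @param G edge topological encodings or \code{NULL}.
#' @param L LPE matrix (needed for S3) or \code{NULL}.
#' @param edge_index edge rows aligned with \code{E}/\code{G}.
#' @return edge embedding matrix, or \code{E} unchanged.
#' @export
edge_embed <- function(scheme, W = NULL, E = NULL, G = NULL, L = NULL,
                       edge_index = NULL) {
  if (scheme == "S1") return(E)
  use_enc <- scheme_channels(scheme)$use_encodings
  if (use_enc) {
    if (is.null(W)) return(E)        # edge_embed_dim = 0: raw pass-through
    if (is.null(G) && is.null(E)) stop("no edge channels available to embed")
    Z <- concat_channels(list(E = E, G = G))
  } else {
    if (is.null(L)) stop("S3 edge embedding requires LPE")
    Ld <- lpe_edge_diff(L, edge_index)
    Z <- concat_channels(list(E = E, Ldiff = Ld))
  }
  stopifnot(nrow(W) == ncol(Z))
  Z %*% W
}

#' Embedding cost estimate
#'
#' The two dominant dense-multiplication costs plus the LPE-difference term
#' when applicable; used for logging only.
#'
#' @param n_nodes,n_edges graph sizes.
#' @param d_node_in,d_h node input/output widths.
#' @param d_edge_in,d_e edge input/output widths.
#' @param d_l LPE width of the difference channel (0 when unused).
#' @return list with \code{node}, \code{edge} and \code{lpe_diff} term
#'   estimates.
#' @export
embedding_flops <- function(n_nodes, n_edges, d_node_in, d_h,
                            d_edge_in = 0, d_e = 0, d_l = 0) {
  list(node = n_nodes * d_node_in * d_h,
       edge = n_edges * d_edge_in * d_e,
       lpe_diff = n_edges * d_l)
}
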