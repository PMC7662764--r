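#' Canonical 19-node tennis skeleton
#'
#' Node names and spatial edges of the reduced human-plus-racket skeleton:
#' an axial chain (head, neck, upper and lower spine, pelvis), two arms
#' (neck to shoulder to elbow to hand), two legs (pelvis to hip to knee to
#' foot) and the racket attached to the dominant (right) hand through the
#' handle and head nodes.  Exactly 19 nodes and 18 undirected edges.
#'
#' @return A list with components `nodes` (character vector of length 19 in
#'   canonical order) and `edges` (18 x 2 character matrix of undirected
#'   spatial edges).
#' @export
#' @examples
#' sk <- tennis_skeleton()
#' length(sk$nodes)  # 19
tennis_skeleton <- function() {
  nodes <- c("head", "neck", "spine_upper", "spine_lower", "pelvis",
             "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
             "hand_l", "hand_r", "hip_l", "hip_r", "knee_l", "knee_r",
             "foot_l", "foot_r", "racket_handle", "racket_head")
  edges <- rbind(
    c("head", "neck"),
    c("neck", "spine_upper"),
    c("spine_upper", "spine_lower"),
    c("spine_lower", "pelvis"),
    c("neck", "shoulder_l"), c("shoulder_l", "elbow_l"), c("elbow_l", "hand_l"),
    c("neck", "shoulder_r"), c("shoulder_r", "elbow_r"), c("elbow_r", "hand_r"),
    c("pelvis", "hip_l"), c("hip_l", "knee_l"), c("knee_l", "foot_l"),
    c("pelvis", "hip_r"), c("hip_r", "knee_r"), c("knee_r", "foot_r"),
    c("hand_r", "racket_handle"), c("racket_handle", "racket_head"))
  list(nodes = nodes, edges = edges)
}

#' Build a skeleton graph with cached normalized adjacency
#'
#' Constructs the spatial graph G = (V, E) of a skeleton together with its
#' binary adjacency matrix A, the identity self-link matrix I, the diagonal
#' degree matrix Lambda with entries Lambda_ii = sum_j (A_ij + I_ij), and the
#' symmetrically normalized adjacency Lambda^-1/2 (A + I) Lambda^-1/2 used by
#' the spatial graph convolution.
#'
#' @param nodes Character vector of unique node names, or a list with
#'   `nodes` and `edges` components such as [tennis_skeleton()] returns
#'   (in which case `edges` may be omitted).
#' @param edges Two-column matrix of undirected edges, as node names or
#'   1-based node indices.  Self-loops are not allowed; self-links enter
#'   through the identity matrix I.
#' @return An object of class `skeleton_graph`: a list with `nodes`,
#'   `edges` (integer index pairs), `A`, `I`, `Lambda` (degree vector) and
#'   `A_norm`.
#' @export
#' @examples
#' g <- skeleton_graph(tennis_skeleton())
#' sum(g$A != 0)  # 36 = 2 * 18 directed entries
skeleton_graph <- function(nodes, edges = NULL) {
  if (is.list(nodes) && !is.null(nodes$nodes)) {
    if (is.null(edges)) edges <- nodes$edges
    nodes <- nodes$nodes
  }
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop("duplicate node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  V <- length(nodes)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have two columns")
  if (is.character(edges)) {
    idx <- matrix(match(edges, nodes), ncol = 2L)
    if (anyNA(idx)) {
      bad <- unique(edges[is.na(idx)])
      stop("edge references unknown node(s): ", paste(bad, collapse = ", "))
    }
  } else {
    idx <- matrix(as.integer(edges), ncol = 2L)
    if (anyNA(idx) || any(idx < 1L) || any(idx > V))
      stop("edge index out of range 1..", V)
  }
  if (any(idx[, 1L] == idx[, 2L]))
    stop("self-loops are not allowed in the spatial edge set")
  A <- matrix(0, V, V, dimnames = list(nodes, nodes))
  A[idx] <- 1
  A[idx[, 2:1, drop = FALSE]] <- 1
  structure(list(
    nodes = nodes,
    edges = idx,
    A = A,
    I = diag(V),
    Lambda = rowSums(A) + 1,
    A_norm = normalize_adjacency(A)
  ), class = "skeleton_graph")
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes Lambda^-1/2 (A + I) Lambda^-1/2 where Lambda is the diagonal
#' matrix with Lambda_ii = sum_j (A_ij + I_ij).  Self-links through I
#' guarantee every degree is positive, so the normalization is always
#' defined; the result is symmetric with spectral radius at most 1.
#'
#' @param A Square, symmetric, nonnegative adjacency matrix (zero diagonal).
#' @return The normalized adjacency, same dimensions and dimnames as `A`.
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("'A' must be square")
  if (!isSymmetric(unname(A))) stop("'A' must be symmetric")
  if (any(A < 0)) stop("'A' must be nonnegative")
  d <- rowSums(A) + 1          # Lambda_ii = sum_j (A_ij + I_ij)
  s <- 1 / sqrt(d)
  AI <- A + diag(nrow(A))
  s * AI * rep(s, each = nrow(A))   # diag(s) %*% AI %*% diag(s)
}

#' Neighbor set of a node within path distance D
#'
#' Returns all nodes whose shortest-path distance to `node` is at most `D`,
#' including the node itself (distance 0).  D = 1 reproduces the sampling
#' neighborhood used by the spatial graph convolution.
#'
#' @param graph A `skeleton_graph`.
#' @param node Node name or 1-based index.
#' @param D Nonnegative integer maximum path length (default 1).
#' @return Sorted integer vector of node indices, named by node name.
#' @export
neighbor_set <- function(graph, node, D = 1L) {
  stopifnot(inherits(graph, "skeleton_graph"), D >= 0)
  if (is.character(node)) node <- match(node, graph$nodes)
  V <- length(graph$nodes)
  if (is.na(node) || node < 1L || node > V) stop("invalid node")
  # breadth-first search out to depth D
  dist <- rep(NA_integer_, V)
  dist[node] <- 0L
  frontier <- node
  depth <- 0L
  while (length(frontier) && depth < D) {
    depth <- depth + 1L
    nxt <- which(colSums(graph$A[frontier, , drop = FALSE] > 0) > 0)
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- depth
    frontier <- nxt
  }
  out <- sort(which(!is.na(dist)))
  names(out) <- graph$nodes[out]
  out
}

#' Spatial graph convolution of node features
#'
#' The graph convolution primitive: for node features `f` (one row per node)
#' and a weight matrix `W`, computes A_norm f W, i.e. degree-normalized
#' aggregation over each node's D = 1 neighborhood (including the self-link)
#' followed by a linear map of channels.  Equivalent to the per-node sum over
#' the neighbor set with weights A_norm[i, j] W.
#'
#' @param features Numeric V x C_in matrix of node features.
#' @param graph A `skeleton_graph` with V nodes.
#' @param W Numeric C_in x C_out weight matrix.
#' @return V x C_out matrix of output features.
#' @export
graph_conv <- function(features, graph, W) {
  stopifnot(inherits(graph, "skeleton_graph"))
  features <- as.matrix(features)
  W <- as.matrix(W)
  V <- length(graph$nodes)
  if (nrow(features) != V)
    stop("'features' must have one row per graph node (", V, ")")
  if (ncol(features) != nrow(W))
    stop("channel mismatch: features have ", ncol(features),
         " channels but W expects ", nrow(W))
  graph$A_norm %*% features %*% W
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("Skeleton graph:", length(x$nodes), "nodes,",
      nrow(x$edges), "undirected spatial edges\n")
  cat("Nodes:", paste(x$nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Write a graph as an edge-list text file
#'
#' One `nameA nameB` pair per line; the companion reader is
#' [read_edge_list()].
#'
#' @param graph A `skeleton_graph`.
#' @param path Output file path.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "skeleton_graph"))
  lines <- paste(graph$nodes[graph$edges[, 1L]], graph$nodes[graph$edges[, 2L]])
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph from an edge-list text file
#'
#' @param path File with one `nameA nameB` pair per line.
#' @param nodes Optional canonical node order; defaults to order of first
#'   appearance in the file.
#' @return A `skeleton_graph`.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(parts) != 2L)) stop("each line must contain two node names")
  edges <- do.call(rbind, parts)
  if (is.null(nodes)) nodes <- unique(as.vector(t(edges)))
  skeleton_graph(nodes, edges)
}
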