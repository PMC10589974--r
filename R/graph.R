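#' District adjacency graphs
#'
#' A `district_graph` stores the areal units of a study region (e.g. the 30
#' districts of Rwanda) and their adjacency structure. It is the basis for
#' the intrinsic CAR precision matrix used by [fit_star()] and the spatial
#' weight matrices used by [global_moran()].
#'
#' @param labels character vector of unique district identifiers.
#' @param edges two-column integer matrix of 1-based vertex index pairs
#'   (unordered; each pair stored once). May have zero rows.
#'
#' @return An object of class `district_graph` with elements `labels`,
#'   `edges` (canonicalised: `edges[,1] < edges[,2]`, sorted, deduplicated)
#'   and `n`.
#' @seealso [make_lattice()], [read_graph()], [car_precision()],
#'   [moran_weights()]
#' @export
district_graph <- function(labels, edges = matrix(integer(0), ncol = 2)) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate district labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  n <- length(labels)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) {
      stop("edge endpoint index out of range [1, ", n, "]")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(labels = labels, edges = edges, n = n),
            class = "district_graph")
}

#' @export
print.district_graph <- function(x, ...) {
  cat("district_graph:", x$n, "districts,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
format.district_graph <- function(x, ...) {
  paste0("district_graph(", x$n, " districts, ", nrow(x$edges), " edges)")
}

#' Test two district graphs for equality
#'
#' Graphs are equal when they have the same label set and the same set of
#' label pairs as edges; internal index order is irrelevant.
#'
#' @param g1,g2 `district_graph` objects.
#' @return logical scalar.
#' @export
graph_identical <- function(g1, g2) {
  if (!setequal(g1$labels, g2$labels)) return(FALSE)
  ep <- function(g) {
    if (nrow(g$edges) == 0) return(character(0))
    a <- g$labels[g$edges[, 1]]
    b <- g$labels[g$edges[, 2]]
    sort(paste(pmin(a, b), pmax(a, b)))
  }
  identical(ep(g1), ep(g2))
}

#' Vertex degrees
#' @param graph a `district_graph`.
#' @return integer vector of neighbour counts, named by label.
#' @export
graph_degrees <- function(graph) {
  d <- integer(graph$n)
  if (nrow(graph$edges) > 0) {
    t <- tabulate(c(graph$edges[, 1], graph$edges[, 2]), nbins = graph$n)
    d <- as.integer(t)
  }
  names(d) <- graph$labels
  d
}

# adjacency as a dense 0/1 matrix with label dimnames
adjacency_matrix <- function(graph) {
  A <- matrix(0, graph$n, graph$n, dimnames = list(graph$labels, graph$labels))
  if (nrow(graph$edges) > 0) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Rook-adjacency lattice graph
#'
#' Builds a regular grid of `rows` x `cols` districts where units sharing a
#' grid edge are neighbours. Used as a synthetic stand-in map for a set of
#' administrative districts (e.g. `make_lattice(5, 6)` for 30 units).
#'
#' @param rows,cols positive integers; `rows * cols >= 2`.
#' @return A `district_graph` with labels `"r{i}c{j}"`.
#' @export
make_lattice <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1 || length(cols) != 1 || is.na(rows) || is.na(cols) ||
      rows < 1 || cols < 1 || rows * cols < 2) {
    stop("make_lattice() needs positive rows, cols with rows*cols >= 2")
  }
  idx <- function(i, j) (i - 1L) * cols + j
  labels <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                              function(i, j) sprintf("r%dc%d", i, j))))
  e <- list()
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      if (j < cols) e[[length(e) + 1L]] <- c(idx(i, j), idx(i, j + 1L))
      if (i < rows) e[[length(e) + 1L]] <- c(idx(i, j), idx(i + 1L, j))
    }
  }
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(0), ncol = 2)
  district_graph(labels, edges)
}

#' Intrinsic CAR precision structure
#'
#' Returns the graph Laplacian `K = diag(degrees) - adjacency`, the precision
#' structure of the intrinsic (Besag) CAR prior for the spatially structured
#' district effect. `K` is symmetric positive semidefinite with row sums
#' zero; its rank is `n` minus the number of connected components. Isolated
#' districts contribute a zero row/column (their spatial effect is then
#' carried entirely by the unstructured term).
#'
#' @param graph a `district_graph` with at least 2 districts.
#' @return an `n x n` numeric matrix with label dimnames.
#' @export
car_precision <- function(graph) {
  if (graph$n < 2) stop("car_precision() needs at least 2 districts")
  A <- adjacency_matrix(graph)
  diag(rowSums(A)) - A
}

#' Spatial weight matrix for Moran statistics
#'
#' @param graph a `district_graph` with at least 2 districts.
#' @param style `"binary"` (raw adjacency) or `"row_standardized"` (each
#'   nonzero row divided by its degree). Isolated districts get an all-zero
#'   row in either style.
#' @return an `n x n` numeric matrix.
#' @export
moran_weights <- function(graph, style = c("row_standardized", "binary")) {
  style <- match.arg(style)
  if (graph$n < 2) stop("moran_weights() needs at least 2 districts")
  W <- adjacency_matrix(graph)
  if (style == "row_standardized") {
    d <- rowSums(W)
    nz <- d > 0
    W[nz, ] <- W[nz, , drop = FALSE] / d[nz]
  }
  W
}

#' Read a district adjacency graph
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`edge_list`}{whitespace-separated label pairs, one edge per line;
#'     a line with a single label declares an isolated district; `#` starts
#'     a comment. Labels are taken in order of first appearance.}
#'   \item{`gra`}{areal-model interchange layout: line 1 holds the district
#'     count `n`; then for each district three lines — its label, its
#'     neighbour count, and its neighbours as 0-based indices into the file
#'     order. Adjacency must be declared symmetrically.}
#' }
#'
#' @param path file path.
#' @param dialect `"edge_list"` or `"gra"`.
#' @return a `district_graph`.
#' @export
read_graph <- function(path, dialect = c("edge_list", "gra")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "edge_list") {
    lines <- sub("#.*$", "", lines)
    toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
    toks <- toks[vapply(toks, length, 1L) > 0]
    bad <- vapply(toks, length, 1L) > 2
    if (any(bad)) stop("edge_list format error: line with >2 tokens")
    labels <- unique(unlist(toks))
    edges <- do.call(rbind, lapply(toks, function(t) {
      if (length(t) == 2) match(t, labels) else NULL
    }))
    if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)
    if (nrow(edges) > 0 && any(edges[, 1] == edges[, 2])) {
      stop("edge_list format error: self-loop")
    }
    district_graph(labels, edges)
  } else {
    lines <- trimws(lines)
    if (length(lines) < 1) stop("gra format error: empty file")
    n <- suppressWarnings(as.integer(lines[1]))
    if (is.na(n) || n < 1) stop("gra format error: bad district count")
    if (length(lines) < 1 + 3 * n) stop("gra format error: truncated file")
    labels <- character(n)
    nbrs <- vector("list", n)
    for (k in seq_len(n)) {
      base <- 1L + (k - 1L) * 3L
      labels[k] <- lines[base + 1L]
      cnt <- suppressWarnings(as.integer(lines[base + 2L]))
      if (is.na(cnt) || cnt < 0) stop("gra format error: bad neighbour count")
      ids <- strsplit(lines[base + 3L], "\\s+")[[1]]
      ids <- ids[nzchar(ids)]
      if (length(ids) != cnt) {
        stop("gra format error: neighbour count mismatch for '", labels[k], "'")
      }
      v <- suppressWarnings(as.integer(ids))
      if (anyNA(v) || any(v < 0) || any(v >= n)) {
        stop("gra format error: neighbour index out of range for '",
             labels[k], "'")
      }
      nbrs[[k]] <- v + 1L
    }
    if (anyDuplicated(labels)) stop("gra format error: duplicate labels")
    # symmetry check
    for (k in seq_len(n)) {
      for (j in nbrs[[k]]) {
        if (!(k %in% nbrs[[j]])) {
          stop("gra format error: asymmetric adjacency ", labels[k], " ~ ",
               labels[j])
        }
      }
    }
    e <- list()
    for (k in seq_len(n)) {
      for (j in nbrs[[k]]) if (j > k) e[[length(e) + 1L]] <- c(k, j)
    }
    edges <- if (length(e)) do.call(rbind, e) else matrix(integer(0), ncol = 2)
    district_graph(labels, edges)
  }
}

#' Write a district adjacency graph
#'
#' Output is bit-stable: labels are emitted in sorted order and neighbour
#' lists sorted, so writing the same graph always produces the same file.
#'
#' @param graph a `district_graph`.
#' @param path file path.
#' @param dialect `"edge_list"` or `"gra"` (see [read_graph()]).
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, dialect = c("edge_list", "gra")) {
  dialect <- match.arg(dialect)
  ord <- order(graph$labels)
  labs <- graph$labels[ord]
  rank <- match(graph$labels, labs)  # old index -> new index
  edges <- graph$edges
  if (nrow(edges) > 0) {
    edges <- cbind(rank[edges[, 1]], rank[edges[, 2]])
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  if (dialect == "edge_list") {
    deg <- integer(length(labs))
    if (nrow(edges) > 0) {
      deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = length(labs))
    }
    out <- character(0)
    if (nrow(edges) > 0) {
      out <- paste(labs[edges[, 1]], labs[edges[, 2]])
    }
    out <- c(out, labs[deg == 0])  # isolated districts as singleton lines
    writeLines(out, path)
  } else {
    nbr <- vector("list", length(labs))
    for (k in seq_along(labs)) nbr[[k]] <- integer(0)
    if (nrow(edges) > 0) {
      for (r in seq_len(nrow(edges))) {
        i <- edges[r, 1]; j <- edges[r, 2]
        nbr[[i]] <- c(nbr[[i]], j)
        nbr[[j]] <- c(nbr[[j]], i)
      }
    }
    out <- as.character(length(labs))
    for (k in seq_along(labs)) {
      v <- sort(nbr[[k]]) - 1L  # 0-based on file
      out <- c(out, labs[k], as.character(length(v)),
               paste(v, collapse = " "))
    }
    writeLines(out, path)
  }
  invisible(path)
}
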