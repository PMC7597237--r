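# Williams-Beer redundancy lattices and Moebius inversion.
#
# Nodes are antichains of non-empty source subsets; alpha <= beta iff every
# collection in beta contains some collection of alpha.  Cumulative
# redundancy values on the lattice yield partial-information atoms by the
# recursive Moebius inverse: atom(n) = value(n) - sum of atoms strictly
# below n.

.subset_leq <- function(a, b) all(a %in% b)

.antichains <- function(n) {
  subsets <- list()
  for (k in 1:(2L^n - 1L))
    subsets <- c(subsets, list(which(bitwAnd(k, 2L^(0:(n - 1L))) > 0L)))
  out <- list()
  m <- length(subsets)
  for (mask in 1:(2L^m - 1L)) {
    sel <- subsets[which(bitwAnd(mask, 2L^(0:(m - 1L))) > 0L)]
    ok <- TRUE
    if (length(sel) > 1L)
      for (i in seq_along(sel)) for (j in seq_along(sel))
        if (i != j && .subset_leq(sel[[i]], sel[[j]])) { ok <- FALSE; break }
    if (ok) out <- c(out, list(sel))
  }
  out
}

.node_label <- function(node) {
  paste(vapply(node, function(s) paste0("{", paste(s, collapse = ""), "}"), ""),
        collapse = "")
}

#' Build the redundancy lattice for 2 or 3 sources
#'
#' @param n_sources 2 or 3.
#' @return A `pid_lattice`: `nodes` (list of antichains, each a list of
#'   integer vectors), `labels`, the order relation `leq` (matrix;
#'   `leq[i, j]` is `TRUE` iff node i lies below or at node j) and a
#'   bottom-up linear extension `order`.
#' @export
build_lattice <- function(n_sources) {
  if (!n_sources %in% c(2L, 3L))
    stop("only 2- and 3-source lattices are supported")
  nodes <- .antichains(as.integer(n_sources))
  nodes <- lapply(nodes, function(node)
    node[order(vapply(node, length, 1L),
               vapply(node, function(s) paste(s, collapse = ""), ""))])
  labels <- vapply(nodes, .node_label, "")
  k <- length(nodes)
  leq <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k))
    leq[i, j] <- all(vapply(nodes[[j]], function(b)
      any(vapply(nodes[[i]], function(a) .subset_leq(a, b), TRUE)), TRUE))
  ord <- order(colSums(leq)) # nodes with fewer elements below come first
  structure(list(n_sources = as.integer(n_sources), nodes = nodes,
                 labels = labels, leq = leq, order = ord),
            class = "pid_lattice")
}

#' @export
print.pid_lattice <- function(x, ...) {
  cat(sprintf("redundancy lattice, %d sources, %d nodes\n",
              x$n_sources, length(x$nodes)))
  cat(paste(x$labels[x$order], collapse = " < ... "), "\n")
  invisible(x)
}

#' Moebius inversion of cumulative lattice values
#'
#' @param lattice a [build_lattice()] result.
#' @param cumulative_values numeric vector of cumulative redundancy values,
#'   either in node order or named by node labels.
#' @return Named numeric vector of partial-information atoms, in node order.
#' @export
moebius_atoms <- function(lattice, cumulative_values) {
  stopifnot(inherits(lattice, "pid_lattice"))
  k <- length(lattice$nodes)
  if (!is.null(names(cumulative_values))) {
    if (!setequal(names(cumulative_values), lattice$labels))
      stop("named values must cover exactly the lattice node labels")
    cumulative_values <- cumulative_values[lattice$labels]
  }
  if (length(cumulative_values) != k)
    stop("need one cumulative value per lattice node")
  atoms <- numeric(k)
  for (i in lattice$order) {
    below <- which(lattice$leq[, i] & seq_len(k) != i)
    atoms[i] <- cumulative_values[i] - sum(atoms[below])
  }
  names(atoms) <- lattice$labels
  atoms
}

#' Cumulative redundancy values on a lattice
#'
#' Single-collection nodes take the self-redundancy value I(join; target);
#' multi-collection nodes take the path-based redundancy of their
#' collections.  The 3-source lattice is experimental plumbing: the numeric
#' decomposition validated against printed references is the 2-source one.
#'
#' @param pmf a [joint_pmf].
#' @param sources list of variable groups (length = lattice arity).
#' @param target variable group.
#' @param lattice optional [build_lattice()] result (built from the number of
#'   sources otherwise).
#' @param graph optional [infer_graph()] result.
#' @param strict passed to [enumerate_redundancy_paths()].
#' @return Named numeric vector of cumulative values, in node order.
#' @export
lattice_values <- function(pmf, sources, target, lattice = NULL, graph = NULL,
                           strict = FALSE) {
  sources <- .as_groups(sources)
  if (is.null(lattice)) lattice <- build_lattice(length(sources))
  if (is.null(graph)) graph <- infer_graph(pmf)
  target <- as.character(target)
  vals <- vapply(lattice$nodes, function(node) {
    colls <- lapply(node, function(idx) unique(unlist(sources[idx])))
    if (length(colls) == 1L)
      .group_mi(pmf, colls[[1L]], target)
    else
      path_redundancy(pmf, colls, target, graph = graph, strict = strict)
  }, numeric(1L))
  names(vals) <- lattice$labels
  vals
}
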