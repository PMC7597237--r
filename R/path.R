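# Paths through the system and path-based mutual information.
#
# A path {X1}{X2}...{Xl} is an ordered sequence of vertex groups.  Its tensor
# is the ordered product of the per-edge channel tensors, all estimated from
# the full joint pmf.  The distributions entering the path-based MI are the
# *path-propagated* ones -- the joint diag(p(source)) . T and the propagated
# target marginal p(source) . T -- not the empirical endpoint joint.  With a
# single edge the two coincide and the measure reduces to ordinary mutual
# information.

#' Construct a path of vertex groups
#'
#' @param ... vertex groups in order: character vectors (joins such as
#'   `c("X","Y")`) or single variable names.  Alternatively a single list of
#'   groups.  A group may repeat only in consecutive positions (the noiseless
#'   self-path used for self-redundancy).
#' @return A list of character vectors with class `info_path`.
#' @examples
#' info_path("X", "Y", "Z")          # {X}{Y}{Z}
#' info_path(c("X", "Y"), "Z")       # {XY}{Z}
#' @export
info_path <- function(...) {
  nodes <- list(...)
  if (length(nodes) == 1L && is.list(nodes[[1L]])) nodes <- nodes[[1L]]
  nodes <- lapply(nodes, as.character)
  if (length(nodes) < 2L) stop("a path needs at least two nodes")
  keys <- vapply(nodes, function(g) paste(sort(g), collapse = .SEP), "")
  for (i in seq_along(keys)) for (j in seq_along(keys))
    if (keys[i] == keys[j] && abs(i - j) > 1L)
      stop("a vertex group may repeat only in consecutive positions")
  structure(nodes, class = "info_path")
}

.as_path <- function(path) {
  if (inherits(path, "info_path")) return(path)
  if (is.character(path)) return(info_path(as.list(path)))
  if (is.list(path)) return(info_path(path))
  stop("cannot interpret `path`")
}

.path_label <- function(path) {
  paste0("{", vapply(path, paste, "", collapse = ""), "}", collapse = "")
}

#' @export
print.info_path <- function(x, ...) {
  cat("path", .path_label(x), "\n")
  invisible(x)
}

#' Reverse a path
#'
#' Traversing the reversed path uses the Bayes-reversed channel of every edge
#' automatically, since all channels are estimated from the same joint pmf.
#' @param path an [info_path()].
#' @return The reversed `info_path`.
#' @export
reverse_path <- function(path) {
  path <- .as_path(path)
  info_path(rev(unclass(path)))
}

.edge_channel <- function(pmf, g1, g2) {
  if (setequal(g1, g2)) delta_channel(pmf, g1) else
    channel_from_joint(pmf, g1, g2)
}

#' Tensor of a whole path
#'
#' The ordered matrix product of the per-edge channels; consecutive identical
#' groups contribute a Kronecker delta.
#'
#' @param pmf a [joint_pmf].
#' @param path an [info_path()], character vector of single variables, or
#'   list of groups.
#' @return A `dmc_channel` from the first to the last group of the path.
#' @export
path_tensor <- function(pmf, path) {
  path <- .as_path(path)
  for (g in path) .check_vars(pmf, g)
  out <- .edge_channel(pmf, path[[1L]], path[[2L]])
  for (i in seq_len(length(path) - 2L))
    out <- compose_channels(out, .edge_channel(pmf, path[[i + 1L]], path[[i + 2L]]))
  out
}

#' Path-propagated distributions of a path
#'
#' All distributions associated with a path: the source marginal p(x), the
#' path tensor p1(target|source), the propagated joint
#' p1(target, source) = p(x) p1(target|x) and the propagated target marginal
#' p1(target).  For a single-edge path these equal the empirical
#' distributions.
#'
#' @inheritParams path_tensor
#' @return A `path_dist` object with fields `source`, `target`, `p_source`,
#'   `tensor`, `joint` (rows = source states, columns = target states) and
#'   `target_marginal`.
#' @export
path_joint <- function(pmf, path) {
  path <- .as_path(path)
  tensor <- path_tensor(pmf, path)
  ps <- .group_marginal(pmf, path[[1L]])
  joint <- tensor$matrix * ps # row-wise scaling
  structure(list(source = path[[1L]], target = path[[length(path)]],
                 path = path, p_source = ps, tensor = tensor,
                 joint = joint, target_marginal = colSums(joint)),
            class = "path_dist")
}

#' @export
print.path_dist <- function(x, digits = 4L, ...) {
  cat("path distributions for", .path_label(x$path), "\n")
  cat("p(source):\n"); print(round(x$p_source, digits))
  cat("p1(target|source) [path tensor]:\n"); print(round(x$tensor$matrix, digits))
  cat("p1(target):\n"); print(round(x$target_marginal, digits))
  invisible(x)
}

#' @export
as.data.frame.path_dist <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(source = rep(rownames(x$joint), ncol(x$joint)),
             target = rep(colnames(x$joint), each = nrow(x$joint)),
             p = as.numeric(x$joint))
}

#' Path-based mutual information, in bits
#'
#' The mutual information carried by a path, evaluated on the
#' path-propagated joint and target marginal:
#' sum p1(x, t) log2( T\[x, t\] / p1(t) ).  Along a single edge this equals
#' the ordinary mutual information of the endpoints.
#'
#' @inheritParams path_tensor
#' @return Path-based mutual information in bits (non-negative up to
#'   rounding).
#' @export
path_mutual_information <- function(pmf, path) {
  pd <- path_joint(pmf, path)
  q <- pd$joint
  m <- pd$target_marginal
  pos <- which(q > 0, arr.ind = TRUE)
  sum(q[pos] * log2(pd$tensor$matrix[pos] / m[pos[, 2L]]))
}

#' Data-processing-inequality report for a path
#'
#' Computes the ordinary mutual information of every edge, the path-based
#' mutual information of the whole path, and checks the bound
#' path MI <= min(edge MIs).  A violation indicates an implementation bug,
#' never a property of the data.
#'
#' @inheritParams path_tensor
#' @param tol numerical slack for the bound check.
#' @return A list with `edges` (data.frame of per-edge MIs), `path_mi`,
#'   `bound` and logical `satisfied`.
#' @export
dpi_report <- function(pmf, path, tol = 1e-9) {
  path <- .as_path(path)
  n <- length(path)
  edge_mi <- vapply(seq_len(n - 1L), function(i) {
    g1 <- path[[i]]; g2 <- path[[i + 1L]]
    if (setequal(g1, g2)) .group_entropy(pmf, g1) else .group_mi(pmf, g1, g2)
  }, numeric(1L))
  pmi <- path_mutual_information(pmf, path)
  edges <- data.frame(
    from = vapply(path[-n], paste, "", collapse = ","),
    to = vapply(path[-1L], paste, "", collapse = ","),
    mi_bits = edge_mi)
  list(path = .path_label(path), edges = edges, path_mi = pmi,
       bound = min(edge_mi), satisfied = pmi <= min(edge_mi) + tol)
}
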