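# Association-graph inference.
#
# An edge is removed for one of two reasons: the channel transmits no
# information at all (identical rows -> "absent"), or the direct tensor is
# exactly reproduced by a length-2 cascade through a third vertex in both
# orientations ("indirect", with the witness path recorded).  Indirect edges
# keep their channels: by default they remain traversable for redundancy
# paths, because several systems (e.g. the triadic set) admit mutually
# exclusive prunings, and only absent edges make a path non-existent in the
# default reading of the redundancy definition.  Strict pruning, which also
# disqualifies indirect edges, is available and is what makes the
# Markov-chain consequence "no unique information from the distal source"
# exact.

.pair_key <- function(u, v) paste(sort(c(u, v)), collapse = "|")
.chan_key <- function(u, v) paste(u, v, sep = ">")

#' Infer the association graph of a discrete system
#'
#' @param pmf a [joint_pmf] over at least 2 variables.
#' @param tol tolerance for the null-channel and cascade-equality tests;
#'   widen it explicitly for empirical (sampled) pmfs.
#' @return A `system_graph`: vertices, an `edges` data.frame with columns
#'   `v1`, `v2`, `status` (`retained`, `absent`, `indirect`) and `witness`
#'   (first witness path label, `NA` otherwise), a `witnesses` list holding
#'   every witness path per indirect edge (mutually exclusive candidate
#'   prunings are all reported), and the per-orientation channels.
#' @export
infer_graph <- function(pmf, tol = 1e-9) {
  stopifnot(inherits(pmf, "joint_pmf"))
  vars <- pmf$variables
  if (length(vars) < 2L) stop("graph inference needs at least 2 variables")
  chans <- list()
  for (u in vars) for (v in setdiff(vars, u))
    chans[[.chan_key(u, v)]] <- channel_from_joint(pmf, u, v)
  pairs <- utils::combn(vars, 2L)
  edges <- data.frame(v1 = pairs[1L, ], v2 = pairs[2L, ],
                      status = "retained", witness = NA_character_,
                      stringsAsFactors = FALSE)
  witnesses <- list()
  for (r in seq_len(nrow(edges))) {
    u <- edges$v1[r]; v <- edges$v2[r]
    fwd <- chans[[.chan_key(u, v)]]
    bwd <- chans[[.chan_key(v, u)]]
    if (is_null_channel(fwd, tol) && is_null_channel(bwd, tol)) {
      edges$status[r] <- "absent"
      next
    }
    wit <- list()
    for (m in setdiff(vars, c(u, v))) {
      casc_f <- compose_channels(chans[[.chan_key(u, m)]], chans[[.chan_key(m, v)]])
      casc_b <- compose_channels(chans[[.chan_key(v, m)]], chans[[.chan_key(m, u)]])
      if (channels_equal(fwd, casc_f, tol) && channels_equal(bwd, casc_b, tol))
        wit <- c(wit, list(info_path(u, m, v)))
    }
    if (length(wit)) {
      edges$status[r] <- "indirect"
      edges$witness[r] <- .path_label(wit[[1L]])
      witnesses[[.pair_key(u, v)]] <- wit
    }
  }
  structure(list(pmf = pmf, vertices = vars, edges = edges,
                 witnesses = witnesses, channels = chans, tol = tol),
            class = "system_graph")
}

.edge_status <- function(graph, u, v) {
  e <- graph$edges
  hit <- (e$v1 == u & e$v2 == v) | (e$v1 == v & e$v2 == u)
  e$status[hit][1L]
}

# Can a redundancy path traverse the association g1 -> g2?  Singleton pairs
# are looked up in the graph; joint groups are tested directly for a null
# channel (a null group channel is an absent association).
.edge_traversable <- function(graph, g1, g2, strict = FALSE) {
  if (setequal(g1, g2)) return(TRUE) # delta edge
  if (length(g1) == 1L && length(g2) == 1L) {
    st <- .edge_status(graph, g1, g2)
    if (st == "absent") return(FALSE)
    if (strict && st == "indirect") return(FALSE)
    return(TRUE)
  }
  !is_null_channel(channel_from_joint(graph$pmf, g1, g2), graph$tol)
}

.perms <- function(items) {
  n <- length(items)
  if (n == 1L) return(list(items))
  out <- list()
  for (i in seq_len(n))
    for (rest in .perms(items[-i]))
      out <- c(out, list(c(items[i], rest)))
  out
}

.as_groups <- function(sources) {
  if (is.character(sources)) sources <- as.list(sources)
  lapply(sources, as.character)
}

#' Enumerate the admissible indirect paths feeding the redundancy measure
#'
#' Candidate paths are all permutations of the sources followed by the
#' target; a path is kept iff every consecutive association is traversable in
#' the graph.  By default only absent edges disqualify a path; with
#' `strict = TRUE` cascade-explained (indirect) edges do as well.
#'
#' @param graph a [infer_graph()] result.
#' @param sources list of variable groups (or character vector of single
#'   variables), at least one.
#' @param target variable group, disjoint from every source.
#' @param strict logical; see Description.
#' @return List of [info_path()] objects (possibly empty).
#' @export
enumerate_redundancy_paths <- function(graph, sources, target, strict = FALSE) {
  stopifnot(inherits(graph, "system_graph"))
  sources <- .as_groups(sources)
  if (!length(sources)) stop("`sources` must be non-empty")
  target <- as.character(target)
  for (s in sources)
    if (setequal(s, target))
      stop("the target may not be listed among the sources")
  out <- list()
  for (perm in .perms(seq_along(sources))) {
    nodes <- c(sources[perm], list(target))
    ok <- TRUE
    for (i in seq_len(length(nodes) - 1L))
      if (!.edge_traversable(graph, nodes[[i]], nodes[[i + 1L]], strict)) {
        ok <- FALSE; break
      }
    if (ok) out <- c(out, list(info_path(nodes)))
  }
  out
}

#' @export
print.system_graph <- function(x, ...) {
  cat(sprintf("system graph over %s\n", paste(x$vertices, collapse = ", ")))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Export a system graph as an edge-list data frame
#'
#' @param graph a `system_graph`.
#' @return data.frame with columns `vertex1`, `vertex2`, `status`, `witness`.
#' @export
graph_edge_list <- function(graph) {
  stopifnot(inherits(graph, "system_graph"))
  data.frame(vertex1 = graph$edges$v1, vertex2 = graph$edges$v2,
             status = graph$edges$status, witness = graph$edges$witness,
             stringsAsFactors = FALSE)
}

#' Write a system graph to TSV or JSON
#'
#' @param graph a `system_graph`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- graph_edge_list(graph)
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    jsonlite::write_json(
      list(vertices = graph$vertices, edges = df,
           witnesses = lapply(graph$witnesses, function(w)
             vapply(w, .path_label, ""))),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
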