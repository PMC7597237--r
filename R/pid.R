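# Path-based partial information decomposition.
#
# Redundancy is the minimum path-based MI over the admissible indirect paths
# that visit all sources and end at the target; with no admissible path the
# redundancy is zero (the only convention consistent with the printed
# independent-source decompositions).  Unique information follows from
# I(source; target) = U + R, and synergy is the additivity remainder, which
# makes the decomposition additive by construction and turns the interaction
# information identity S - R = I(X;Y|Z) - I(X;Y) into a genuine cross-check.

#' Path-based redundancy, in bits
#'
#' For a single source this is the self-redundancy I(source; target),
#' realized through the noiseless self-path {X}{X}{target}.  For several
#' sources it is the minimum path-based mutual information over the
#' admissible permutation paths; an empty admissible set yields 0.
#'
#' @param pmf a [joint_pmf].
#' @param sources list of variable groups, or character vector of single
#'   variables.
#' @param target variable group, disjoint from every source.
#' @param graph optional precomputed [infer_graph()] result.
#' @param strict if `TRUE`, cascade-explained (indirect) edges also
#'   disqualify paths; see [enumerate_redundancy_paths()].
#' @param tol tolerance used when the graph has to be inferred.
#' @return Redundancy in bits.
#' @export
path_redundancy <- function(pmf, sources, target, graph = NULL,
                            strict = FALSE, tol = 1e-9) {
  stopifnot(inherits(pmf, "joint_pmf"))
  sources <- .as_groups(sources)
  target <- as.character(target)
  for (s in sources)
    if (setequal(s, target))
      stop("the target may not be listed among the sources")
  if (length(sources) == 1L) {
    p <- info_path(sources[[1L]], sources[[1L]], target)
    return(path_mutual_information(pmf, p))
  }
  if (is.null(graph)) graph <- infer_graph(pmf, tol)
  paths <- enumerate_redundancy_paths(graph, sources, target, strict = strict)
  if (!length(paths)) return(0)
  min(vapply(paths, function(p) path_mutual_information(pmf, p), numeric(1L)))
}

#' Path-based unique information, in bits
#'
#' U(source; target) = I(source; target) - R(all sources; target).  A
#' negative value beyond tolerance signals inconsistent inputs (hidden
#' variables, over-determination) and raises an error rather than being
#' silently clipped; values within tolerance are clipped to zero.
#'
#' @param pmf a [joint_pmf].
#' @param source one variable group.
#' @param other_sources list of the remaining source groups.
#' @param target variable group.
#' @inheritParams path_redundancy
#' @return Unique information in bits (non-negative).
#' @export
unique_information <- function(pmf, source, other_sources, target,
                               graph = NULL, strict = FALSE, tol = 1e-9) {
  source <- as.character(source)
  others <- .as_groups(other_sources)
  R <- path_redundancy(pmf, c(list(source), others), target,
                       graph = graph, strict = strict, tol = tol)
  U <- .group_mi(pmf, source, as.character(target)) - R
  if (U < -1e-9)
    stop(sprintf(paste0("negative unique information (%.6g bits) for {%s}: ",
                        "redundancy exceeds the source-target information, ",
                        "which signals inconsistent inputs"),
                 U, paste(source, collapse = "")))
  max(U, 0)
}

#' Path-based synergy for two sources, in bits
#'
#' The additivity remainder
#' S = I(sources-join; target) - U1 - U2 - R.  May be negative; a negative
#' synergy is a diagnostic signal (unobserved common causes or
#' over-determined systems), not an error.
#'
#' @param pmf a [joint_pmf].
#' @param sources list of exactly two variable groups.
#' @inheritParams path_redundancy
#' @return Synergy in signed bits.
#' @export
synergy <- function(pmf, sources, target, graph = NULL, strict = FALSE,
                    tol = 1e-9) {
  sources <- .as_groups(sources)
  if (length(sources) != 2L)
    stop("the numeric decomposition is defined for exactly two sources")
  target <- as.character(target)
  if (is.null(graph)) graph <- infer_graph(pmf, tol)
  R <- path_redundancy(pmf, sources, target, graph = graph, strict = strict)
  U1 <- .group_mi(pmf, sources[[1L]], target) - R
  U2 <- .group_mi(pmf, sources[[2L]], target) - R
  join <- unique(unlist(sources))
  .group_mi(pmf, join, target) - U1 - U2 - R
}

#' Full two-source path-based partial information decomposition
#'
#' Orchestrates graph inference, admissible-path enumeration, redundancy,
#' unique and synergistic atoms, and the two-source lattice with cumulative
#' values and Moebius atoms.
#'
#' @param pmf a [joint_pmf].
#' @param sources list of exactly two variable groups (or character vector of
#'   two variable names).
#' @param target variable group, disjoint from the sources.
#' @param tol tolerance for graph inference and diagnostics.
#' @param strict passed to [enumerate_redundancy_paths()].
#' @return A `pid_result` with fields `sources`, `target`, `R`, `U` (named),
#'   `S`, `total`, `paths_used` (admissible paths with their MIs), `graph`,
#'   `lattice`, `cumulative`, `atoms` and `negative_synergy`.
#' @examples
#' xor <- named_distribution("xor")
#' decompose(xor, c("X", "Y"), "Z")
#' @export
decompose <- function(pmf, sources, target, tol = 1e-9, strict = FALSE) {
  stopifnot(inherits(pmf, "joint_pmf"))
  sources <- .as_groups(sources)
  if (length(sources) != 2L)
    stop("the numeric decomposition is defined for exactly two sources")
  target <- as.character(target)
  .check_vars(pmf, target, "`target`")
  for (s in sources) {
    .check_vars(pmf, s, "source")
    if (setequal(s, target))
      stop("the target may not be listed among the sources")
  }
  graph <- infer_graph(pmf, tol)
  paths <- enumerate_redundancy_paths(graph, sources, target, strict = strict)
  pmis <- vapply(paths, function(p) path_mutual_information(pmf, p),
                 numeric(1L))
  R <- if (length(pmis)) min(pmis) else 0
  I1 <- .group_mi(pmf, sources[[1L]], target)
  I2 <- .group_mi(pmf, sources[[2L]], target)
  U <- c(I1, I2) - R
  slab <- vapply(sources, paste, "", collapse = "")
  if (any(U < -1e-9))
    stop(sprintf(paste0("negative unique information for {%s}: redundancy ",
                        "exceeds the source-target information"),
                 paste(slab[U < -1e-9], collapse = ", ")))
  U <- pmax(U, 0)
  names(U) <- slab
  total <- .group_mi(pmf, unique(unlist(sources)), target)
  S <- total - sum(U) - R
  lat <- build_lattice(2L)
  cumulative <- c("{1}{2}" = R, "{1}" = I1, "{2}" = I2, "{12}" = total)
  atoms <- moebius_atoms(lat, cumulative)
  structure(list(sources = sources, target = target, R = R, U = U, S = S,
                 total = total,
                 paths_used = data.frame(
                   path = vapply(paths, .path_label, ""),
                   path_mi = pmis),
                 graph = graph, lattice = lat, cumulative = cumulative,
                 atoms = atoms, negative_synergy = S < -tol,
                 strict = strict),
            class = "pid_result")
}

#' @export
print.pid_result <- function(x, digits = 4L, ...) {
  cat(sprintf("path-based PID: sources {%s}, {%s}; target {%s}\n",
              paste(x$sources[[1L]], collapse = ""),
              paste(x$sources[[2L]], collapse = ""),
              paste(x$target, collapse = "")))
  tab <- pid_table(x)
  tab$atom_bits <- round(tab$atom_bits, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("total I(sources;target) = %.4f bits\n", x$total))
  if (nrow(x$paths_used))
    cat("admissible paths:",
        paste(sprintf("%s (%.4f)", x$paths_used$path, x$paths_used$path_mi),
              collapse = ", "), "\n")
  else cat("admissible path set empty; redundancy set to 0\n")
  if (x$negative_synergy)
    cat("NOTE: negative synergy -- diagnostic signal of an unobserved",
        "common cause or an over-determined system\n")
  invisible(x)
}

#' Lattice/atom table of a decomposition
#'
#' Four rows mirroring the standard presentation: `{12}`, `{2}`, `{1}`,
#' `{1}{2}`.
#'
#' @param result a `pid_result`.
#' @return data.frame with columns `lattice_node` and `atom_bits`.
#' @export
pid_table <- function(result) {
  stopifnot(inherits(result, "pid_result"))
  ord <- c("{12}", "{2}", "{1}", "{1}{2}")
  data.frame(lattice_node = ord,
             atom_bits = as.numeric(result$atoms[ord]),
             stringsAsFactors = FALSE)
}

#' Write a decomposition as TSV or JSON
#'
#' @param result a `pid_result`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- pid_table(result)
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(sources = lapply(result$sources, as.list),
           target = as.list(result$target),
           atoms = as.list(result$atoms),
           redundancy = result$R, unique = as.list(result$U),
           synergy = result$S, total = result$total,
           negative_synergy = result$negative_synergy,
           paths = result$paths_used),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Williams-Beer Imin redundancy, in bits
#'
#' The expected minimum source-specific information per target state:
#' Imin = sum_t p(t) min_k sum_a p(a|t) log2( p(t|a) / p(t) ).
#'
#' @param pmf a [joint_pmf].
#' @param sources list of variable groups (at least one).
#' @param target variable group.
#' @return Imin in bits (non-negative); equals I(source; target) for a single
#'   source.
#' @export
imin <- function(pmf, sources, target) {
  stopifnot(inherits(pmf, "joint_pmf"))
  sources <- .as_groups(sources)
  if (!length(sources)) stop("`sources` must be non-empty")
  target <- as.character(target)
  pt <- .group_marginal(pmf, target)
  spec <- vapply(sources, function(s) {
    M <- .joint_matrix(pmf, target, s) # rows t, cols a
    pa <- colSums(M)
    out <- numeric(length(pt))
    for (t in seq_along(pt)) {
      if (pt[t] <= 0) next
      j <- which(M[t, ] > 0)
      out[t] <- sum((M[t, j] / pt[t]) * log2((M[t, j] / pa[j]) / pt[t]))
    }
    out
  }, numeric(length(pt)))
  spec <- matrix(spec, nrow = length(pt))
  sum(pt * apply(spec, 1L, min))
}

#' Unique-information divergence diagnostic for a three-variable system
#'
#' Returns the two divergence sums whose maximum the direct tensor-form
#' expression for unique information comprises: the divergence between the
#' direct channel source -> target and the indirect path through the third
#' variable, and the divergence between the direct channel and the cascade
#' entered at the third variable.  The first vanishes when the
#' source-target association is indirect; the second vanishes when the
#' source is a noiseless copy of the third variable.  This is a diagnostic,
#' not the primary unique-information estimate.
#'
#' @param pmf a [joint_pmf] over exactly three variables.
#' @param source the source variable (the "Y" of U(Y;Z)).
#' @param target the target variable.
#' @return Named numeric vector `c(indirect_path, copy)` in bits.
#' @export
unique_eq25_diagnostic <- function(pmf, source, target) {
  stopifnot(inherits(pmf, "joint_pmf"))
  if (length(pmf$variables) != 3L)
    stop("the diagnostic is defined for three-variable systems")
  source <- as.character(source); target <- as.character(target)
  .check_vars(pmf, source); .check_vars(pmf, target)
  other <- setdiff(pmf$variables, c(source, target))
  if (length(other) != 1L) stop("source and target must be distinct variables")
  B <- channel_from_joint(pmf, source, target)$matrix
  indirect <- path_tensor(pmf, info_path(source, other, target))$matrix
  cascade <- path_tensor(pmf, info_path(other, source, target))$matrix
  df <- as.data.frame(pmf)
  iy <- match(df[[source]], rownames(B))
  iz <- match(df[[target]], colnames(B))
  ix <- match(df[[other]], rownames(cascade))
  pos <- df$p > 0
  s1 <- sum(df$p[pos] * log2(B[cbind(iy, iz)][pos] /
                             indirect[cbind(iy, iz)][pos]))
  s2 <- sum(df$p[pos] * log2(B[cbind(iy, iz)][pos] /
                             cascade[cbind(ix, iz)][pos]))
  c(indirect_path = s1, copy = s2)
}

#' Verify the redundancy axioms on a concrete system
#'
#' Checks, with the two compared numbers reported per axiom: symmetry,
#' self-redundancy of both sources, monotonicity, the redundancy bound
#' R <= min(I(X;Y), I(X;Z), I(Y;Z)), the identity property
#' R(X,Y;XY) = I(X;Y), the three-variable redundancy inequality
#' R(X,Y;Z) >= min(R(Z,Y;X), R(Z,X;Y)) (singleton systems only, and only
#' when every admissible path set is non-empty, the regime in which it is
#' claimed), and left monotonicity when the target has two variables.
#'
#' @param pmf a [joint_pmf].
#' @param sources list of two variable groups.
#' @param target variable group.
#' @param tol numerical slack.
#' @param strict passed through to the redundancy computations.
#' @return data.frame with columns `axiom`, `lhs`, `rhs`, `holds`.
#' @export
verify_axioms <- function(pmf, sources, target, tol = 1e-9, strict = FALSE) {
  sources <- .as_groups(sources)
  stopifnot(length(sources) == 2L)
  target <- as.character(target)
  graph <- infer_graph(pmf, tol)
  Rf <- function(srcs, tgt) path_redundancy(pmf, srcs, tgt, graph = graph,
                                            strict = strict)
  rows <- list()
  add <- function(axiom, lhs, rhs, holds)
    rows[[length(rows) + 1L]] <<- data.frame(axiom = axiom, lhs = lhs,
                                             rhs = rhs, holds = holds)
  R12 <- Rf(sources, target)
  add("symmetry", R12, Rf(rev(sources), target),
      abs(R12 - Rf(rev(sources), target)) <= tol)
  for (i in 1:2) {
    Ri <- Rf(sources[i], target)
    Ii <- .group_mi(pmf, sources[[i]], target)
    add(sprintf("self-redundancy source %d", i), Ri, Ii, abs(Ri - Ii) <= tol)
  }
  mono_rhs <- min(Rf(sources[1L], target), Rf(sources[2L], target))
  add("monotonicity", R12, mono_rhs, R12 <= mono_rhs + tol)
  bound <- min(.group_mi(pmf, sources[[1L]], sources[[2L]]),
               .group_mi(pmf, sources[[1L]], target),
               .group_mi(pmf, sources[[2L]], target))
  add("redundancy bound", R12, bound, R12 <= bound + tol)
  join <- unique(unlist(sources))
  if (!length(intersect(join, target))) {
    Rid <- path_redundancy(pmf, sources, join, graph = graph, strict = strict)
    Iid <- .group_mi(pmf, sources[[1L]], sources[[2L]])
    add("identity", Rid, Iid, abs(Rid - Iid) <= tol)
  }
  if (all(lengths(sources) == 1L) && length(target) == 1L) {
    sets <- list(list(sources, target),
                 list(list(target, sources[[2L]]), sources[[1L]]),
                 list(list(target, sources[[1L]]), sources[[2L]]))
    nonempty <- vapply(sets, function(s)
      length(enumerate_redundancy_paths(graph, s[[1L]], s[[2L]],
                                        strict = strict)) > 0, TRUE)
    if (all(nonempty)) {
      rhs <- min(Rf(sets[[2L]][[1L]], sets[[2L]][[2L]]),
                 Rf(sets[[3L]][[1L]], sets[[3L]][[2L]]))
      add("redundancy inequality", R12, rhs, R12 >= rhs - tol)
    }
  }
  if (length(target) >= 2L) {
    R1 <- Rf(sources, target[1L])
    add("left monotonicity", R12, R1, R12 >= R1 - tol)
  }
  do.call(rbind, rows)
}
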