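# Joint probability mass functions over named discrete variables.
#
# A `joint_pmf` is the single source of truth for every measure in the
# package.  It stores the full state table -- including zero-probability
# states, so that channel row indexing is stable -- in canonical
# lexicographic order (first declared variable varies slowest).

.SEP <- "\x1f" # internal state-key separator; symbols must not contain it

#' Construct a joint probability mass function
#'
#' @param states data.frame of symbols, one column per variable, one row per
#'   state.  Columns are coerced to character.
#' @param p numeric vector of probabilities, one per row of `states`.
#' @param alphabets optional named list giving the ordered symbol alphabet of
#'   each variable; defaults to first-appearance order in `states`.  States
#'   not listed in `states` receive probability zero.
#' @param tol tolerance on the total probability (default `1e-9`).
#' @param aggregate if `TRUE`, duplicate state rows are summed instead of
#'   rejected.
#'
#' @return An object of class `joint_pmf` with fields `variables`,
#'   `alphabets`, `states` (full canonical state table) and `p`.
#' @examples
#' xor <- joint_pmf(data.frame(X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1),
#'                             Z = c(0, 1, 1, 0)), rep(1 / 4, 4))
#' entropy(xor)
#' @export
joint_pmf <- function(states, p, alphabets = NULL, tol = 1e-9,
                      aggregate = FALSE) {
  if (!is.data.frame(states) || ncol(states) < 1L)
    stop("`states` must be a data.frame with at least one variable column")
  vars <- names(states)
  if (anyDuplicated(vars)) stop("duplicate variable names")
  states[] <- lapply(states, as.character)
  p <- as.numeric(p)
  if (length(p) != nrow(states))
    stop("`p` must have one entry per state row")
  if (any(!is.finite(p)) || any(p < -1e-12))
    stop("probabilities must be finite and non-negative")
  p[p < 0] <- 0
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probabilities sum to %.12g, not 1 (deficit %.3g)",
                 sum(p), 1 - sum(p)))
  if (is.null(alphabets)) {
    alphabets <- lapply(states, function(col) unique(col))
  } else {
    if (!setequal(names(alphabets), vars))
      stop("`alphabets` must be named by the variables")
    alphabets <- lapply(alphabets[vars], as.character)
  }
  for (v in vars) {
    if (grepl(.SEP, paste(alphabets[[v]], collapse = ""), fixed = TRUE))
      stop("symbols may not contain the reserved separator byte 0x1f")
    bad <- setdiff(states[[v]], alphabets[[v]])
    if (length(bad))
      stop(sprintf("symbol(s) %s of %s missing from declared alphabet",
                   paste(bad, collapse = ", "), v))
  }
  key <- do.call(paste, c(states, sep = .SEP))
  if (anyDuplicated(key)) {
    if (!aggregate) stop("duplicate state rows (use aggregate = TRUE to sum)")
    p <- as.numeric(tapply(p, key, sum)[unique(key)])
    key <- unique(key)
  }
  full <- .group_states(alphabets, vars)
  fp <- numeric(nrow(full))
  idx <- match(key, do.call(paste, c(full, sep = .SEP)))
  stopifnot(!anyNA(idx))
  fp[idx] <- p
  fp <- fp / sum(fp)
  structure(list(variables = vars, alphabets = alphabets,
                 states = full, p = fp),
            class = "joint_pmf")
}

# Full state table for a variable group, lexicographic with the first listed
# variable varying slowest.
.group_states <- function(alphabets, group) {
  stopifnot(length(group) >= 1L)
  g <- do.call(expand.grid,
               c(rev(alphabets[group]), KEEP.OUT.ATTRS = FALSE,
                 stringsAsFactors = FALSE))
  g <- g[, rev(seq_along(group)), drop = FALSE]
  names(g) <- group
  rownames(g) <- NULL
  g
}

.check_vars <- function(pmf, group, what = "variable group") {
  if (length(group) == 0L) stop(what, " must be non-empty")
  bad <- setdiff(group, pmf$variables)
  if (length(bad))
    stop(sprintf("unknown variable(s): %s", paste(bad, collapse = ", ")))
  if (anyDuplicated(group)) stop(what, " contains duplicated variables")
  invisible(group)
}

.state_labels <- function(df) do.call(paste, c(df, sep = ","))

# Joint probability matrix p(a, b) for two variable groups (may overlap):
# rows indexed by the product states of `ga`, columns by those of `gb`.
# Inconsistent overlapping combinations have probability zero.
.joint_matrix <- function(pmf, ga, gb) {
  ra <- .group_states(pmf$alphabets, ga)
  rb <- .group_states(pmf$alphabets, gb)
  ka <- do.call(paste, c(pmf$states[ga], sep = .SEP))
  kb <- do.call(paste, c(pmf$states[gb], sep = .SEP))
  i <- match(ka, do.call(paste, c(ra, sep = .SEP)))
  j <- match(kb, do.call(paste, c(rb, sep = .SEP)))
  M <- matrix(0, nrow(ra), nrow(rb),
              dimnames = list(.state_labels(ra), .state_labels(rb)))
  lin <- (j - 1L) * nrow(ra) + i
  agg <- tapply(pmf$p, lin, sum)
  M[as.integer(names(agg))] <- agg
  M
}

.group_marginal <- function(pmf, group) {
  k <- do.call(paste, c(pmf$states[group], sep = .SEP))
  full <- .group_states(pmf$alphabets, group)
  idx <- match(k, do.call(paste, c(full, sep = .SEP)))
  p <- numeric(nrow(full))
  agg <- tapply(pmf$p, idx, sum)
  p[as.integer(names(agg))] <- agg
  names(p) <- .state_labels(full)
  p
}

.H <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

.group_entropy <- function(pmf, group) .H(.group_marginal(pmf, group))

# Mutual information between two groups, no disjointness check (internal use:
# join targets, self paths).  I(A;B) = H(A) + H(B) - H(A u B).
.group_mi <- function(pmf, ga, gb) {
  M <- .joint_matrix(pmf, ga, gb)
  pa <- rowSums(M)
  pb <- colSums(M)
  pos <- which(M > 0, arr.ind = TRUE)
  sum(M[pos] * log2(M[pos] / (pa[pos[, 1]] * pb[pos[, 2]])))
}

#' Marginalize a joint pmf onto a subset of its variables
#'
#' @param pmf a [joint_pmf].
#' @param keep character vector of variable names to keep (order respected).
#' @return A [joint_pmf] over `keep`.
#' @export
marginalize <- function(pmf, keep) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .check_vars(pmf, keep, "`keep`")
  p <- .group_marginal(pmf, keep)
  joint_pmf(.group_states(pmf$alphabets, keep), as.numeric(p),
            alphabets = pmf$alphabets[keep])
}

#' Shannon entropy of a joint pmf, in bits
#'
#' Uses log base 2 with the convention 0 log 0 = 0.
#' @param pmf a [joint_pmf].
#' @return Entropy in bits.
#' @export
entropy <- function(pmf) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .H(pmf$p)
}

#' Mutual information between two variable groups, in bits
#'
#' I(A;B) = sum p(a,b) log2 p(a,b) / (p(a) p(b)), the group-wise form of the
#' classical bivariate measure; joins are represented by product alphabets in
#' lexicographic order.
#'
#' @param pmf a [joint_pmf].
#' @param groupA,groupB disjoint character vectors of variable names.
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(pmf, groupA, groupB) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .check_vars(pmf, groupA, "`groupA`")
  .check_vars(pmf, groupB, "`groupB`")
  if (length(intersect(groupA, groupB)))
    stop("`groupA` and `groupB` must be disjoint")
  .group_mi(pmf, groupA, groupB)
}

#' Conditional mutual information I(A;B|C), in bits
#'
#' Computed through the entropy identity
#' I(A;B|C) = H(A,C) + H(B,C) - H(A,B,C) - H(C), which keeps the chain rule
#' I(A,B;C) = I(A;C) + I(B;C|A) exact to floating point.
#'
#' @param pmf a [joint_pmf].
#' @param groupA,groupB,cond pairwise-disjoint character vectors of variables.
#' @return Conditional mutual information in bits.
#' @export
conditional_mutual_information <- function(pmf, groupA, groupB, cond) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .check_vars(pmf, groupA, "`groupA`")
  .check_vars(pmf, groupB, "`groupB`")
  .check_vars(pmf, cond, "`cond`")
  gs <- list(groupA, groupB, cond)
  for (i in 1:2) for (j in (i + 1):3)
    if (length(intersect(gs[[i]], gs[[j]])))
      stop("variable groups must be pairwise disjoint")
  .group_entropy(pmf, c(groupA, cond)) + .group_entropy(pmf, c(groupB, cond)) -
    .group_entropy(pmf, c(groupA, groupB, cond)) - .group_entropy(pmf, cond)
}

#' Interaction information I(X;Y|Z) - I(X;Y), in signed bits
#'
#' Negative values indicate redundancy-dominated systems; under the partial
#' information decomposition this quantity equals synergy minus redundancy.
#'
#' @param pmf a [joint_pmf].
#' @param X,Y,Z pairwise-disjoint variable groups.
#' @return Signed interaction information in bits.
#' @export
interaction_information <- function(pmf, X, Y, Z) {
  conditional_mutual_information(pmf, X, Y, Z) - mutual_information(pmf, X, Y)
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("joint pmf over %s (%d states, %d with positive probability)\n",
              paste(x$variables, collapse = ", "),
              length(x$p), sum(x$p > 0)))
  df <- cbind(x$states, p = x$p)
  print(utils::head(df[df$p > 0, ], 20L), row.names = FALSE)
  if (sum(x$p > 0) > 20L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.joint_pmf <- function(x, row.names = NULL, optional = FALSE,
                                    drop_zero = FALSE, ...) {
  df <- cbind(x$states, p = x$p)
  if (drop_zero) df <- df[df$p > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}
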