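# Discrete memoryless channel tensors.
#
# A channel is the row-stochastic conditional-probability matrix of one
# oriented association between two (possibly joint, possibly overlapping)
# variable groups.  Rows with zero source probability are undefined; they are
# set to the uniform row and flagged, and flagged rows are excluded from the
# null-channel and equality comparisons so that unreachable states can never
# drive edge pruning.

.new_channel <- function(matrix, source, dest, flagged) {
  structure(list(source = source, dest = dest, matrix = matrix,
                 flagged = flagged),
            class = "dmc_channel")
}

#' Estimate the channel tensor of an oriented association
#'
#' Returns the row-stochastic matrix with entries p(dest-state | src-state)
#' computed from the joint pmf.  `src` and `dst` may overlap (needed for
#' joint-endpoint paths such as a join target) but may not be the same set;
#' the noiseless self-channel is the Kronecker delta, see [delta_channel()].
#'
#' @param pmf a [joint_pmf].
#' @param src,dst variable groups (character vectors).
#' @return A `dmc_channel`: fields `source`, `dest`, `matrix` (rows = source
#'   states, columns = destination states) and `flagged` (zero-mass rows).
#' @export
channel_from_joint <- function(pmf, src, dst) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .check_vars(pmf, src, "`src`")
  .check_vars(pmf, dst, "`dst`")
  if (setequal(src, dst))
    stop("`src` and `dst` are the same group; use delta_channel() for the ",
         "noiseless self-channel")
  M <- .joint_matrix(pmf, src, dst)
  px <- rowSums(M)
  flagged <- px <= 0
  out <- M
  out[!flagged, ] <- M[!flagged, , drop = FALSE] / px[!flagged]
  if (any(flagged)) out[flagged, ] <- 1 / ncol(M)
  .new_channel(out, src, dst, flagged)
}

#' Kronecker-delta (noiseless copy) channel of a variable group
#'
#' @param pmf a [joint_pmf].
#' @param group variable group to copy.
#' @return A `dmc_channel` whose matrix is the identity.
#' @export
delta_channel <- function(pmf, group) {
  stopifnot(inherits(pmf, "joint_pmf"))
  .check_vars(pmf, group)
  lab <- .state_labels(.group_states(pmf$alphabets, group))
  M <- diag(length(lab))
  dimnames(M) <- list(lab, lab)
  .new_channel(M, group, group, flagged = rep(FALSE, length(lab)))
}

#' Bayes reversal of an association
#'
#' The channel with entries p(src-state | dst-state); propagating the
#' destination marginal through it reconstructs the source marginal.
#'
#' @inheritParams channel_from_joint
#' @return A `dmc_channel` from `dst` to `src`.
#' @export
reverse_channel <- function(pmf, src, dst) channel_from_joint(pmf, dst, src)

#' Propagate a probability vector through a channel
#'
#' @param row_pmf numeric probability vector over the channel's source states.
#' @param channel a `dmc_channel`.
#' @param tol tolerance on the input normalization.
#' @return Numeric probability vector over the destination states.
#' @export
propagate <- function(row_pmf, channel, tol = 1e-6) {
  stopifnot(inherits(channel, "dmc_channel"))
  row_pmf <- as.numeric(row_pmf)
  if (length(row_pmf) != nrow(channel$matrix))
    stop("input length does not match the source alphabet size")
  if (abs(sum(row_pmf) - 1) > tol) stop("input vector is not normalized")
  out <- as.numeric(row_pmf %*% channel$matrix)
  names(out) <- colnames(channel$matrix)
  out
}

#' Compose two channels into the cascade tensor
#'
#' Matrix product of the constituent tensors: the tensor of the cascade
#' src -> mid -> dst.
#'
#' @param c1,c2 `dmc_channel` objects with matching interface alphabets.
#' @return A `dmc_channel` from `c1$source` to `c2$dest`.
#' @export
compose_channels <- function(c1, c2) {
  stopifnot(inherits(c1, "dmc_channel"), inherits(c2, "dmc_channel"))
  if (ncol(c1$matrix) != nrow(c2$matrix) ||
      !identical(colnames(c1$matrix), rownames(c2$matrix)))
    stop("interface alphabets of the two channels do not match")
  .new_channel(c1$matrix %*% c2$matrix, c1$source, c2$dest, c1$flagged)
}

#' Test whether a channel can transmit information
#'
#' A channel with identical rows maps every source pmf to the same
#' destination pmf and therefore represents an absent association.  Flagged
#' (zero source mass) rows are ignored.
#'
#' @param c a `dmc_channel`.
#' @param tol maximum tolerated row-to-row deviation.
#' @return `TRUE` iff all unflagged rows agree within `tol`.
#' @export
is_null_channel <- function(c, tol = 1e-9) {
  stopifnot(inherits(c, "dmc_channel"))
  M <- c$matrix[!c$flagged, , drop = FALSE]
  if (nrow(M) <= 1L) return(TRUE)
  dev <- apply(M, 2L, function(col) diff(range(col)))
  max(dev) <= tol
}

#' Elementwise equality of two channels
#'
#' Rows flagged in either channel are excluded from the comparison.
#'
#' @param c1,c2 `dmc_channel` objects of identical shape.
#' @param tol maximum tolerated elementwise deviation.
#' @return `TRUE` iff the unflagged rows agree within `tol`.
#' @export
channels_equal <- function(c1, c2, tol = 1e-9) {
  stopifnot(inherits(c1, "dmc_channel"), inherits(c2, "dmc_channel"))
  if (!identical(dim(c1$matrix), dim(c2$matrix)))
    stop("channels have different shapes")
  keep <- !(c1$flagged | c2$flagged)
  if (!any(keep)) return(TRUE)
  max(abs(c1$matrix[keep, , drop = FALSE] -
          c2$matrix[keep, , drop = FALSE])) <= tol
}

#' @export
print.dmc_channel <- function(x, digits = 4L, ...) {
  cat(sprintf("channel {%s} -> {%s}%s\n",
              paste(x$source, collapse = ""), paste(x$dest, collapse = ""),
              if (any(x$flagged))
                sprintf("  [%d zero-mass row(s) flagged]", sum(x$flagged))
              else ""))
  print(round(x$matrix, digits))
  invisible(x)
}
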