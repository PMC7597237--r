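# Programmatic reconstruction of the benchmark distributions.
#
# Every named distribution is built from its printed state table (or from
# its boolean hidden-cause mechanism) with exact fractional arithmetic, so
# no external data is needed anywhere in the test surface.

.fixture_df <- function(X, Y, Z, p) {
  joint_pmf(data.frame(X = as.character(X), Y = as.character(Y),
                       Z = as.character(Z), stringsAsFactors = FALSE),
            p,
            alphabets = list(X = sort(unique(as.character(X))),
                             Y = sort(unique(as.character(Y))),
                             Z = sort(unique(as.character(Z)))),
            aggregate = TRUE)
}

#' Benchmark distributions by name
#'
#' Reconstructs the standard worked-example distributions exactly:
#' `two_bit_copy`, `common_cause_3var` / `common_cause_4var` (an unobserved
#' common cause driving X = W1, Y = W1 OR W2, Z = W1 AND W2),
#' `neg_synergy_3var` / `neg_synergy_4var` (X = W1 AND W2,
#' Y = W1 AND NOT W2, Z = W2), `dyadic`, `triadic`, `pwunq`, `5a`, `5b`,
#' `5c`, `reduced_or`, `xor`, `and`, `or`, `sum`.  The `5c` table as printed
#' repeats one full state; the duplicate rows are summed (p(0,1,1) = 1/3),
#' and the resulting distribution is known to be internally inconsistent
#' with an additive decomposition -- it is provided verbatim for study, not
#' as a reference result.
#'
#' @param name distribution name (case-insensitive).
#' @return A [joint_pmf] with variables `X`, `Y`, `Z` (plus `W` for the
#'   4-variable hidden-cause systems).
#' @examples
#' named_distribution("xor")
#' @export
named_distribution <- function(name) {
  name <- tolower(as.character(name)[1L])
  switch(name,
    two_bit_copy = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1),
      Z = c("00", "01", "10", "11"), p = rep(1 / 4, 4)),
    common_cause_3var = hidden_cause_system(
      list(X = quote(W1), Y = quote(W1 | W2), Z = quote(W1 & W2)),
      n_hidden = 2L, marginalize_hidden = TRUE),
    common_cause_4var = hidden_cause_system(
      list(X = quote(W1), Y = quote(W1 | W2), Z = quote(W1 & W2)),
      n_hidden = 2L, marginalize_hidden = FALSE),
    neg_synergy_3var = hidden_cause_system(
      list(X = quote(W1 & W2), Y = quote(W1 & !W2), Z = quote(W2)),
      n_hidden = 2L, marginalize_hidden = TRUE),
    neg_synergy_4var = hidden_cause_system(
      list(X = quote(W1 & W2), Y = quote(W1 & !W2), Z = quote(W2)),
      n_hidden = 2L, marginalize_hidden = FALSE),
    dyadic = .fixture_df(
      X = c(0, 0, 1, 1, 2, 2, 3, 3), Y = c(0, 2, 0, 2, 1, 3, 1, 3),
      Z = c(0, 1, 2, 3, 0, 1, 2, 3), p = rep(1 / 8, 8)),
    triadic = .fixture_df(
      X = c(0, 1, 0, 1, 2, 3, 2, 3), Y = c(0, 1, 2, 3, 0, 1, 2, 3),
      Z = c(0, 1, 2, 3, 2, 3, 0, 1), p = rep(1 / 8, 8)),
    pwunq = .fixture_df(
      X = c(0, 1, 0, 2), Y = c(1, 0, 2, 0), Z = c(1, 1, 2, 2),
      p = rep(1 / 4, 4)),
    `5a` = .fixture_df(
      X = c(0, 0, 1), Y = c(0, 1, 0), Z = c(0, 1, 2), p = rep(1 / 3, 3)),
    `5b` = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1), Z = c(0, 1, 2, 1),
      p = rep(1 / 4, 4)),
    `5c` = .fixture_df(
      X = c(0, 0, 1, 1, 0, 1), Y = c(0, 1, 0, 1, 1, 1),
      Z = c(0, 1, 2, 0, 1, 1), p = rep(1 / 6, 6)),
    reduced_or = .fixture_df(
      X = c(0, 0, 1), Y = c(0, 1, 0), Z = c(0, 1, 1), p = c(1 / 2, 1 / 4, 1 / 4)),
    xor = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1), Z = c(0, 1, 1, 0),
      p = rep(1 / 4, 4)),
    `and` = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1), Z = c(0, 0, 0, 1),
      p = rep(1 / 4, 4)),
    `or` = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1), Z = c(0, 1, 1, 1),
      p = rep(1 / 4, 4)),
    sum = .fixture_df(
      X = c(0, 0, 1, 1), Y = c(0, 1, 0, 1), Z = c(0, 1, 1, 2),
      p = rep(1 / 4, 4)),
    stop(sprintf("unknown distribution name: '%s'", name))
  )
}

#' Deterministic system driven by uniform hidden bits
#'
#' Builds the joint distribution of variables that are boolean functions of
#' `n_hidden` independent uniform bits `W1, ..., Wn`.  Each formula is a
#' quoted R expression over the bit names (bits evaluate as 0/1 integers,
#' so both logical and arithmetic operators work); the observed symbol is
#' the integer value of the formula.
#'
#' @param formulas named list of quoted expressions, one per observed
#'   variable.
#' @param n_hidden number of hidden bits.
#' @param marginalize_hidden if `FALSE`, the hidden word is kept as an extra
#'   variable `W` with symbols `"00"`, `"01"`, ...
#' @return A [joint_pmf].
#' @examples
#' hidden_cause_system(list(X = quote(W1), Y = quote(W1 | W2),
#'                          Z = quote(W1 & W2)), n_hidden = 2)
#' @export
hidden_cause_system <- function(formulas, n_hidden, marginalize_hidden = TRUE) {
  if (is.null(names(formulas)) || any(!nzchar(names(formulas))))
    stop("`formulas` must be a named list")
  n_hidden <- as.integer(n_hidden)
  stopifnot(n_hidden >= 1L)
  bits <- paste0("W", seq_len(n_hidden))
  words <- .group_states(stats::setNames(rep(list(c("0", "1")), n_hidden),
                                         bits), bits)
  vals <- lapply(formulas, function(f) {
    out <- vapply(seq_len(nrow(words)), function(r) {
      env <- list2env(stats::setNames(as.list(as.integer(unlist(words[r, ]))),
                                      bits), parent = baseenv())
      v <- try(eval(f, env), silent = TRUE)
      if (inherits(v, "try-error") || length(v) != 1L || is.na(v))
        stop("malformed boolean formula: ", deparse(f))
      as.integer(v)
    }, integer(1L))
    as.character(out)
  })
  df <- as.data.frame(vals, stringsAsFactors = FALSE)
  if (!marginalize_hidden)
    df$W <- do.call(paste0, words)
  joint_pmf(df, rep(1 / nrow(words), nrow(words)), aggregate = TRUE)
}
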