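# Random channel systems for property testing.
#
# Systems are drawn exactly under the modeling assumptions of the method: a
# DAG of discrete memoryless channels with Dirichlet(1) (uniform simplex)
# conditional rows, so every generated joint pmf is Markovian by
# construction and strictly positive with probability one.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.dirichlet_row <- function(k) {
  g <- stats::rgamma(k, shape = 1)
  g / sum(g)
}

.sys_var_names <- function(n)
  if (n <= 4L) c("X", "Y", "Z", "W")[seq_len(n)] else paste0("V", seq_len(n))

#' Random discrete channel system
#'
#' Draws a random DAG over `n_vars` variables in a fixed topological order
#' (`edge_density` is the independent probability of each forward edge),
#' samples Dirichlet(1) conditional rows for every node given its parents,
#' and returns the implied joint pmf.
#'
#' @param n_vars number of variables (>= 2).
#' @param alphabet_sizes integer vector (recycled) of per-variable alphabet
#'   sizes.
#' @param edge_density probability of each forward edge; 0 gives fully
#'   independent variables.
#' @param seed integer seed fixing the draw (required for reproducibility).
#' @return A [joint_pmf]; variables are named `X`, `Y`, `Z`, `W` (up to 4)
#'   or `V1`, `V2`, ...
#' @export
random_channel_system <- function(n_vars, alphabet_sizes = 2L,
                                  edge_density = 0.5, seed) {
  n_vars <- as.integer(n_vars)
  if (n_vars < 2L) stop("need at least 2 variables")
  sizes <- rep_len(as.integer(alphabet_sizes), n_vars)
  if (any(sizes < 2L)) stop("alphabet sizes must be at least 2")
  .with_seed(seed, {
    adj <- matrix(FALSE, n_vars, n_vars)
    for (i in seq_len(n_vars - 1L)) for (j in (i + 1L):n_vars)
      adj[i, j] <- stats::runif(1) < edge_density
    .dag_system(adj, sizes)
  })
}

#' Random Markov chain X -> Y -> ... over `length(alphabet_sizes)` variables
#'
#' A chain DAG with random Dirichlet(1) channels; by construction every
#' non-adjacent association is exactly explained by the cascade through the
#' mediators.
#'
#' @param seed integer seed.
#' @param alphabet_sizes per-variable alphabet sizes (length >= 3).
#' @return A [joint_pmf].
#' @export
random_markov_chain <- function(seed, alphabet_sizes = c(2L, 2L, 2L)) {
  sizes <- as.integer(alphabet_sizes)
  n <- length(sizes)
  if (n < 3L) stop("a chain fixture needs at least 3 variables")
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) adj[i, i + 1L] <- TRUE
  .with_seed(seed, .dag_system(adj, sizes))
}

# Joint pmf of a DAG of Dirichlet channels. adj[i, j] TRUE means i -> j with
# i < j (topological order).
.dag_system <- function(adj, sizes) {
  n <- nrow(adj)
  vars <- .sys_var_names(n)
  alphabets <- stats::setNames(lapply(sizes, function(k)
    as.character(seq_len(k) - 1L)), vars)
  states <- .group_states(alphabets, vars)
  p <- rep(1, nrow(states))
  for (j in seq_len(n)) {
    parents <- which(adj[, j])
    if (!length(parents)) {
      marg <- .dirichlet_row(sizes[j])
      p <- p * marg[as.integer(states[[j]]) + 1L]
    } else {
      pkey <- do.call(paste, c(states[vars[parents]], sep = .SEP))
      ukey <- unique(pkey)
      rows <- lapply(ukey, function(k) .dirichlet_row(sizes[j]))
      names(rows) <- ukey
      for (r in seq_len(nrow(states)))
        p[r] <- p[r] * rows[[pkey[r]]][as.integer(states[[j]][r]) + 1L]
    }
  }
  joint_pmf(states, p, alphabets = alphabets)
}
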