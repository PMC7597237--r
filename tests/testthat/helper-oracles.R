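# Independent brute-force oracles.  Deliberately written with explicit loops
# over data.frame state tables -- no shared code with the package internals --
# so that agreement is a genuine cross-check.

o_table <- function(pmf) as.data.frame(pmf)

o_marg <- function(df, vars) {
  key <- do.call(paste, df[vars])
  lv <- unique(key)
  p <- vapply(lv, function(k) sum(df$p[key == k]), numeric(1))
  names(p) <- lv
  p
}

o_H <- function(df, vars) {
  p <- o_marg(df, vars)
  p <- p[p > 0]
  -sum(p * log2(p))
}

o_mi <- function(df, A, B) {
  ka <- do.call(paste, df[A]); kb <- do.call(paste, df[B])
  la <- unique(ka); lb <- unique(kb)
  s <- 0
  for (a in la) for (b in lb) {
    pab <- sum(df$p[ka == a & kb == b])
    if (pab > 0)
      s <- s + pab * log2(pab / (sum(df$p[ka == a]) * sum(df$p[kb == b])))
  }
  s
}

o_cmi <- function(df, A, B, C)
  o_H(df, c(A, C)) + o_H(df, c(B, C)) - o_H(df, c(A, B, C)) - o_H(df, C)

# conditional matrix p(d|s) with rows/cols in first-appearance order
o_chan <- function(df, s, d) {
  ks <- do.call(paste, df[s]); kd <- do.call(paste, df[d])
  ls <- unique(ks); ld <- unique(kd)
  M <- matrix(0, length(ls), length(ld), dimnames = list(ls, ld))
  for (i in seq_along(ls)) {
    ps <- sum(df$p[ks == ls[i]])
    for (j in seq_along(ld))
      M[i, j] <- if (ps > 0) sum(df$p[ks == ls[i] & kd == ld[j]]) / ps
                 else 1 / length(ld)
  }
  M
}

o_null <- function(M, tol = 1e-9) {
  if (nrow(M) <= 1) return(TRUE)
  dev <- 0
  for (j in seq_len(ncol(M))) dev <- max(dev, max(M[, j]) - min(M[, j]))
  dev <= tol
}

# path MI by step-by-step matrix multiplication over single-variable nodes
o_pathmi <- function(df, nodes) {
  Tm <- o_chan(df, nodes[1], nodes[2])
  if (length(nodes) > 2)
    for (i in 2:(length(nodes) - 1))
      Tm <- Tm %*% o_chan(df, nodes[i], nodes[i + 1])
  ps <- o_marg(df, nodes[1])[rownames(Tm)]
  m <- as.numeric(ps %*% Tm)
  s <- 0
  for (i in seq_along(ps)) for (j in seq_along(m)) {
    q <- ps[i] * Tm[i, j]
    if (q > 0) s <- s + q * log2(Tm[i, j] / m[j])
  }
  unname(s)
}

# permutation-path redundancy with the default admissibility rule (a path is
# excluded iff it uses an edge whose channel is null in both orientations)
o_redundancy <- function(df, sources, target, tol = 1e-9) {
  perm_list <- if (length(sources) == 2) list(sources, rev(sources))
               else stop("oracle handles two sources")
  vals <- numeric(0)
  for (perm in perm_list) {
    nodes <- c(perm, target)
    ok <- TRUE
    for (i in seq_len(length(nodes) - 1))
      if (o_null(o_chan(df, nodes[i], nodes[i + 1]), tol) &&
          o_null(o_chan(df, nodes[i + 1], nodes[i]), tol)) { ok <- FALSE; break }
    if (ok) vals <- c(vals, o_pathmi(df, nodes))
  }
  if (length(vals)) min(vals) else 0
}
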