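# Shared random-system pools for the property sweeps.  Built once per test
# run; seeds are fixed so every run sees the same systems.

make_systems <- function(n, n_vars, sizes, density, seed0) {
  lapply(seq_len(n), function(i)
    random_channel_system(n_vars, sizes, density, seed = seed0 + i))
}

# 1000 three-variable systems, mixed binary/ternary alphabets, as specified
# for the cheap property sweeps.
systems_3 <- c(make_systems(500, 3, c(2, 2, 2), 0.8, 1000),
               make_systems(500, 3, c(2, 3, 2), 0.8, 2000))

# fully connected systems for the bounds that assume alternative paths exist
systems_3_full <- make_systems(300, 3, c(2, 3, 2), 1, 3000)
systems_4_full <- make_systems(120, 4, 2, 1, 4000)

# Markov chains X -> Y -> Z (mediator Y)
chains_3 <- lapply(1:150, function(i)
  random_markov_chain(5000 + i, c(2, 3, 2)))

# three-variable chain whose X-Z channel is exactly null while X-Y and Y-Z
# carry information: A = [[1,0,0],[0,.5,.5]], B = [[.5,.5],[1,0],[0,1]]
chain_absent_xz <- function() {
  A <- rbind(c(1, 0, 0), c(0, 0.5, 0.5))
  B <- rbind(c(0.5, 0.5), c(1, 0), c(0, 1))
  states <- expand.grid(Z = c("0", "1"), Y = c("0", "1", "2"),
                        X = c("0", "1"), stringsAsFactors = FALSE)[, 3:1]
  p <- mapply(function(x, y, z)
    0.5 * A[as.integer(x) + 1, as.integer(y) + 1] *
      B[as.integer(y) + 1, as.integer(z) + 1],
    states$X, states$Y, states$Z)
  joint_pmf(states, p)
}

# Y an exact relabeling of X, Z a noisy function of X
copy_system <- function() {
  states <- expand.grid(Z = c("0", "1"), Y = c("a", "b"), X = c("0", "1"),
                        stringsAsFactors = FALSE)[, 3:1]
  p <- mapply(function(x, y, z) {
    if ((x == "0") != (y == "a")) return(0) # Y relabels X: 0->a, 1->b
    0.5 * if (x == z) 0.8 else 0.2
  }, states$X, states$Y, states$Z)
  joint_pmf(states, p)
}
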