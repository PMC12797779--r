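# Fixture builders and independent oracle implementations. Oracles are
# deliberately naive (full enumeration / direct summation) and share no code
# with the package internals they check.

tiny_table <- function() {
  genotype_table(matrix(c(2L, 1L, 1L, 0L, 0L, NA), nrow = 3, ncol = 2),
                 population = c("P1", "P1", "P2"),
                 superpopulation = c("S1", "S1", "S2"),
                 sample_ids = c("a", "b", "c"))
}

random_table <- function(n = 8, L = 5, seed = 1, miss = 0.1) {
  set.seed(seed)
  d <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  d[matrix(runif(n * L) < miss, n, L)] <- NA
  pops <- rep(c("P1", "P2"), length.out = n)
  genotype_table(d, population = pops,
                 superpopulation = ifelse(pops == "P1", "S1", "S2"),
                 sample_ids = sprintf("ind%02d", seq_len(n)))
}

# Levene exact HWE distribution by enumeration over genotype configurations
hwe_oracle_p <- function(n_II, n_ID, n_DD) {
  n <- n_II + n_ID + n_DD
  n_ins <- 2 * n_II + n_ID
  configs <- expand.grid(a = 0:n, h = 0:n)
  configs <- configs[configs$a + configs$h <= n, ]
  configs$d <- n - configs$a - configs$h
  configs <- configs[2 * configs$a + configs$h == n_ins, ]
  w <- apply(configs, 1, function(r)
    exp(lfactorial(n) - lfactorial(r["a"]) - lfactorial(r["h"]) -
          lfactorial(r["d"]) + r["h"] * log(2)))
  prob <- w / sum(w)
  obs <- prob[configs$h == n_ID]
  sum(prob[prob <= obs + 1e-12])
}

# Rosenberg informativeness by direct term-by-term summation
in_oracle <- function(p) {
  K <- length(p)
  total <- 0
  for (allele in list(p, 1 - p)) {
    pbar <- sum(allele) / K
    t1 <- if (pbar > 0) -pbar * log(pbar) else 0
    t2 <- 0
    for (i in seq_len(K)) if (allele[i] > 0)
      t2 <- t2 + allele[i] * log(allele[i]) / K
    total <- total + t1 + t2
  }
  total
}

# all permutations of 1..n (recursive, independent of the package helper)
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_oracle(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

# joint genotype-pair distribution by enumeration of ordered allele draws:
# IBD state, then explicit allele-by-allele sampling paths
joint_oracle <- function(g1, g2, p, k) {
  q <- 1 - p
  gp <- c(q^2, 2 * p * q, p^2)
  # one-shared-allele kernel built by brute force over which allele is shared
  pr <- 0
  # k0 term
  pr <- pr + k[1] * gp[g1 + 1] * gp[g2 + 1]
  # k1 term: enumerate individual 1's ordered alleles and the shared pick
  for (a1 in 0:1) for (a2 in 0:1) {
    pa <- (p^a1 * q^(1 - a1)) * (p^a2 * q^(1 - a2))
    if (a1 + a2 != g1) next
    for (pick in 1:2) {
      shared <- if (pick == 1) a1 else a2
      for (b in 0:1) {
        pb <- p^b * q^(1 - b)
        if (shared + b == g2) pr <- pr + k[2] * pa * 0.5 * pb
      }
    }
  }
  # k2 term
  if (g1 == g2) pr <- pr + k[3] * gp[g1 + 1]
  pr
}
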