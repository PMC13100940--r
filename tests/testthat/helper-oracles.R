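# Independent brute-force oracles and shared fixtures. Oracles deliberately
# avoid the implementation's code paths (explicit loops, enumeration, or a
# separate DP) so agreement is evidence, not tautology.

# A small field that still satisfies the >= 20 negative cells rule:
# 34 cells at 40% positive -> 14 positive, 20 negative.
small_field_spec <- function(...) {
  args <- list(height_px = 160, width_px = 160, n_cells = 34,
               positive_fraction = 0.4)
  do.call(field_spec, utils::modifyList(args, list(...)))
}

# Hodges-Lehmann estimate + Moses CI by explicit loops.
oracle_hl <- function(x, y, conf_level = 0.95) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  d <- sort(d)
  N <- length(d)
  med <- if (N %% 2 == 1) d[(N + 1) / 2] else (d[N / 2] + d[N / 2 + 1]) / 2
  z <- qnorm(1 - (1 - conf_level) / 2)
  K <- max(1, floor(N / 2 - z * sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12)))
  list(hl = med, ci_low = d[K], ci_high = d[N + 1 - K], diffs = d)
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (tie-free samples only).
oracle_mw_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(!any(duplicated(c(x, y))))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Semi-global affine-gap alignment score (region global, subject free end
# gaps) by Gotoh dynamic programming; open/extend as positive costs, a gap
# of length L costing open + L * extend.
oracle_semiglobal_score <- function(p, s, mat, open = 11, extend = 1) {
  pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(pc); m <- length(sc)
  NEG <- -1e9
  # D: p_i ~ s_j ; P: p_i ~ gap ; Q: s_j ~ gap (internal only)
  D <- P <- Q <- matrix(NEG, n + 1, m + 1)
  best_prev <- function(i, j) {            # best score of p[1..i] vs s[..j]
    if (i == 0) return(0)                  # free leading subject gap
    max(D[i + 1, j + 1], P[i + 1, j + 1], Q[i + 1, j + 1])
  }
  for (i in seq_len(n)) {
    P[i + 1, 1] <- -(open + i * extend)
    for (j in 0:m) {
      if (j >= 1) {
        D[i + 1, j + 1] <- mat[pc[i], sc[j]] + best_prev(i - 1, j - 1)
        q_cand <- c(D[i + 1, j] - (open + extend), Q[i + 1, j] - extend)
        Q[i + 1, j + 1] <- max(q_cand)
      }
      if (j >= 1 || i > 1) {
        p_cand <- c(if (i == 1) -(open + extend) else NEG,
                    D[i, j + 1] - (open + extend),
                    P[i, j + 1] - extend)
        P[i + 1, j + 1] <- max(P[i + 1, j + 1], p_cand)
      }
    }
  }
  max(pmax(D[n + 1, ], P[n + 1, ]))        # free trailing subject gap
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE), collapse = "")
}
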