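# Independent oracles used to cross-check the implementation.

# Exact 16-state enumeration of the noisy-OR network: mechanisms are
# independent Bernoulli variables (the GWAS category activates with the
# updated prior pi_vl and causes the phenotype with certainty; the others
# activate with q_c and cause it with rho_c).
enum_posterior <- function(q_vh, q_gh, q_gl, pi_vl, rho_vh, rho_gh, rho_gl) {
  states <- expand.grid(svl = 0:1, svh = 0:1, sgh = 0:1, sgl = 0:1)
  total <- 0
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    p_state <- (if (s$svl) pi_vl else 1 - pi_vl) *
      (if (s$svh) q_vh else 1 - q_vh) *
      (if (s$sgh) q_gh else 1 - q_gh) *
      (if (s$sgl) q_gl else 1 - q_gl)
    p_y <- 1 - (1 - s$svl) * (1 - rho_vh * s$svh) *
      (1 - rho_gh * s$sgh) * (1 - rho_gl * s$sgl)
    total <- total + p_state * p_y
  }
  total
}

# Hand-rolled bisection on the Hardy-Weinberg mean-risk equation, kept
# independent of the package's root finder.
bisect_penetrance <- function(or, f, prior, tol = 1e-12) {
  w <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  g <- function(o0) sum(w * (o0 * or^(0:2)) / (1 + o0 * or^(0:2))) - prior
  lo <- 1e-12; hi <- 1e3
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  o0 <- (lo + hi) / 2
  o <- o0 * or^(0:2)
  o / (1 + o)
}

# Brute-force AUC by pair counting with half credit for ties.
auc_brute <- function(scores, statuses) {
  keep <- !is.na(statuses)
  s <- scores[keep]; y <- statuses[keep]
  cases <- s[y == 1]; controls <- s[y == 0]
  if (length(cases) == 0 || length(controls) == 0) return(NA_real_)
  total <- 0
  for (a in cases) for (b in controls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(controls))
}
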