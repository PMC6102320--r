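# Shared fixtures: shipped defaults and an independent term-by-term
# evaluation of the electrochemical flux factor used as an oracle.

d_p <- ncx_params()
d_env <- cell_env()
d_hp <- homeostasis_params()

# Independent evaluation of the exchanger cycle rate: every term of the
# numerator and denominator is computed separately and combined at the end,
# so shared subexpressions (and their rounding) differ from the package
# implementation.
oracle_jde <- function(Ca_i, Na_i, env, p) {
  if (length(Ca_i) > 1 || length(Na_i) > 1)
    return(mapply(oracle_jde, Ca_i, Na_i, MoreArgs = list(env = env, p = p)))
  v <- env$V * env$F / (env$R * env$T)
  t_in <- (Na_i^3) * env$Ca_o * exp(p$eta * v)
  t_out <- (env$Na_o^3) * Ca_i * exp((p$eta - 1) * v)
  kx_terms <- c(
    p$KM_Cao * Na_i^3,
    (p$KM_Nao^3) * Ca_i,
    (p$KM_Nai^3) * env$Ca_o,
    (p$KM_Nai^3) * env$Ca_o * Ca_i / p$KM_Cai,
    p$KM_Cai * env$Na_o^3,
    p$KM_Cai * env$Na_o^3 * (Na_i^3) / (p$KM_Nai^3),
    (Na_i^3) * env$Ca_o,
    (env$Na_o^3) * Ca_i)
  (t_in - t_out) / (sum(kx_terms) * (1 + p$ksat * exp((p$eta - 1) * v)))
}

# Deterministic pseudo-random state draws for property tests.
draw_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    Ca = 10^stats::runif(n, -5, -2),   # 10 nM .. 10 uM
    Na = stats::runif(n, 2, 90),
    h = stats::runif(n))
}

# Relative comparison against the vector's own scale, so elements sitting
# near a sign change (e.g. the reversal manifold) do not divide by ~0.
expect_rel_equal <- function(x, y, tol) {
  scale <- pmax(abs(y), max(abs(y)))
  expect_lt(max(abs(x - y) / scale), tol)
}
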