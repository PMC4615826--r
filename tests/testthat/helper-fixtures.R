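# shared fixtures, built once per test run and cached
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small session with one constant coupling, alert-to-drowsy decline
small_coupled_session <- function() {
  fixture("small_coupled_session", function() {
    gen_session(session_config(n_trials = 30, seed = 301),
                list(coupling_truth("Cz", "Pz", lag = 2, shape = "constant",
                                    strength = 1)))
  })
}

# population Granger causality of the gen_coupled_pair model with
# lag 1, from the stationary covariance of the joint VAR(1)
# z_t = A z_{t-1} + e_t, A = [[a, c], [0, b]] (Lyapunov fixed point)
pop_gc_coupled <- function(a, b, c_coef, noise_sd = 1) {
  A <- matrix(c(a, 0, c_coef, b), 2, 2)
  Q <- diag(noise_sd^2, 2)
  S <- Q
  for (i in 1:200) S <- A %*% S %*% t(A) + Q
  cov_lag1 <- (A %*% S)[1, 1]          # cov(x_t, x_{t-1})
  resid_restricted <- S[1, 1] - cov_lag1^2 / S[1, 1]
  log(resid_restricted / noise_sd^2)
}

# exact plug-in transfer entropy (bits) of a binary Markov pair:
# y_t depends on y_{t-1} via py; x_t depends on (x_{t-1}, y_{t-1})
# via px[x+1, y+1] = P(x_t = 1 | .)
markov_te_exact <- function(py, px) {
  st <- expand.grid(x = 0:1, y = 0:1)
  P <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    xp <- px[st$x[i] + 1, st$y[i] + 1]
    yp <- py[st$y[i] + 1]
    P[i, j] <- (if (st$x[j] == 1) xp else 1 - xp) *
               (if (st$y[j] == 1) yp else 1 - yp)
  }
  e <- eigen(t(P))
  pi0 <- Re(e$vectors[, 1]); pi0 <- pi0 / sum(pi0)
  pxy <- matrix(0, 2, 2)
  for (i in 1:4) pxy[st$x[i] + 1, st$y[i] + 1] <- pi0[i]
  px_marg <- rowSums(pxy)
  p_next_given_x <- vapply(0:1, function(x) {
    sum(vapply(0:1, function(y) pxy[x + 1, y + 1] * px[x + 1, y + 1],
               numeric(1))) / px_marg[x + 1]
  }, numeric(1))
  te <- 0
  for (x in 0:1) for (y in 0:1) for (xn in 0:1) {
    pc <- if (xn == 1) px[x + 1, y + 1] else 1 - px[x + 1, y + 1]
    pm <- if (xn == 1) p_next_given_x[x + 1] else 1 - p_next_given_x[x + 1]
    te <- te + pxy[x + 1, y + 1] * pc * log2(pc / pm)
  }
  te
}

simulate_markov_pair <- function(py, px, n, seed) {
  set.seed(seed)
  x <- integer(n); y <- integer(n)
  for (t in 2:n) {
    y[t] <- stats::rbinom(1, 1, py[y[t - 1] + 1])
    x[t] <- stats::rbinom(1, 1, px[x[t - 1] + 1, y[t - 1] + 1])
  }
  list(x = x, y = y)
}
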