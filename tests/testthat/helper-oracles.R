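# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain rotation matrices, Runge-Kutta integration
# of the projectile ODE, and a loop-based sums-of-squares decomposition.

# Hand position via an explicit 2-D rotation matrix: rotate the reference
# hand offset (arm, trunk) clockwise by theta about the hip pivot.
oracle_target <- function(hip, trunk, arm, theta_deg) {
  th <- theta_deg * pi / 180
  Rm <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)  # clockwise in (x, z)
  v <- Rm %*% c(arm, trunk)
  c(anterior = v[1], vertical = hip + v[2])
}

# Fixed-step RK4 integration of dx/dt = vx, dz/dt = vz, dvz/dt = -g.
oracle_flight_rk4 <- function(x0, z0, vx0, vz0, g, t_end, n_steps = 4000) {
  h <- t_end / n_steps
  state <- c(x0, z0, vx0, vz0)
  deriv <- function(s) c(s[3], s[4], 0, -g)
  for (i in seq_len(n_steps)) {
    k1 <- deriv(state)
    k2 <- deriv(state + h / 2 * k1)
    k3 <- deriv(state + h / 2 * k2)
    k4 <- deriv(state + h * k3)
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  c(x = state[1], z = state[2])
}

# Loop-based within-subject sums-of-squares decomposition for a full
# n x a x b design (one observation per cell). Y is an array [n, a, b].
oracle_rm_ss <- function(Y) {
  n <- dim(Y)[1]; a <- dim(Y)[2]; b <- dim(Y)[3]
  m <- mean(Y)
  m_s <- apply(Y, 1, mean); m_j <- apply(Y, 2, mean); m_k <- apply(Y, 3, mean)
  m_sj <- apply(Y, c(1, 2), mean); m_sk <- apply(Y, c(1, 3), mean)
  m_jk <- apply(Y, c(2, 3), mean)
  ss <- list(A = 0, B = 0, AB = 0, AS = 0, BS = 0, ABS = 0)
  for (j in 1:a) ss$A <- ss$A + n * b * (m_j[j] - m)^2
  for (k in 1:b) ss$B <- ss$B + n * a * (m_k[k] - m)^2
  for (j in 1:a) for (k in 1:b) ss$AB <- ss$AB + n * (m_jk[j, k] - m_j[j] - m_k[k] + m)^2
  for (s in 1:n) for (j in 1:a) ss$AS <- ss$AS + b * (m_sj[s, j] - m_s[s] - m_j[j] + m)^2
  for (s in 1:n) for (k in 1:b) ss$BS <- ss$BS + a * (m_sk[s, k] - m_s[s] - m_k[k] + m)^2
  for (s in 1:n) for (j in 1:a) for (k in 1:b) {
    ss$ABS <- ss$ABS + (Y[s, j, k] - m_sj[s, j] - m_sk[s, k] - m_jk[j, k] +
                          m_s[s] + m_j[j] + m_k[k] - m)^2
  }
  df <- list(A = a - 1, B = b - 1, AB = (a - 1) * (b - 1),
             AS = (a - 1) * (n - 1), BS = (b - 1) * (n - 1),
             ABS = (a - 1) * (b - 1) * (n - 1))
  list(ss = ss, df = df,
       F = c(A = (ss$A / df$A) / (ss$AS / df$AS),
             B = (ss$B / df$B) / (ss$BS / df$BS),
             AB = (ss$AB / df$AB) / (ss$ABS / df$ABS)))
}

# Long-format test table from an [n, a, b] array.
long_from_array <- function(Y, games = c("reachality", "fishality", "dodgeality"),
                            thetas = c(15, 30, 45, 60)) {
  n <- dim(Y)[1]
  grid <- expand.grid(participant = sprintf("S%02d", 1:n),
                      game = games[seq_len(dim(Y)[2])],
                      theta_deg = thetas[seq_len(dim(Y)[3])],
                      stringsAsFactors = FALSE)
  grid$y <- NA_real_
  for (r in seq_len(nrow(grid))) {
    s <- match(grid$participant[r], sprintf("S%02d", 1:n))
    j <- match(grid$game[r], games)
    k <- match(grid$theta_deg[r], thetas)
    grid$y[r] <- Y[s, j, k]
  }
  tibble::as_tibble(grid)
}

# Minimal plan-item row for direct synthesize_trial calls.
make_item <- function(game, theta, kind = if (game == "reachality") "reach" else "launch",
                      hand = "right") {
  tibble::tibble(game = game, event_kind = kind, theta_deg = theta, hand = hand,
                 set_index = 1L, trial_index = 1L)
}

default_test_anthro <- function() anthropometry(0.93, 0.47, 0.62)
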