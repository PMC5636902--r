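# Independent brute-force oracles for the estimators and simulators.
# These deliberately use the most literal, slowest formulation available so
# they stay independent of the vectorised implementations they check.

msd_naive <- function(x, y, max_lag) {
  n <- length(x)
  vapply(seq_len(max_lag), function(l) {
    s <- 0
    for (i in 1:(n - l)) {
      s <- s + (x[i + l] - x[i])^2 + (y[i + l] - y[i])^2
    }
    s / (n - l)
  }, numeric(1))
}

dacf_naive <- function(x, y, k, max_lag) {
  n <- length(x)
  raw <- vapply(0:max_lag, function(l) {
    s <- 0
    for (i in 1:(n - l - k)) {
      s <- s + ((x[i + l + k] - x[i + l]) * (x[i + k] - x[i]) +
                  (y[i + l + k] - y[i + l]) * (y[i + k] - y[i])) / k^2
    }
    s / (n - l - k)
  }, numeric(1))
  raw / raw[[1]]
}

# Exhaustive run-length scan for suprathreshold episodes.
runs_naive <- function(above, min_samples) {
  onsets <- integer(0); ends <- integer(0)
  i <- 1
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_samples) {
        onsets <- c(onsets, i); ends <- c(ends, j)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  list(onset = onsets, end = ends)
}

# Literal replay of the multi-step engine built on full-matrix state and the
# engine's documented random-number contract (pregenerated draw vectors,
# consumed by iteration index). Supports the plain SAW and all four delayed
# variants by storing complete field snapshots -- the representation the
# optimised engine avoids. Returns recorded positions (centred) and event
# count.
saw_naive <- function(n_steps, params, variant = "saw", tau = 0L,
                      noise_sd = 0, noise_enabled = FALSE, seed = 1) {
  p <- params
  L <- p$L
  i0 <- (L + 1L) / 2L
  u <- outer(seq_len(L), seq_len(L),
             function(i, j) potential_u(i, j, p))
  u1 <- outer(seq_len(L), seq_len(L),
              function(i, j) potential_u1(i, j, p))
  post <- identical(p$trigger, "post-deposit")
  delayed_read <- variant %in% c("dr", "dar")
  delayed_set <- variant %in% c("da", "dar")
  delayed_field <- variant == "ds"
  random_prefix <- variant %in% c("dr", "dar", "ds")
  nsd <- if (noise_enabled) noise_sd else 0
  set.seed(seed)
  h <- matrix(runif(L * L), L, L)
  total <- p$burn_in + n_steps
  zx <- rnorm(total); zy <- rnorm(total); ut <- runif(total)
  pos <- c(i0, i0)
  pos_hist <- list()    # pos_hist[[t]] = position at start of iteration t
  field_hist <- list()  # field_hist[[t]] = field after iteration t's deposit, before decay
  traj <- matrix(0, n_steps, 2)
  n_events <- 0L
  clamp <- function(v) pmin(pmax(v, 1L), L)
  for (t in seq_len(total)) {
    prefix <- t <= tau
    pos_hist[[t]] <- pos
    ndx <- as.integer(round(zx[t] * nsd)); ndy <- as.integer(round(zy[t] * nsd))
    # deposit
    skip_set <- delayed_set && prefix
    if (delayed_set && !prefix) {
      b <- pos_hist[[t - tau]]
      set_pos <- clamp(c(b[1] + ndx, b[2] + ndy))
    } else if (delayed_field) {
      set_pos <- clamp(c(pos[1] + ndx, pos[2] + ndy))
    } else {
      set_pos <- pos
    }
    if (post && !skip_set) h[set_pos[1], set_pos[2]] <- h[set_pos[1], set_pos[2]] + 1
    field_hist[[t]] <- h # field as seen at this iteration's decision time
    # trigger: current position; field the variant reads
    trig_field <- if (delayed_field && tau > 0 && !prefix) field_hist[[t - tau]] else h
    if (trig_field[pos[1], pos[2]] > p$h_c) {
      tot <- h + u + u1
      cand <- which(tot - min(tot) <= p$tie_tol)
      k <- cand[[1L + (as.integer(ut[t] * length(cand)) %% length(cand))]]
      nxt <- c(((k - 1L) %% L) + 1L, ((k - 1L) %/% L) + 1L)
      if (t > p$burn_in) n_events <- n_events + 1L
    } else if (prefix && random_prefix) {
      ki <- pos[1] + c(-1L, 1L, 0L, 0L); kj <- pos[2] + c(0L, 0L, -1L, 1L)
      ok <- ki >= 1 & ki <= L & kj >= 1 & kj <= L
      ki <- ki[ok]; kj <- kj[ok]
      k <- 1L + (as.integer(ut[t] * length(ki)) %% length(ki))
      nxt <- c(ki[k], kj[k])
    } else {
      rc <- if (delayed_read) {
        b <- if (tau > 0) pos_hist[[t - tau]] else pos
        clamp(c(b[1] + ndx, b[2] + ndy))
      } else {
        pos
      }
      ki <- rc[1] + c(-1L, 1L, 0L, 0L); kj <- rc[2] + c(0L, 0L, -1L, 1L)
      ok <- ki >= 1 & ki <= L & kj >= 1 & kj <= L
      ki <- ki[ok]; kj <- kj[ok]
      read_field <- if (delayed_field && tau > 0 && !prefix) field_hist[[t - tau]] else h
      vals <- read_field[cbind(ki, kj)] + u[cbind(ki, kj)]
      cand <- which(vals - min(vals) <= p$tie_tol)
      k <- cand[[1L + (as.integer(ut[t] * length(cand)) %% length(cand))]]
      nxt <- clamp(c(pos[1] + (ki[k] - rc[1]), pos[2] + (kj[k] - rc[2])))
    }
    if (!post && !skip_set) h[set_pos[1], set_pos[2]] <- h[set_pos[1], set_pos[2]] + 1
    if (!(delayed_set && prefix)) h <- h * (1 - p$epsilon)
    if (t > p$burn_in) traj[t - p$burn_in, ] <- pos - i0
    pos <- nxt
  }
  list(traj = traj, n_events = n_events)
}

# Small random trajectory helper.
random_traj <- function(n, dt = 0.002, scale = 1) {
  new_trajectory(cumsum(rnorm(n, sd = scale)), cumsum(rnorm(n, sd = scale)), dt = dt)
}
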