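# Field state of iteration t - tau evaluated at sites ss, reconstructed from
# the current raw field by removing the deposits made since then and rescaling
# to that iteration's decay level g_then. Slot r of the deposit ring holds
# iteration t - tau's own deposit, which belongs to that state under the
# post-deposit convention and is therefore kept.
ds_delayed_value <- function(h, ss, site_now, amt_now, inc_site, inc_amt, r,
                             g_then, post, tau) {
  hv <- h[ss]
  if (post && !is.na(site_now)) {
    hit <- ss == site_now
    if (any(hit)) hv[hit] <- hv[hit] - amt_now
  }
  for (q in seq_len(tau)) {
    if ((q != r || !post) && !is.na(inc_site[[q]])) {
      hit <- ss == inc_site[[q]]
      if (any(hit)) hv[hit] <- hv[hit] - inc_amt[[q]]
    }
  }
  g_then * hv
}

# Optimised multi-step simulator shared by the plain SAW and the four
# time-delayed variants. Semantics per iteration match saw_iteration();
# the global decay is carried lazily as a scalar scale factor g with
# true_field = g * h_raw, so an iteration costs O(1) instead of O(L^2)
# (a full-lattice scan happens only when a microsaccade fires).
#
# Random-number contract (part of the reproducibility guarantee): after
# set.seed(seed) the engine draws, in this order, runif(L^2) for the initial
# field, rnorm(total) twice for the per-iteration readout-noise offsets, and
# runif(total) for the per-iteration tie-break / random-step / landing
# decision. Draws are consumed by position in these pregenerated vectors, so
# all variants share identical randomness given the same seed: with tau = 0
# and noise disabled every variant reproduces the plain SAW bit for bit.
saw_engine <- function(n_steps, params, variant = c("saw", "ds", "dr", "da", "dar"),
                       tau = 0L, noise_sd = 0.3, noise_enabled = TRUE,
                       seed = NULL, dt = 0.002) {
  variant <- match.arg(variant)
  p <- params
  stopifnot(inherits(p, "saw_params"), n_steps >= 1, tau >= 0, noise_sd >= 0)
  tau <- as.integer(tau)
  n_steps <- as.integer(n_steps)
  L <- p$L
  i0 <- as.integer((L + 1L) / 2L) # lattice centre (L is odd)
  n_sites <- L * L
  ivec <- rep(seq_len(L), times = L)
  jvec <- rep(seq_len(L), each = L)
  uvec <- p$L * (p$lambda_hor * ((ivec - i0) / i0)^2 +
                   p$lambda_ver * ((jvec - i0) / i0)^2)
  uu1 <- uvec + p$chi * p$L * ((ivec - i0) / i0)^2 * ((jvec - i0) / i0)^2
  post <- identical(p$trigger, "post-deposit")
  tol <- p$tie_tol
  eps <- p$epsilon
  hc <- p$h_c
  delayed_read <- variant %in% c("dr", "dar")   # readout around x(t - tau)
  delayed_set <- variant %in% c("da", "dar")    # activation setting at x(t - tau)
  delayed_field <- variant == "ds"              # readout of field state at t - tau
  random_prefix <- variant %in% c("dr", "dar", "ds")
  nsd <- if (noise_enabled) noise_sd else 0

  if (!is.null(seed)) set.seed(seed)
  h <- runif(n_sites)
  g <- 1
  total <- p$burn_in + n_steps
  zx <- rnorm(total)
  zy <- rnorm(total)
  ut <- runif(total)

  ci <- i0; cj <- i0
  use_ring <- tau > 0L
  if (use_ring) {
    pos_ring_i <- integer(tau); pos_ring_j <- integer(tau)
    inc_site <- rep(NA_integer_, tau); inc_amt <- numeric(tau)
    g_ring <- numeric(tau)
  }
  traj_i <- integer(n_steps); traj_j <- integer(n_steps)
  ev_step <- integer(0); ev_fi <- integer(0); ev_fj <- integer(0)
  ev_ti <- integer(0); ev_tj <- integer(0)
  trap_sites <- rep(-1L, 4L); trap_n <- 0L; trap_warned <- FALSE

  for (t in seq_len(total)) {
    if (g < 1e-150) { # keep the lazy scale in double range (rare)
      h <- h * g
      if (use_ring) { inc_amt <- inc_amt * g; g_ring <- g_ring / g }
      g <- 1
    }
    prefix <- t <= tau
    cur <- (cj - 1L) * L + ci
    r <- if (use_ring) ((t - 1L) %% tau) + 1L else 0L

    # noisy readout/setting offset for this iteration (one pair of draws)
    ndx <- as.integer(round(zx[[t]] * nsd))
    ndy <- as.integer(round(zy[[t]] * nsd))

    # where (and whether) this iteration deposits activation; the read-out
    # noise blurs the deposit position of the delayed-setting variants and,
    # symmetrically, of the delayed-state variant (whose deposits are the
    # quantity read with a delay)
    skip_set <- delayed_set && prefix
    if (delayed_set && !prefix) {
      bi <- if (use_ring) pos_ring_i[[r]] else ci
      bj <- if (use_ring) pos_ring_j[[r]] else cj
      set_site <- (min(max(bj + ndy, 1L), L) - 1L) * L + min(max(bi + ndx, 1L), L)
    } else if (delayed_field) {
      set_site <- (min(max(cj + ndy, 1L), L) - 1L) * L + min(max(ci + ndx, 1L), L)
    } else {
      set_site <- cur
    }
    site_now <- NA_integer_; amt_now <- 0
    if (post && !skip_set) {
      amt_now <- 1 / g
      site_now <- set_site
      h[[set_site]] <- h[[set_site]] + amt_now
    }

    # decision: microsaccade trigger. The position tested is always the
    # walker's current one (a delay-free, efference-copy-like position
    # signal); the activation value tested is the same field the variant
    # reads out, i.e. the delayed state for "ds" and the current state
    # otherwise. This keeps the delayed-state and delayed-setting variants
    # symmetric: both test a field that lacks the marks of the last tau
    # visits.
    trig_val <- if (delayed_field && use_ring && t > tau) {
      ds_delayed_value(h, cur, site_now, amt_now, inc_site, inc_amt, r,
                       g_ring[[r]], post, tau)
    } else {
      g * h[[cur]]
    }
    if (trig_val > hc) {
      tot_field <- g * h + uu1
      cand <- which(tot_field - min(tot_field) <= tol)
      pick <- tie_pick(cand, ut[[t]])
      ni <- ((pick - 1L) %% L) + 1L
      nj <- ((pick - 1L) %/% L) + 1L
      if (t > p$burn_in) {
        ev_step <- c(ev_step, t - p$burn_in)
        ev_fi <- c(ev_fi, ci); ev_fj <- c(ev_fj, cj)
        ev_ti <- c(ev_ti, ni); ev_tj <- c(ev_tj, nj)
      }
    } else if (prefix && random_prefix) {
      # delay buffers not yet primed: isotropic step among available sites
      ki <- ci + c(-1L, 1L, 0L, 0L); kj <- cj + c(0L, 0L, -1L, 1L)
      ok <- ki >= 1L & ki <= L & kj >= 1L & kj <= L
      ki <- ki[ok]; kj <- kj[ok]
      pick <- tie_pick(seq_along(ki), ut[[t]])
      ni <- ki[[pick]]; nj <- kj[[pick]]
    } else {
      # state readout: argmin of field + u over the neighbourhood of rc
      if (delayed_read) {
        bi <- if (use_ring) pos_ring_i[[r]] else ci
        bj <- if (use_ring) pos_ring_j[[r]] else cj
        rci <- min(max(bi + ndx, 1L), L); rcj <- min(max(bj + ndy, 1L), L)
      } else {
        rci <- ci; rcj <- cj
      }
      ki <- rci + c(-1L, 1L, 0L, 0L); kj <- rcj + c(0L, 0L, -1L, 1L)
      ok <- ki >= 1L & ki <= L & kj >= 1L & kj <= L
      ki <- ki[ok]; kj <- kj[ok]
      ss <- (kj - 1L) * L + ki
      if (delayed_field && use_ring && !prefix) {
        vals <- ds_delayed_value(h, ss, site_now, amt_now, inc_site, inc_amt,
                                 r, g_ring[[r]], post, tau) + uvec[ss]
      } else {
        vals <- g * h[ss] + uvec[ss]
      }
      cand <- which(vals - min(vals) <= tol)
      pick <- tie_pick(cand, ut[[t]])
      # the winning site defines a relative step applied at the true position
      ni <- min(max(ci + (ki[[pick]] - rci), 1L), L)
      nj <- min(max(cj + (kj[[pick]] - rcj), 1L), L)
    }

    if (!post && !skip_set) {
      amt_now <- 1 / g
      site_now <- set_site
      h[[set_site]] <- h[[set_site]] + amt_now
    }

    g_now <- g
    if (!(delayed_set && prefix)) g <- g * (1 - eps) # decay paused in DA/DAR prefix

    if (t > p$burn_in) {
      kk <- t - p$burn_in
      traj_i[[kk]] <- ci; traj_j[[kk]] <- cj
    }
    if (use_ring) {
      pos_ring_i[[r]] <- ci; pos_ring_j[[r]] <- cj
      inc_site[[r]] <- site_now; inc_amt[[r]] <- amt_now
      g_ring[[r]] <- g_now
    }

    # trapping diagnostic: persistent revisiting of a <= 4-site cycle
    nxt_site <- (nj - 1L) * L + ni
    if (nxt_site %in% trap_sites) {
      trap_n <- trap_n + 1L
      if (trap_n > 500L && !trap_warned) {
        warn(sprintf("walker trapped in a small cycle for > 500 iterations (%s, tau = %d)",
                     variant, tau),
             class = "femwalk_trapped")
        trap_warned <- TRUE
      }
    } else {
      trap_n <- 0L
    }
    trap_sites[[(t %% 4L) + 1L]] <- nxt_site

    ci <- ni; cj <- nj
  }

  times <- (seq_len(n_steps) - 1) * dt
  structure(
    list(
      trajectory = tibble(time = times, x = as.double(traj_i - i0),
                          y = as.double(traj_j - i0)),
      events = tibble(step = ev_step, time = (ev_step - 1) * dt,
                      from_x = as.double(ev_fi - i0), from_y = as.double(ev_fj - i0),
                      to_x = as.double(ev_ti - i0), to_y = as.double(ev_tj - i0)),
      params = p, variant = variant, tau = tau, noise_sd = nsd,
      noise_enabled = noise_enabled, seed = seed, dt = dt
    ),
    class = "saw_sim"
  )
}
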