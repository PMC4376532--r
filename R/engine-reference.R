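# Naive per-agent reference scheduler.
#
# A direct transcription of the four-phase generation loop, one agent at
# a time, used as the oracle against which the compiled engine is
# verified: both consume R's uniform stream through the same bounded
# integer draws and Fisher-Yates permutations, so given the same seed
# they must produce identical trajectories.

# one uniform draw -> integer in 1..n
rng_int <- function(n) {
  j <- floor(runif(1) * n)
  if (j >= n) j <- n - 1
  as.integer(j) + 1L
}

# Fisher-Yates permutation of 1..k, matching the compiled engine's
# draw order (positions k down to 2, swap with a draw in 1..i)
rng_perm <- function(k) {
  idx <- seq_len(k)
  if (k >= 2L) {
    for (i in seq.int(k, 2L)) {
      j <- rng_int(i)
      tmp <- idx[i]; idx[i] <- idx[j]; idx[j] <- tmp
    }
  }
  idx
}

reference_generation <- function(p0, c0, k, rails, it_p, it_c, init_dist,
                                 cap, eta, phi, mu, n_iter) {
  n <- length(p0)
  nf <- length(rails)
  x <- as.numeric(p0); y <- as.numeric(c0)
  FF <- exp(-mu * sqrt((it_p - x)^2 + (it_c - y)^2) / init_dist)
  status <- integer(n)          # 0 searching, 1 feeding, 2 displaced
  food <- rep(-1L, n); pos <- rep(-1L, n)
  beta_sum <- numeric(n)
  feed_events <- integer(n); displaced <- integer(n)
  c_init <- integer(n); c_inv <- integer(n); c_won <- integer(n)
  occ <- vector("list", nf)
  for (f in seq_len(nf)) occ[[f]] <- integer(0)

  geom <- function(i, f) {
    dx <- it_p - x[i]; dy <- it_c - y[i]
    dist <- sqrt(dx^2 + dy^2)
    if (dist > 0) {
      beta <- abs(atan2(dy, dx) - rails[f])
      a <- max(0, dist * cos(beta))
    } else {
      beta <- 0; a <- 0
    }
    c(beta, a)
  }

  iter <- 0L
  while (iter < n_iter) {
    # Choose Food
    searchers <- which(status == 0L)
    m <- length(searchers)
    if (m > 0L) {
      ord <- rng_perm(m)
      for (t in seq_len(m)) {
        s <- searchers[ord[t]]
        f <- rng_int(nf)
        if (length(occ[[f]]) < cap) {
          occ[[f]] <- c(occ[[f]], s)
          pos[s] <- length(occ[[f]])
          food[s] <- f
          status[s] <- 1L
        } else {
          oi <- rng_int(length(occ[[f]]))
          opp <- occ[[f]][oi]
          q <- 1 / (1 + exp(-eta * (FF[s] - FF[opp])))
          u <- runif(1)
          c_init[s] <- c_init[s] + 1L
          c_inv[s] <- c_inv[s] + 1L
          c_inv[opp] <- c_inv[opp] + 1L
          if (u < q) {
            c_won[s] <- c_won[s] + 1L
            occ[[f]][oi] <- s
            pos[s] <- oi
            food[s] <- f
            status[s] <- 1L
            status[opp] <- 2L
            food[opp] <- -1L
            pos[opp] <- -1L
            displaced[opp] <- displaced[opp] + 1L
          } else {
            c_won[opp] <- c_won[opp] + 1L
            status[s] <- 2L
            displaced[s] <- displaced[s] + 1L
          }
        }
      }
    }

    # Eat
    for (i in seq_len(n)) {
      if (status[i] != 1L) next
      ba <- geom(i, food[i])
      d <- min(ba[2], phi)
      x[i] <- x[i] + d * cos(rails[food[i]])
      y[i] <- y[i] + d * sin(rails[food[i]])
      beta_sum[i] <- beta_sum[i] + ba[1]
      feed_events[i] <- feed_events[i] + 1L
    }

    # Calculate Fitness
    for (i in seq_len(n)) {
      FF[i] <- exp(-mu * sqrt((it_p - x[i])^2 + (it_c - y[i])^2) / init_dist)
    }

    # Leave
    for (i in seq_len(n)) {
      if (status[i] == 2L) {
        status[i] <- 0L
      } else if (status[i] == 1L) {
        ba <- geom(i, food[i])
        pl <- (1 - k[i]) * ba[1] / (pi / 2) + max(0, (k[i] * phi - ba[2]) / phi)
        pl <- min(1, max(0, pl))
        u <- runif(1)
        if (u < pl) {
          f <- food[i]
          pi_ <- pos[i]
          last <- length(occ[[f]])
          if (pi_ != last) {
            occ[[f]][pi_] <- occ[[f]][last]
            pos[occ[[f]][pi_]] <- pi_
          }
          occ[[f]] <- occ[[f]][-last]
          status[i] <- 0L
          food[i] <- -1L
          pos[i] <- -1L
        }
      }
    }

    iter <- iter + 1L
    stopifnot(sum(status == 1L) + sum(status == 0L) + sum(status == 2L) == n)
  }

  list(p = x, c = y, fitness = FF, feed_events = feed_events,
       beta_sum = beta_sum, iterations_displaced = displaced,
       contests_initiated = c_init, contests_involved = c_inv,
       contests_won = c_won, n_iterations = iter,
       arrivals = integer(0), aborted = FALSE)
}
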