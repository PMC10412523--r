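# Independent I-DT oracle: for every window start it finds the maximal end
# whose ALL-PAIRS angular dispersion (recomputed from scratch in degrees)
# stays at or below the threshold, using galloping + binary search over the
# monotone window extension; accepted windows are split greedily. This
# shares no code with the package's incremental cosine-space kernel.
oracle_idt <- function(t, x, thr_deg, min_dur = 0.1, max_dur = 0.5,
                       split = TRUE) {
  n <- length(t)
  disp_deg <- function(i, j) {
    a <- x[i:j, , drop = FALSE]
    cc <- a %*% t(a)
    max(acos(pmin(pmax(cc, -1), 1))) * 180 / pi
  }
  max_end <- function(i) {
    if (i + 1 > n || disp_deg(i, i + 1) > thr_deg) return(i)
    e <- i + 1
    step <- 1
    while (e + step <= n && disp_deg(i, e + step) <= thr_deg) {
      e <- e + step
      step <- 2 * step
    }
    lo <- e
    hi <- min(n, e + step - 1)
    while (lo < hi) {
      m <- (lo + hi + 1) %/% 2
      if (disp_deg(i, m) <= thr_deg) lo <- m else hi <- m - 1
    }
    lo
  }
  out <- list()
  i <- 1
  while (i < n) {
    e <- max_end(i)
    if (e > i && t[e] - t[i] >= min_dur) {
      if (!split || t[e] - t[i] <= max_dur) {
        out[[length(out) + 1]] <- c(i, e)
      } else {
        s <- i
        while (s <= e) {
          m <- s
          while (m + 1 <= e && t[m + 1] - t[s] <= max_dur) m <- m + 1
          if (t[m] - t[s] >= min_dur) out[[length(out) + 1]] <- c(s, m)
          s <- m + 1
        }
      }
      i <- e + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_t = numeric(), end_t = numeric(),
      n_samples = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(
    start_t = t[m[, 1]], end_t = t[m[, 2]],
    n_samples = m[, 2] - m[, 1] + 1L
  )
}

# random gaze trace: piecewise-constant plateaus with per-sample jitter and
# occasional large jumps; spread scales chosen so windows open and close
# near the 1-degree threshold
random_trace <- function(seed, n = 300, hz = 120) {
  withr::with_seed(seed, {
    t <- seq(0, by = 1 / hz, length.out = n)
    az <- el <- numeric(n)
    cur_az <- runif(1, -20, 20)
    cur_el <- runif(1, -10, 10)
    jit <- runif(1, 0.05, 0.6)
    for (i in seq_len(n)) {
      if (runif(1) < 0.02) { # saccade-like jump
        cur_az <- cur_az + sample(c(-1, 1), 1) * runif(1, 2, 25)
        cur_el <- cur_el + rnorm(1, 0, 3)
        jit <- runif(1, 0.05, 0.6)
      }
      az[i] <- cur_az + rnorm(1, 0, jit)
      el[i] <- cur_el + rnorm(1, 0, jit)
    }
    azr <- az * pi / 180
    elr <- el * pi / 180
    x <- cbind(cos(azr) * cos(elr), sin(azr) * cos(elr), sin(elr))
    list(t = t, x = x)
  })
}

as_gaze <- function(t, x, valid = TRUE) {
  tibble::tibble(
    t = t, gx = x[, 1], gy = x[, 2], gz = x[, 3],
    hx = 0, hy = 0, hz = 0, valid = valid
  )
}

# unit direction at the given azimuth/elevation (degrees)
dir_az <- function(az_deg, el_deg = 0) {
  a <- az_deg * pi / 180
  e <- el_deg * pi / 180
  c(cos(a) * cos(e), sin(a) * cos(e), sin(e))
}
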