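# Shared fixtures built in code.

# exactly four-piece linear TVC whose knots lie on the sample grid
make_exact_tvc <- function(n = 60, rr = 150, edv = 60, esv = 15,
                           fr = c(0.1, 0.3, 0.2, 0.4)) {
  b <- cumsum(fr) * rr
  times <- (0:(n - 1)) / n * rr
  knot_t <- c(0, b[1], b[2], b[3], rr)
  knot_v <- c(edv, edv, esv, esv, edv)
  v <- approx(knot_t, knot_v, xout = times)$y
  time_volume_curve(times, v, rr = rr)
}

# 12-point strain-time fixture used by the index oracle tests: a negative
# (circumferential-like) curve peaking at cycle fraction 4/12 with a small
# pre-shortening stretch and post-systolic accentuation
strain_fixture <- function() {
  list(times = (0:11) / 12,
       strain = c(0, 1.2, -6, -12, -17.5, -16, -18.2, -11, -6, -3.5, -1.8, -0.6),
       end_systole = 4 / 12)
}

# brute-force strain-index oracle: plain loops, no shared code with the
# implementation beyond the index definitions
oracle_strain_indices <- function(e, t, es_time) {
  n <- length(e)
  ipk <- 1
  for (i in 2:n) if (abs(e[i]) > abs(e[ipk])) ipk <- i
  s <- if (e[ipk] >= 0) 1 else -1
  emax <- abs(e[ipk])
  tpeak <- t[ipk]
  sys <- which(t <= es_time)
  post <- which(t > es_time)
  es <- NA
  for (i in sys) if (is.na(es) || s * e[i] > s * es) es <- e[i]
  ees <- approx(t, e, xout = es_time)$y
  epost <- ees
  for (i in post) if (s * e[i] > s * epost) epost <- e[i]
  psi <- (epost - ees) / emax
  ss <- 0
  for (i in sys) if (-s * e[i] > ss) ss <- -s * e[i]
  rate <- numeric(n)
  for (i in 1:n) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    rate[i] <- (e[hi] - e[lo]) / (t[hi] - t[lo])
  }
  srmax <- NA
  for (i in sys) if (is.na(srmax) || s * rate[i] > s * srmax) srmax <- rate[i]
  mid <- es_time + (1 - es_time) / 2
  sre <- NA; sra <- NA
  for (i in post) {
    if (t[i] <= mid) {
      if (is.na(sre) || -s * rate[i] > -s * sre) sre <- rate[i]
    } else {
      if (is.na(sra) || -s * rate[i] > -s * sra) sra <- rate[i]
    }
  }
  list(es = es, ees = ees, epost = epost, emax = emax, psi = psi,
       tpeak = tpeak, srmax = srmax, sre = sre, sra = sra,
       sre_a = sre / sra, ss = ss)
}

# place two filled disks in a matrix (centres as (row, col))
two_disk_mask <- function(size = 80, centres = list(c(25, 25), c(25, 55)),
                          r = 5) {
  m <- matrix(0L, size, size)
  for (ct in centres) {
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    m[(rows - ct[1])^2 + (cols - ct[2])^2 <= r^2] <- 1L
  }
  m
}
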