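# Fixture builders and independent brute-force oracles shared across tests.
# Oracles are deliberately naive (explicit loops) so they cannot share a bug
# with the vectorised implementations they check.

T0 <- as.POSIXct("2019-03-04 00:00:00", tz = "UTC")   # a Monday

make_epochs <- function(enmo, wear = TRUE, sleep = NA, el = 5, start = T0) {
  epoch_series(time = start + (seq_along(enmo) - 1) * el, enmo = enmo,
               wear = wear, sleep = sleep, epoch_length = el)
}

# one full civil day of epochs at a given epoch length
make_day <- function(enmo, wear = TRUE, el = 5, start = T0) {
  n <- 86400 / el
  stopifnot(length(enmo) == n || length(enmo) == 1)
  make_epochs(rep_len(enmo, n), wear = rep_len(wear, n), el = el, start = start)
}

random_day <- function(seed, el = 300) {
  set.seed(seed)
  n <- 86400 / el
  enmo <- stats::rexp(n, rate = 1 / 0.05) * stats::rbinom(n, 1, 0.6)
  wear <- stats::runif(n) > 0.1
  make_epochs(enmo, wear = wear, el = el)
}

# --- oracles ----------------------------------------------------------------

# run-length scan for bouted MVPA, one epoch at a time
oracle_bouted <- function(enmo, wear, el = 5, min_bout = 10, moderate = 0.1) {
  is_mvpa <- wear & enmo >= moderate
  total <- 0L; run <- 0L
  for (i in seq_along(is_mvpa)) {
    if (is_mvpa[i]) {
      run <- run + 1L
    } else {
      if (run * el >= min_bout * 60) total <- total + run
      run <- 0L
    }
  }
  if (run * el >= min_bout * 60) total <- total + run
  total * el / 60
}

# exhaustive evaluation of every start epoch for the most active window
oracle_window <- function(x, wlen) {
  best <- -Inf; best_start <- NA_integer_
  for (s in 1:(length(x) - wlen + 1)) {
    v <- 0
    for (j in s:(s + wlen - 1)) v <- v + x[j]
    if (v > best + 1e-12) { best <- v; best_start <- s }
  }
  list(start = best_start, value = best)
}

# brute-force 30-s (3-point) rolling-mean maximum
oracle_peak_vo2 <- function(x) {
  best <- -Inf
  for (s in 1:(length(x) - 2)) {
    best <- max(best, (x[s] + x[s + 1] + x[s + 2]) / 3)
  }
  best
}

# per-epoch tally of class minutes (wear epochs only)
oracle_class_minutes <- function(enmo, wear, el = 5,
                                 cuts = c(0.03, 0.1, 0.4)) {
  mins <- c(sedentary = 0, LPA = 0, MPA = 0, VPA = 0)
  for (i in seq_along(enmo)) {
    if (!wear[i]) next
    k <- if (enmo[i] < cuts[1]) 1 else if (enmo[i] < cuts[2]) 2
         else if (enmo[i] < cuts[3]) 3 else 4
    mins[k] <- mins[k] + el / 60
  }
  mins
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- n * (n + m + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
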