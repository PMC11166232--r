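# Independent direct-summation oracles, deliberately written in plain R
# against the definitions, for cross-checking the package implementations.

oracle_F <- function(w, smin = 0, smax = 100) {
  m <- length(w)
  s <- sign(diff(w))
  breaks <- 1L
  dir <- 0L
  for (i in seq_len(m - 1)) {
    if (s[i] != 0) {
      if (dir != 0 && s[i] != dir) breaks <- c(breaks, i)
      dir <- s[i]
    }
  }
  breaks <- c(breaks, m)
  total <- 0
  for (k in seq_len(length(breaks) - 1)) {
    a <- breaks[k]
    b <- breaks[k + 1]
    total <- total + abs(w[b] - w[a]) / (b - a)
  }
  total / ((smax - smin) * (m - 1))
}

oracle_D <- function(w, smin = 0, smax = 100) {
  m <- length(w)
  y <- sort(w)
  d <- (smax - smin) / (m - 1)
  deficit <- 0
  total <- 0
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      ideal <- (j - i) * d
      total <- total + ideal
      deficit <- deficit + max(0, ideal - (y[j] - y[i]))
    }
  }
  1 - deficit / total
}

# exhaustive split scan for the mean change point, naive segment means
oracle_cp_mean_day <- function(x) {
  n <- length(x)
  sse <- function(seg) sum((seg - mean(seg))^2)
  best <- Inf
  bestk <- NA_integer_
  for (k in 2:n) {
    cost <- sse(x[1:(k - 1)]) + sse(x[k:n])
    if (cost < best - 1e-9) {
      best <- cost
      bestk <- k
    }
  }
  bestk
}

# exhaustive split scan for the trend change point using lm() per segment
oracle_cp_trend_day <- function(x) {
  n <- length(x)
  sse_line <- function(idx) {
    if (length(idx) <= 2) return(0)
    fit <- stats::lm(x[idx] ~ idx)
    sum(stats::resid(fit)^2)
  }
  best <- Inf
  bestk <- NA_integer_
  for (k in 3:(n - 1)) {
    cost <- sse_line(1:(k - 1)) + sse_line(k:n)
    if (cost < best - 1e-9) {
      best <- cost
      bestk <- k
    }
  }
  bestk
}

# small item-level series straight from a values matrix
make_series <- function(values, schema = NULL, case_id = "t") {
  if (is.null(schema)) {
    items <- rownames(values)
    schema <- tpq_schema(stats::setNames(as.list(items), items))
  }
  process_series(case_id, seq_len(ncol(values)), values,
                 matrix(FALSE, nrow(values), ncol(values)), schema, "item")
}
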