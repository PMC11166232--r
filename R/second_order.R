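#' Parameters for delay embedding and recurrence plots
#'
#' @param embed_dim embedding dimension m (>= 1); each embedded point is a
#'   snippet of `embed_dim` values.
#' @param delay_tau embedding delay in days (>= 1).
#' @param target_rr target recurrence rate; the distance threshold epsilon
#'   is set to this quantile of all pairwise embedded distances, which makes
#'   the recurrence structure comparable across channels with different
#'   variances.
#' @return An object of class `recurrence_params`.
#' @export
recurrence_params <- function(embed_dim = 3, delay_tau = 1, target_rr = 0.10) {
  stopifnot(embed_dim >= 1, delay_tau >= 1, target_rr > 0, target_rr < 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 delay_tau = as.integer(delay_tau),
                 norm = "euclidean", epsilon_rule = "fixed_recurrence_rate",
                 target_rr = target_rr),
            class = "recurrence_params")
}

#' Delay embedding of a channel
#'
#' Maps a scalar series into state-space vectors
#' `(x_t, x_{t+tau}, ..., x_{t+(m-1)tau})`.
#'
#' @param x numeric vector of length n.
#' @param params a [recurrence_params()].
#' @return A matrix with `n - (m - 1) * tau` rows (one embedded vector per
#'   row) and `m` columns.
#' @examples
#' delay_embed(1:10, recurrence_params(embed_dim = 3, delay_tau = 1))
#' @export
delay_embed <- function(x, params = recurrence_params()) {
  m <- params$embed_dim
  tau <- params$delay_tau
  n <- length(x)
  k <- n - (m - 1) * tau
  if (k < 1) stop("series too short for embedding dimension ", m,
                  " with delay ", tau)
  idx <- outer(seq_len(k), (seq_len(m) - 1) * tau, "+")
  matrix(x[idx], nrow = k, ncol = m)
}

#' Recurrence matrix of embedded vectors
#'
#' `R[i, j] = 1` iff the euclidean distance between embedded points i and j
#' is at most epsilon, where epsilon is the `target_rr` quantile of all
#' pairwise distances. The matrix is symmetric with a unit diagonal. If all
#' embedded points coincide the distance distribution is degenerate; an
#' all-ones matrix is returned with `degenerate = TRUE` and a warning.
#'
#' @param vectors matrix of embedded vectors (rows), e.g. [delay_embed()].
#' @param params a [recurrence_params()].
#' @return An object of class `recurrence_matrix`: binary `matrix`,
#'   realized `epsilon`, `recurrence_rate` (proportion of off-diagonal
#'   ones) and `degenerate` flag.
#' @export
recurrence_matrix <- function(vectors, params = recurrence_params()) {
  if (!is.matrix(vectors)) vectors <- matrix(vectors, ncol = 1)
  n <- nrow(vectors)
  if (n < 2) stop("need at least 2 embedded vectors")
  d <- stats::dist(vectors)
  degenerate <- FALSE
  if (max(d) == 0) {
    warning("all embedded vectors identical; returning all-ones recurrence matrix")
    degenerate <- TRUE
    eps <- 0
    R <- matrix(1L, n, n)
  } else {
    eps <- stats::quantile(d, params$target_rr, names = FALSE)
    R <- as.matrix(d) <= eps
    storage.mode(R) <- "integer"
    diag(R) <- 1L
  }
  rr <- (sum(R) - n) / (n * (n - 1))
  structure(list(matrix = R, epsilon = eps, recurrence_rate = rr,
                 degenerate = degenerate, params = params),
            class = "recurrence_matrix")
}

#' Time-frequency distribution of a channel
#'
#' Windowed periodogram: for each day `t >= window_w` the right-aligned
#' window is mean-removed and discrete-Fourier transformed; the squared
#' magnitude at each positive frequency bin `omega_k = k / window_w`
#' cycles/day (k = 1..floor(window_w / 2)) is stored as `P(t, omega_k)`.
#' The first `window_w - 1` columns are `NA`.
#'
#' @param x numeric channel (no missing values).
#' @param window_w window width in days (>= 4).
#' @return An object of class `tfd_matrix`: `values` (frequencies x days),
#'   `frequencies` (cycles/day) and `window_w`.
#' @export
tfd_matrix <- function(x, window_w = 7) {
  if (window_w < 4) stop("window_w must be >= 4")
  n <- length(x)
  if (n < window_w) stop("channel shorter than the window")
  if (anyNA(x)) stop("impute the channel first")
  nfreq <- window_w %/% 2
  vals <- matrix(NA_real_, nfreq, n)
  for (t in window_w:n) {
    w <- x[(t - window_w + 1):t]
    w <- w - mean(w)
    sp <- stats::fft(w)
    vals[, t] <- Mod(sp[2:(nfreq + 1)])^2
  }
  structure(list(values = vals, frequencies = seq_len(nfreq) / window_w,
                 window_w = as.integer(window_w)),
            class = "tfd_matrix")
}
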