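# Linear prediction: Levinson-Durbin recursion, line spectral frequencies.

#' Solve the Yule-Walker equations by Levinson-Durbin recursion
#'
#' Fits the order-`p` linear predictor `xhat(n) = sum_k a_k x(n - k)` that
#' minimizes the mean squared prediction error for a process with the given
#' autocorrelation sequence. Identical (to numerical precision) to a direct
#' solve of the Yule-Walker linear system.
#'
#' @param autocorr Autocorrelation values `r_0..r_p` (length at least
#'   `order + 1`); `r_0` must be positive.
#' @param order Prediction order `p`.
#' @return An `lp_model`: list with `order`, `coefficients` (the predictor
#'   coefficients `a_1..a_p`), `gain` (final prediction-error energy) and
#'   `reflection` (reflection coefficients `k_1..k_p`).
#' @export
levinson_durbin <- function(autocorr, order) {
  r <- as.numeric(autocorr)
  if (length(r) < order + 1L) abort("need r_0..r_p: autocorr too short")
  if (!all(is.finite(r))) abort("autocorrelation must be finite")
  if (r[1] <= 0) abort("r_0 must be positive")
  a <- numeric(order)        # error-filter coefficients (A(z) = 1 + sum a_k z^-k)
  k_all <- numeric(order)
  e <- r[1]
  for (m in seq_len(order)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc + sum(a[seq_len(m - 1L)] * r[m:2])
    if (e <= 0) abort("singular Yule-Walker system: prediction error collapsed to zero")
    k <- -acc / e
    k_all[m] <- k
    if (m > 1L) {
      a[seq_len(m - 1L)] <- a[seq_len(m - 1L)] + k * rev(a[seq_len(m - 1L)])
    }
    a[m] <- k
    e <- e * (1 - k^2)
  }
  structure(
    list(order = order, coefficients = -a, gain = e, reflection = k_all),
    class = "lp_model"
  )
}

#' Is a linear-prediction model stable?
#'
#' Stability (all roots of the error filter strictly inside the unit circle)
#' is equivalent to all reflection coefficients having magnitude below 1.
#'
#' @param model An `lp_model`.
#' @param tol Margin from the unit circle.
#' @return Logical.
#' @export
lp_is_stable <- function(model, tol = 1e-9) {
  if (!is.null(model$reflection)) {
    return(all(abs(model$reflection) < 1 - tol))
  }
  # A as a polynomial in u = z^-1 (increasing powers); stable iff all roots
  # in u lie strictly outside the unit circle
  roots <- polyroot(c(1, -model$coefficients))
  all(Mod(roots) > 1 + tol)
}

#' Convert a linear-prediction model to line spectral frequencies
#'
#' Forms the palindromic and anti-palindromic polynomials
#' `P(z) = A(z) + z^-(p+1) A(z^-1)` and `Q(z) = A(z) - z^-(p+1) A(z^-1)`
#' from the prediction-error filter `A(z)`, and returns the sorted angles of
#' their upper-half-plane unit-circle roots, excluding the trivial roots at
#' 0 and pi. For a stable model the P- and Q-angles strictly interleave.
#'
#' @param model A stable `lp_model`.
#' @param tol Tolerance for unit-circle residence of the roots.
#' @return An `lsf_vector`: numeric vector of `p` strictly increasing angles
#'   in (0, pi), with attribute `"source"` marking whether each angle is a
#'   root of `"P"` or `"Q"`.
#' @export
lp_to_lsf <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "lp_model"))
  if (!lp_is_stable(model)) {
    abort("unstable LP model: LSF interlacing is not guaranteed")
  }
  p <- model$order
  a_pad <- c(1, -model$coefficients, 0)   # A(z) coefficients, padded to p+2
  P <- a_pad + rev(a_pad)
  Q <- a_pad - rev(a_pad)

  angles_of <- function(coefs) {
    # coefs in increasing powers of u = z^-1; the root sets of the
    # (anti)palindromic polynomials are invariant under u -> 1/u, so the
    # angle set is the same in z and z^-1
    if (length(coefs) < 2L) return(numeric(0))
    roots <- polyroot(coefs)
    bad <- abs(Mod(roots) - 1) > tol
    if (any(bad)) {
      abort(sprintf("LSF root off the unit circle by %.2e", max(abs(Mod(roots) - 1))))
    }
    ang <- Arg(roots)
    ang <- ang[ang > tol & ang < pi - tol]
    sort(ang)
  }

  ap <- angles_of(P)
  aq <- angles_of(Q)
  ord <- order(c(ap, aq))
  freqs <- c(ap, aq)[ord]
  src <- c(rep("P", length(ap)), rep("Q", length(aq)))[ord]
  if (length(freqs) != p) {
    abort(sprintf("expected %d line spectral frequencies, found %d", p, length(freqs)))
  }
  structure(freqs, source = src, class = "lsf_vector")
}

# Biased autocorrelation r_0..r_lag of one frame.
frame_autocorr <- function(x, max_lag) {
  n <- length(x)
  vapply(0:max_lag, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / n
  }, numeric(1))
}

#' Compute line-spectral-frequency frame features
#'
#' Per 25 ms Hamming frame: biased autocorrelation, order-`order` linear
#' prediction via [levinson_durbin], conversion to line spectral frequencies
#' via [lp_to_lsf]. Frames yielding unstable or degenerate models (e.g.
#' silence) are excluded from the output and recorded in the `"excluded"`
#' attribute.
#'
#' @param clip An [audio_clip] of at least 25 ms.
#' @param order Linear-prediction order (default 12).
#' @param grid Analysis [frame_grid].
#' @param verbose Report excluded frames with a message.
#' @return A `frame_features` matrix (`n_valid_frames x order`, kind
#'   `"LSF"`) of angles in (0, pi).
#' @export
compute_lsf_features <- function(clip, order = 12L, grid = frame_grid(),
                                 verbose = FALSE) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) < grid$window_length) {
    abort("clip is shorter than one analysis window (25 ms)")
  }
  frames <- frame_signal(clip, grid)
  rows <- vector("list", nrow(frames))
  excluded <- integer(0)
  for (i in seq_len(nrow(frames))) {
    lsf <- tryCatch({
      r <- frame_autocorr(frames[i, ], order)
      as.numeric(lp_to_lsf(levinson_durbin(r, order)))
    }, error = function(e) NULL)
    if (is.null(lsf)) excluded <- c(excluded, i) else rows[[i]] <- lsf
  }
  if (length(excluded) && verbose) {
    inform(sprintf("excluded %d unstable/degenerate frame(s): %s",
                   length(excluded), paste(excluded, collapse = ", ")))
  }
  valid <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(valid)) abort("no frame yielded a stable LP model")
  out <- do.call(rbind, valid)
  colnames(out) <- paste0("lsf", seq_len(order))
  frame_features(out, kind = "LSF", grid = grid, rate = clip$rate,
                 excluded = excluded)
}
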