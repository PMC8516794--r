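#' Spherical-spline channel interpolation
#'
#' Replaces bad channels by Perrin-style spherical-spline estimates computed
#' from the good channels' signals and unit-sphere electrode positions
#' (spline order `m = 4`, Legendre series truncated at `n_terms`). Good
#' channels are untouched; the spline reproduces constants exactly.
#'
#' @param rec An `eeg_recording`.
#' @param bad Labels to interpolate; empty input returns `rec` unchanged.
#' @param coords Tibble with `label`, `x`, `y`, `z` on the unit sphere
#'   (default [ceegrid_coords()]).
#' @param m Spline stiffness order.
#' @param n_terms Legendre series length.
#' @param reg Ridge regularization added to the spline system.
#' @return The `eeg_recording` with `bad` channels replaced.
#' @export
interpolate_spherical <- function(rec, bad, coords = ceegrid_coords(rec$labels),
                                  m = 4, n_terms = 7, reg = 1e-8) {
  if (length(bad) == 0) return(rec)
  good <- setdiff(rec$labels, bad)
  if (length(good) < 4) abort("need at least 4 good channels to interpolate.")
  if (!all(c(good, bad) %in% coords$label)) {
    abort("missing electrode coordinates for some channels.")
  }
  pos <- as.matrix(coords[match(rec$labels, coords$label), c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))

  gi <- match(good, rec$labels); bi <- match(bad, rec$labels)
  cosang <- function(a, b) pmin(1, pmax(-1, tcrossprod(pos[a, , drop = FALSE],
                                                       pos[b, , drop = FALSE])))
  G <- g_spline(cosang(gi, gi), m, n_terms)
  Gb <- g_spline(cosang(bi, gi), m, n_terms)

  ng <- length(gi)
  A <- rbind(cbind(G + reg * diag(ng), rep(1, ng)), c(rep(1, ng), 0))
  rhs <- rbind(rec$eeg[gi, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  cvec <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1, ]
  rec$eeg[bi, ] <- Gb %*% cvec + matrix(c0, length(bi), ncol(rec$eeg),
                                        byrow = TRUE)
  rec
}

# Perrin spherical-spline kernel g(cos angle): sum over Legendre degrees n of
# (2n+1) / (n (n+1))^m * P_n(x) / (4 pi)
g_spline <- function(x, m = 4, n_terms = 7) {
  dims <- dim(x)
  x <- as.numeric(x)
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  if (n_terms > 1) {
    for (n in 2:n_terms) {
      p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
      p_prev <- p_cur; p_cur <- p_next
    }
  }
  out <- acc / (4 * pi)
  dim(out) <- dims
  out
}
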