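# Non-negative least squares via the Lawson-Hanson active-set method,
# formulated on the normal equations. For the Tikhonov system the Gram
# matrix K'K + alpha^2 L'L is formed once per regularization parameter
# from cached K'K and L'L, which makes scans across alpha cheap.

# Solve min ||A x - b||^2 s.t. x >= 0 given AtA = A'A and Atb = A'b.
# Deterministic; returns the exact KKT point of the strictly convex QP
# (AtA positive definite for any alpha > 0).
nnls_normal <- function(AtA, Atb, tol = NULL) {
  n <- length(Atb)
  if (is.null(tol)) tol <- 1e-10 * max(abs(Atb), 1)
  x <- numeric(n)
  passive <- logical(n)
  w <- Atb                       # gradient of -0.5 objective at x = 0
  iter <- 0L
  max_iter <- 30L * n
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) stop("NNLS did not converge")
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      idx <- which(passive)
      s <- tryCatch(
        solve(AtA[idx, idx, drop = FALSE], Atb[idx]),
        error = function(e) qr.solve(AtA[idx, idx, drop = FALSE], Atb[idx]))
      if (all(s > 0)) {
        x[] <- 0; x[idx] <- s
        break
      }
      neg <- s <= 0
      step <- min(x[idx][neg] / (x[idx][neg] - s[neg]))
      x[idx] <- x[idx] + step * (s - x[idx])
      passive[idx[x[idx] <= tol * max(x, 1)]] <- FALSE
      x[!passive] <- 0
    }
    w <- Atb - as.vector(AtA %*% x)
  }
  x
}
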