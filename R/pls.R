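# Uncentered PLS2 (NIPALS with per-component SVD weights, regression mode).
#
# The cold-start model is a strictly linear map H = F B: an all-zero feature
# row must score zero and scaling features must scale scores. An intercept
# (implied by the usual centering step) would break both properties, so the
# decomposition is run on the raw matrices. With ncomp equal to the column
# rank of X the coefficients coincide with the no-intercept least-squares
# solution; with fewer components they give the usual PLS shrinkage.
pls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop_invalid("X and Y must have the same rows.")
  p <- ncol(X); q <- ncol(Y)
  ncomp <- min(ncomp, p, nrow(X))
  if (ncomp < 1) stop_invalid("PLS needs at least one component.")
  Wm <- matrix(0, p, ncomp)
  Pm <- matrix(0, p, ncomp)
  Qm <- matrix(0, q, ncomp)
  Xd <- X; Yd <- Y
  a <- 0
  for (comp in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)
    if (max(abs(M)) < 1e-12) break
    w <- svd(M, nu = 1, nv = 0)$u[, 1]
    tt <- Xd %*% w
    ss <- sum(tt * tt)
    if (ss < 1e-12) break
    pp <- crossprod(Xd, tt) / ss
    qq <- crossprod(Yd, tt) / ss
    Xd <- Xd - tt %*% t(pp)
    Yd <- Yd - tt %*% t(qq)
    a <- comp
    Wm[, a] <- w; Pm[, a] <- pp; Qm[, a] <- qq
  }
  if (a == 0) {
    stop_numerical("PLS failed: X'Y carries no signal (all-zero cross-product).")
  }
  Wm <- Wm[, seq_len(a), drop = FALSE]
  Pm <- Pm[, seq_len(a), drop = FALSE]
  Qm <- Qm[, seq_len(a), drop = FALSE]
  R <- tryCatch(solve(crossprod(Pm, Wm), t(Qm)),
                error = function(e) NULL)
  if (is.null(R)) stop_numerical("PLS coefficient system is singular.")
  B <- Wm %*% R
  dimnames(B) <- list(colnames(X), colnames(Y))
  list(B = B, ncomp = a)
}
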