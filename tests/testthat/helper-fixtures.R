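# Shared fixtures and independent oracles used across the suite.

# Small long-format panel from a participants x weeks matrix of values
# (rows named by participant, columns by gestational week).
panel_from_matrix <- function(values) {
  data.frame(
    participant_id = rep(rownames(values), each = ncol(values)),
    gestational_week = rep(as.integer(colnames(values)), times = nrow(values)),
    stress = as.integer(t(values)),
    stringsAsFactors = FALSE
  )
}

# Complete constant-free toy panel on the full grid: n participants with
# seeded random 0-6 values.
random_complete_panel <- function(n, seed = 1) {
  set.seed(seed)
  v <- matrix(sample(0:6, n * 27, replace = TRUE), n, 27,
              dimnames = list(sprintf("P%04d", seq_len(n)), 15:41))
  panel_from_matrix(v)
}

# Exact minimizer of sum (y - b0 - x b)^2 + lambda * sum w_j |b_j| for
# small p, by enumerating all 3^p sign patterns and solving each KKT
# system: the independent oracle for the coordinate-descent solver.
lasso_sign_oracle <- function(x, y, w, lambda) {
  x <- as.matrix(x)
  p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), p)))
  best <- NULL
  best_obj <- Inf
  for (r in seq_len(nrow(patterns))) {
    s <- patterns[r, ]
    A <- which(s != 0)
    if (any(!is.finite(w[A]))) next
    b <- rep(0, p)
    if (length(A)) {
      XA <- xc[, A, drop = FALSE]
      rhs <- crossprod(XA, yc) - lambda * w[A] * s[A] / 2
      bA <- tryCatch(drop(solve(crossprod(XA), rhs)), error = function(e) NULL)
      if (is.null(bA) || any(sign(bA) != s[A])) next
      b[A] <- bA
    }
    res <- yc - xc %*% b
    Z <- which(s == 0)
    if (length(Z)) {
      grad0 <- abs(2 * drop(crossprod(xc[, Z, drop = FALSE], res)))
      if (any(grad0 > lambda * w[Z] + 1e-8)) next
    }
    obj <- sum(res^2) + lambda * sum(w[A] * abs(b[A]))
    if (obj < best_obj) {
      best_obj <- obj
      best <- b
    }
  }
  list(beta = best, intercept = mean(y) - drop(colMeans(x) %*% best),
       objective = best_obj)
}

# Adaptive-LASSO objective as written: RSS + lambda * sum w |beta|.
alasso_objective <- function(x, y, intercept, beta, w, lambda) {
  pen <- w * abs(beta)
  sum((y - intercept - as.matrix(x) %*% beta)^2) + lambda * sum(pen[beta != 0])
}

# Centered orthonormal design (columns orthonormal and orthogonal to the
# intercept), for the closed-form soft-threshold solution.
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- scale(matrix(rnorm(n * p), n, p), center = TRUE, scale = FALSE)
  q <- qr.Q(qr(x))
  colnames(q) <- paste0("q", seq_len(p))
  q
}
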