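# Independent oracles and tiny builders shared across the test files.
# Oracles deliberately avoid the package's own code paths.

# brute-force Euclidean distance (in px) from each vessel pixel to the
# nearest background pixel
edt_brute <- function(pixels) {
  bg <- which(pixels == 0, arr.ind = TRUE)
  out <- matrix(0, nrow(pixels), ncol(pixels))
  fg <- which(pixels != 0, arr.ind = TRUE)
  if (nrow(bg) == 0) return(out)
  for (r in seq_len(nrow(fg))) {
    out[fg[r, 1], fg[r, 2]] <-
      sqrt(min((bg[, 1] - fg[r, 1])^2 + (bg[, 2] - fg[r, 2])^2))
  }
  out
}

# dense finite-difference solve of the steady AF equation on a 1D grid,
# assembled entry-by-entry in flux form: interior fluxes (af_{i+1}-af_i)/h
# between neighbours, zero flux through the ends
af_oracle_1d <- function(phi, cvec, p, h) {
  n <- length(phi)
  H <- as.numeric(cvec > 0)
  A <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in c(i - 1, i + 1)) {
      if (j < 1 || j > n) next   # boundary: no flux through the wall
      A[i, j] <- A[i, j] - p$D_af / h^2
      A[i, i] <- A[i, i] + p$D_af / h^2
    }
    A[i, i] <- A[i, i] + p$V_uc * H[i] + p$V_d
  }
  b <- p$V_pT * phi * (1 - H)
  solve(A, b)
}

# small 2D domain with nodes roughly n x n
tiny_domain <- function(n = 16, h = 0.01) {
  sim_domain(rep((n - 1) * h, 2), h = h, dim = 2)
}

# smooth blob initial phase field (tanh disk), values in (-1, 1)
blob_field <- function(domain, center = NULL, radius = NULL, width = NULL) {
  if (is.null(center)) center <- domain$origin + domain$extent / 2
  if (is.null(radius)) radius <- min(domain$extent) / 4
  if (is.null(width)) width <- 2 * domain$h
  ax <- grid_axes(domain)
  r <- sqrt(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`))
  tanh((radius - r) / width)
}

# 8-connected component labelling by flood fill
label_components <- function(pixels) {
  lab <- matrix(0L, nrow(pixels), ncol(pixels))
  nxt <- 0L
  n1 <- nrow(pixels); n2 <- ncol(pixels)
  for (start in which(pixels != 0 & lab == 0)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      i <- (q - 1) %% n1 + 1
      j <- (q - 1) %/% n1 + 1
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n1 || jj < 1 || jj > n2) next
        qq <- (jj - 1) * n1 + ii
        if (pixels[qq] != 0 && lab[qq] == 0) {
          lab[qq] <- nxt
          queue <- c(queue, qq)
        }
      }
    }
  }
  lab
}

expect_rel_equal <- function(actual, expected, rtol = 1e-8) {
  expect_lt(abs(actual - expected), rtol * max(abs(expected), 1e-300))
}
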