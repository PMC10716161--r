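# Independent oracles and small-problem builders shared across tests.

# brute-force non-uniform DFT: (1/N) sum_n x[n] exp(-2i pi k . n),
# n centered at the matrix center -- the reference for the gridding NUFFT
nudft_forward <- function(img, kc) {
  N <- nrow(img)
  nctr <- (0:(N - 1)) - N %/% 2
  vapply(seq_len(nrow(kc)), function(s) {
    e1 <- exp(-2i * pi * kc[s, 1] * nctr)
    e2 <- exp(-2i * pi * kc[s, 2] * nctr)
    sum(img * outer(e1, e2)) / N
  }, complex(1))
}

# flatten a trajectory's kcoords the way nufft_plan does (spoke-major,
# readout fastest)
traj_kc <- function(tr) {
  cbind(as.vector(t(tr$kcoords[, , 1])), as.vector(t(tr$kcoords[, , 2])))
}

# naive windowed SSIM, straight from the definition (double loop over
# window positions; independent of the package's separable filtering)
naive_ssim <- function(x, y, size = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  stopifnot(all(dim(x) == dim(y)))
  peak <- max(x)
  x <- x / peak; y <- y / peak
  g <- outer(seq_len(size) - (size + 1) / 2, seq_len(size) - (size + 1) / 2,
             function(a, b) exp(-(a^2 + b^2) / (2 * sigma^2)))
  g <- g / sum(g)
  C1 <- K1^2; C2 <- K2^2
  nr <- nrow(x) - size + 1; nc <- ncol(x) - size + 1
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      wx <- x[i:(i + size - 1), j:(j + size - 1)]
      wy <- y[i:(i + size - 1), j:(j + size - 1)]
      mx <- sum(g * wx); my <- sum(g * wy)
      vx <- sum(g * wx^2) - mx^2; vy <- sum(g * wy^2) - my^2
      cxy <- sum(g * wx * wy) - mx * my
      vals[i, j] <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
        ((mx^2 + my^2 + C1) * (vx + vy + C2))
    }
  }
  mean(vals)
}

# term-by-term naive evaluation of the five-term objective
naive_objective <- function(dd, op, L, S, w) {
  r <- enc_forward(op, L + S)$data - dd
  term_data <- 0.5 * sum(Mod(r)^2)
  term_nuc <- w$lambda_L * sum(svd(matrix(L, prod(dim(L)[1:2]), dim(L)[3]))$d)
  term_tv <- if (dim(S)[3] > 1) {
    nt <- dim(S)[3]
    w$lambda_s * sum(Mod(S[, , 2:nt, drop = FALSE] - S[, , 1:(nt - 1), drop = FALSE]))
  } else 0
  term_fl <- w$lambda_L_psi * sum(Mod(framelet_analysis(L)))
  term_fs <- w$lambda_S_psi * sum(Mod(framelet_analysis(S)))
  list(total = term_data + term_nuc + term_tv + term_fl + term_fs,
       data = term_data, nuc = term_nuc, tv = term_tv, fl = term_fl, fs = term_fs)
}

rand_cplx <- function(dims, sd = 1) {
  array(complex(real = stats::rnorm(prod(dims), sd = sd),
                imaginary = stats::rnorm(prod(dims), sd = sd)), dim = dims)
}

# small radial problem: operator + smooth-ish truth + data
toy_problem <- function(N = 16, spf = 4, fpg = 3, n_coils = 3, seed = 1) {
  set.seed(seed)
  tr <- make_trajectory(trajectory_config(N), group_scheme(spf, fpg))
  sens <- simulate_coilmaps(n_coils, N)
  op <- encoding_operator(sens, tr)
  truth <- array(0, c(N, N, fpg))
  truth[(N %/% 4):(3 * N %/% 4), (N %/% 4):(3 * N %/% 4), ] <- 1
  truth[N %/% 2, N %/% 2, seq(2, fpg)] <- 0.2
  truth <- truth + 0i
  list(op = op, truth = truth, d = enc_forward(op, truth), tr = tr)
}
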