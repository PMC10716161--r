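# tiny shared instance: 8x8, 2 frames, 2 coils
tiny_net_problem <- function(seed = 3) {
  set.seed(seed)
  N <- 8; nt <- 2
  tr <- make_trajectory(trajectory_config(N), group_scheme(3, nt))
  op <- encoding_operator(simulate_coilmaps(2, N), tr)
  truth <- rand_cplx(c(N, N, nt), sd = 0.3)
  list(op = op, truth = truth, d = enc_forward(op, truth), N = N, nt = nt)
}

test_that("network construction is deterministic and counts parameters by the closed form", {
  p <- tiny_net_problem()
  cfg <- net_config(n_blocks = 3, n_conv_layers = 2, n_features = 4, seed = 2)
  n1 <- build_net(cfg, p$op, p$d)
  n2 <- build_net(cfg, p$op, p$d)
  expect_identical(n1$par, n2$par)

  K <- 27; F <- 4; nc <- 2
  ana <- (K * 2 * F + F) + (nc - 1) * (K * F * F + F)
  syn <- (nc - 1) * (K * F * F + F) + (K * F * 2 + 2)
  expect_equal(net_n_params(n1), 3 * (6 + 2 * ana + 2 * syn))

  # channel contract: first analysis layer carries 2 input channels,
  # last synthesis layer emits 2
  expect_equal(dim(n1$par$b1.AL1.W), c(K * 2, F))
  expect_equal(dim(n1$par[[paste0("b1.SL", nc, ".W")]]), c(K * F, 2))
})

test_that("zeroed transforms and thresholds reduce the net to data-consistency gradient steps", {
  p <- tiny_net_problem(4)
  cfg <- net_config(n_blocks = 3, n_conv_layers = 2, n_features = 4, seed = 2)
  net <- build_net(cfg, p$op, p$d)
  for (nm in names(net$par)) {
    if (grepl("\\.(W|b)$", nm)) net$par[[nm]] <- net$par[[nm]] * 0
    if (grepl("(tau|thL|thS|tht)$", nm)) net$par[[nm]] <- 0
  }
  fw <- net_forward(net, p$d, p$op)
  L <- enc_adjoint(p$op, p$d$data)$frames
  S <- L * 0
  for (b in 1:3) {
    gam <- net$par[[paste0("b", b, ".gamma")]]
    g <- enc_adjoint(p$op, enc_forward(p$op, L + S)$data - p$d$data)$frames
    L <- L - gam * g; S <- S - gam * g
  }
  expect_lt(max(abs(fw$L - L)), 1e-12)
  expect_lt(max(abs(fw$S - S)), 1e-12)
})

test_that("forward pass is deterministic, additive in L + S, and zero for zero data", {
  p <- tiny_net_problem(5)
  net <- build_net(net_config(2, 2, 3, seed = 9), p$op, p$d)
  f1 <- net_forward(net, p$d, p$op)
  f2 <- net_forward(net, p$d, p$op)
  expect_identical(f1$L, f2$L)
  expect_identical(f1$S, f2$S)
  expect_equal(f1$x$frames, f1$L + f1$S)

  d0 <- p$d; d0$data <- d0$data * 0
  f0 <- net_forward(net, d0, p$op)
  expect_equal(max(abs(f0$x$frames)), 0)

  # mismatched trajectory is rejected
  tr2 <- make_trajectory(trajectory_config(8), group_scheme(2, 2))
  op2 <- encoding_operator(simulate_coilmaps(2, 8), tr2)
  expect_error(net_forward(net, p$d, op2), "match")
})

test_that("a 2-block net with Haar-frozen transforms reproduces 2 classical iterations", {
  p <- toy_problem(N = 16, spf = 4, fpg = 3, n_coils = 3, seed = 44)
  sol <- lsfp_reconstruct(p$d, p$op, lsfp_params(max_iter = 2, tol = 0))
  dg <- sol$diagnostics
  net <- build_net(net_config(n_blocks = 2, n_conv_layers = 1,
                              transforms = "haar", seed = 1))
  for (b in 1:2) {
    pb <- paste0("b", b, ".")
    net$par[[paste0(pb, "gamma")]] <- dg$gamma
    net$par[[paste0(pb, "lam")]] <- dg$lam
    net$par[[paste0(pb, "tau")]] <- dg$gamma * dg$weights$L
    net$par[[paste0(pb, "thL")]] <- (dg$gamma / dg$lam) * dg$weights$Lpsi
    net$par[[paste0(pb, "thS")]] <- (dg$gamma / dg$lam) * dg$weights$Spsi
    net$par[[paste0(pb, "tht")]] <- (dg$gamma / dg$lam) * dg$weights$s
  }
  fw <- net_forward(net, p$d, p$op)
  scale <- max(abs(sol$x$frames))
  expect_lt(max(abs(fw$L - sol$L)) / scale, 1e-5)
  expect_lt(max(abs(fw$S - sol$S)) / scale, 1e-5)
})

test_that("analytic gradients agree with numerical gradients on a tiny instance", {
  p <- tiny_net_problem(3)
  net <- build_net(net_config(2, 2, 3, seed = 5), p$op, p$d)
  # jitter all parameters so the check sits away from ReLU/soft-threshold
  # kinks (the zero-bias initialization is exactly at one)
  set.seed(99)
  for (nm in names(net$par)) {
    net$par[[nm]] <- net$par[[nm]] +
      stats::rnorm(length(net$par[[nm]]), sd = 0.01)
  }
  lg <- net_loss_grad(net, p$d, p$truth, p$op)
  set.seed(11)
  nms <- names(net$par)
  checked <- 0
  for (k in sample(seq_along(nms), 10)) {
    nm <- nms[k]
    j <- sample(length(net$par[[nm]]), 1)
    eps <- 1e-6 * max(abs(net$par[[nm]][j]), 1e-3)
    np <- net; np$par[[nm]][j] <- np$par[[nm]][j] + eps
    nmm <- net; nmm$par[[nm]][j] <- nmm$par[[nm]][j] - eps
    gn <- (net_loss_grad(np, p$d, p$truth, p$op)$loss -
             net_loss_grad(nmm, p$d, p$truth, p$op)$loss) / (2 * eps)
    ga <- lg$grads[[nm]][j]
    denom <- max(abs(gn), abs(ga))
    if (denom < 1e-8) next  # both zero up to finite-difference noise
    expect_lt(abs(gn - ga) / denom, 1e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
})

test_that("training runs, checkpoints, and aborts on non-finite losses", {
  p <- tiny_net_problem(6)
  d2 <- enc_forward(p$op, p$truth * 0.5)
  ds <- list(list(d = p$d, truth = p$truth),
             list(d = d2, truth = p$truth * 0.5))
  net <- build_net(net_config(1, 2, 2, seed = 3), p$op, p$d)
  ck <- tempfile(fileext = ".rds")
  res <- net_train(net, ds, train_config(lr = 1e-4, epochs = 1), p$op,
                   val = ds[1], checkpoint_path = ck)
  expect_equal(nrow(res$history), 1)
  expect_true(file.exists(ck))
  reloaded <- net_load_checkpoint(ck)
  f1 <- net_forward(res$net, p$d, p$op)
  f2 <- net_forward(reloaded, p$d, p$op)
  expect_equal(f1$x$frames, f2$x$frames)

  # blowing up the primal step produces a non-finite loss -> named abort
  bad <- net
  bad$par$b1.gamma <- 1e200
  expect_error(net_train(bad, ds, train_config(lr = 1e-4, epochs = 1), p$op),
               "sample 1")
})
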