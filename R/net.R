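## Unrolled LSFP network.
##
## Each block is structurally one primal-dual fixed-point iteration of
## the LSFP model, with the fixed framelet analysis/synthesis pair
## replaced by four independent 3D-convolutional stacks (learned
## analysis and synthesis transforms for L and for S) and per-block
## learnable scalars: the primal and dual step sizes, the singular-value
## threshold of the exact SVT, and the three soft-threshold levels. The
## nuclear prox is kept exact (SVT) with a learnable threshold.
##
## No autodiff framework is used: forward passes record a tape of
## intermediates and the backward pass applies hand-derived adjoints
## (conv3d via im2col/col2im, complex soft-threshold Jacobian, and SVT
## differentiated through the Hermitian matrix function
## SVT(M) = M h(M^H M)). The numerical-gradient test pins correctness.

#' Network architecture configuration
#'
#' @param n_blocks Number of unrolled blocks (iterations), N_b.
#' @param n_conv_layers Layers per transform stack, N_c.
#' @param n_features Hidden channels (default 32); the first analysis
#'   layer takes 2 channels (real, imaginary) and the last synthesis
#'   layer emits 2.
#' @param kernel Spatial-temporal kernel size (default `c(3, 3, 3)`).
#' @param transforms `"conv"` (learned, default) or `"haar"` (transforms
#'   frozen to the framelet frame; only the scalars remain learnable).
#' @param seed Initialization seed.
#' @return Object of class `net_config`.
#' @export
net_config <- function(n_blocks = 3, n_conv_layers = 3, n_features = 32,
                       kernel = c(3, 3, 3), transforms = c("conv", "haar"),
                       seed = 1) {
  transforms <- match.arg(transforms)
  stopifnot(n_blocks >= 1, n_conv_layers >= 1, n_features >= 1,
            length(kernel) == 3, all(kernel %% 2 == 1))
  structure(list(n_blocks = as.integer(n_blocks),
                 n_conv_layers = as.integer(n_conv_layers),
                 n_features = as.integer(n_features),
                 kernel = as.integer(kernel), transforms = transforms,
                 seed = as.integer(seed)),
            class = "net_config")
}

#' Training configuration (Adam)
#'
#' Defaults follow the standard unrolled-reconstruction recipe:
#' `beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`, learning rate 1e-4,
#' batch size 1.
#'
#' @param lr Learning rate.
#' @param beta1,beta2,epsilon Adam constants.
#' @param batch_size Batch size (only 1 is implemented).
#' @param epochs Training epochs.
#' @param loss `"mse"` (complex mean squared error, real + imaginary).
#' @param lr_schedule `"constant"` (default) or `"cosine"` (cosine decay
#'   of the learning rate to zero over the epochs; helps the batch-1
#'   optimizer settle once progress becomes gradient-noise limited).
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, batch_size = 1, epochs = 10,
                         loss = "mse", lr_schedule = c("constant", "cosine")) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(lr > 0, batch_size == 1, epochs >= 1, loss == "mse")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 lr_schedule = lr_schedule),
            class = "train_config")
}

## ---- conv3d via im2col ------------------------------------------------

# linear gather indices: voxel-major (dim order fastest first), one
# column per kernel tap, into the zero-padded single-channel volume
.im2col_idx <- function(d, kd) {
  dp <- as.integer(d + kd - 1L)
  i <- seq_len(d[1]); j <- seq_len(d[2]); t <- seq_len(d[3])
  base <- outer(outer(as.integer(i), as.integer((j - 1L) * dp[1]), `+`),
                as.integer((t - 1L) * dp[1] * dp[2]), `+`)
  storage.mode(base) <- "integer"
  base <- as.vector(base)
  taps <- as.vector(outer(outer(0:(kd[1] - 1L), (0:(kd[2] - 1L)) * dp[1], `+`),
                          (0:(kd[3] - 1L)) * dp[1] * dp[2], `+`))
  taps <- as.integer(taps)
  idx <- outer(base, taps, `+`)
  storage.mode(idx) <- "integer"
  list(idx = as.vector(idx), dp = dp,
       center = base + taps[(length(taps) + 1L) %/% 2L],
       nvox = prod(d), ntap = length(taps))
}

# flip kernel taps and swap channel roles: adjoint of the zero-padded
# 'same' correlation is correlation with the flipped kernel
.flip_w <- function(W, ntap) {
  cin <- nrow(W) / ntap
  cout <- ncol(W)
  a <- array(W, dim = c(ntap, cin, cout))
  a <- a[rev(seq_len(ntap)), , , drop = FALSE]
  matrix(aperm(a, c(1, 3, 2)), ntap * cout, cin)
}

.conv3d_fwd <- function(X, W, b, ii) {
  cpp_conv3d_fwd(X, ii$idx, ii$center, prod(ii$dp), W, b)
}

# conv stack with ReLU between layers (none after the last); caches the
# layer inputs for the backward pass
.stack_fwd <- function(X, layers, ii) {
  nl <- length(layers)
  cache <- vector("list", nl)
  for (l in seq_len(nl)) {
    cache[[l]] <- list(X = X)
    X <- .conv3d_fwd(X, layers[[l]]$W, layers[[l]]$b, ii)
    if (l < nl) {
      mask <- X > 0
      X <- X * mask
      cache[[l]]$relu_mask <- mask
    }
  }
  list(out = X, cache = cache)
}

.stack_bwd <- function(gY, layers, cache, ii) {
  nl <- length(layers)
  npad <- prod(ii$dp)
  g <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    if (l < nl) gY <- gY * cache[[l]]$relu_mask
    g[[l]] <- list(gW = cpp_conv3d_gw(cache[[l]]$X, ii$idx, ii$center, npad, gY),
                   gb = colSums(gY))
    gY <- cpp_conv3d_fwd(gY, ii$idx, ii$center, npad,
                         .flip_w(layers[[l]]$W, ii$ntap),
                         numeric(ncol(cache[[l]]$X)))
  }
  list(gX = gY, glayers = g)
}

## ---- prox forward/backward -------------------------------------------

# SVT through the Hermitian route: O = M h(M^H M), h(x) = max(1 - tau/sqrt(x), 0)
.svt_fwd <- function(M, tau) {
  W <- crossprod(Conj(M), M)
  if (!all(is.finite(Re(W)))) {
    # overflow upstream (e.g. a diverging step size): propagate the
    # non-finite values so training aborts with a named sample
    return(list(out = M * NaN, M = M, V = NULL, lam = NULL, sg = NULL,
                h = NULL, tau = tau, Z = NULL))
  }
  e <- eigen(W, symmetric = TRUE)
  lam <- pmax(Re(e$values), 0)
  sg <- sqrt(lam)
  h <- ifelse(sg > tau, 1 - tau / pmax(sg, 1e-300), 0)
  V <- e$vectors
  Z <- V %*% (h * Conj(t(V)))
  list(out = M %*% Z, M = M, V = V, lam = lam, sg = sg, h = h, tau = tau, Z = Z)
}

.svt_bwd <- function(G, cc) {
  V <- cc$V; lam <- cc$lam; sg <- cc$sg; h <- cc$h; tau <- cc$tau; M <- cc$M
  gZ <- crossprod(Conj(M), G)
  gZ <- (gZ + Conj(t(gZ))) / 2
  A <- Conj(t(V)) %*% gZ %*% V
  f <- length(lam)
  hp <- ifelse(sg > tau, tau / (2 * pmax(sg, 1e-300)^3), 0)
  K <- matrix(0, f, f)
  for (i in seq_len(f)) for (j in seq_len(f)) {
    dl <- lam[i] - lam[j]
    K[i, j] <- if (abs(dl) > 1e-9 * max(lam[1], 1)) (h[i] - h[j]) / dl else hp[i]
  }
  gW <- V %*% (K * A) %*% Conj(t(V))
  gM <- G %*% cc$Z + 2 * (M %*% gW)
  dh_dtau <- ifelse(sg > tau, -1 / pmax(sg, 1e-300), 0)
  dO_dtau <- M %*% (V %*% (dh_dtau * Conj(t(V))))
  gtau <- sum(Re(Conj(G) * dO_dtau))
  list(gM = gM, gtau = gtau)
}

# complex soft threshold with tape
.softc_fwd <- function(z, tau) {
  a <- abs(z)
  act <- a > tau
  scl <- 1 - tau / pmax(a, 1e-300)
  scl[!act] <- 0
  list(out = z * scl, z = z, a = a, act = act, tau = tau)
}

.softc_bwd <- function(g, cc) {
  a <- pmax(cc$a, 1e-300)
  u <- cc$z / a
  gin <- ifelse(cc$act, (1 - cc$tau / (2 * a)) * g + (cc$tau * u^2 / (2 * a)) * Conj(g), 0)
  gtau <- -sum(Re(Conj(g) * u)[cc$act])
  list(gin = gin, gtau = gtau)
}

# real soft threshold (conv-feature duals)
.softr_fwd <- function(z, tau) {
  act <- abs(z) > tau
  list(out = ifelse(act, z - tau * sign(z), 0), z = z, act = act, tau = tau)
}

.softr_bwd <- function(g, cc) {
  list(gin = g * cc$act, gtau = -sum((sign(cc$z) * g)[cc$act]))
}

## ---- network construction --------------------------------------------

.stack_shapes <- function(cfg, kind) {
  # channel progression for one transform stack
  nc <- cfg$n_conv_layers
  F <- cfg$n_features
  chans <- if (kind == "analysis") c(2, rep(F, nc)) else c(rep(F, nc), 2)
  lapply(seq_len(nc), function(l) c(cin = chans[l], cout = chans[l + 1]))
}

.init_stack <- function(cfg, kind) {
  K <- prod(cfg$kernel)
  lapply(.stack_shapes(cfg, kind), function(sh) {
    sd <- sqrt(2 / (K * sh["cin"]))
    list(W = matrix(stats::rnorm(K * sh["cin"] * sh["cout"], sd = sd),
                    K * sh["cin"], sh["cout"]),
         b = numeric(sh["cout"]))
  })
}

#' Build an unrolled LSFP network
#'
#' Scalars default to the solver's auto-set steps when an encoding
#' operator and a representative k-space group are supplied (the
#' data-scaled thresholds the classical solver would use); otherwise
#' generic small values. Conv weights are He-initialized from
#' `cfg$seed`, so two builds with the same seed are bit-identical.
#'
#' @param cfg A [net_config()].
#' @param op Optional [encoding_operator()] for step-size defaults.
#' @param ref_kspace Optional `kspace_group` for data-scaled threshold
#'   defaults.
#' @return Object of class `lsfp_net` with `cfg` and flat parameter list
#'   `par`.
#' @export
build_net <- function(cfg, op = NULL, ref_kspace = NULL) {
  stopifnot(inherits(cfg, "net_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  gamma0 <- 0.5; lam0 <- 0.2; tau0 <- 1e-3; th0 <- 1e-3
  if (!is.null(op)) {
    Esq <- enc_norm_sq(op)
    gamma0 <- 0.9 / (2 * Esq)
    lam0 <- 1 / .b_norm_sq(op$scheme$fpg)
    if (!is.null(ref_kspace)) {
      dd <- if (inherits(ref_kspace, "kspace_group")) ref_kspace$data else ref_kspace
      scl <- max(abs(enc_adjoint(op, dd)$frames))
      tau0 <- gamma0 * 0.01 * scl
      th0 <- (gamma0 / lam0) * 0.005 * scl
    }
  }
  par <- list()
  for (b in seq_len(cfg$n_blocks)) {
    p <- paste0("b", b, ".")
    par[[paste0(p, "gamma")]] <- gamma0
    par[[paste0(p, "lam")]] <- lam0
    par[[paste0(p, "tau")]] <- tau0
    par[[paste0(p, "thL")]] <- th0
    par[[paste0(p, "thS")]] <- th0
    par[[paste0(p, "tht")]] <- th0
    if (cfg$transforms == "conv") {
      for (nm in c("AL", "AS")) {
        st <- .init_stack(cfg, "analysis")
        for (l in seq_along(st)) {
          par[[paste0(p, nm, l, ".W")]] <- st[[l]]$W
          par[[paste0(p, nm, l, ".b")]] <- st[[l]]$b
        }
      }
      for (nm in c("SL", "SS")) {
        st <- .init_stack(cfg, "synthesis")
        for (l in seq_along(st)) {
          par[[paste0(p, nm, l, ".W")]] <- st[[l]]$W
          par[[paste0(p, nm, l, ".b")]] <- st[[l]]$b
        }
      }
    }
  }
  structure(list(cfg = cfg, par = par), class = "lsfp_net")
}

#' Number of learnable parameters of a network
#'
#' @param net An `lsfp_net`.
#' @return Integer count.
#' @export
net_n_params <- function(net) {
  sum(vapply(net$par, length, integer(1)))
}

.get_stack <- function(par, b, nm, nl) {
  lapply(seq_len(nl), function(l) {
    list(W = par[[paste0("b", b, ".", nm, l, ".W")]],
         b = par[[paste0("b", b, ".", nm, l, ".b")]])
  })
}

# complex image (N,N,nt) <-> feature matrix (nvox, C)
.c2m <- function(z) cbind(Re(as.vector(z)), Im(as.vector(z)))
.m2c <- function(m, dims) array(m[, 1] + 1i * m[, 2], dim = dims)

## ---- forward ----------------------------------------------------------

#' Run the unrolled network on one k-space group
#'
#' Deterministic given parameters and input; the reconstruction is
#' exactly `L + S`. Initialization matches the classical solver:
#' `L = E^H d`, `S = 0`, all duals zero.
#'
#' @param net An `lsfp_net` from [build_net()].
#' @param d A `kspace_group` (or bare data array).
#' @param op The [encoding_operator()] matching the trajectory the net
#'   was configured for.
#' @param with_tape Keep intermediates for [net_backward()] (internal).
#' @return List with `L`, `S`, `x` (an [image_group()]); with a tape
#'   attached when requested.
#' @export
net_forward <- function(net, d, op, with_tape = FALSE) {
  cfg <- net$cfg
  dd <- if (inherits(d, "kspace_group")) d$data else d
  N <- op$N; nt <- op$scheme$fpg
  if (dim(dd)[2] != op$scheme$spokes_per_group) {
    stop("k-space group shape does not match the operator's trajectory")
  }
  dims <- c(N, N, nt)
  ii <- if (cfg$transforms == "conv") .im2col_idx(dims, cfg$kernel) else NULL
  L <- enc_adjoint(op, dd)$frames
  S <- array(0i, dim = dims)
  conv <- cfg$transforms == "conv"
  vL <- if (conv) matrix(0, prod(dims), cfg$n_features) else array(0i, c(dims, 4))
  vS <- vL
  vt <- array(0i, dim = c(N, N, max(nt - 1, 0)))
  tape <- vector("list", cfg$n_blocks)
  nl <- cfg$n_conv_layers
  for (b in seq_len(cfg$n_blocks)) {
    par <- net$par
    pg <- function(nm) par[[paste0("b", b, ".", nm)]]
    gamma <- pg("gamma"); lam <- pg("lam"); tau <- pg("tau")
    tb <- list(L = L, S = S, vL = vL, vS = vS, vt = vt)
    x <- L + S
    r <- enc_forward(op, x)$data - dd
    g <- enc_adjoint(op, r)$frames
    Lb <- L - gamma * g; Sb <- S - gamma * g
    if (conv) {
      SLs <- .get_stack(par, b, "SL", nl); SSs <- .get_stack(par, b, "SS", nl)
      ALs <- .get_stack(par, b, "AL", nl); ASs <- .get_stack(par, b, "AS", nl)
      f5 <- .stack_fwd(vL, SLs, ii); pL <- .m2c(f5$out, dims)
      f6 <- .stack_fwd(vS, SSs, ii); pS <- .m2c(f6$out, dims)
    } else {
      pL <- framelet_synthesis(vL)
      pS <- framelet_synthesis(vS)
    }
    qS <- temporal_diff_adjoint(vt, nt)
    ML <- .casorati(Lb - lam * pL)
    s8 <- .svt_fwd(ML, tau)
    yL <- array(s8$out, dim = dims)
    yS <- Sb - lam * (pS + qS)
    if (conv) {
      f10 <- .stack_fwd(.c2m(yL), ALs, ii); aL <- f10$out
      f11 <- .stack_fwd(.c2m(yS), ASs, ii); aS <- f11$out
      uL <- aL + vL; uS <- aS + vS
      sL <- .softr_fwd(uL, pg("thL")); vL2 <- uL - sL$out
      sS <- .softr_fwd(uS, pg("thS")); vS2 <- uS - sS$out
    } else {
      aL <- framelet_analysis(yL); aS <- framelet_analysis(yS)
      uL <- aL + vL; uS <- aS + vS
      sL <- .softc_fwd(uL, pg("thL")); vL2 <- uL - sL$out
      sS <- .softc_fwd(uS, pg("thS")); vS2 <- uS - sS$out
    }
    at <- temporal_diff(yS); ut <- at + vt
    st <- .softc_fwd(ut, pg("tht")); vt2 <- ut - st$out
    if (conv) {
      f13 <- .stack_fwd(vL2, SLs, ii); pL2 <- .m2c(f13$out, dims)
      f14 <- .stack_fwd(vS2, SSs, ii); pS2 <- .m2c(f14$out, dims)
    } else {
      pL2 <- framelet_synthesis(vL2)
      pS2 <- framelet_synthesis(vS2)
    }
    ML2 <- .casorati(Lb - lam * pL2)
    s13 <- .svt_fwd(ML2, tau)
    Lout <- array(s13$out, dim = dims)
    qS2 <- temporal_diff_adjoint(vt2, nt)
    Sout <- Sb - lam * (pS2 + qS2)
    if (with_tape) {
      tb <- c(tb, list(g = g, pL = pL, pS = pS, qS = qS, s8 = s8, yL = yL,
                       yS = yS, uL = uL, uS = uS, ut = ut, sL = sL, sS = sS,
                       st = st, vL2 = vL2, vS2 = vS2, vt2 = vt2, pL2 = pL2,
                       pS2 = pS2, qS2 = qS2, s13 = s13,
                       gamma = gamma, lam = lam))
      if (conv) tb <- c(tb, list(f5 = f5, f6 = f6, f10 = f10, f11 = f11,
                                 f13 = f13, f14 = f14))
      tape[[b]] <- tb
    }
    L <- Lout; S <- Sout; vL <- vL2; vS <- vS2; vt <- vt2
  }
  out <- list(L = L, S = S, x = image_group(L + S))
  if (with_tape) {
    out$tape <- tape
    out$ii <- ii
    out$dims <- dims
  }
  out
}

## ---- backward ----------------------------------------------------------

.cdot <- function(g, x) sum(Re(Conj(g) * x))

#' Backpropagate a loss gradient through the network
#'
#' @param net An `lsfp_net`.
#' @param fwd Output of `net_forward(..., with_tape = TRUE)`.
#' @param gL,gS Complex cotangents of the output L and S components.
#' @param op The encoding operator used in the forward pass.
#' @return Flat named list of parameter gradients (same names as
#'   `net$par`).
#' @export
net_backward <- function(net, fwd, gL, gS, op) {
  cfg <- net$cfg
  conv <- cfg$transforms == "conv"
  nl <- cfg$n_conv_layers
  dims <- fwd$dims; nt <- dims[3]
  ii <- fwd$ii
  grads <- lapply(net$par, function(p) if (is.matrix(p)) p * 0 else p * 0)
  zerovd <- if (conv) matrix(0, prod(dims), cfg$n_features) else array(0i, c(dims, 4))
  gvL <- zerovd; gvS <- zerovd
  gvt <- array(0i, dim = c(dims[1], dims[2], max(nt - 1, 0)))
  acc <- function(nm, val) grads[[nm]] <<- grads[[nm]] + val
  for (b in rev(seq_len(cfg$n_blocks))) {
    tb <- fwd$tape[[b]]
    p <- paste0("b", b, ".")
    gamma <- tb$gamma; lam <- tb$lam
    par <- net$par
    if (conv) {
      SLs <- .get_stack(par, b, "SL", nl); SSs <- .get_stack(par, b, "SS", nl)
      ALs <- .get_stack(par, b, "AL", nl); ASs <- .get_stack(par, b, "AS", nl)
    }
    add_stack <- function(nm, glayers) {
      for (l in seq_len(nl)) {
        acc(paste0(p, nm, l, ".W"), glayers[[l]]$gW)
        acc(paste0(p, nm, l, ".b"), glayers[[l]]$gb)
      }
    }
    # step 14: Sout = Sb - lam * (pS2 + qS2)
    gSb <- gS
    gpS2 <- -lam * gS
    gqS2 <- -lam * gS
    acc(paste0(p, "lam"), -.cdot(gS, tb$pS2 + tb$qS2))
    # incoming cotangents of this block's output duals (next block's inputs)
    gvt2 <- gvt + temporal_diff(gqS2)
    if (conv) {
      bw <- .stack_bwd(.c2m(gpS2), SSs, tb$f14$cache, ii)
      add_stack("SS", bw$glayers)
      gvS2 <- gvS + bw$gX
    } else {
      gvS2 <- gvS + framelet_analysis(gpS2)
    }
    # step 13: Lout = SVT(casorati(Lb - lam*pL2), tau)
    sb <- .svt_bwd(.casorati(gL), tb$s13)
    acc(paste0(p, "tau"), sb$gtau)
    gML2 <- array(sb$gM, dim = dims)
    gLb <- gML2
    gpL2 <- -lam * gML2
    acc(paste0(p, "lam"), -.cdot(gML2, tb$pL2))
    if (conv) {
      bw <- .stack_bwd(.c2m(gpL2), SLs, tb$f13$cache, ii)
      add_stack("SL", bw$glayers)
      gvL2 <- gvL + bw$gX
    } else {
      gvL2 <- gvL + framelet_analysis(gpL2)
    }
    # step 12: vt2 = ut - softc(ut, tht)
    sbw <- .softc_bwd(gvt2, tb$st)
    gut <- gvt2 - sbw$gin
    acc(paste0(p, "tht"), -sbw$gtau)
    gvt_in <- gut
    gyS <- temporal_diff_adjoint(gut, nt)
    # step 11: vS2 = uS - soft(uS, thS)
    if (conv) {
      sbw <- .softr_bwd(gvS2, tb$sS)
      guS <- gvS2 - sbw$gin
    } else {
      sbw <- .softc_bwd(gvS2, tb$sS)
      guS <- gvS2 - sbw$gin
    }
    acc(paste0(p, "thS"), -sbw$gtau)
    gvS_in <- guS
    if (conv) {
      bw <- .stack_bwd(guS, ASs, tb$f11$cache, ii)
      add_stack("AS", bw$glayers)
      gyS <- gyS + .m2c(bw$gX, dims)
    } else {
      gyS <- gyS + framelet_synthesis(guS)
    }
    # step 10: vL2 = uL - soft(uL, thL)
    if (conv) {
      sbw <- .softr_bwd(gvL2, tb$sL)
      guL <- gvL2 - sbw$gin
    } else {
      sbw <- .softc_bwd(gvL2, tb$sL)
      guL <- gvL2 - sbw$gin
    }
    acc(paste0(p, "thL"), -sbw$gtau)
    gvL_in <- guL
    if (conv) {
      bw <- .stack_bwd(guL, ALs, tb$f10$cache, ii)
      add_stack("AL", bw$glayers)
      gyL <- .m2c(bw$gX, dims)
    } else {
      gyL <- framelet_synthesis(guL)
    }
    # step 9: yS = Sb - lam * (pS + qS)
    gSb <- gSb + gyS
    gpS <- -lam * gyS
    gqS <- -lam * gyS
    acc(paste0(p, "lam"), -.cdot(gyS, tb$pS + tb$qS))
    gvt_in <- gvt_in + temporal_diff(gqS)
    if (conv) {
      bw <- .stack_bwd(.c2m(gpS), SSs, tb$f6$cache, ii)
      add_stack("SS", bw$glayers)
      gvS_in <- gvS_in + bw$gX
    } else {
      gvS_in <- gvS_in + framelet_analysis(gpS)
    }
    # step 8: yL = SVT(casorati(Lb - lam*pL), tau)
    sb <- .svt_bwd(.casorati(gyL), tb$s8)
    acc(paste0(p, "tau"), sb$gtau)
    gML <- array(sb$gM, dim = dims)
    gLb <- gLb + gML
    gpL <- -lam * gML
    acc(paste0(p, "lam"), -.cdot(gML, tb$pL))
    if (conv) {
      bw <- .stack_bwd(.c2m(gpL), SLs, tb$f5$cache, ii)
      add_stack("SL", bw$glayers)
      gvL_in <- gvL_in + bw$gX
    } else {
      gvL_in <- gvL_in + framelet_analysis(gpL)
    }
    # step 4: Lb = L - gamma g; Sb = S - gamma g
    gLc <- gLb
    gSc <- gSb
    acc(paste0(p, "gamma"), -.cdot(gLb, tb$g) - .cdot(gSb, tb$g))
    gg <- -gamma * (gLb + gSb)
    # steps 1-3: g = E^H (E(L+S) - d)
    gr <- enc_forward(op, gg)$data
    gx <- enc_adjoint(op, gr)$frames
    gL <- gLc + gx
    gS <- gSc + gx
    gvL <- gvL_in; gvS <- gvS_in; gvt <- gvt_in
  }
  grads
}

#' Loss and gradients for one sample
#'
#' Complex mean squared error against the ground-truth group: the mean
#' over real and imaginary parts of all voxels.
#'
#' @param net An `lsfp_net`.
#' @param d k-space group.
#' @param truth Complex ground-truth array (N x N x fpg).
#' @param op Encoding operator.
#' @return List `loss`, `grads` (flat list matching `net$par`).
#' @export
net_loss_grad <- function(net, d, truth, op) {
  fwd <- net_forward(net, d, op, with_tape = TRUE)
  x <- fwd$L + fwd$S
  diff <- x - truth
  M <- 2 * length(diff)
  loss <- sum(abs(diff)^2) / M
  if (!is.finite(loss)) {
    # skip the backward pass: the caller aborts on a non-finite loss
    return(list(loss = loss, grads = NULL, x = x))
  }
  gx <- 2 * diff / M
  grads <- net_backward(net, fwd, gx, gx, op)
  list(loss = loss, grads = grads, x = x)
}

#' Train an unrolled network with Adam
#'
#' Batch size 1; per-epoch mean training loss and (optionally)
#' validation loss are recorded, and the best-validation parameters are
#' kept as the checkpoint. A non-finite loss aborts with the offending
#' sample index.
#'
#' @param net An `lsfp_net`.
#' @param dataset List of samples, each `list(d = , truth = )`.
#' @param tcfg A [train_config()].
#' @param op Shared encoding operator for all samples.
#' @param val Optional validation list (same structure).
#' @param checkpoint_path Optional RDS path for the best checkpoint.
#' @param verbose Print per-epoch losses (default FALSE).
#' @return List `net` (best checkpoint if validation given, else final),
#'   `final_net`, `history` (data.frame epoch/train_loss/val_loss).
#' @export
net_train <- function(net, dataset, tcfg, op, val = NULL,
                      checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(tcfg, "train_config"))
  par <- net$par
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  t_step <- 0
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_par <- par
  val_loss_of <- function(net) {
    mean(vapply(val, function(s) {
      fwd <- net_forward(net, s$d, op)
      x <- fwd$L + fwd$S
      sum(abs(x - s$truth)^2) / (2 * length(x))
    }, numeric(1)))
  }
  for (ep in seq_len(tcfg$epochs)) {
    lr_ep <- if (identical(tcfg$lr_schedule, "cosine")) {
      tcfg$lr * 0.5 * (1 + cos(pi * (ep - 1) / tcfg$epochs))
    } else {
      tcfg$lr
    }
    tl <- numeric(length(dataset))
    for (i in seq_along(dataset)) {
      net$par <- par
      lg <- net_loss_grad(net, dataset[[i]]$d, dataset[[i]]$truth, op)
      if (!is.finite(lg$loss)) {
        stop("non-finite loss at epoch ", ep, ", sample ", i)
      }
      tl[i] <- lg$loss
      t_step <- t_step + 1
      bc1 <- 1 - tcfg$beta1^t_step
      bc2 <- 1 - tcfg$beta2^t_step
      for (nm in names(par)) {
        g <- lg$grads[[nm]]
        m[[nm]] <- tcfg$beta1 * m[[nm]] + (1 - tcfg$beta1) * g
        v[[nm]] <- tcfg$beta2 * v[[nm]] + (1 - tcfg$beta2) * g^2
        par[[nm]] <- par[[nm]] -
          lr_ep * (m[[nm]] / bc1) / (sqrt(v[[nm]] / bc2) + tcfg$epsilon)
      }
    }
    net$par <- par
    vl <- if (is.null(val)) NA_real_ else val_loss_of(net)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tl),
                                   val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d: train %.3e val %.3e", ep, mean(tl), vl))
    }
    if (!is.null(val) && vl < best_val) {
      best_val <- vl
      best_par <- par
      if (!is.null(checkpoint_path)) {
        saveRDS(list(cfg = net$cfg, par = par, epoch = ep, val_loss = vl),
                checkpoint_path)
      }
    }
  }
  final <- net
  best <- net
  best$par <- if (is.null(val)) par else best_par
  if (is.null(val) && !is.null(checkpoint_path)) {
    saveRDS(list(cfg = net$cfg, par = par, epoch = tcfg$epochs,
                 val_loss = NA_real_), checkpoint_path)
  }
  list(net = best, final_net = final, history = hist)
}

#' Load a checkpoint written by [net_train()]
#'
#' @param path RDS checkpoint path.
#' @return An `lsfp_net`.
#' @export
net_load_checkpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(cfg = ck$cfg, par = ck$par), class = "lsfp_net")
}
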