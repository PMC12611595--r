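# 3D fusion residual U-net for dose prediction, implemented on top of the
# package's own im2col/col2im kernels: strided 2x2x2 convolutions down,
# transposed 2x2x2 convolutions up, residual blocks, instance normalization,
# PReLU activations, and deep supervision (each decoder level emits a
# prediction through a 1x1x1 convolution; lower-level predictions are
# upsampled by 2 and added to the next level's). Gradients are hand-derived
# per layer; Adam does the updates. Everything runs on CPU at desk scale.

#' Network configuration
#'
#' @param in_channels input channels (CT, target channel, OAR channel).
#' @param depth number of resolution levels; input extents must be divisible
#'   by `2^(depth - 1)`.
#' @param base_width feature channels at full resolution; doubled per level.
#'   The default 16 is a desk-scale choice.
#' @param deep_supervision emit and fuse a prediction at every decoder level.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 3, depth = 4, base_width = 16,
                           deep_supervision = TRUE) {
  stopifnot(depth >= 2, base_width >= 4, in_channels >= 1)
  structure(list(in_channels = as.integer(in_channels), depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 deep_supervision = isTRUE(deep_supervision)),
            class = "network_config")
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param steps optimization steps.
#' @param seed seed for weight init and rank-pair sampling.
#' @param w_mse,w_mae,w_rank composite-loss weights.
#' @param rank_pairs voxel pairs sampled per step for the rank term.
#' @param rank_margin hinge margin of the rank term.
#' @param augment_flip randomly mirror the left-right axis per step.
#' @return An object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, steps = 200, seed = 1L,
                            w_mse = 1, w_mae = 1, w_rank = 1,
                            rank_pairs = 1024, rank_margin = 0,
                            augment_flip = FALSE) {
  stopifnot(learning_rate > 0, steps >= 1, w_mse >= 0, w_mae >= 0, w_rank >= 0,
            rank_pairs >= 1, rank_margin >= 0)
  structure(list(learning_rate = learning_rate, steps = as.integer(steps),
                 seed = as.integer(seed), w_mse = w_mse, w_mae = w_mae,
                 w_rank = w_rank, rank_pairs = as.integer(rank_pairs),
                 rank_margin = rank_margin, augment_flip = isTRUE(augment_flip)),
            class = "training_config")
}

# ---- layer primitives (forward + closure backward) ------------------------

conv_op <- function(x, W, b, stride, pad) {
  kd <- dim(W)[1:3]; cin <- dim(W)[4]; cout <- dim(W)[5]
  K <- cpp_im2col(x, as.integer(kd), as.integer(rep_len(stride, 3)),
                  as.integer(rep_len(pad, 3)))
  Wm <- matrix(W, nrow = prod(kd) * cin)
  y <- crossprod(Wm, K) + b
  d <- dim(x)[1:3]; s <- rep_len(stride, 3); p <- rep_len(pad, 3)
  oshape <- (d + 2 * p - kd) %/% s + 1
  out <- array(t(y), dim = c(oshape, cout))
  list(out = out, bwd = function(dout) {
    dY <- t(matrix(dout, ncol = cout))
    dW <- K %*% t(dY)
    dx <- cpp_col2im(Wm %*% dY, dim(x), as.integer(kd), as.integer(s),
                     as.integer(p))
    list(dx = dx, dW = array(dW, dim = dim(W)), db = rowSums(dY))
  })
}

# Transposed convolution, expressed as the adjoint of a strided convolution:
# weight shape (k, k, k, cout, cin).
tconv_op <- function(x, W, b, stride = 2) {
  kd <- dim(W)[1:3]; cout <- dim(W)[4]; cin <- dim(W)[5]
  d <- dim(x)[1:3]; s <- rep_len(stride, 3)
  oshape <- d * s  # exact for k == s, pad 0
  Wm <- matrix(W, nrow = prod(kd) * cout)
  Xt <- t(matrix(x, ncol = cin))
  cols <- Wm %*% Xt
  out <- cpp_col2im(cols, as.integer(c(oshape, cout)), as.integer(kd),
                    as.integer(s), c(0L, 0L, 0L))
  out <- out + array(rep(b, each = prod(oshape)), dim = c(oshape, cout))
  list(out = out, bwd = function(dout) {
    dcols <- cpp_im2col(dout, as.integer(kd), as.integer(s), c(0L, 0L, 0L))
    dW <- dcols %*% t(Xt)
    dxm <- crossprod(Wm, dcols)  # cin x N
    db <- colSums(matrix(dout, ncol = cout))
    list(dx = array(t(dxm), dim = dim(x)), dW = array(dW, dim = dim(W)),
         db = db)
  })
}

in_op <- function(x, g, beta, eps = 1e-5) {
  cdim <- dim(x)[4]; nvox <- prod(dim(x)[1:3])
  xm <- matrix(x, nvox, cdim)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  sd <- sqrt(v + eps)
  xhat <- sweep(xc, 2, sd, "/")
  y <- sweep(sweep(xhat, 2, g, "*"), 2, beta, "+")
  list(out = array(y, dim = dim(x)), bwd = function(dout) {
    dy <- matrix(dout, nvox, cdim)
    dg <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    dxh <- sweep(dy, 2, g, "*")
    m1 <- colMeans(dxh)
    m2 <- colMeans(dxh * xhat)
    dx <- sweep(dxh, 2, m1) - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, sd, "/")
    list(dx = array(dx, dim = dim(x)), dg = dg, dbeta = dbeta)
  })
}

prelu_op <- function(x, a) {
  cdim <- dim(x)[4]; nvox <- prod(dim(x)[1:3])
  xm <- matrix(x, nvox, cdim)
  pos <- xm > 0
  y <- xm * pos + sweep(xm * !pos, 2, a, "*")
  list(out = array(y, dim = dim(x)), bwd = function(dout) {
    dy <- matrix(dout, nvox, cdim)
    da <- colSums(dy * xm * !pos)
    dx <- dy * pos + sweep(dy * !pos, 2, a, "*")
    list(dx = array(dx, dim = dim(x)), da = da)
  })
}

upsample2_op <- function(x) {
  d <- dim(x)
  ix <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  iz <- rep(seq_len(d[3]), each = 2)
  out <- x[ix, iy, iz, , drop = FALSE]
  list(out = out, bwd = function(dout) {
    dx <- array(0, dim = d)
    for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
      dx <- dx + dout[seq(1 + ox, 2 * d[1], 2), seq(1 + oy, 2 * d[2], 2),
                      seq(1 + oz, 2 * d[3], 2), , drop = FALSE]
    }
    dx
  })
}

# ---- parameter initialisation ---------------------------------------------

he_w <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

init_cip <- function(p, prefix, k, cin, cout) {
  p[[paste0(prefix, ".W")]] <- he_w(k, cin, cout)
  p[[paste0(prefix, ".b")]] <- numeric(cout)
  p[[paste0(prefix, ".g")]] <- rep(1, cout)
  p[[paste0(prefix, ".beta")]] <- numeric(cout)
  p[[paste0(prefix, ".a")]] <- rep(0.25, cout)
  p
}

#' Build an untrained network
#'
#' Allocates and He-initializes all weights of the residual U-net described
#' in [network_config()]. Deterministic given `seed`.
#'
#' @param config a [network_config()].
#' @param seed integer init seed.
#' @return An object of class `fresunet` (`params`, `config`).
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  widths <- config$base_width * 2^(0:(config$depth - 1))
  with_seed(seed, {
    p <- list()
    p <- init_cip(p, "stem", 3, config$in_channels, widths[1])
    for (l in seq_len(config$depth - 1)) {
      p <- init_cip(p, sprintf("down%d", l), 2, widths[l], widths[l + 1])
      p <- init_cip(p, sprintf("res%d.c1", l), 3, widths[l + 1], widths[l + 1])
      # second conv of the residual block has no activation before the add
      p[[sprintf("res%d.c2.W", l)]] <- he_w(3, widths[l + 1], widths[l + 1])
      p[[sprintf("res%d.c2.b", l)]] <- numeric(widths[l + 1])
      p[[sprintf("res%d.c2.g", l)]] <- rep(1, widths[l + 1])
      p[[sprintf("res%d.c2.beta", l)]] <- numeric(widths[l + 1])
      p[[sprintf("res%d.out.a", l)]] <- rep(0.25, widths[l + 1])
    }
    for (l in seq(config$depth - 1, 1)) {
      # transposed conv weight: (k,k,k,cout,cin) with cout = widths[l]
      p[[sprintf("up%d.W", l)]] <- array(
        stats::rnorm(8 * widths[l] * widths[l + 1], 0, sqrt(2 / (8 * widths[l + 1]))),
        dim = c(2, 2, 2, widths[l], widths[l + 1]))
      p[[sprintf("up%d.b", l)]] <- numeric(widths[l])
      p[[sprintf("up%d.g", l)]] <- rep(1, widths[l])
      p[[sprintf("up%d.beta", l)]] <- numeric(widths[l])
      p[[sprintf("up%d.a", l)]] <- rep(0.25, widths[l])
      if (l >= 2) {
        p <- init_cip(p, sprintf("dres%d.c1", l), 3, widths[l], widths[l])
        p[[sprintf("dres%d.c2.W", l)]] <- he_w(3, widths[l], widths[l])
        p[[sprintf("dres%d.c2.b", l)]] <- numeric(widths[l])
        p[[sprintf("dres%d.c2.g", l)]] <- rep(1, widths[l])
        p[[sprintf("dres%d.c2.beta", l)]] <- numeric(widths[l])
        p[[sprintf("dres%d.out.a", l)]] <- rep(0.25, widths[l])
      }
      p[[sprintf("head%d.W", l)]] <- he_w(1, widths[l], 1) * 0.1
      p[[sprintf("head%d.b", l)]] <- numeric(1)
    }
    structure(list(params = p, config = config), class = "fresunet")
  })
}

#' @export
print.fresunet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<fresunet> depth %d, base width %d, %s deep supervision, %s parameters\n",
              x$config$depth, x$config$base_width,
              if (x$config$deep_supervision) "with" else "without",
              format(np, big.mark = ",")))
  invisible(x)
}

#' Number of trainable parameters
#' @param network a `fresunet`.
#' @return Total parameter count.
#' @export
n_parameters <- function(network) {
  sum(vapply(network$params, length, numeric(1)))
}

check_divisible <- function(shape, depth) {
  f <- 2^(depth - 1)
  if (any(shape %% f != 0)) {
    need <- (f - shape %% f) %% f
    stop(sprintf("input extent %s is not divisible by %d; pad by (%s) voxels",
                 paste(shape, collapse = "x"), f, paste(need, collapse = ", ")))
  }
}

# Forward pass; returns the fused prediction (nx, ny, nz, 1) and a backward
# closure mapping d(prediction) to the full gradient list.
net_forward <- function(net, x) {
  cfg <- net$config; p <- net$params
  check_divisible(dim(x)[1:3], cfg$depth)
  tape <- list()
  G <- new.env(parent = emptyenv()); G$g <- list()
  acc <- function(key, val) {
    G$g[[key]] <- if (is.null(G$g[[key]])) val else G$g[[key]] + val
  }
  cip <- function(prefix, x, stride, pad) {
    cv <- conv_op(x, p[[paste0(prefix, ".W")]], p[[paste0(prefix, ".b")]],
                  stride, pad)
    nn <- in_op(cv$out, p[[paste0(prefix, ".g")]], p[[paste0(prefix, ".beta")]])
    pr <- prelu_op(nn$out, p[[paste0(prefix, ".a")]])
    list(out = pr$out, bwd = function(dout) {
      b1 <- pr$bwd(dout); acc(paste0(prefix, ".a"), b1$da)
      b2 <- nn$bwd(b1$dx)
      acc(paste0(prefix, ".g"), b2$dg); acc(paste0(prefix, ".beta"), b2$dbeta)
      b3 <- cv$bwd(b2$dx)
      acc(paste0(prefix, ".W"), b3$dW); acc(paste0(prefix, ".b"), b3$db)
      b3$dx
    })
  }
  resblock <- function(prefix, x) {
    c1 <- cip(paste0(prefix, ".c1"), x, 1, 1)
    cv2 <- conv_op(c1$out, p[[paste0(prefix, ".c2.W")]],
                   p[[paste0(prefix, ".c2.b")]], 1, 1)
    nn2 <- in_op(cv2$out, p[[paste0(prefix, ".c2.g")]],
                 p[[paste0(prefix, ".c2.beta")]])
    pr <- prelu_op(nn2$out + x, p[[paste0(prefix, ".out.a")]])
    list(out = pr$out, bwd = function(dout) {
      b1 <- pr$bwd(dout); acc(paste0(prefix, ".out.a"), b1$da)
      b2 <- nn2$bwd(b1$dx)
      acc(paste0(prefix, ".c2.g"), b2$dg); acc(paste0(prefix, ".c2.beta"), b2$dbeta)
      b3 <- cv2$bwd(b2$dx)
      acc(paste0(prefix, ".c2.W"), b3$dW); acc(paste0(prefix, ".c2.b"), b3$db)
      c1$bwd(b3$dx) + b1$dx  # skip connection adds the identity gradient
    })
  }
  upblock <- function(l, x) {
    tc <- tconv_op(x, p[[sprintf("up%d.W", l)]], p[[sprintf("up%d.b", l)]])
    nn <- in_op(tc$out, p[[sprintf("up%d.g", l)]], p[[sprintf("up%d.beta", l)]])
    pr <- prelu_op(nn$out, p[[sprintf("up%d.a", l)]])
    list(out = pr$out, bwd = function(dout) {
      b1 <- pr$bwd(dout); acc(sprintf("up%d.a", l), b1$da)
      b2 <- nn$bwd(b1$dx)
      acc(sprintf("up%d.g", l), b2$dg); acc(sprintf("up%d.beta", l), b2$dbeta)
      b3 <- tc$bwd(b2$dx)
      acc(sprintf("up%d.W", l), b3$dW); acc(sprintf("up%d.b", l), b3$db)
      b3$dx
    })
  }
  # encoder
  enc <- vector("list", cfg$depth)
  stem <- cip("stem", x, 1, 1)
  enc[[1]] <- stem
  cur <- stem$out
  down <- list(); res <- list()
  for (l in seq_len(cfg$depth - 1)) {
    down[[l]] <- cip(sprintf("down%d", l), cur, 2, 0)
    res[[l]] <- resblock(sprintf("res%d", l), down[[l]]$out)
    cur <- res[[l]]$out
    enc[[l + 1]] <- res[[l]]
  }
  # decoder with deep supervision: stage l consumes c_{l+1} (c_L = bottom
  # encoder features) and produces c_l; each stage's head prediction is
  # fused by upsampling the running accumulation and adding.
  ups <- list(); dres <- list(); heads <- list(); upsamps <- list()
  head_op <- function(l, x) {
    conv_op(x, p[[sprintf("head%d.W", l)]], p[[sprintf("head%d.b", l)]], 1, 0)
  }
  pred_acc <- NULL
  for (l in seq(cfg$depth - 1, 1)) {
    ups[[l]] <- upblock(l, cur)
    merged <- ups[[l]]$out + enc[[l]]$out
    if (l >= 2) {
      dres[[l]] <- resblock(sprintf("dres%d", l), merged)
      cur <- dres[[l]]$out
    } else {
      cur <- merged
    }
    if (cfg$deep_supervision || l == 1) {
      heads[[l]] <- head_op(l, cur)
      if (is.null(pred_acc)) {
        pred_acc <- heads[[l]]$out
      } else {
        upsamps[[l]] <- upsample2_op(pred_acc)
        pred_acc <- heads[[l]]$out + upsamps[[l]]$out
      }
    }
  }
  neg <- pred_acc < 0
  out <- pred_acc * !neg  # linear output clamped at zero
  bwd <- function(dout) {
    G$g <- list()
    d_acc <- dout * !neg           # gradient at the level-1 accumulation
    d_c <- vector("list", cfg$depth)   # pending gradient at each c_l / e_L
    d_skip <- vector("list", cfg$depth)  # gradient into encoder features e_l
    # ascend the decoder stages l = 1 .. depth-1
    getl <- function(lst, i) if (i <= length(lst)) lst[[i]] else NULL
    for (l in seq(1, cfg$depth - 1)) {
      d_level <- d_c[[l]]
      head_l <- getl(heads, l)
      if (!is.null(head_l)) {
        hb <- head_l$bwd(d_acc)
        acc(sprintf("head%d.W", l), hb$dW); acc(sprintf("head%d.b", l), hb$db)
        d_level <- if (is.null(d_level)) hb$dx else d_level + hb$dx
        up_l <- getl(upsamps, l)
        d_acc <- if (!is.null(up_l)) up_l$bwd(d_acc) else NULL
      }
      d_merged <- if (l >= 2) dres[[l]]$bwd(d_level) else d_level
      d_skip[[l]] <- d_merged                 # into encoder e_l
      d_into <- ups[[l]]$bwd(d_merged)        # into c_{l+1} (or e_L)
      d_c[[l + 1]] <- if (is.null(d_c[[l + 1]])) d_into else d_c[[l + 1]] + d_into
    }
    # unwind the encoder from the bottom: e_{l+1} = res_l(down_l(e_l))
    d_e_next <- d_c[[cfg$depth]]
    for (l in seq(cfg$depth - 1, 1)) {
      d_after_down <- res[[l]]$bwd(d_e_next)
      d_e <- down[[l]]$bwd(d_after_down)
      d_e_next <- if (is.null(d_skip[[l]])) d_e else d_e + d_skip[[l]]
    }
    stem$bwd(d_e_next)  # accumulates stem grads; input gradient discarded
    G$g
  }
  list(out = out, bwd = bwd)
}

# ---- composite loss -------------------------------------------------------

#' Composite training loss (MSE + MAE + rank)
#'
#' `w_mse * mean((p - t)^2) + w_mae * mean(|p - t|) + w_rank * rank`, where
#' the rank term samples `rank_pairs` voxel pairs (seeded, so reproducible),
#' keeps those with `t_i > t_j`, and averages the hinge
#' `max(0, margin - (p_i - p_j))`. With zero margin the loss is zero exactly
#' when the prediction equals the truth, and the rank term is zero whenever
#' predicted voxel ordering matches the truth on the sampled pairs.
#'
#' @param pred,truth arrays of one shape, normalized to `[0, 1]`.
#' @param config a [training_config()] (weights, pair count, margin).
#' @param seed pair-sampling seed.
#' @param gradient also return the gradient w.r.t. `pred`.
#' @return `list(total, mse, mae, rank)` (+ `grad` when requested).
#' @export
composite_loss <- function(pred, truth, config = training_config(), seed = 1L,
                           gradient = FALSE) {
  if (!identical(dim(pred), dim(truth))) {
    stop("composite_loss: pred and truth shapes differ")
  }
  n <- length(pred)
  diff <- pred - truth
  mse <- mean(diff^2)
  mae <- mean(abs(diff))
  pairs <- with_seed(seed, {
    cbind(sample.int(n, config$rank_pairs, replace = TRUE),
          sample.int(n, config$rank_pairs, replace = TRUE))
  })
  ord <- truth[pairs[, 1]] > truth[pairs[, 2]]
  i <- pairs[ord, 1]; j <- pairs[ord, 2]
  nk <- length(i)
  if (nk > 0) {
    h <- pmax(0, config$rank_margin - (pred[i] - pred[j]))
    rank_term <- mean(h)
  } else {
    rank_term <- 0
  }
  total <- config$w_mse * mse + config$w_mae * mae + config$w_rank * rank_term
  out <- list(total = total, mse = mse, mae = mae, rank = rank_term)
  if (gradient) {
    g <- config$w_mse * 2 * diff / n + config$w_mae * sign(diff) / n
    if (nk > 0) {
      active <- which(h > 0)
      if (length(active) > 0) {
        gi <- i[active]; gj <- j[active]
        gr <- numeric(n)
        # tabulate handles repeated indices (a voxel can occur in many pairs)
        gr <- gr - config$w_rank / nk * tabulate(gi, nbins = n)
        gr <- gr + config$w_rank / nk * tabulate(gj, nbins = n)
        g <- g + gr
      }
    }
    dim(g) <- dim(pred)
    out$grad <- g
  }
  out
}

# ---- model input encoding -------------------------------------------------

OAR_CHANNEL_ORDER <- c("bladder", "rectum", "small_intestine",
                       "femoral_head_l", "femoral_head_r")

#' Encode a case as the 3-channel network input
#'
#' Channel 1: windowed/normalized CT. Channel 2: targets — PTV45 voxels 0.5,
#' PTV50 voxels 1 (labels \{0, 1, 2\} scaled to `[0, 1]`). Channel 3: OARs —
#' one labeled channel, organ `i` of the fixed order (bladder, rectum, small
#' intestine, left/right femoral head) coded `i / 5`; overlaps keep the
#' larger label.
#'
#' @param case a [patient_case()].
#' @param config a [preprocess_config()].
#' @return Array `(nx, ny, nz, 3)` in `[0, 1]`.
#' @export
make_model_input <- function(case, config = preprocess_config()) {
  geo <- case$ct$geometry
  ct <- window_normalize_ct(case$ct, config)$values
  st <- case$structures
  ptv <- array(0, geo$shape)
  if (!is.null(st[["PTV45"]])) ptv <- ptv + st[["PTV45"]]$values
  if (!is.null(st[["PTV50"]])) ptv <- ptv + st[["PTV50"]]$values
  ptv <- ptv / 2
  oar <- array(0, geo$shape)
  for (i in seq_along(OAR_CHANNEL_ORDER)) {
    nm <- OAR_CHANNEL_ORDER[i]
    if (!is.null(st[[nm]])) {
      oar <- pmax(oar, st[[nm]]$values * i / length(OAR_CHANNEL_ORDER))
    }
  }
  array(c(ct, ptv, oar), dim = c(geo$shape, 3))
}

# ---- training -------------------------------------------------------------

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (key in names(g)) {
    if (is.null(state$m[[key]])) {
      state$m[[key]] <- g[[key]] * 0
      state$v[[key]] <- g[[key]] * 0
    }
    state$m[[key]] <- 0.9 * state$m[[key]] + 0.1 * g[[key]]
    state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g[[key]]^2
    mhat <- state$m[[key]] / (1 - beta1^state$t)
    vhat <- state$v[[key]] / (1 - beta2^state$t)
    p[[key]] <- p[[key]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = p, state = state)
}

#' Train the network on phantom cases
#'
#' Full-volume steps cycling through the cases, minimizing
#' [composite_loss()] with Adam. Deterministic given the seed (weight init,
#' pair sampling and augmentation all derive from it). Training stops with
#' an error naming the step if the loss becomes non-finite.
#'
#' @param cases list of [patient_case()]s, each with a reference dose.
#' @param training a [training_config()].
#' @param network a [network_config()] or a prebuilt `fresunet` to continue
#'   training.
#' @param preprocess a [preprocess_config()] (input encoding and dose
#'   normalization).
#' @return `list(network = <fresunet>, history = <data.frame step/total/
#'   mse/mae/rank>)`.
#' @export
train_network <- function(cases, training = training_config(),
                          network = network_config(),
                          preprocess = preprocess_config()) {
  stopifnot(length(cases) >= 1)
  for (cs in cases) {
    if (is.null(cs$dose)) stop("train_network: every case needs a reference dose")
  }
  net <- if (inherits(network, "fresunet")) network
         else build_network(network, seed = training$seed)
  check_divisible(cases[[1]]$ct$geometry$shape, net$config$depth)
  xs <- lapply(cases, make_model_input, config = preprocess)
  ts <- lapply(cases, function(cs) {
    v <- normalize_dose(cs$dose, cs$modality, preprocess)$values
    array(v, dim = c(dim(v), 1))
  })
  p <- net$params
  state <- new.env(parent = emptyenv()); state$t <- 0
  state$m <- list(); state$v <- list()
  hist <- matrix(NA_real_, training$steps, 4,
                 dimnames = list(NULL, c("total", "mse", "mae", "rank")))
  flips <- if (training$augment_flip) {
    with_seed(training$seed + 7L, sample(c(TRUE, FALSE), training$steps, TRUE))
  } else rep(FALSE, training$steps)
  for (step in seq_len(training$steps)) {
    ci <- (step - 1) %% length(cases) + 1
    x <- xs[[ci]]; tt <- ts[[ci]]
    if (flips[step]) {  # mirror the left-right (x) axis
      x <- x[rev(seq_len(dim(x)[1])), , , , drop = FALSE]
      tt <- tt[rev(seq_len(dim(tt)[1])), , , , drop = FALSE]
    }
    net$params <- p
    fw <- net_forward(net, x)
    ls <- composite_loss(fw$out, tt, training, seed = training$seed + step,
                         gradient = TRUE)
    if (!is.finite(ls$total)) {
      stop(sprintf("train_network: loss diverged (non-finite) at step %d", step))
    }
    hist[step, ] <- c(ls$total, ls$mse, ls$mae, ls$rank)
    g <- fw$bwd(ls$grad)
    upd <- adam_step(p, g, state, training$learning_rate)
    p <- upd$params
  }
  net$params <- p
  list(network = net,
       history = data.frame(step = seq_len(training$steps), hist))
}

#' Predict a dose distribution for a case
#'
#' Runs the forward pass on the encoded case and denormalizes the output to
#' Gy (modality maximum: 55 Gy VMAT, 50 Gy IMRT). Output is non-negative and
#' on the case geometry.
#'
#' @param network a trained `fresunet`.
#' @param case a [patient_case()] (already preprocessed / on a grid whose
#'   extents are divisible by `2^(depth-1)`).
#' @param preprocess a [preprocess_config()].
#' @return A [dose_grid()].
#' @export
predict_dose <- function(network, case, preprocess = preprocess_config()) {
  stopifnot(inherits(network, "fresunet"), inherits(case, "patient_case"))
  x <- make_model_input(case, preprocess)
  out <- net_forward(network, x)$out
  dmax <- dose_norm_max(preprocess, case$modality)
  pres <- if (case$case_type == "SIB") c(PTV45 = 45, PTV50 = 50) else c(PTV45 = 45)
  dose_grid(pmax(array(out, dim = dim(out)[1:3]), 0) * dmax,
            case$ct$geometry, pres)
}

#' Save / load a network checkpoint
#'
#' Single-file checkpoint holding the weights and both configurations.
#'
#' @param network a `fresunet`.
#' @param path checkpoint file path.
#' @return `save_network`: invisibly `path`; `load_network`: the `fresunet`.
#' @export
save_network <- function(network, path) {
  stopifnot(inherits(network, "fresunet"))
  saveRDS(network, path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "fresunet")) stop("load_network: not a network checkpoint")
  net
}
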