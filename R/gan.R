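# Wasserstein GAN with gradient penalty (WGAN-GP) for tabular expression
# profiles. Generator and critic are fully connected multilayer
# perceptrons trained with Adam; the critic is softly constrained to be
# 1-Lipschitz by penalizing the deviation of its input-gradient norm from
# 1 at points interpolated between real and generated batches. Both
# networks and all gradients (including the second-order gradient of the
# penalty with respect to the critic weights) are implemented directly in
# R matrix algebra: for piecewise-linear activations the activation
# pattern is locally constant, so the double-backward pass reuses the
# forward masks.

#' WGAN-GP training configuration
#'
#' Defaults follow the standard tabular WGAN-GP recipe: a 100-dimensional
#' latent vector, generator widths 250-500-1000 with LeakyReLU(0.2) and a
#' Tanh output, a mirrored critic (1000-500-250) with a linear scalar
#' output, gradient-penalty weight 10, Adam at learning rate 1e-4 with
#' beta1 = 0 and beta2 = 0.9, batch size 2, 2000 epochs, and 5 critic
#' updates per generator update (the canonical ratio).
#'
#' @param z_dim Latent dimension.
#' @param gen_hidden Generator hidden widths.
#' @param critic_hidden Critic hidden widths.
#' @param leaky_alpha LeakyReLU negative slope.
#' @param gp_lambda Gradient-penalty weight.
#' @param lr Adam learning rate for the critic.
#' @param lr_gen Adam learning rate for the generator; defaults to
#'   `lr / 5` (two-timescale rule: a slower generator against a critic
#'   kept close to optimality stabilizes training on very small
#'   minority sets).
#' @param betas Adam `(beta1, beta2)`.
#' @param epochs Training epochs (one epoch = one pass over the minority
#'   samples in shuffled batches).
#' @param batch_size Minibatch size (>= 2: interpolation needs pairs).
#' @param critic_steps_per_gen Critic updates per generator update.
#' @param seed RNG seed controlling initialization and all sampling.
#' @return A list of class `gan_config`.
#' @export
gan_config <- function(z_dim = 100, gen_hidden = c(250, 500, 1000),
                       critic_hidden = c(1000, 500, 250),
                       leaky_alpha = 0.2, gp_lambda = 10, lr = 1e-4,
                       lr_gen = lr / 5,
                       betas = c(0, 0.9), epochs = 2000, batch_size = 2,
                       critic_steps_per_gen = 5, seed = 1L) {
  stopifnot(z_dim >= 1, all(gen_hidden >= 1), all(critic_hidden >= 1),
            leaky_alpha > 0, gp_lambda >= 0, lr > 0,
            length(betas) == 2, epochs >= 1, batch_size >= 2,
            critic_steps_per_gen >= 1, lr_gen > 0)
  structure(
    list(z_dim = z_dim, gen_hidden = gen_hidden,
         critic_hidden = critic_hidden, leaky_alpha = leaky_alpha,
         gp_lambda = gp_lambda, lr = lr, lr_gen = lr_gen, betas = betas,
         epochs = epochs,
         batch_size = batch_size,
         critic_steps_per_gen = critic_steps_per_gen, seed = seed),
    class = "gan_config"
  )
}

# --- feature scaling --------------------------------------------------------

#' Fit a per-gene min-max scaler to [-1, 1]
#'
#' The Tanh generator output lives in (-1, 1); training data are scaled
#' into the same range gene-wise. Constant genes (min == max) map to -1
#' and are inverse-mapped back to their constant. The inverse transform
#' clamps to the training range, so generated values never leave it.
#'
#' @param x Numeric matrix, samples in rows, genes in columns.
#' @return A `feature_scaler` with `min` and `max` per column.
#' @export
fit_scaler <- function(x) {
  stopifnot(is.matrix(x))
  structure(
    list(min = apply(x, 2, min), max = apply(x, 2, max),
         genes = colnames(x)),
    class = "feature_scaler"
  )
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler`.
#' @export
scale_features <- function(x, scaler) {
  rng <- scaler$max - scaler$min
  rng[rng == 0] <- 1  # constant genes map to -1
  sweep(sweep(x, 2, scaler$min), 2, rng, "/") * 2 - 1
}

#' @rdname fit_scaler
#' @param y Scaled matrix in [-1, 1].
#' @export
inverse_scale_features <- function(y, scaler) {
  y <- pmin(pmax(y, -1), 1)
  rng <- scaler$max - scaler$min
  out <- sweep(sweep((y + 1) / 2, 2, rng, "*"), 2, scaler$min, "+")
  colnames(out) <- scaler$genes
  out
}

# --- MLP primitives ---------------------------------------------------------

mlp_new <- function(sizes, acts) {
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[l + 1]),
      b = numeric(sizes[l + 1]),
      act = acts[l]
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

mlp_act <- function(a, act, alpha) {
  switch(act,
         lrelu = ifelse(a > 0, a, alpha * a),
         tanh = tanh(a),
         linear = a)
}

mlp_dact <- function(a, h, act, alpha) {
  switch(act,
         lrelu = ifelse(a > 0, 1, alpha),
         tanh = 1 - h^2,
         linear = array(1, dim(a)))
}

# forward pass; X is batch x d_in. Returns output and per-layer caches.
mlp_forward <- function(net, X, alpha) {
  H <- X
  cache <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    A <- H %*% ly$W
    A <- sweep(A, 2, ly$b, "+")
    Hn <- mlp_act(A, ly$act, alpha)
    cache[[l]] <- list(H_in = H, A = A, H_out = Hn)
    H <- Hn
  }
  list(out = H, cache = cache)
}

# backward pass from upstream gradient dL/d(out); returns parameter
# gradients and dL/dX.
mlp_backward <- function(net, cache, dout, alpha) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dout
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    ca <- cache[[l]]
    dA <- delta * mlp_dact(ca$A, ca$H_out, ly$act, alpha)
    grads[[l]] <- list(W = crossprod(ca$H_in, dA), b = colSums(dA))
    delta <- dA %*% t(ly$W)
  }
  list(grads = grads, dX = delta)
}

# gradient of the scalar critic output w.r.t. its input, plus the masks
# needed by the double-backward pass. Critic output must be linear scalar.
critic_input_grad <- function(net, cache, alpha) {
  L <- length(net$layers)
  deltas <- vector("list", L)  # delta_l = dD/dA_l  (batch x width_l)
  delta <- matrix(1, nrow(cache[[L]]$A), ncol(cache[[L]]$A))
  deltas[[L]] <- delta
  for (l in rev(seq_len(L - 1L))) {
    ca <- cache[[l]]
    M <- mlp_dact(ca$A, ca$H_out, net$layers[[l]]$act, alpha)
    delta <- (delta %*% t(net$layers[[l + 1L]]$W)) * M
    deltas[[l]] <- delta
  }
  G <- deltas[[1L]] %*% t(net$layers[[1L]]$W)
  list(G = G, deltas = deltas)
}

#' Gradient penalty of a critic on interpolated samples
#'
#' Draws one uniform mixing coefficient per row, forms interpolates
#' `u * real + (1 - u) * fake`, and returns
#' `gp_lambda * mean((||grad_x critic(x)||_2 - 1)^2)`. Used inside
#' critic updates to softly enforce 1-Lipschitz continuity; exported for
#' direct verification against analytic critics.
#'
#' @param critic An `mlp` critic (scalar linear output).
#' @param real_batch,fake_batch Matrices of identical shape
#'   (batch x genes).
#' @param gp_lambda Penalty weight (default 10).
#' @param alpha LeakyReLU slope used by the critic (default 0.2).
#' @param u Optional fixed mixing coefficients (length = batch) for
#'   reproducibility; drawn from Uniform(0,1) per row when `NULL`.
#' @return Scalar penalty (>= 0), with attribute `grad_norms`.
#' @export
gradient_penalty <- function(critic, real_batch, fake_batch,
                             gp_lambda = 10, alpha = 0.2, u = NULL) {
  stopifnot(is.matrix(real_batch), is.matrix(fake_batch))
  if (!all(dim(real_batch) == dim(fake_batch))) {
    stop("real and fake batches must have identical shape", call. = FALSE)
  }
  B <- nrow(real_batch)
  if (is.null(u)) u <- stats::runif(B)
  Xhat <- real_batch * u + fake_batch * (1 - u)
  fw <- mlp_forward(critic, Xhat, alpha)
  ig <- critic_input_grad(critic, fw$cache, alpha)
  s <- sqrt(rowSums(ig$G^2))
  pen <- gp_lambda * mean((s - 1)^2)
  attr(pen, "grad_norms") <- s
  pen
}

# gradient penalty with parameter gradients (double backprop). The
# activation masks are treated as locally constant (exact a.e. for
# LeakyReLU), so the second backward pass runs over the linear recursion
# that produced the input gradient.
gp_with_param_grads <- function(critic, Xhat, gp_lambda, alpha) {
  fw <- mlp_forward(critic, Xhat, alpha)
  ig <- critic_input_grad(critic, fw$cache, alpha)
  G <- ig$G
  deltas <- ig$deltas
  B <- nrow(G)
  s <- sqrt(rowSums(G^2))
  pen <- gp_lambda * mean((s - 1)^2)

  coef <- ifelse(s > 1e-12, 2 * gp_lambda * (s - 1) / (B * s), 0)
  Gbar <- G * coef
  L <- length(critic$layers)
  Wg <- vector("list", L)
  # G = delta_1 W_1^T
  Wg[[1L]] <- crossprod(Gbar, deltas[[1L]])
  dbar <- Gbar %*% critic$layers[[1L]]$W  # adjoint of delta_1
  if (L >= 2L) {
    for (l in seq_len(L - 1L)) {
      ca_A <- fw$cache[[l]]$A
      M <- mlp_dact(ca_A, fw$cache[[l]]$H_out, critic$layers[[l]]$act, alpha)
      Zbar <- dbar * M  # delta_l = Z_l * M_l
      # Z_l = delta_{l+1} W_{l+1}^T
      Wg[[l + 1L]] <- crossprod(Zbar, deltas[[l + 1L]])
      dbar <- Zbar %*% critic$layers[[l + 1L]]$W
    }
  }
  list(penalty = pen, W_grads = Wg)
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(net) {
  lapply(net$layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
}

adam_step <- function(net, grads, state, t, lr, betas, eps = 1e-8) {
  b1 <- betas[1]
  b2 <- betas[2]
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    st <- state[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    mhW <- st$mW / (1 - b1^t)
    vhW <- st$vW / (1 - b2^t)
    mhb <- st$mb / (1 - b1^t)
    vhb <- st$vb / (1 - b2^t)
    net$layers[[l]]$W <- net$layers[[l]]$W - lr * mhW / (sqrt(vhW) + eps)
    net$layers[[l]]$b <- net$layers[[l]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[l]] <- st
  }
  list(net = net, state = state)
}

zero_like_grads <- function(net) {
  lapply(net$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
}

add_W_grads <- function(grads, Wg) {
  for (l in seq_along(grads)) {
    if (!is.null(Wg[[l]])) grads[[l]]$W <- grads[[l]]$W + Wg[[l]]
  }
  grads
}

# --- training ---------------------------------------------------------------

#' Train a WGAN-GP on minority-class expression profiles
#'
#' Trains generator and critic on the given samples (genes as features).
#' Data are min-max scaled to [-1, 1] per gene to match the Tanh output.
#' Each epoch is one pass over the samples in shuffled batches; per
#' batch the critic takes `critic_steps_per_gen` updates (fresh latent
#' draws each) followed by one generator update. Fully reproducible from
#' `config$seed`.
#'
#' @param data An [expr_matrix()] (all its samples are used; subset to
#'   the minority class first, e.g. with [subset_samples()]), or a
#'   numeric matrix with samples in rows and genes in columns.
#' @param config A [gan_config()].
#' @return A `wgan_gp` fit: generator, critic, scaler, gene ids, config,
#'   and a `loss_history` tibble (epoch, critic_loss, generator_loss).
#' @export
train_wgan_gp <- function(data, config = gan_config()) {
  if (inherits(data, "expr_matrix")) {
    lab <- unique(data$samples$label)
    if (length(lab) > 1L) {
      stop("training data contain ", length(lab), " classes; subset to ",
           "the minority class first", call. = FALSE)
    }
    X <- t(data$values)  # samples x genes
    minority_label <- lab
  } else {
    X <- data
    minority_label <- NA_character_
  }
  stopifnot(is.matrix(X))
  if (nrow(X) < 2L) {
    stop("need at least 2 minority samples to train ",
         "(gradient-penalty interpolation requires pairs)", call. = FALSE)
  }
  n_genes <- ncol(X)
  set.seed(config$seed)

  scaler <- fit_scaler(X)
  Xs <- scale_features(X, scaler)

  gen <- mlp_new(c(config$z_dim, config$gen_hidden, n_genes),
                 c(rep("lrelu", length(config$gen_hidden)), "tanh"))
  cri <- mlp_new(c(n_genes, config$critic_hidden, 1L),
                 c(rep("lrelu", length(config$critic_hidden)), "linear"))
  ad_g <- adam_new(gen)
  ad_c <- adam_new(cri)
  t_g <- 0L
  t_c <- 0L
  alpha <- config$leaky_alpha
  B <- config$batch_size

  n <- nrow(Xs)
  history <- matrix(NA_real_, config$epochs, 2)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    closses <- numeric(0)
    glosses <- numeric(0)
    for (start in seq(1L, n, by = B)) {
      idx <- ord[start:min(start + B - 1L, n)]
      if (length(idx) < 2L) {
        # top up a short tail batch so interpolation has pairs
        idx <- c(idx, ord[seq_len(2L - length(idx))])
      }
      real <- Xs[idx, , drop = FALSE]
      bsz <- nrow(real)
      for (step in seq_len(config$critic_steps_per_gen)) {
        # fresh real minibatch per critic step (standard WGAN-GP recipe)
        idx_c <- sample.int(n, bsz, replace = bsz > n)
        real_c <- Xs[idx_c, , drop = FALSE]
        Z <- matrix(stats::rnorm(bsz * config$z_dim), bsz, config$z_dim)
        fake <- mlp_forward(gen, Z, alpha)$out
        fw_r <- mlp_forward(cri, real_c, alpha)
        fw_f <- mlp_forward(cri, fake, alpha)
        # critic loss: E[D(fake)] - E[D(real)] + GP
        g_r <- mlp_backward(cri, fw_r$cache,
                            matrix(-1 / bsz, bsz, 1), alpha)$grads
        g_f <- mlp_backward(cri, fw_f$cache,
                            matrix(1 / bsz, bsz, 1), alpha)$grads
        u <- stats::runif(bsz)
        Xhat <- real_c * u + fake * (1 - u)
        gp <- gp_with_param_grads(cri, Xhat, config$gp_lambda, alpha)
        grads <- zero_like_grads(cri)
        for (l in seq_along(grads)) {
          grads[[l]]$W <- g_r[[l]]$W + g_f[[l]]$W
          grads[[l]]$b <- g_r[[l]]$b + g_f[[l]]$b
        }
        grads <- add_W_grads(grads, gp$W_grads)
        t_c <- t_c + 1L
        up <- adam_step(cri, grads, ad_c, t_c, config$lr, config$betas)
        cri <- up$net
        ad_c <- up$state
        closses <- c(closses,
                     mean(fw_f$out) - mean(fw_r$out) + gp$penalty)
      }
      # generator update: minimize -E[D(G(z))]
      Z <- matrix(stats::rnorm(bsz * config$z_dim), bsz, config$z_dim)
      fw_g <- mlp_forward(gen, Z, alpha)
      fw_c <- mlp_forward(cri, fw_g$out, alpha)
      bk_c <- mlp_backward(cri, fw_c$cache,
                           matrix(-1 / bsz, bsz, 1), alpha)
      g_gen <- mlp_backward(gen, fw_g$cache, bk_c$dX, alpha)$grads
      t_g <- t_g + 1L
      up <- adam_step(gen, g_gen, ad_g, t_g,
                      config$lr_gen %||% config$lr, config$betas)
      gen <- up$net
      ad_g <- up$state
      glosses <- c(glosses, -mean(fw_c$out))
    }
    history[ep, ] <- c(mean(closses), mean(glosses))
  }

  structure(
    list(
      generator = gen, critic = cri, scaler = scaler,
      gene_ids = colnames(X), minority_label = minority_label,
      config = config,
      loss_history = tibble::tibble(
        epoch = seq_len(config$epochs),
        critic_loss = history[, 1],
        generator_loss = history[, 2]
      )
    ),
    class = "wgan_gp"
  )
}

#' @export
print.wgan_gp <- function(x, ...) {
  cat(sprintf(
    "<wgan_gp> %d genes, z_dim %d, %d epochs trained (class '%s')\n",
    length(x$gene_ids), x$config$z_dim, nrow(x$loss_history),
    x$minority_label
  ))
  invisible(x)
}

#' Loss history of a WGAN-GP fit
#'
#' @param x A `wgan_gp`.
#' @param ... Unused.
#' @return The per-epoch loss tibble.
#' @export
tidy.wgan_gp <- function(x, ...) x$loss_history

#' One-row training summary of a WGAN-GP fit
#'
#' @param x A `wgan_gp`.
#' @param ... Unused.
#' @export
glance.wgan_gp <- function(x, ...) {
  h <- x$loss_history
  k <- max(1L, ceiling(nrow(h) / 10))
  tibble::tibble(
    n_genes = length(x$gene_ids),
    epochs = nrow(h),
    critic_loss_start = stats::median(h$critic_loss[seq_len(k)]),
    critic_loss_end = stats::median(h$critic_loss[nrow(h) - k + seq_len(k)])
  )
}

#' Generate scaled profiles from a trained generator
#'
#' @param fit A `wgan_gp`.
#' @param n Number of profiles.
#' @return Matrix (n x genes) in the Tanh range (-1, 1). Uses the
#'   current RNG state.
#' @keywords internal
generate_scaled <- function(fit, n) {
  Z <- matrix(stats::rnorm(n * fit$config$z_dim), n, fit$config$z_dim)
  mlp_forward(fit$generator, Z, fit$config$leaky_alpha)$out
}

#' Sample synthetic expression profiles from a trained WGAN-GP
#'
#' Draws latent vectors, maps them through the generator, inverse-scales
#' to the original expression space (clamped to the training range and at
#' zero), and returns them as an [expr_matrix()] labelled with the
#' minority class and `origin = "synthetic"`.
#'
#' @param fit A `wgan_gp` from [train_wgan_gp()].
#' @param n Number of profiles to generate (the source study drew 251).
#' @param seed RNG seed.
#' @param label Class label for the synthetic samples; defaults to the
#'   label of the training data.
#' @param prefix Sample-id prefix (default `"syn"`).
#' @return An `expr_matrix` with `n` synthetic samples.
#' @export
sample_synthetic <- function(fit, n, seed = 1L, label = NULL,
                             prefix = "syn") {
  stopifnot(inherits(fit, "wgan_gp"))
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (is.null(label)) label <- fit$minority_label
  set.seed(seed)
  Y <- generate_scaled(fit, n)
  X <- inverse_scale_features(Y, fit$scaler)
  X[X < 0] <- 0
  sids <- sprintf("%s%03d", prefix, seq_len(n))
  vals <- t(X)
  rownames(vals) <- fit$gene_ids
  colnames(vals) <- sids
  expr_matrix(
    vals,
    labels = stats::setNames(rep(label, n), sids),
    origin = stats::setNames(rep("synthetic", n), sids)
  )
}
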