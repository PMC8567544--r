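#' Training configuration for the full pipeline
#'
#' Bundles every tunable of [fit_joint()] and [cross_validate()]. Defaults
#' are sized for the bundled synthetic benchmark scale (see the methods
#' vignette); for association networks of several hundred entities per side,
#' fusion ranks in the low hundreds (selected by [grid_search()]) are the
#' regime reported effective in the literature this model follows.
#'
#' @param rank_disease,rank_drug fusion decomposition rank per side.
#' @param out_dim_disease,out_dim_drug fused feature widths f_d, f_g.
#' @param f_p latent dimension of the bilinear projection `P = W H'`.
#' @param lambda ridge penalty on the completion factors.
#' @param gamma_prime GIP kernel bandwidth pre-factor.
#' @param lr initial gradient-descent learning rate (adapted by halving on
#'   non-improving steps).
#' @param epochs full-batch gradient steps over all parameters.
#' @param warm_iters ALS sweeps used to warm-start the bilinear factors
#'   before gradient refinement.
#' @param als_finish run [fit_als()] on the frozen fused features after
#'   gradient training.
#' @param als_iters,als_tol ALS sweep budget and stopping tolerance.
#' @param pos_weight weight (>= 1) on observed positive cells.
#' @param append_one append a constant 1 to each modality input in fusion.
#' @param seed root seed; stage seeds are derived from it.
#' @return A list of class `train_config`.
#' @export
train_config <- function(rank_disease = 8, rank_drug = 8,
                         out_dim_disease = 128, out_dim_drug = 128,
                         f_p = 32, lambda = 20, gamma_prime = 1,
                         lr = 1e-4, epochs = 50, warm_iters = 10,
                         als_finish = TRUE, als_iters = 60, als_tol = 1e-9,
                         pos_weight = 1, append_one = TRUE, seed = 1) {
  stopifnot(rank_disease >= 1, rank_drug >= 1, out_dim_disease >= 1,
            out_dim_drug >= 1, f_p >= 1, lambda >= 0, lr > 0, epochs >= 0,
            pos_weight >= 1)
  structure(list(rank_disease = rank_disease, rank_drug = rank_drug,
                 out_dim_disease = out_dim_disease, out_dim_drug = out_dim_drug,
                 f_p = f_p, lambda = lambda, gamma_prime = gamma_prime,
                 lr = lr, epochs = epochs, warm_iters = warm_iters,
                 als_finish = als_finish,
                 als_iters = als_iters, als_tol = als_tol,
                 pos_weight = pos_weight, append_one = append_one,
                 seed = as.integer(seed)),
            class = c("train_config", "list"))
}

# forward pass through one fusion side, keeping the caches backprop needs
fusion_forward <- function(view, f) {
  Z <- fusion_inputs(view, f)
  A <- fusion_projections(Z, f)
  prod_all <- Reduce(`*`, A)
  n <- nrow(prod_all)
  pa <- prod_all
  dim(pa) <- c(n, f$out_dim, f$rank)
  fused <- rowSums(pa, dims = 2) + matrix(f$bias, n, f$out_dim, byrow = TRUE)
  rownames(fused) <- rownames(view[[1]])
  list(fused = fused, Z = Z, A = A)
}

# gradient of a scalar loss wrt fusion factors and bias, given dL/dfused
fusion_backward <- function(G, cache, f) {
  n <- nrow(G)
  Gfull <- G[, rep(seq_len(f$out_dim), f$rank), drop = FALSE]
  M <- length(cache$A)
  grads <- vector("list", M)
  for (m in seq_len(M)) {
    others <- Gfull
    for (m2 in seq_len(M)) {
      if (m2 != m) others <- others * cache$A[[m2]]
    }
    g <- crossprod(cache$Z[[m]], others)
    dim(g) <- dim(f$factors[[m]])
    grads[[m]] <- g
  }
  list(factors = grads, bias = colSums(G))
}

joint_loss_and_grads <- function(sims, fd, fg, W, H, O, lambda, pos_weight,
                                 want_grads = TRUE) {
  fwd_d <- fusion_forward(sims$disease, fd)
  fwd_g <- fusion_forward(sims$drug, fg)
  X <- fwd_d$fused; Y <- fwd_g$fused
  XW <- X %*% W
  YH <- Y %*% H
  S <- XW %*% t(YH)
  R <- S - O
  Wt <- if (pos_weight == 1) NULL else 1 + (pos_weight - 1) * O
  loss <- (if (is.null(Wt)) sum(R^2) else sum(Wt * R^2)) +
    lambda / 2 * (sum(W^2) + sum(H^2))
  if (!want_grads) return(list(loss = loss))
  E <- if (is.null(Wt)) 2 * R else 2 * Wt * R
  dX <- (E %*% YH) %*% t(W)
  dY <- (crossprod(E, XW)) %*% t(H)
  dW <- crossprod(X, E %*% YH) + lambda * W
  dH <- crossprod(Y, crossprod(E, XW)) + lambda * H
  list(loss = loss,
       g_fd = fusion_backward(dX, fwd_d, fd),
       g_fg = fusion_backward(dY, fwd_g, fg),
       dW = dW, dH = dH)
}

apply_step <- function(f, g, lr) {
  f$factors <- lapply(seq_along(f$factors),
                      function(m) f$factors[[m]] - lr * g$factors[[m]])
  f$bias <- f$bias - lr * g$bias
  f
}

#' Jointly train fusion factors and the completion model
#'
#' End-to-end fit on a dataset bundle: builds the similarity modalities
#' (GIP kernels from the bundle's association matrix, semantic similarity,
#' fingerprint Jaccard), initializes fusion factors from the root seed
#' (passthrough scheme when `append_one` is on, see
#' [init_fusion_factors()]), warm-starts the bilinear factors with a few ALS
#' sweeps, and then minimizes the regularized squared-error objective
#' `sum_(i,j)(O_ij - x_i W H' y_j')^2 + lambda/2(||W||^2 + ||H||^2)` by
#' full-batch gradient descent over all parameters (fusion factors, biases,
#' `W_imc`, `H_imc`). Steps that fail to decrease the loss are rejected and
#' the learning rate halved, so the recorded loss trace is non-increasing.
#' By default the fit finishes with [fit_als()] on the frozen fused features,
#' which solves the completion subproblem to optimality.
#'
#' @param bundle a `dd_bundle` (use a training-masked copy inside
#'   cross-validation).
#' @param config a [train_config()].
#' @return List with `factors_disease`, `factors_drug` (fusion factors),
#'   `model` (an `imc_model`), `X`, `Y` (fused features), `scores` (the full
#'   score matrix), and `report` (loss traces, seed, config echo).
#' @export
fit_joint <- function(bundle, config = train_config()) {
  O <- bundle$associations
  sims_all <- bundle_similarities(bundle, config$gamma_prime)
  sims <- list(disease = lapply(sims_all$disease, strip_modality),
               drug = lapply(sims_all$drug, strip_modality))
  n_d <- nrow(O); n_g <- ncol(O)
  init_method <- if (config$append_one) "passthrough" else "random"
  fd <- init_fusion_factors(rep(n_d, length(sims$disease)), config$rank_disease,
                            config$out_dim_disease, stage_seed(config$seed, 1),
                            config$append_one, method = init_method)
  fg <- init_fusion_factors(rep(n_g, length(sims$drug)), config$rank_drug,
                            config$out_dim_drug, stage_seed(config$seed, 2),
                            config$append_one, method = init_method)
  # warm-start the bilinear factors by a few ALS sweeps on the initial
  # features, so gradient refinement begins from a well-scaled solution
  X0 <- fusion_forward(sims$disease, fd)$fused
  Y0 <- fusion_forward(sims$drug, fg)$fused
  warm <- fit_als(X0, Y0, O, f_p = config$f_p, lambda = config$lambda,
                  max_iter = config$warm_iters, tol = config$als_tol,
                  seed = stage_seed(config$seed, 3),
                  pos_weight = config$pos_weight)
  W <- warm$model$W_imc
  H <- warm$model$H_imc
  lr <- config$lr
  cur <- joint_loss_and_grads(sims, fd, fg, W, H, O,
                              config$lambda, config$pos_weight)
  if (!is.finite(cur$loss)) {
    stop_validation("non-finite loss at initialization; use a smaller learning rate")
  }
  trace <- cur$loss
  for (ep in seq_len(config$epochs)) {
    accepted <- FALSE
    while (!accepted && lr > 1e-15) {
      fd2 <- apply_step(fd, cur$g_fd, lr)
      fg2 <- apply_step(fg, cur$g_fg, lr)
      W2 <- W - lr * cur$dW
      H2 <- H - lr * cur$dH
      nxt <- joint_loss_and_grads(sims, fd2, fg2, W2, H2, O,
                                  config$lambda, config$pos_weight)
      if (is.finite(nxt$loss) && nxt$loss <= cur$loss) {
        fd <- fd2; fg <- fg2; W <- W2; H <- H2
        cur <- nxt
        lr <- lr * 1.1
        accepted <- TRUE
      } else {
        lr <- lr / 2
      }
    }
    trace <- c(trace, cur$loss)
    if (!accepted) break   # step size underflow: converged/stalled
  }
  X <- fusion_forward(sims$disease, fd)$fused
  Y <- fusion_forward(sims$drug, fg)$fused
  als_report <- NULL
  if (config$als_finish) {
    fit <- fit_als(X, Y, O, f_p = config$f_p, lambda = config$lambda,
                   max_iter = config$als_iters, tol = config$als_tol,
                   pos_weight = config$pos_weight,
                   init = list(W_imc = W, H_imc = H))
    model <- fit$model
    als_report <- fit$report
  } else {
    model <- imc_model(W, H, config$lambda)
  }
  scores <- predict_all(X, model, Y)
  list(factors_disease = fd, factors_drug = fg, model = model,
       X = X, Y = Y, scores = scores,
       report = list(objective = trace, iterations = length(trace) - 1,
                     converged = length(trace) - 1 < config$epochs,
                     als = als_report, seed = config$seed,
                     config = unclass(config)))
}

strip_modality <- function(s) {
  attr(s, "modality") <- NULL
  s
}
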