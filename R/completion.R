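#' Construct an inductive matrix completion model
#'
#' Scores pair (i, j) as the bilinear form `x_i P y_j'` of fused disease and
#' drug feature vectors, with the projection factored low rank as
#' `P = W_imc H_imc'` (`W_imc`: f_d x f_p, `H_imc`: f_g x f_p). Only the
#' product `P` is identified; the individual factors carry gauge freedom
#' `(W G, H G^-T)`.
#'
#' @param W_imc disease-side factor, f_d x f_p.
#' @param H_imc drug-side factor, f_g x f_p.
#' @param lambda non-negative ridge penalty the model was fitted with.
#' @return An object of class `imc_model`.
#' @export
imc_model <- function(W_imc, H_imc, lambda = 0) {
  stopifnot(is.matrix(W_imc), is.matrix(H_imc),
            ncol(W_imc) == ncol(H_imc), ncol(W_imc) >= 1,
            all(is.finite(W_imc)), all(is.finite(H_imc)), lambda >= 0)
  structure(list(W_imc = W_imc, H_imc = H_imc,
                 lambda = lambda, f_p = ncol(W_imc)),
            class = "imc_model")
}

#' Score a single disease-drug pair
#'
#' @param x_i fused disease feature vector (length f_d).
#' @param model an `imc_model`.
#' @param y_j fused drug feature vector (length f_g).
#' @return The scalar association score `x_i W_imc H_imc' y_j'`.
#' @export
score_pair <- function(x_i, model, y_j) {
  x_i <- as.numeric(x_i); y_j <- as.numeric(y_j)
  if (length(x_i) != nrow(model$W_imc)) {
    stop_validation(sprintf("disease vector length %d != model f_d %d",
                            length(x_i), nrow(model$W_imc)))
  }
  if (length(y_j) != nrow(model$H_imc)) {
    stop_validation(sprintf("drug vector length %d != model f_g %d",
                            length(y_j), nrow(model$H_imc)))
  }
  drop(crossprod(x_i, model$W_imc) %*% crossprod(model$H_imc, y_j))
}

#' Score every disease-drug pair
#'
#' @param X fused disease feature matrix (N_d x f_d).
#' @param model an `imc_model`.
#' @param Y fused drug feature matrix (N_g x f_g).
#' @return Dense N_d x N_g score matrix with disease/drug ids as dimnames.
#' @export
predict_all <- function(X, model, Y) {
  if (ncol(X) != nrow(model$W_imc) || ncol(Y) != nrow(model$H_imc)) {
    stop_validation("feature widths do not match model factors")
  }
  S <- (X %*% model$W_imc) %*% t(Y %*% model$H_imc)
  dimnames(S) <- list(rownames(X), rownames(Y))
  S
}

imc_objective <- function(X, Y, O, W, H, lambda, pos_weight = 1) {
  S <- (X %*% W) %*% t(Y %*% H)
  R <- O - S
  wse <- if (pos_weight == 1) sum(R^2) else sum((1 + (pos_weight - 1) * O) * R^2)
  wse + lambda / 2 * (sum(W^2) + sum(H^2))
}

# Exact solution of A M C + (lambda/2) M = D for symmetric PSD A, C via
# eigendecompositions; denominators floored at 1e-10 against singular systems.
solve_stein_ridge <- function(A, C, D, lambda) {
  eA <- eigen(A, symmetric = TRUE)
  eC <- eigen(C, symmetric = TRUE)
  den <- outer(pmax(eA$values, 0), pmax(eC$values, 0)) + lambda / 2
  den[den < 1e-10] <- 1e-10
  eA$vectors %*% ((crossprod(eA$vectors, D) %*% eC$vectors) / den) %*% t(eC$vectors)
}

#' Fit the bilinear completion model by alternating least squares
#'
#' Minimizes, over `W_imc` and `H_imc`,
#' `sum_(i,j) (O_ij - x_i W H' y_j')^2 + lambda/2 (||W||_F^2 + ||H||_F^2)`
#' with the sum over all pairs (unobserved cells treated as 0). Each half
#' step is an exactly solved ridge least-squares problem, so the objective is
#' non-increasing at every iteration. An optional weight `pos_weight >= 1` on
#' positive cells is handled by majorization (each half step minimizes a tight
#' upper bound, preserving monotonicity in the weighted objective).
#'
#' @param X fused disease features (N_d x f_d).
#' @param Y fused drug features (N_g x f_g).
#' @param O numeric association (or real-valued target) matrix, N_d x N_g.
#' @param f_p latent dimension of the factorization `P = W H'`.
#' @param lambda non-negative ridge penalty.
#' @param max_iter maximum ALS sweeps.
#' @param tol stop when the relative objective decrease falls below this.
#' @param seed seed for the Gaussian factor initialization.
#' @param pos_weight weight (>= 1) on cells with `O == 1`.
#' @param init optional list with `W_imc`, `H_imc` to start from (overrides
#'   the seeded initialization).
#' @return List with `model` (an `imc_model`) and `report` (objective trace,
#'   iterations, convergence flag, seed).
#' @export
fit_als <- function(X, Y, O, f_p = 16, lambda = 1, max_iter = 100,
                    tol = 1e-10, seed = 1, pos_weight = 1, init = NULL) {
  stopifnot(nrow(X) == nrow(O), nrow(Y) == ncol(O), f_p >= 1,
            lambda >= 0, pos_weight >= 1)
  f_d <- ncol(X); f_g <- ncol(Y)
  if (is.null(init)) {
    with_seed(seed, {
      W <- matrix(stats::rnorm(f_d * f_p) / sqrt(f_p), f_d, f_p)
      H <- matrix(stats::rnorm(f_g * f_p) / sqrt(f_p), f_g, f_p)
    })
  } else {
    W <- init$W_imc; H <- init$H_imc
    stopifnot(ncol(W) == f_p, ncol(H) == f_p)
  }
  XtX <- crossprod(X)
  YtY <- crossprod(Y)
  obj <- imc_objective(X, Y, O, W, H, lambda, pos_weight)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Otgt <- O
    lam_eff <- lambda
    if (pos_weight > 1) {
      # majorize: surrogate target pulls weighted residuals, scaled by w_max
      S <- (X %*% W) %*% t(Y %*% H)
      Wt <- 1 + (pos_weight - 1) * O
      Otgt <- S + (Wt / pos_weight) * (O - S)
      lam_eff <- lambda / pos_weight
    }
    B <- Y %*% H
    W <- solve_stein_ridge(XtX, crossprod(B), crossprod(X, Otgt %*% B), lam_eff)
    if (pos_weight > 1) {
      S <- (X %*% W) %*% t(Y %*% H)
      Wt <- 1 + (pos_weight - 1) * O
      Otgt <- S + (Wt / pos_weight) * (O - S)
    }
    A <- X %*% W
    H <- solve_stein_ridge(YtY, crossprod(A), crossprod(Y, crossprod(Otgt, A)), lam_eff)
    obj_new <- imc_objective(X, Y, O, W, H, lambda, pos_weight)
    if (!is.finite(obj_new)) {
      stop_validation(sprintf("numerical failure: non-finite objective at iteration %d", it))
    }
    trace <- c(trace, obj_new)
    if (obj > 0 && (obj - obj_new) / max(obj, .Machine$double.eps) < tol) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  list(model = imc_model(W, H, lambda),
       report = list(objective = trace, iterations = length(trace) - 1,
                     converged = converged, seed = seed))
}
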