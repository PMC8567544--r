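#' Construct low-rank multimodal fusion factors
#'
#' The fusion layer maps M per-modality feature vectors `z_1..z_M` of an
#' entity to one fused vector of width `out_dim`. Conceptually the map is a
#' multilinear layer `f = W . (z_1 x ... x z_M) + b` whose order-(M+1) weight
#' tensor `W` is never materialized: it is factorized as a sum of `rank`
#' modality-wise outer products, `W = sum_i w_1^(i) x ... x w_M^(i)`, so the
#' fused output is
#' `f = sum_i (z_1' w_1^(i)) o (z_2' w_2^(i)) o ... + b`
#' with `o` the element-wise product. With `append_one`, a constant 1 is
#' appended to each modality vector so unimodal terms survive the product.
#'
#' @param factors list (one per modality) of arrays with dim
#'   `(input_width, out_dim, rank)`.
#' @param bias numeric vector of length `out_dim`.
#' @param append_one whether a constant 1 is appended to each modality input.
#' @return An object of class `fusion_factors`.
#' @export
fusion_factors <- function(factors, bias, append_one = TRUE) {
  stopifnot(is.list(factors), length(factors) >= 1)
  dims3 <- lapply(factors, dim)
  if (any(vapply(dims3, length, 1L) != 3)) {
    stop_validation("each modality factor must be a 3-d array (width, out_dim, rank)")
  }
  out_dim <- dims3[[1]][2]
  rank <- dims3[[1]][3]
  for (m in seq_along(factors)) {
    if (dims3[[m]][2] != out_dim || dims3[[m]][3] != rank) {
      stop_validation(sprintf("modality %d factor disagrees on out_dim/rank", m))
    }
    if (!all(is.finite(factors[[m]]))) {
      stop_validation(sprintf("non-finite entries in modality %d factors", m))
    }
  }
  stopifnot(length(bias) == out_dim, all(is.finite(bias)))
  structure(list(factors = factors, bias = as.numeric(bias),
                 rank = as.integer(rank), out_dim = as.integer(out_dim),
                 append_one = isTRUE(append_one)),
            class = "fusion_factors")
}

#' Initialize fusion factors reproducibly
#'
#' Two schemes, both seeded and fully reproducible:
#' \describe{
#'   \item{`random`}{Gaussian entries with per-modality scale
#'     `1 / sqrt(rank * d_m)` (so the summed rank-1 products start at unit
#'     order), zero bias.}
#'   \item{`passthrough`}{rank terms are assigned round-robin to modalities;
#'     a term owned by modality m carries a Gaussian projection of that
#'     modality and, via the appended constant, contributes exactly 1 for
#'     every other modality. The fused map therefore starts as an additive
#'     random projection of the concatenated modalities, and gradient
#'     training moves it toward genuinely multiplicative interactions.
#'     Requires `append_one`.}
#' }
#'
#' @param dims integer vector of modality input widths (before the appended
#'   constant).
#' @param rank decomposition rank of the fusion weight tensor.
#' @param out_dim fused output width.
#' @param seed integer seed.
#' @param append_one append a constant 1 to each modality input.
#' @param method initialization scheme, `"random"` (default) or
#'   `"passthrough"`.
#' @return A `fusion_factors` object.
#' @export
init_fusion_factors <- function(dims, rank, out_dim, seed, append_one = TRUE,
                                method = c("random", "passthrough")) {
  stopifnot(all(dims >= 1), rank >= 1, out_dim >= 1)
  method <- match.arg(method)
  if (method == "passthrough" && !append_one) {
    stop_validation("passthrough initialization requires append_one")
  }
  with_seed(seed, {
    M <- length(dims)
    factors <- if (method == "random") {
      lapply(seq_along(dims), function(m) {
        d_in <- dims[m] + as.integer(append_one)
        array(stats::rnorm(d_in * out_dim * rank) / sqrt(rank * dims[m]),
              dim = c(d_in, out_dim, rank))
      })
    } else {
      sel <- rep_len(seq_len(M), rank)
      lapply(seq_along(dims), function(m) {
        arr <- array(0, dim = c(dims[m] + 1, out_dim, rank))
        n_own <- max(sum(sel == m), 1)
        for (i in seq_len(rank)) {
          if (sel[i] == m) {
            arr[seq_len(dims[m]), , i] <-
              stats::rnorm(dims[m] * out_dim) / sqrt(n_own * dims[m])
          } else {
            arr[dims[m] + 1, , i] <- 1
          }
        }
        arr
      })
    }
    fusion_factors(factors, bias = rep(0, out_dim), append_one = append_one)
  })
}

# Append the constant-1 column and check widths; errors name the modality.
fusion_inputs <- function(view, f) {
  stopifnot(is.list(view), length(view) == length(f$factors))
  n <- nrow(view[[1]])
  lapply(seq_along(view), function(m) {
    z <- view[[m]]
    if (!is.matrix(z) || nrow(z) != n) {
      stop_validation(sprintf("modality %d: expected a matrix with %d rows", m, n))
    }
    if (f$append_one) z <- cbind(z, 1)
    if (ncol(z) != dim(f$factors[[m]])[1]) {
      stop_validation(sprintf(
        "modality %d: input width %d does not match factor width %d",
        m, ncol(z), dim(f$factors[[m]])[1]))
    }
    z
  })
}

# Per-modality projections A_m = Z_m W_m, as n x (out_dim * rank) matrices
# with column (i - 1) * out_dim + o holding rank-term i, output coordinate o.
fusion_projections <- function(Z, f) {
  lapply(seq_along(Z), function(m) {
    Z[[m]] %*% matrix(f$factors[[m]], nrow = dim(f$factors[[m]])[1])
  })
}

#' Apply the low-rank multimodal fusion map
#'
#' Computes, for every entity (row of the modality matrices), the fused
#' vector `sum_i prod_m (z_m' w_m^(i)) + b` without materializing the weight
#' tensor. The element-wise product runs over modalities in input order.
#'
#' @param view list of per-modality feature matrices, one row per entity, all
#'   sharing row count and order.
#' @param f a `fusion_factors` object.
#' @return Matrix of fused features, one row per entity (rownames propagated
#'   from the first modality).
#' @export
lmf_transform <- function(view, f) {
  Z <- fusion_inputs(view, f)
  A <- fusion_projections(Z, f)
  prod_all <- Reduce(`*`, A)
  n <- nrow(prod_all)
  dim(prod_all) <- c(n, f$out_dim, f$rank)
  fused <- rowSums(prod_all, dims = 2)
  if (f$rank == 1) fused <- matrix(fused, n, f$out_dim)
  fused <- fused + matrix(f$bias, n, f$out_dim, byrow = TRUE)
  rownames(fused) <- rownames(view[[1]])
  fused
}

#' Full-tensor reference for the fusion map (test oracle)
#'
#' Materializes the input tensor `Z = z_1 x ... x z_M` per entity,
#' reconstructs the full weight tensor `W = sum_i x_m w_m^(i)`, and returns
#' the explicit contraction `W . Z + b`. Exponential in memory; refuses
#' instances whose tensor exceeds `cap` elements. Exists to validate
#' [lmf_transform()], which must agree with it to numerical precision.
#'
#' @inheritParams lmf_transform
#' @param cap maximum number of elements in the materialized weight tensor.
#' @return Matrix of fused features identical in layout to [lmf_transform()].
#' @export
full_tensor_oracle <- function(view, f, cap = 1e6) {
  Z <- fusion_inputs(view, f)
  widths <- vapply(Z, ncol, 1L)
  if (prod(widths) * f$out_dim > cap) {
    stop_validation(sprintf(
      "full_tensor_oracle refused: tensor of %g elements exceeds cap %g (oracle is test-scale only)",
      prod(widths) * f$out_dim, cap))
  }
  # W flattened: prod(widths) x out_dim; column o is sum_i kron of w_m^(i)[, o]
  Wmat <- matrix(0, prod(widths), f$out_dim)
  for (o in seq_len(f$out_dim)) {
    for (i in seq_len(f$rank)) {
      vecs <- lapply(f$factors, function(w) w[, o, i])
      Wmat[, o] <- Wmat[, o] + as.vector(Reduce(function(a, b) outer(a, b), vecs))
    }
  }
  n <- nrow(Z[[1]])
  fused <- matrix(NA_real_, n, f$out_dim)
  for (e in seq_len(n)) {
    zvecs <- lapply(Z, function(z) z[e, ])
    zt <- as.vector(Reduce(function(a, b) outer(a, b), zvecs))
    fused[e, ] <- as.vector(crossprod(Wmat, zt)) + f$bias
  }
  rownames(fused) <- rownames(view[[1]])
  fused
}

#' Fuse one entity side from its similarity networks
#'
#' The modality-m feature vector of entity e is its row in similarity
#' network m, so each entity is described by its similarity to all entities
#' of its own type under each data source. All networks must share entity ids
#' in identical order.
#'
#' @param sim_matrices list of square similarity matrices with identical
#'   dimnames.
#' @param f a `fusion_factors` object whose modality widths equal the number
#'   of entities.
#' @return Matrix of fused features, one row per entity.
#' @export
fuse_entity_side <- function(sim_matrices, f) {
  stopifnot(length(sim_matrices) >= 1)
  ids <- rownames(sim_matrices[[1]])
  for (m in seq_along(sim_matrices)) {
    if (!identical(rownames(sim_matrices[[m]]), ids)) {
      stop_validation(sprintf("modality %d entity ids differ in content or order", m))
    }
  }
  view <- lapply(sim_matrices, function(s) {
    attr(s, "modality") <- NULL
    s
  })
  lmf_transform(view, f)
}
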