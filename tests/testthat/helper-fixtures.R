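# Shared fixtures, built in code at test time.

# small labeled binary association matrix
tiny_assoc <- function(n_d = 4, n_g = 5, seed = 42, density = 0.4) {
  with_seed <- drfuse:::with_seed
  with_seed(seed, {
    O <- matrix(rbinom(n_d * n_g, 1, density), n_d, n_g)
    dimnames(O) <- list(paste0("dis", seq_len(n_d)), paste0("drg", seq_len(n_g)))
    O
  })
}

# random fusion instance: view + factors with small dimensions
random_fusion_instance <- function(M, dmax = 4, rmax = 3, omax = 3, n = 3,
                                   append_one = TRUE) {
  dims <- sample(dmax, M, replace = TRUE)
  rank <- sample(rmax, 1)
  out_dim <- sample(omax, 1)
  view <- lapply(dims, function(d) matrix(rnorm(n * d), n, d))
  factors <- lapply(dims, function(d) {
    array(rnorm((d + append_one) * out_dim * rank), c(d + append_one, out_dim, rank))
  })
  f <- fusion_factors(factors, bias = rnorm(out_dim), append_one = append_one)
  list(view = view, f = f)
}

# brute-force AUROC by exhaustive positive-negative pair counting, ties 1/2
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# a small synthetic bundle for pipeline tests (cheap but informative)
small_bundle <- function(seed = 7, flip_noise = 0.02, semantic_noise = 0.05,
                         n_diseases = 40, n_drugs = 50) {
  generate_bundle(synth_config(
    n_diseases = n_diseases, n_drugs = n_drugs, latent_dim = 4,
    target_density = 0.08, fingerprint_bits = 64,
    semantic_noise = semantic_noise, flip_noise = flip_noise, seed = seed
  ))
}

# lightweight training configuration for pipeline tests
fast_config <- function(...) {
  train_config(out_dim_disease = 32, out_dim_drug = 32, f_p = 8,
               rank_disease = 4, rank_drug = 4, epochs = 10, lambda = 5, ...)
}
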