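#' Configuration for the synthetic benchmark generator
#'
#' Defaults emulate the shape of public disease-drug repositioning
#' benchmarks at a scale where full cross-validation runs in minutes on one
#' CPU: a sparse binary bipartite association matrix driven by a genuinely
#' low-rank latent signal, chemical-fingerprint-like bit tables correlated
#' with the drug factors, and a smooth disease-disease similarity matrix
#' correlated with the disease factors.
#'
#' @param n_diseases,n_drugs entity counts.
#' @param latent_dim rank of the latent association signal.
#' @param target_density expected fraction of positive cells, in (0, 1).
#' @param fingerprint_bits number of fingerprint descriptor positions.
#' @param semantic_noise sd of the symmetric Gaussian noise added to the
#'   semantic similarity matrix.
#' @param flip_noise probability each association cell is flipped, in
#'   `[0, 0.5)`.
#' @param seed integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_diseases = 120, n_drugs = 150, latent_dim = 8,
                         target_density = 0.05, fingerprint_bits = 256,
                         semantic_noise = 0.05, flip_noise = 0.02, seed = 7) {
  stopifnot(n_diseases >= 2, n_drugs >= 2, latent_dim >= 1,
            target_density > 0, target_density < 1, fingerprint_bits >= 1,
            semantic_noise >= 0, flip_noise >= 0, flip_noise < 0.5)
  structure(list(n_diseases = n_diseases, n_drugs = n_drugs,
                 latent_dim = latent_dim, target_density = target_density,
                 fingerprint_bits = fingerprint_bits,
                 semantic_noise = semantic_noise, flip_noise = flip_noise,
                 seed = as.integer(seed)),
            class = c("synth_config", "list"))
}

# intercept c such that mean sigmoid(signal + c) hits the target density
calibrate_intercept <- function(signal, target, tol = 0.005) {
  dens <- function(c) mean(sigmoid(signal + c))
  lo <- -50; hi <- 50
  if (dens(lo) > target || dens(hi) < target) {
    stop_validation("target density unreachable given the latent signal scale")
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    d <- dens(mid)
    if (abs(d - target) <= tol) return(mid)
    if (d < target) lo <- mid else hi <- mid
  }
  stop_validation("density calibration failed to converge")
}

#' Generate a synthetic dataset bundle with known ground truth
#'
#' Latent factors `U` (diseases) and `V` (drugs) are i.i.d. standard normal.
#' Cell (i, j) is positive with probability `sigmoid(u_i . v_j + c)`, with
#' `c` calibrated by bisection so the expected density matches
#' `target_density` within 0.005; each cell is then flipped independently
#' with probability `flip_noise`. Fingerprint bit b of drug j is set with
#' probability `sigmoid(v_j . beta_b)`, `beta_b` seeded normal with variance
#' `1/latent_dim`. Disease semantic similarity is the Gaussian kernel
#' `exp(-||u_i - u_k||^2 / (2 sigma^2))` with `sigma` the median pairwise
#' distance, plus symmetric Gaussian noise, clipped to `[0, 1]`, diagonal
#' forced to 1.
#'
#' @param cfg a [synth_config()].
#' @return List with `bundle` (a validated `dd_bundle`) and `truth` (latent
#'   `U`, `V` and the real-valued signal matrix `U V'`).
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_d <- cfg$n_diseases; n_g <- cfg$n_drugs; r <- cfg$latent_dim
    disease_ids <- sprintf("disease_%03d", seq_len(n_d))
    drug_ids <- sprintf("drug_%03d", seq_len(n_g))
    U <- matrix(stats::rnorm(n_d * r), n_d, r, dimnames = list(disease_ids, NULL))
    V <- matrix(stats::rnorm(n_g * r), n_g, r, dimnames = list(drug_ids, NULL))
    signal <- U %*% t(V)
    cc <- calibrate_intercept(signal, cfg$target_density)
    prob <- sigmoid(signal + cc)
    O <- matrix(as.double(stats::rbinom(n_d * n_g, 1, prob)), n_d, n_g,
                dimnames = list(disease_ids, drug_ids))
    if (cfg$flip_noise > 0) {
      flips <- matrix(stats::rbinom(n_d * n_g, 1, cfg$flip_noise), n_d, n_g)
      O <- abs(O - flips)
      dimnames(O) <- list(disease_ids, drug_ids)
    }
    beta <- matrix(stats::rnorm(cfg$fingerprint_bits * r, sd = 1 / sqrt(r)),
                   cfg$fingerprint_bits, r)
    fp_prob <- sigmoid(V %*% t(beta))
    fp <- matrix(as.double(stats::rbinom(length(fp_prob), 1, fp_prob)), n_g,
                 cfg$fingerprint_bits,
                 dimnames = list(drug_ids,
                                 sprintf("bit_%03d", seq_len(cfg$fingerprint_bits))))
    d2 <- as.matrix(stats::dist(U))^2
    sigma <- stats::median(stats::dist(U))
    S <- exp(-d2 / (2 * sigma^2))
    if (cfg$semantic_noise > 0) {
      E <- matrix(stats::rnorm(n_d * n_d, sd = cfg$semantic_noise), n_d, n_d)
      S <- S + (E + t(E)) / 2
    }
    S <- pmin(pmax(S, 0), 1)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(disease_ids, disease_ids)
    bundle <- dd_bundle(
      associations = O, fingerprints = fp, disease_semantic_sim = S,
      metadata = list(generator = "drfuse-synthetic", seed = cfg$seed,
                      latent_dim = r, target_density = cfg$target_density,
                      flip_noise = cfg$flip_noise,
                      semantic_noise = cfg$semantic_noise)
    )
    list(bundle = bundle,
         truth = list(U = U, V = V, signal = signal, intercept = cc))
  })
}

#' Permute association labels (null-model fixture)
#'
#' Shuffles the association cells uniformly across the whole matrix,
#' preserving the total positive count while destroying any relation to the
#' similarity structure. Fingerprints and semantic similarity are untouched.
#'
#' @param bundle a `dd_bundle`.
#' @param seed integer seed.
#' @return A `dd_bundle` with permuted associations.
#' @export
permute_labels <- function(bundle, seed) {
  O <- bundle$associations
  v <- with_seed(seed, sample(as.vector(O)))
  O2 <- matrix(v, nrow(O), ncol(O), dimnames = dimnames(O))
  bundle$associations <- O2
  bundle
}
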