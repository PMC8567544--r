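#' Interaction profiles from an association matrix
#'
#' The interaction profile of a disease is its row of the binary association
#' matrix; the profile of a drug is its column, transposed so that profiles
#' are always rows of the returned matrix.
#'
#' @param assoc binary labeled association matrix (diseases x drugs).
#' @return A binary matrix, one profile per row.
#' @export
disease_profiles <- function(assoc) {
  stopifnot(is_binary_matrix(assoc))
  assoc
}

#' @rdname disease_profiles
#' @export
drug_profiles <- function(assoc) {
  stopifnot(is_binary_matrix(assoc))
  t(assoc)
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Similarity between two entities x and y with binary interaction profiles
#' `Y(x)`, `Y(y)` is `exp(-gamma * ||Y(x) - Y(y)||^2)`, with the bandwidth
#' normalized by the mean squared profile norm:
#' `gamma = gamma_prime * n / sum_x ||Y(x)||^2`. Entities with identical
#' profiles get similarity 1; the kernel is symmetric and positive
#' semidefinite.
#'
#' @param profiles binary matrix, one interaction profile per row (see
#'   [disease_profiles()] / [drug_profiles()]).
#' @param gamma_prime positive bandwidth pre-factor (default 1, the standard
#'   normalization).
#' @param modality name recorded on the result (attribute `modality`).
#' @return A symmetric unit-diagonal similarity matrix with entries in
#'   `(0, 1]`, entity ids in its dimnames.
#' @export
gip_similarity <- function(profiles, gamma_prime = 1, modality = "gip") {
  stopifnot(is.matrix(profiles), gamma_prime > 0)
  if (!is_binary_matrix(profiles)) stop_validation("profiles must be binary")
  n <- nrow(profiles)
  norms2 <- rowSums(profiles^2)
  mean_norm2 <- mean(norms2)
  if (mean_norm2 == 0) {
    stop_validation(
      "degenerate bandwidth: all interaction profiles are zero (mean squared norm 0)")
  }
  gamma <- gamma_prime / mean_norm2
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b
  g <- tcrossprod(profiles)
  d2 <- outer(norms2, norms2, "+") - 2 * g
  d2[d2 < 0] <- 0
  s <- exp(-gamma * d2)
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(rownames(profiles), rownames(profiles))
  attr(s, "modality") <- modality
  s
}

#' Jaccard (Tanimoto) similarity between binary fingerprints
#'
#' For fingerprint bit sets P and Q the similarity is
#' `|P intersect Q| / |P union Q|`, counting set bits. Two drugs with empty
#' fingerprints have no defined overlap; by convention the diagonal stays 1
#' and an empty fingerprint scores 0 against every other drug (a warning is
#' emitted when empty fingerprints are present).
#'
#' @param fps binary matrix of fingerprints, one drug per row, drug ids as
#'   rownames.
#' @param modality name recorded on the result.
#' @return A symmetric similarity matrix with entries in `[0, 1]`.
#' @export
jaccard_similarity <- function(fps, modality = "fingerprint-jaccard") {
  stopifnot(is.matrix(fps), nrow(fps) > 0)
  if (!is_binary_matrix(fps)) stop_validation("fingerprints must be binary")
  inter <- tcrossprod(fps)
  sizes <- rowSums(fps)
  uni <- outer(sizes, sizes, "+") - inter
  s <- ifelse(uni > 0, inter / uni, 0)
  empty <- sizes == 0
  if (any(empty)) {
    warning(sprintf(
      "%d drug(s) have empty fingerprints; convention: self-similarity 1, 0 elsewhere",
      sum(empty)))
  }
  diag(s) <- 1
  s <- (s + t(s)) / 2
  dimnames(s) <- list(rownames(fps), rownames(fps))
  attr(s, "modality") <- modality
  s
}

#' Check a matrix satisfies the similarity-matrix contract
#'
#' Symmetry and unit diagonal within 1e-10, entries in `[0, 1]`.
#'
#' @param s matrix to check.
#' @return `TRUE` invisibly, or an error.
#' @keywords internal
#' @export
assert_similarity <- function(s) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  if (nrow(s) > 0) {
    if (max(abs(s - t(s))) > 1e-10) stop_validation("similarity not symmetric")
    if (max(abs(diag(s) - 1)) > 1e-10) stop_validation("similarity diagonal not 1")
    if (min(s) < -1e-10 || max(s) > 1 + 1e-10) {
      stop_validation("similarity entries outside [0, 1]")
    }
  }
  invisible(TRUE)
}

#' All similarity modalities of a bundle
#'
#' Builds the modality lists both fusion sides consume: for diseases the GIP
#' kernel on association rows plus the precomputed semantic similarity; for
#' drugs the GIP kernel on association columns plus fingerprint Jaccard
#' similarity. GIP similarities are computed from the bundle's (possibly
#' training-masked) association matrix, so cross-validation recomputes them
#' without test labels.
#'
#' @param bundle a `dd_bundle`.
#' @param gamma_prime GIP bandwidth pre-factor.
#' @return A list with elements `disease` and `drug`, each a list of
#'   similarity matrices sharing entity ids.
#' @export
bundle_similarities <- function(bundle, gamma_prime = 1) {
  O <- bundle$associations
  list(
    disease = list(
      gip = gip_similarity(disease_profiles(O), gamma_prime, "disease-gip"),
      semantic = structure(bundle$disease_semantic_sim, modality = "disease-semantic")
    ),
    drug = list(
      gip = gip_similarity(drug_profiles(O), gamma_prime, "drug-gip"),
      jaccard = jaccard_similarity(bundle$fingerprints)
    )
  )
}
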