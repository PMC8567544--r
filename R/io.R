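#' Read a labeled numeric matrix from delimited text
#'
#' Parses a rectangular whitespace- or tab-delimited numeric grid into a base
#' matrix with row and column identifiers in its `dimnames`. When a header is
#' present the first line carries the column ids and each data line leads with
#' a row id; a corner token in the header line (same field count as the data
#' lines) is ignored. Headerless files receive generated ids `r0, r1, ...` and
#' `c0, c1, ...`.
#'
#' @param path path to the file.
#' @param has_header `NA` (default) to auto-detect (first token non-numeric
#'   implies a header), or `TRUE`/`FALSE` to force.
#' @param sep field separator regular expression; the default splits on runs
#'   of tabs or spaces.
#' @return A numeric matrix with unique `rownames` and `colnames`.
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "x\t1\t0", "y\t0\t1"), f)
#' read_matrix(f)
#' @export
read_matrix <- function(path, has_header = NA, sep = "[\t ]+") {
  if (!file.exists(path)) {
    stop_validation(sprintf("file not found: %s", path))
  }
  lines <- readLines(path)
  # trailing blank lines are tolerated; internal blank lines are not
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0 || (length(lines) == 1 && !nzchar(trimws(lines[1])))) {
    m <- matrix(numeric(0), 0, 0)
    dimnames(m) <- list(character(0), character(0))
    return(m)
  }
  tok <- strsplit(trimws(lines), sep)
  first <- tok[[1]][1]
  if (is.na(has_header)) {
    has_header <- is.na(suppressWarnings(as.numeric(first)))
  }
  if (has_header) {
    col_ids <- tok[[1]]
    body <- tok[-1]
    if (length(body) == 0) {
      m <- matrix(numeric(0), 0, length(col_ids))
      dimnames(m) <- list(character(0), col_ids)
      return(m)
    }
    widths <- lengths(body)
    if (length(unique(widths)) != 1) {
      bad <- which(widths != widths[1])[1] + 1
      stop_validation(sprintf("ragged rows: line %d has %d fields, expected %d",
                              bad + 1, widths[bad - 1], widths[1]))
    }
    if (length(col_ids) == widths[1]) {
      col_ids <- col_ids[-1]   # corner token present
    } else if (length(col_ids) != widths[1] - 1) {
      stop_validation(sprintf(
        "header has %d fields but data rows have %d", length(col_ids), widths[1]))
    }
    row_ids <- vapply(body, `[`, character(1), 1)
    cells <- lapply(body, function(x) x[-1])
  } else {
    body <- tok
    widths <- lengths(body)
    if (length(unique(widths)) != 1) {
      bad <- which(widths != widths[1])[1]
      stop_validation(sprintf("ragged rows: line %d has %d fields, expected %d",
                              bad, widths[bad], widths[1]))
    }
    row_ids <- paste0("r", seq_along(body) - 1)
    col_ids <- paste0("c", seq_len(widths[1]) - 1)
    cells <- body
  }
  n <- length(cells)
  p <- length(col_ids)
  vals <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop_validation(sprintf("non-numeric cell '%s' at row %d, column %d",
                              cells[[i]][j], i, j))
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids)) stop_validation("duplicate row ids")
  if (anyDuplicated(col_ids)) stop_validation("duplicate column ids")
  dimnames(vals) <- list(row_ids, col_ids)
  vals
}

#' Write a labeled numeric matrix as delimited text
#'
#' Inverse of [read_matrix()]: tab-separated, header line with column ids,
#' each data line led by its row id. Values are written with 17 significant
#' digits so the read/write round trip is value-identical for finite doubles.
#'
#' @param m numeric matrix with `rownames` and `colnames` (generated when
#'   absent).
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (nrow(m) == 0 && ncol(m) == 0) {
    writeLines("", path)
    return(invisible(path))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)) - 1)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)) - 1)
  ids <- c(rownames(m), colnames(m))
  if (any(grepl("[\t ]", ids))) {
    stop_validation("row/column ids must not contain the delimiter (tab or space)")
  }
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste(colnames(m), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t")
    }, character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Assemble and validate a disease-drug dataset bundle
#'
#' A bundle holds the three components every analysis needs, with diseases as
#' rows and drugs as columns throughout:
#' \describe{
#'   \item{associations}{binary disease x drug matrix `O` (`O[i, j] = 1` when
#'     disease i is known to be associated with drug j).}
#'   \item{fingerprints}{binary drug x descriptor-bit matrix of chemical
#'     substructure fingerprints.}
#'   \item{disease_semantic_sim}{precomputed disease-disease semantic
#'     similarity (e.g. text-mining derived), symmetric with unit diagonal,
#'     values in `[0, 1]`.}
#' }
#'
#' @param associations binary labeled matrix, diseases x drugs.
#' @param fingerprints binary labeled matrix, drugs x bits.
#' @param disease_semantic_sim labeled square matrix, diseases x diseases.
#' @param metadata named list of free-form metadata.
#' @return An object of class `dd_bundle`.
#' @export
dd_bundle <- function(associations, fingerprints, disease_semantic_sim,
                      metadata = list()) {
  b <- structure(
    list(associations = associations, fingerprints = fingerprints,
         disease_semantic_sim = disease_semantic_sim, metadata = metadata),
    class = "dd_bundle"
  )
  validate_bundle(b)
}

#' Validate a dataset bundle's invariants
#'
#' Checks binarity of associations and fingerprints, id consistency between
#' components, and symmetry/unit diagonal (tolerance 1e-8) of the semantic
#' similarity matrix. Association columns are reordered to the fingerprint
#' drug order when both carry ids.
#'
#' @param b a `dd_bundle`.
#' @return The (possibly column-reordered) validated bundle.
#' @export
validate_bundle <- function(b) {
  O <- b$associations
  if (!is_binary_matrix(O)) {
    bad <- which(!(O %in% c(0, 1)))[1]
    stop_validation(sprintf(
      "association matrix must be binary; found %g at cell %d", O[bad], bad))
  }
  fp <- b$fingerprints
  if (!is_binary_matrix(fp)) stop_validation("fingerprint bits must be 0/1")
  if (anyDuplicated(rownames(fp))) stop_validation("duplicate fingerprint drug ids")
  missing_fp <- setdiff(rownames(fp), colnames(O))
  if (length(missing_fp) > 0) {
    stop_validation(paste0("fingerprint drug ids absent from associations: ",
                           paste(utils::head(missing_fp, 5), collapse = ", ")))
  }
  if (!setequal(rownames(fp), colnames(O))) {
    stop_validation(paste0("association drugs without fingerprints: ",
      paste(utils::head(setdiff(colnames(O), rownames(fp)), 5), collapse = ", ")))
  }
  # canonical drug order comes from the fingerprint table
  b$associations <- O[, rownames(fp), drop = FALSE]
  S <- b$disease_semantic_sim
  if (!identical(rownames(S), rownames(O)) || !identical(colnames(S), rownames(O))) {
    stop_validation("semantic similarity ids must equal association disease ids")
  }
  if (nrow(S) > 0) {
    if (max(abs(S - t(S))) > 1e-8) {
      stop_validation("semantic similarity matrix is not symmetric (tol 1e-8)")
    }
    if (max(abs(diag(S) - 1)) > 1e-8) {
      stop_validation("semantic similarity diagonal must be 1 (tol 1e-8)")
    }
    if (min(S) < -1e-8 || max(S) > 1 + 1e-8) {
      stop_validation("semantic similarity entries must lie in [0, 1]")
    }
  }
  b
}

#' @export
print.dd_bundle <- function(x, ...) {
  cat(sprintf("<dd_bundle> %d diseases x %d drugs, %d associations (density %.4f)\n",
              nrow(x$associations), ncol(x$associations),
              sum(x$associations),
              mean(x$associations)))
  cat(sprintf("  fingerprints: %d bits; semantic similarity: %dx%d\n",
              ncol(x$fingerprints), nrow(x$disease_semantic_sim),
              ncol(x$disease_semantic_sim)))
  invisible(x)
}

#' Load a dataset bundle from a manifest
#'
#' The manifest is a YAML (or JSON) file naming the three component files,
#' with paths resolved relative to the manifest's directory:
#' ```yaml
#' associations: associations.tsv
#' fingerprints: fingerprints.tsv
#' disease_semantic_sim: disease_semantic_sim.tsv
#' ```
#' A directory may be given instead; `manifest.yaml` inside it is used.
#'
#' @param path manifest file or directory containing `manifest.yaml`.
#' @return A validated `dd_bundle`.
#' @export
load_bundle <- function(path) {
  if (dir.exists(path)) {
    cand <- file.path(path, c("manifest.yaml", "manifest.yml", "manifest.json"))
    path <- cand[file.exists(cand)][1]
    if (is.na(path)) stop_validation("no manifest.yaml found in directory")
  }
  if (!file.exists(path)) stop_validation(sprintf("manifest not found: %s", path))
  man <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("associations", "fingerprints", "disease_semantic_sim")
  if (!all(need %in% names(man))) {
    stop_validation(paste0("manifest must name: ", paste(need, collapse = ", ")))
  }
  base <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  dd_bundle(
    associations = read_matrix(rel(man$associations)),
    fingerprints = read_matrix(rel(man$fingerprints)),
    disease_semantic_sim = read_matrix(rel(man$disease_semantic_sim)),
    metadata = if (is.null(man$metadata)) list() else as.list(man$metadata)
  )
}

#' Write a dataset bundle to a directory
#'
#' Writes the three component matrices as labeled TSVs plus a
#' `manifest.yaml`, in the layout [load_bundle()] reads.
#'
#' @param b a `dd_bundle`.
#' @param dir destination directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_bundle <- function(b, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(b$associations, file.path(dir, "associations.tsv"))
  write_matrix(b$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_matrix(b$disease_semantic_sim, file.path(dir, "disease_semantic_sim.tsv"))
  man <- list(associations = "associations.tsv",
              fingerprints = "fingerprints.tsv",
              disease_semantic_sim = "disease_semantic_sim.tsv")
  if (length(b$metadata) > 0) man$metadata <- b$metadata
  yaml::write_yaml(man, file.path(dir, "manifest.yaml"))
  invisible(file.path(dir, "manifest.yaml"))
}
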