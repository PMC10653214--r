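#' ECFP4 fingerprints
#'
#' Encodes molecules as hashed extended-connectivity fingerprints of diameter
#' 4 (Morgan radius 2) folded to `n_bits` binary positions — the fixed-length
#' descriptor the whole workflow runs on. Deterministic for a given canonical
#' SMILES. One batched RDKit call handles the whole input.
#'
#' @param records a `molecule_table` or character vector of SMILES.
#' @param n_bits fingerprint length (default 2048).
#' @return a `descriptor_matrix`: integer 0/1 matrix, one row per molecule
#'   (rownames = ids when available), with attributes `n_bits` and
#'   `has_affinity = FALSE`.
#' @export
ecfp4 <- function(records, n_bits = 2048L) {
  smiles <- if (is.character(records)) records else records$smiles
  ids <- if (is.character(records)) NULL else records$id
  stopifnot(n_bits >= 1L)
  if (length(smiles) == 0L) {
    return(descriptor_matrix(matrix(0L, 0L, n_bits), n_bits, FALSE))
  }
  res <- chem_call(list(op = "morgan", smiles = as.list(smiles),
                        n_bits = n_bits, radius = 2L))
  mat <- matrix(0L, nrow = length(smiles), ncol = n_bits)
  for (i in seq_along(res$bits)) {
    bits <- res$bits[[i]]
    if (is.null(bits)) {
      stop("featurization error: invalid molecule",
           if (!is.null(ids)) paste0(" '", ids[i], "'") else paste0(" at row ", i))
    }
    mat[i, unlist(bits) + 1L] <- 1L
  }
  rownames(mat) <- ids
  descriptor_matrix(mat, n_bits, FALSE)
}

descriptor_matrix <- function(mat, n_bits, has_affinity) {
  structure(mat, n_bits = as.integer(n_bits), has_affinity = has_affinity,
            class = c("descriptor_matrix", class(matrix())))
}

#' Tanimoto similarity between fingerprint rows
#'
#' `|a AND b| / |a OR b|` over the binary fingerprint portion; defined as 1
#' when both fingerprints are empty.
#'
#' @param a,b binary vectors (or single rows of a [ecfp4()] matrix) of equal
#'   length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("dimension error: fingerprints of length ", length(a), " vs ", length(b))
  }
  inter <- sum(a > 0 & b > 0)
  union <- sum(a > 0 | b > 0)
  if (union == 0) 1.0 else inter / union
}

#' Append a binding-affinity co-descriptor column
#'
#' Implements the structure-plus-affinity descriptor: the fingerprint bits are
#' kept exactly and a single scaled affinity column (kcal/mol divided by
#' `scale`) is appended. The default `scale` makes the affinity column's
#' spread comparable to that of a binary bit (sd about 0.5), so one
#' real-valued column cannot dominate 2048 binary ones in Euclidean distance:
#' `scale = 2 * sd(affinity)` (falling back to 1 when the sd is 0).
#'
#' @param descriptors a `descriptor_matrix` without an affinity column.
#' @param affinity numeric vector, kcal/mol, one per row; must be finite.
#' @param scale positive divisor applied to `affinity`; `NULL` (default) uses
#'   the sd-matching rule above.
#' @return a `descriptor_matrix` with `n_bits + 1` columns and
#'   `has_affinity = TRUE`.
#' @export
augment_with_affinity <- function(descriptors, affinity, scale = NULL) {
  if (isTRUE(attr(descriptors, "has_affinity"))) {
    stop("descriptors already carry an affinity column")
  }
  if (length(affinity) != nrow(descriptors)) {
    stop("need one affinity per descriptor row")
  }
  if (any(!is.finite(affinity))) stop("non-finite affinity value(s)")
  if (is.null(scale)) {
    s <- stats::sd(affinity)
    scale <- if (is.na(s) || s == 0) 1 else 2 * s
  }
  if (scale <= 0) stop("scale must be positive")
  out <- cbind(unclass(descriptors), affinity = affinity / scale)
  descriptor_matrix(out, attr(descriptors, "n_bits"), TRUE)
}

#' Export a descriptor matrix
#'
#' Dense CSV (`format = "dense"`) or sparse coordinate text
#' (`format = "coo"`: header `row,col,value`, 1-based indices, zeros omitted).
#'
#' @param descriptors a `descriptor_matrix`.
#' @param path output file path.
#' @param format `"dense"` or `"coo"`.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path, format = c("dense", "coo")) {
  format <- match.arg(format)
  m <- unclass(descriptors)
  if (format == "dense") {
    utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  } else {
    nz <- which(m != 0, arr.ind = TRUE)
    utils::write.csv(
      data.frame(row = nz[, 1], col = nz[, 2], value = m[nz]),
      path, row.names = FALSE
    )
  }
  invisible(path)
}
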