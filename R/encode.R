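# One-hot encoding of sequence windows with symmetric zero padding of half
# the first-layer filter size on each side. Channel order (A, C, G, U);
# N encodes as the all-zero column.

BASE_CHANNELS <- c(A = 1L, C = 2L, G = 3L, U = 4L)

#' One-hot encode a sequence window
#'
#' Base `i` of the sequence becomes column `pad + i` of a 4-row 0/1 matrix
#' with A=(1,0,0,0), C=(0,1,0,0), G=(0,0,1,0), U=(0,0,0,1) and N the
#' all-zero column; `pad = floor(filter_size_1 / 2)` all-zero columns flank
#' each side, so the first convolution sees symmetric zero padding.
#'
#' @param sequence String over \{A,C,G,U,N\} (run [normalize_rna] inputs
#'   with T/lowercase through [read_fasta()] first).
#' @param filter_size_1 First-layer convolution filter width (default 10).
#' @param window_id Optional provenance id stored on the result.
#' @return An `m6a_encoded` object: `matrix` (4 x (pad + L + pad)), `pad`,
#'   `length` (core L), `origin`.
#' @export
encode_onehot <- function(sequence, filter_size_1 = 10L, window_id = NA_character_) {
  pad <- as.integer(filter_size_1) %/% 2L
  chars <- if (nchar(sequence) > 0L) strsplit(sequence, "")[[1L]] else character(0)
  L <- length(chars)
  idx <- BASE_CHANNELS[chars]
  bad <- which(is.na(idx) & chars != "N")
  if (length(bad) > 0L) {
    stopf("invalid character '%s' at offset %d (alphabet is A,C,G,U,N)",
          chars[bad[1L]], bad[1L] - 1L)
  }
  m <- matrix(0, nrow = 4L, ncol = pad + L + pad)
  keep <- which(!is.na(idx))
  if (length(keep) > 0L) {
    m[cbind(idx[keep], pad + keep)] <- 1
  }
  structure(list(matrix = m, pad = pad, length = L, origin = window_id),
            class = "m6a_encoded")
}

#' Decode a one-hot matrix back to its sequence
#'
#' Inverse of [encode_onehot()] on the core (non-pad) columns; all-zero
#' core columns decode to `N`.
#'
#' @param encoded An `m6a_encoded` object.
#' @return The decoded sequence string.
#' @export
decode_onehot <- function(encoded) {
  stopifnot(inherits(encoded, "m6a_encoded"))
  m <- encoded$matrix
  core <- seq_len(encoded$length) + encoded$pad
  if (encoded$length == 0L) return("")
  sums <- colSums(m[, core, drop = FALSE])
  if (any(sums > 1)) {
    stopf("malformed one-hot column at offset %d: column sum %g > 1",
          which(sums > 1)[1L] - 1L, max(sums))
  }
  bases <- rep("N", encoded$length)
  hit <- which(sums == 1)
  if (length(hit) > 0L) {
    ch <- apply(m[, core[hit], drop = FALSE], 2L, which.max)
    bases[hit] <- names(BASE_CHANNELS)[ch]
  }
  paste(bases, collapse = "")
}

# Stack sequences into one 4 x width x B array for the network. Sequences
# are individually padded symmetrically by `pad`, then right-padded with
# zero columns to the batch max width; true core lengths are recorded and
# the BLSTM masks positions beyond each sequence's valid range.
encode_batch <- function(sequences, filter_size_1, window_ids = NULL) {
  pad <- as.integer(filter_size_1) %/% 2L
  enc <- lapply(sequences, encode_onehot, filter_size_1 = filter_size_1)
  lens <- vapply(enc, `[[`, integer(1), "length")
  width <- max(lens) + 2L * pad
  B <- length(enc)
  X <- array(0, dim = c(4L, width, B))
  for (i in seq_len(B)) {
    w <- ncol(enc[[i]]$matrix)
    X[, seq_len(w), i] <- enc[[i]]$matrix
  }
  list(X = X, core_len = lens, pad = pad,
       window_ids = window_ids %||% names(sequences))
}
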