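# Sequence encoding and signal normalization.

#' One-hot encode a DNA sequence
#'
#' Each base becomes a length-4 indicator row in fixed column order
#' A, C, G, T; any other symbol (N, gaps, IUPAC ambiguity codes) becomes an
#' all-zero row, so it contributes nothing to a convolution.
#'
#' @param seq A non-empty DNA string (case-insensitive).
#' @return An `L x 4` numeric matrix with colnames `c("A","C","G","T")`.
#' @examples
#' one_hot_encode("ACGT") # 4x4 identity
#' @export
one_hot_encode <- function(seq) {
  abort_if(!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L,
           "seq must be a single non-empty string")
  bases <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(bases, c("A", "C", "G", "T"))
  m <- matrix(0, nrow = length(bases), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1
  m
}

#' Decode a one-hot matrix back to a sequence string
#'
#' Inverse of [one_hot_encode()] for A/C/G/T-only input; all-zero rows
#' decode to `"N"`.
#'
#' @param m An `L x 4` one-hot matrix.
#' @return A DNA string of length `L`.
#' @export
one_hot_decode <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 4L)
  out <- rep("N", nrow(m))
  hit <- which(rowSums(m) > 0)
  out[hit] <- c("A", "C", "G", "T")[max.col(m[hit, , drop = FALSE])]
  paste0(out, collapse = "")
}

#' Normalize a raw signal track
#'
#' Applies the variance-damping transform `v -> log10(1 + v)` per base, the
#' normalization used on the -log10 p-value tracks before training. The
#' transform is strictly monotone and maps 0 to 0.
#'
#' @param track A raw [signal_track()] (`normalized = FALSE`).
#' @return The normalized `signal_track`.
#' @export
normalize_signal <- function(track) {
  stopifnot(inherits(track, "signal_track"))
  abort_if(isTRUE(track$normalized), "track is already normalized")
  abort_if(any(track$values < 0), "raw signal values must be >= 0")
  signal_track(track$interval, log10(1 + track$values), normalized = TRUE)
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}
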