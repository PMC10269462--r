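# Internal helpers: seed handling and small validators.

.rhizonet_cache <- new.env(parent = emptyenv())

#' Derive a stream seed from a master seed
#'
#' Deterministically maps a master seed plus a stream label (or index) to a
#' new 32-bit seed, so that every stage of an analysis draws from its own
#' reproducible stream while the user supplies a single integer.
#'
#' @param seed Master seed (single number).
#' @param stream Integer index or character label of the stream.
#' @return A single integer seed in \[0, 2^31).
#' @export
#' @examples
#' split_seed(1, "rarefy")
#' split_seed(1, 3L)
split_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (is.character(stream)) {
    codes <- utf8ToInt(stream)
    stream <- sum(codes * seq_along(codes))
  }
  stopifnot(is.numeric(stream), length(stream) == 1L)
  # affine map mod a prime below 2^31; operands stay < 2^53 so arithmetic is exact
  as.integer((abs(seed) %% 2147483629 * 48271 + abs(stream) * 7919 + 1) %% 2147483629)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assert_count_matrix <- function(x, what = "count table") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (taxa x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must carry taxon rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon ids in ", what, call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids in ", what, call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " contains negative or non-finite values", call. = FALSE)
  invisible(x)
}
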