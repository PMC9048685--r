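#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means "use the ambient RNG stream" (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent substream seeds from one master seed
#'
#' A single user-facing seed fans out to per-stage seeds so that, e.g., the
#' intensity draw and the clinical-covariate draw of a synthetic cohort do not
#' share an RNG stream. The rule is documented and fixed: seed the generator
#' with the master seed and draw `n` integers uniformly below 2^31 - 1.
#'
#' @param seed single integer master seed.
#' @param n number of substream seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(length(n) == 1L, n >= 1L)
  with_seed(seed, sample.int(2147483646L, n, replace = FALSE))
}

# internal: abort with sprintf-style message
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Mann-Whitney AUC of `scores` for binary `labels` (TRUE = positive class).
# Ties handled by midranks; returns NA when one class is absent.
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
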