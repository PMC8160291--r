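# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.  `seed = NULL` leaves the
# global stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# Deterministic derived seeds, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483629)
}

stop_radscore <- function(msg, class) {
  stop(structure(class = c(class, "radscore_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dice similarity between two binary masks of identical shape.
#' Dice overlap between two binary masks
#'
#' @param a,b logical or 0/1 arrays of identical shape.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_dice <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
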