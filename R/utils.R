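#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join row_number n
#' @importFrom purrr map map2 map_dbl map_int map_lgl map_chr pmap
#' @importFrom stats median sd rnorm runif setNames cor quantile
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible child seed below 2^31 from a parent seed and a tag.
derive_seed <- function(seed, tag) {
  (as.numeric(seed) * 48271 + string_hash(as.character(tag))) %% 2147483563 + 1
}

# Deterministic polynomial rolling hash of a string into [0, 2^31 - 2].
# Used for fingerprint bit assignment and synthetic molecule keys; doubles
# hold exact integers below 2^53 so the modular arithmetic is exact.
string_hash <- function(x) {
  vapply(x, function(s) {
    h <- 7
    for (ci in utf8ToInt(s)) h <- (h * 131 + ci) %% 2147483629
    h
  }, numeric(1), USE.NAMES = FALSE)
}

# ---- parameter-tree helpers (nested lists of numeric arrays) ----------------

param_map <- function(x, f) {
  if (is.list(x)) lapply(x, param_map, f = f) else f(x)
}

param_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- param_map2(x[[i]], y[[i]], f)
    out
  } else {
    f(x, y)
  }
}

param_zeros_like <- function(x) param_map(x, function(a) a * 0)

param_count <- function(x) {
  if (is.list(x)) sum(vapply(x, param_count, numeric(1))) else length(x)
}

param_add <- function(x, y) param_map2(x, y, `+`)

param_scale <- function(x, s) param_map(x, function(a) a * s)

stop_if_not <- function(cond, msg, class = "ms2embed_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
}
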