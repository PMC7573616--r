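#' @importFrom rlang abort warn inform .data :=
#' @importFrom stats pt qt rnorm runif rexp rpois rgeom sd var
#' @importFrom tibble tibble as_tibble
NULL

# Deterministic 31-bit seed derived from a master seed plus string keys.
# Each (subject, session, purpose) combination gets its own stream so adding
# subjects or sessions never perturbs streams already generated.
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "\r")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normal samples truncated to the open interval (lower, upper) by rejection.
rtnorm <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

check_number <- function(x, name, min = NULL, max = NULL, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name),
          class = "lickometry_config_error")
  if (!is.null(min) && (if (strict) x <= min else x < min))
    abort(sprintf("`%s` must be %s %s", name, if (strict) ">" else ">=", min),
          class = "lickometry_config_error")
  if (!is.null(max) && (if (strict) x >= max else x > max))
    abort(sprintf("`%s` must be %s %s", name, if (strict) "<" else "<=", max),
          class = "lickometry_config_error")
  invisible(x)
}

format_p <- function(p, digits = 3) {
  ifelse(p < 10^(-digits),
         paste0("<", format(10^(-digits), scientific = FALSE)),
         formatC(round(p, digits), format = "f", digits = digits))
}
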