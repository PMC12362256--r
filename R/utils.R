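#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom stats dist lm glm binomial residuals coefficients rexp rgamma
#'   rmultinom rpois runif rnorm rbinom median quantile setNames var
#' @importFrom utils head
NULL

# Derive a reproducible substream seed from a master seed and a string label.
# Polynomial byte hash mixed with the master seed; kept inside the 32-bit
# signed range so set.seed() accepts it. Independent of evaluation order.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  mod <- 2147483647
  h <- 0
  for (b in as.integer(charToRaw(as.character(label)))) {
    h <- (h * 131 + b) %% mod
  }
  as.integer((h + (as.numeric(master) %% mod) * 48271) %% mod)
}

# Run code with a temporary RNG state seeded from `seed`; restores the
# caller's RNG stream afterwards so library internals never perturb user code.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
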