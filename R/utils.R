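#' @importFrom stats sd cor rnorm runif rbinom rlnorm fft mvfft kmeans
#'   quantile median setNames wilcox.test p.adjust
#' @importFrom utils head tail write.csv read.csv modifyList
#' @importFrom rlang abort warn .data
#' @importFrom Rcpp evalCpp
#' @useDynLib erpgraph, .registration = TRUE
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "erpgraph_invalid_argument")
}

stop_state <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "erpgraph_invalid_state")
}

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  lo_ok <- if (closed_lower) x >= lower else x > lower
  hi_ok <- if (closed_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("`%s` = %g is outside its allowed range", name, x)
  }
  invisible(x)
}

#' Derive a stage-specific seed from a global seed
#'
#' Stages of the pipeline draw from independent streams derived from one
#' global seed, so toggling stages on or off never shifts the randomness of
#' the stages that remain. The derivation is a small stable string hash
#' (polynomial rolling hash over the stage name, folded into 31 bits).
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  check_scalar_num(seed, "seed")
  h <- as.double(seed %% 2147483647)
  for (cp in utf8ToInt(stage)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
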