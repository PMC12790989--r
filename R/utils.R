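#' caretile: tiling CRISPRa screens and targeted single-cell perturbation maps
#'
#' Analysis pipeline for CRISPRa-responsive element (CaRE) calling from dense
#' tiling activation screens, element-to-gene link identification from
#' targeted single-cell perturbation data, chromatin-feature modelling and
#' multimodal evidence integration, plus a synthetic-data module with planted
#' ground truth.
#'
#' @importFrom stats pnorm pchisq dnorm optimize rnbinom rpois rnorm runif
#'   rlnorm rbinom sd var quantile median coef lm glm glm.fit binomial
#'   ksmooth setNames plogis qlogis .lm.fit
#' @importFrom utils head tail
#' @keywords internal
"_PACKAGE"

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment with a stable tie-break: input order among equal
#' p-values is resolved by `ids` (then by position) so that downstream rank
#' bookkeeping is reproducible. Adjusted values are identical to the textbook
#' procedure.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed, passed through).
#' @param ids optional vector used to break ties deterministically.
#' @return numeric vector of BH-adjusted p-values, same length/order as `p`.
#' @export
bh_adjust <- function(p, ids = NULL) {
  stopifnot(is.numeric(p))
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  n <- length(pv)
  if (n == 0L) return(out)
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  idv <- if (is.null(ids)) seq_along(p)[ok] else ids[ok]
  o <- order(pv, idv)
  adj <- rev(cummin(rev(pv[o] * n / seq_len(n))))
  adj <- pmin(adj, 1)
  res <- numeric(n)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Derive a named substream seed from a master seed
#'
#' All simulator randomness flows from one master seed through named
#' substreams so individual tables can be regenerated independently.
#'
#' @param seed master integer seed.
#' @param name substream name (character scalar).
#' @return an integer seed in \[0, 2^31).
#' @export
sub_seed <- function(seed, name) {
  stopifnot(length(name) == 1L, is.character(name))
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u)) %% 65521
  as.integer((as.numeric(seed) %% 65521) * 32551 + h * 977 + 13) %% 2147483647L
}

# internal: stop unless condition, with sprintf-style message
.need <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# internal: coerce possibly-sparse matrix to base dense matrix
.densify <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}
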