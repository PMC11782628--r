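#' @keywords internal
"_PACKAGE"

# Cap used wherever a zero-variance denominator would make a t statistic
# infinite; documented convention, large enough that any p-value underflows.
T_CAP <- 1e6

#' Map t statistics to z scores preserving two-sided tail probability
#'
#' Uses log-scale tail probabilities so that very large statistics survive the
#' mapping without underflow. Non-finite t (zero residual variance) is capped.
#'
#' @param t numeric vector of t statistics.
#' @param df residual degrees of freedom.
#' @return numeric vector of z scores with the same signs as `t`.
#' @export
t_to_z <- function(t, df) {
  t <- ifelse(is.finite(t), t, sign(t) * T_CAP)
  logp <- stats::pt(abs(t), df = df, lower.tail = FALSE, log.p = TRUE)
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z <- pmin(z, T_CAP)
  sign(t) * z
}

#' Derive a stage seed from a master seed
#'
#' Deterministic hash of `(master_seed, stage)` kept below 2^31 so it is a
#' valid R integer seed. Distinct stage names give distinct streams.
#'
#' @param master_seed integer master seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- as.numeric(master_seed) %% 2147483629
  for (code in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + code) %% 2147483629
  }
  as.integer(h + 1)
}

# One-sample t with capped statistic on zero variance (all-equal input).
capped_t_test <- function(x, mu = 0) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations for a t-test", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    est <- mean(x)
    tstat <- if (est == mu) 0 else sign(est - mu) * T_CAP
    return(list(estimate = est, t = tstat,
                p = if (tstat == 0) 1 else 0, df = n - 1,
                ci = c(est, est)))
  }
  ht <- stats::t.test(x, mu = mu)
  list(estimate = unname(ht$estimate), t = unname(ht$statistic),
       p = ht$p.value, df = unname(ht$parameter), ci = unname(ht$conf.int))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
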