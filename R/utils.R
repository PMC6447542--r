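# Small shared helpers. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (values here are nonnegative). A tiny epsilon
# guards against binary-representation artefacts like 5.165 -> 5.16499999.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

fmt_fixed <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# Rank (Wilcoxon) AUC of a continuous score for a binary label; midranks
# handle ties, so scores with few distinct values are fine.
auc_rank <- function(score, label) {
  label <- as.logical(label)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) stop("auc_rank: both classes must be present")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}

# Largest-remainder apportionment of n units to fractions summing to 1.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    top <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[top] <- base[top] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
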