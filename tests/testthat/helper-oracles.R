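# Independent oracles and fixture builders shared across test files.

# Exhaustive pairwise AUC: P(positive more extreme than negative), ties 0.5.
auc_pair_oracle <- function(scores, truth, fail_direction = "at_or_above") {
  x <- if (fail_direction == "at_or_above") scores else -scores
  pos <- x[truth]; neg <- x[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Trapezoidal area under the empirical ROC from a full threshold sweep.
auc_trapezoid_oracle <- function(scores, truth, fail_direction = "at_or_above") {
  x <- if (fail_direction == "at_or_above") scores else -scores
  th <- c(-Inf, sort(unique(x)), Inf)
  sens <- vapply(th, function(t) mean(x[truth] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(x[!truth] >= t), numeric(1))
  o <- order(fpr, sens)
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
}

# A random valid component spec on an integer-ish grid.
random_spec <- function(name = "X") {
  direction <- sample(c("low_fails", "high_fails"), 1)
  vals <- sort(sample(2:18, 3))
  cuts <- if (direction == "low_fails") rev(vals) else vals
  component_spec(name, direction, cuts, c(0, 20), granularity = 1)
}

toy_cohort <- function() {
  data.frame(CD = c(10, 6, 4), RCFT_Copy = c(32, 29, 24.5),
             FMS_WCST = c(0, 3, 5), RDS = c(10, 8, 7),
             RH_CVLT = c(15, 13, 13))
}
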