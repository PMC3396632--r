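# Independent oracles, coded from the textbook definitions and kept separate
# from the package implementation.

# Classic DerSimonian-Laird pool of logit observations (intercept only).
dl_pool_oracle <- function(y, v) {
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  q <- sum(w * (y - ybar)^2)
  k <- length(y)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  list(mu = mu, se = sqrt(1 / sum(ws)), tau2 = tau2)
}

# Observations (y, v, high_trauma) derived from a generated study table.
observations_from_table <- function(tab) {
  ratio <- pte_adversity_ratio(tab$pte_endorsed, tab$pte_assessed)
  cbind(logit_with_variance(tab$cases, tab$n),
        high_trauma = as.numeric(stratify_exposure(tab$pts, ratio)$trauma == "high"))
}
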