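# Shared builders for tiny in-code fixtures.

# 1-feature dataset from explicit class vectors
tiny_dataset <- function(x1, x2, id = "f1") {
  expression_dataset(
    matrix(c(x1, x2), nrow = 1, dimnames = list(id, NULL)),
    rep(1:2, c(length(x1), length(x2)))
  )
}

# small random two-class dataset (homoscedastic, no DE)
random_dataset <- function(n_features, n1 = 5, n2 = 5, mu = 8, sd = 0.6) {
  m <- matrix(rnorm(n_features * (n1 + n2), mean = mu, sd = sd),
              nrow = n_features)
  expression_dataset(m, rep(1:2, c(n1, n2)))
}

# pure-null simulation config at the default stated world
null_config <- function(seed, n_features = 5000L, profile = variance_profile("flat")) {
  simulation_config(n_features = n_features, n1 = 10L, n2 = 10L, pi = 0,
                    profile = profile, seed = seed)
}

# closed-form E[LV | d = 0] for a flat profile: at d_hat = 0 the total
# sum of squares is the within sum of squares, v * chi^2_{n-2}, so
# E[log2 vT | d=0] = log2 v + (digamma((n-2)/2) + log 2 - log(n-1)) / log 2
expected_lv_at_d0 <- function(v, n) {
  log2(v) + (digamma((n - 2) / 2) + log(2) - log(n - 1)) / log(2)
}

# brute-force pairwise AUC oracle: P(pos > neg) + 0.5 P(tie)
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth]; neg <- scores[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
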