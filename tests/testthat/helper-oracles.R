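# Independent oracles used across tests.

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (no-tie data); doubled smaller tail, capped at 1, matching the classical
# exact two-sided convention
perm_mw_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  u_stat <- function(idx) {
    a <- all_v[idx]; b <- all_v[-idx]
    sum(outer(a, b, ">"))
  }
  u_obs <- u_stat(seq_len(n1))
  us <- apply(utils::combn(length(all_v), n1), 2, u_stat)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# the 8 features with planted group differences under the default generator
sig8_features <- function() names(default_feature_effects())

# standard planted-scenario table: 3 informative features (one per
# phenotype) at standardized shift d among 8 candidates
planted_table <- function(seed, d = 1.5, n_robust = 42, n_frail = 60) {
  planted <- c("mean_hip_angular_velocity_range", "mean_vertical_power_range",
               "cv_vertical_power_range")
  eff <- stats::setNames(c(-d, -d, d), planted)
  tbl <- simulate_feature_table(n_robust, n_frail, seed = seed, effects = eff,
                                features = sig8_features())
  attr(tbl, "planted") <- planted
  tbl
}

null_table <- function(seed, features = sts_feature_names(),
                       n_robust = 42, n_frail = 60) {
  simulate_feature_table(n_robust, n_frail, seed = seed,
                         effects = stats::setNames(numeric(0), character(0)),
                         features = features)
}
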